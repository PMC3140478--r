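test_that("equal indices at long effort give zero differentiation", {
  # every dyad together every period: var = 0, sampling term 0
  n <- 6
  dy <- t(combn(n, 2))
  occ <- occ_from_lists(n, 50, rep(list(dy), 50))
  expect_equal(social_differentiation(occ), 0)
})

test_that("the sampling-variance correction pulls S below the naive CV", {
  # all dyads share alpha = 0.3 but d is small: the naive CV of
  # alpha-hat is inflated by binomial noise; the corrected estimate
  # must fall below it and lie near zero
  set.seed(41)
  n <- 12
  np <- 8
  naive <- corrected <- numeric(20)
  for (r in 1:20) {
    dy <- t(combn(n, 2))
    periods <- lapply(seq_len(np), function(t) {
      dy[runif(nrow(dy)) < 0.3, , drop = FALSE]
    })
    occ <- occ_from_lists(n, np, periods)
    a <- occ$x[upper.tri(occ$x)] / occ$d[upper.tri(occ$d)]
    naive[r] <- sd(a) / mean(a)
    corrected[r] <- social_differentiation(occ)
  }
  expect_true(all(corrected < naive))
  expect_lt(mean(corrected), 0.15)
  expect_gt(mean(naive), 0.3)
})

test_that("parameter recovery at moderate effort", {
  # planted S = 0.8 recovered within tolerance when averaged over seeds
  errs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 15, n_periods = 40,
                      true_assoc_mean = 0.2, true_assoc_cv = 0.8,
                      presence_prob = 0.9, seed = 500 + s)
    sim <- simulate_association_data(cfg)
    social_differentiation(sim$occurrence) - 0.8
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.15)
})

test_that("degenerate occurrences are rejected", {
  occ_none <- occ_from_lists(5, 4, rep(list(NULL), 4))
  expect_error(social_differentiation(occ_none), "no associations")
  pres1 <- matrix(1L, 2, 3, dimnames = list(c("a", "b"), NULL))
  occ1 <- dyadic_occurrence(pres1, rep(list(matrix(c(1L, 2L), 1, 2)), 3))
  expect_error(social_differentiation(occ1), "2 dyads")
})

test_that("classification follows the rule-of-thumb bands", {
  expect_equal(classify_differentiation(0.25), "homogeneous")
  expect_equal(classify_differentiation(0.37), "intermediate")
  expect_equal(classify_differentiation(0.5260), "well_differentiated")
  expect_equal(classify_differentiation(2.5), "extreme")
  expect_equal(classify_differentiation(c(0, 0.5, 2.0)),
               c("homogeneous", "well_differentiated", "well_differentiated"))
})

test_that("bootstrap SE is zero for a constant statistic and seeded", {
  occ <- occ_from_lists(5, 6, rep(list(matrix(c(1L, 2L), 1, 2)), 6))
  se0 <- bootstrap_se(occ, function(o) 7, n_boot = 50, seed = 1)
  expect_equal(as.numeric(se0), 0)
  s1 <- bootstrap_se(occ, social_differentiation, n_boot = 100, seed = 9)
  s2 <- bootstrap_se(occ, social_differentiation, n_boot = 100, seed = 9)
  expect_identical(s1, s2)
})

test_that("bootstrap SE of a per-period mean matches the closed form", {
  # statistic: mean over periods of the number of associating dyads;
  # under column resampling its SE is sd(counts)/sqrt(np) x sqrt((np-1)/np)
  set.seed(17)
  n <- 8
  np <- 40
  dy <- t(combn(n, 2))
  periods <- lapply(seq_len(np), function(t) {
    dy[runif(nrow(dy)) < 0.25, , drop = FALSE]
  })
  occ <- occ_from_lists(n, np, periods)
  counts <- vapply(occ$pairs, nrow, integer(1))
  stat <- function(o) mean(vapply(o$pairs, nrow, integer(1)))
  se <- bootstrap_se(occ, stat, n_boot = 4000, seed = 2)
  closed <- sd(counts) / sqrt(np) * sqrt((np - 1) / np)
  expect_lt(abs(as.numeric(se) - closed) / closed, 0.05)
})

test_that("bootstrap errors when most replicates are undefined", {
  occ <- occ_from_lists(4, 2, list(matrix(c(1L, 2L), 1, 2), NULL))
  flaky <- function(o) {
    if (sum(o$x) == 0) stop("undefined") else 1
  }
  # with 2 periods, ~25% of resamples draw the empty period twice; make
  # the statistic fail unless both periods carry events
  always_bad <- function(o) stop("no")
  expect_error(bootstrap_se(occ, always_bad, n_boot = 40, seed = 3),
               "more data")
})
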
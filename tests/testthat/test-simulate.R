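test_that("infeasible association CV is rejected with the Beta bound", {
  expect_error(sim_config(true_assoc_mean = 0.5, true_assoc_cv = 1.5),
               "sqrt\\(\\(1-mu\\)/mu\\)")
  expect_error(sim_config(true_assoc_mean = 0.5, true_assoc_cv = 1.5), "1")
  # the bound itself: mu = 0.2 allows CV up to 2
  expect_silent(sim_config(true_assoc_mean = 0.2, true_assoc_cv = 1.9))
})

test_that("zero differentiation makes every dyad share the mean exactly", {
  cfg <- sim_config(n_individuals = 6, n_periods = 5, true_assoc_cv = 0,
                    true_assoc_mean = 0.3, seed = 2)
  sim <- simulate_association_data(cfg)
  off <- sim$alpha[upper.tri(sim$alpha)]
  expect_true(all(off == 0.3))
})

test_that("generators are pure functions of (cfg, seed)", {
  cfg <- sim_config(n_individuals = 8, n_periods = 10, seed = 99,
                    rank_assortment = 3)
  a1 <- simulate_association_data(cfg)
  a2 <- simulate_association_data(cfg)
  expect_identical(a1, a2)
  e1 <- simulate_cooperation_events(cfg)
  e2 <- simulate_cooperation_events(cfg)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  w1 <- simulate_agonistic_matrix(cfg)
  expect_identical(w1, simulate_agonistic_matrix(cfg))
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(as.data.frame(b1$events), as.data.frame(b2$events))
})

test_that("occurrence draws respect presence and recover the planted CV", {
  cfg <- sim_config(n_individuals = 12, n_periods = 200,
                    true_assoc_mean = 0.3, true_assoc_cv = 0.8,
                    presence_prob = 0.85, seed = 7)
  sim <- simulate_association_data(cfg)
  occ <- sim$occurrence
  # x never exceeds joint presence
  expect_true(all(occ$x <= occ$d))
  # realised alpha-hat CV approaches the planted CV at long effort
  a <- occ$x[upper.tri(occ$x)] / occ$d[upper.tri(occ$d)]
  true_a <- sim$alpha[upper.tri(sim$alpha)]
  expect_equal(stats::cor(a, true_a) > 0.9, TRUE)
  expect_lt(abs(stats::sd(true_a) / mean(true_a) - 0.8), 0.25)
})

test_that("uniform partner choice gives each large member an equal share", {
  cfg <- sim_config(n_individuals = 8, n_periods = 150,
                    events_per_period = 20, rank_assortment = 0,
                    presence_prob = 1, seed = 21)
  log <- simulate_cooperation_events(cfg)
  roster <- attr(log, "roster")
  large <- roster$id[roster$coop_class == "large"]
  share <- table(factor(log$recipient, large)) / nrow(log)
  expect_true(all(abs(share - 1 / length(large)) < 0.02))
})

test_that("strong rank assortment makes the rank-nearest partner modal", {
  cfg <- sim_config(n_individuals = 10, n_periods = 100,
                    events_per_period = 20, rank_assortment = 20,
                    presence_prob = 1, seed = 22)
  log <- simulate_cooperation_events(cfg)
  roster <- attr(log, "roster")
  r <- cfg$rank_scores
  names(r) <- roster$id
  large <- roster$id[roster$coop_class == "large"]
  for (s in roster$id[roster$coop_class == "small"]) {
    partners <- log$recipient[log$actor == s]
    modal <- names(which.max(table(partners)))
    nearest <- large[which.min(abs(r[large] - r[s]))]
    expect_identical(modal, nearest)
  }
})

test_that("cooperation events always pair the two classes", {
  cfg <- sim_config(n_individuals = 9, n_periods = 30, rank_assortment = 2,
                    seed = 5)
  log <- simulate_cooperation_events(cfg)
  roster <- attr(log, "roster")
  cls <- stats::setNames(roster$coop_class, roster$id)
  expect_true(all(cls[log$actor] == "small"))
  expect_true(all(cls[log$recipient] == "large"))
})

test_that("agonistic outcomes follow the logistic rank model at its limits", {
  cfg0 <- sim_config(n_individuals = 4, rank_scores = rep(0, 4),
                     encounters_per_dyad = 4000, seed = 3)
  w <- simulate_agonistic_matrix(cfg0)
  frac <- w[upper.tri(w)] / 4000
  expect_true(all(abs(frac - 0.5) < 0.03))
  cfg1 <- sim_config(n_individuals = 3, rank_scores = c(60, 0, -60),
                     encounters_per_dyad = 50, seed = 4)
  w1 <- simulate_agonistic_matrix(cfg1)
  expect_true(all(w1[upper.tri(w1)] == 50))
  expect_true(all(t(w1)[upper.tri(w1)] == 0))
})

test_that("pedigree relatedness decays by halving and stays within matrilines", {
  cfg <- sim_config(n_individuals = 12, n_matrilines = 2, seed = 8)
  roster <- simulate_roster(cfg)
  rel <- simulate_relatedness(cfg, roster)
  v <- rel$values[upper.tri(rel$values)]
  expect_true(all(v %in% c(0, 0.5^(1:11))))
  cross <- outer(roster$matriline, roster$matriline, "!=")
  expect_true(all(rel$values[cross] == 0))
  # siblings share a mother, hence relatedness 0.25
  sibs <- sibling_sets(roster)
  for (id in names(sibs)) {
    for (s in sibs[[id]]) expect_equal(rel$values[id, s], 0.25)
  }
})

test_that("a study bundle is complete and loadable from disk", {
  cfg <- sim_config(n_individuals = 8, n_periods = 12, rank_assortment = 5,
                    seed = 31)
  dir <- tempfile()
  write_study(simulate_study(cfg), dir)
  expect_true(all(file.exists(file.path(dir,
    c("roster.csv", "events.csv", "relatedness.csv", "wins.csv",
      "presence.csv", "truth.json")))))
  roster <- read_roster(file.path(dir, "roster.csv"))
  log <- read_event_log(file.path(dir, "events.csv"), roster = roster)
  expect_gt(nrow(log), 0)
  # presence is recoverable from the emitted solo scans
  pres <- presence_from_log(log, roster)
  stored <- as.matrix(utils::read.csv(file.path(dir, "presence.csv"),
                                      check.names = FALSE)[, -1])
  expect_equal(unname(pres), unname(stored))
})
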
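sym_mat <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  m
}

test_that("a matrix correlates perfectly with itself at the p floor", {
  # n = 10 so a sampled permutation is essentially never the identity
  # and no permuted cross-product can reach the observed one
  A <- sym_mat(10, 1)
  res <- mantel_test(A, A, n_perm = 499, seed = 2)
  expect_equal(res$mcc, 1.0)
  expect_equal(res$p, 1 / 500)
})

test_that("sampled p matches exhaustive enumeration on 5x5 matrices", {
  for (s in 1:5) {
    A <- sym_mat(5, 100 + s)
    B <- sym_mat(5, 200 + s)
    exact <- oracle_mantel_exact(A, B)
    res <- mantel_test(A, B, n_perm = 4000, seed = s)
    expect_lt(abs(res$p - exact), 0.02)
  }
})

test_that("with an all-ones mask the test agrees with vegan's Mantel", {
  skip_if_not_installed("vegan")
  A <- sym_mat(12, 5)
  B <- 0.5 * A + sym_mat(12, 6)   # correlated pair
  res <- mantel_test(A, B, n_perm = 2000, seed = 3)
  veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 2000)
  expect_equal(res$mcc, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(res$p - veg$signif), 0.03)
})

test_that("masking restricts the statistic to between-class dyads", {
  roster <- tiny_roster(7, n_small = 2)
  mask <- between_class_mask(roster)
  A <- sym_mat(7, 9)
  B <- sym_mat(7, 10)
  dimnames(A) <- dimnames(B) <- dimnames(mask$values)
  res <- mantel_test(A, B, mask = mask$values, n_perm = 99, seed = 1)
  expect_equal(res$n_dyads, 10)
  sel <- upper.tri(A) & mask$values == 1
  expect_equal(res$mcc, cor(A[sel], B[sel]))
  expect_equal(res$z, sum(A[sel] * B[sel]))
})

test_that("class-constrained permutations leave the mask invariant and mix", {
  roster <- tiny_roster(8, n_small = 2)
  classes <- stats::setNames(roster$coop_class, roster$id)
  # under within-class permutation the class vector is preserved
  set.seed(4)
  for (k in 1:20) {
    pi_k <- vnet:::class_permutation(8, unname(classes))
    expect_equal(unname(classes)[pi_k], unname(classes))
  }
  # permutations actually move large-class labels
  draws <- replicate(50, vnet:::class_permutation(8, unname(classes))[3])
  expect_gt(length(unique(draws)), 1)
})

test_that("degenerate attribute matrices are rejected", {
  A <- sym_mat(5, 11)
  B <- matrix(1, 5, 5)
  diag(B) <- 0
  expect_error(mantel_test(A, B), "degenerate")
})

test_that("one-tailed p near 1 flags opposite-direction effects", {
  # B strongly anticorrelated with A: upper-tail p should be ~1,
  # lower-tail p small
  A <- sym_mat(7, 12)
  B <- -A
  up <- mantel_test(A, B, n_perm = 500, seed = 5, tail = "greater")
  lo <- mantel_test(A, B, n_perm = 500, seed = 5, tail = "less")
  expect_gt(up$p, 0.95)
  expect_equal(lo$p, 1 / 501)
  expect_equal(up$mcc, -1)
})

test_that("partial test with B as its own control is degenerate", {
  A <- sym_mat(6, 13)
  B <- sym_mat(6, 14)
  expect_error(partial_mantel_test(A, B, controls = list(self = B)),
               "collinear")
})

test_that("an irrelevant control leaves p and MCC nearly unchanged", {
  set.seed(15)
  A <- sym_mat(12, 16)
  B <- 0.6 * A + sym_mat(12, 17)
  C <- sym_mat(12, 18)      # independent of both
  raw <- mantel_test(A, B, n_perm = 3000, seed = 6)
  prt <- partial_mantel_test(A, B, controls = list(noise = C),
                             n_perm = 3000, seed = 6)
  expect_lt(abs(raw$mcc - prt$mcc), 0.1)
  expect_lt(abs(raw$p - prt$p), 0.05)
  expect_identical(prt$partial_controls, "noise")
})

test_that("a kin effect mediated by matriline vanishes under control", {
  # A depends on B only through the matriline indicator M; partialling
  # M out should kill the association while the raw test finds it
  set.seed(19)
  n <- 14
  raw_p <- prt_p <- numeric(5)
  for (r in 1:5) {
    mat <- sample(rep(c("x", "y", "z"), length.out = n))
    M <- outer(mat, mat, "==") * 1
    diag(M) <- 0
    ids <- sprintf("V%02d", 1:n)
    dimnames(M) <- list(ids, ids)
    B <- M * 0.4 + sym_mat(n, 20 + 10 * r) * 0.05  # relatedness-like
    A <- M * 2 + sym_mat(n, 21 + 10 * r) * 0.3     # driven by matriline only
    raw_p[r] <- mantel_test(A, B, n_perm = 1000, seed = 7)$p
    prt_p[r] <- partial_mantel_test(A, B, controls = list(matriline = M),
                                    n_perm = 1000, seed = 7)$p
  }
  expect_true(all(raw_p <= 0.01))
  expect_gt(mean(prt_p), 0.15)      # toward uniform once mediated
  expect_gt(min(prt_p / raw_p), 10)
})

test_that("mantel results are reproducible under a fixed seed", {
  A <- sym_mat(9, 30)
  B <- sym_mat(9, 31)
  r1 <- mantel_test(A, B, n_perm = 500, seed = 42)
  r2 <- mantel_test(A, B, n_perm = 500, seed = 42)
  expect_identical(r1, r2)
})
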
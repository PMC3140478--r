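block_rate_matrix <- function() {
  # two well-separated blocks: high rates within {1..4} and {5..8}
  n <- 8
  m <- matrix(0.2, n, n)
  m[1:4, 1:4] <- 5
  m[5:8, 5:8] <- 5
  diag(m) <- 0
  dimnames(m) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  m
}

test_that("well-separated blocks merge within blocks before across", {
  dend <- ward_dendrogram(block_rate_matrix())
  sets <- merge_member_sets(dend$merge)
  # all but the final merge stay inside one block
  for (k in seq_len(length(sets) - 1)) {
    s <- sets[[k]]
    expect_true(all(s <= 4) || all(s >= 5))
  }
  expect_equal(sets[[length(sets)]], 1:8)
  # heights are the Ward SS increments and never decrease
  expect_true(all(diff(dend$height) >= -1e-12))
})

test_that("duplicate individuals merge first at zero cost", {
  m <- block_rate_matrix()
  m[2, ] <- m[1, ]
  m[, 2] <- m[, 1]
  m[1, 2] <- m[2, 1] <- 0  # identical profile rows
  diag(m) <- 0
  dend <- ward_dendrogram(m)
  expect_equal(sort(merge_member_sets(dend$merge)[[1]]), c(1, 2))
  expect_equal(dend$height[1], 0, tolerance = 1e-12)
})

test_that("merge sequence and heights match the exhaustive Ward oracle", {
  set.seed(71)
  for (r in 1:6) {
    n <- sample(5:7, 1)
    m <- random_weight_matrix(n)
    dend <- ward_dendrogram(m)
    # the oracle agglomerates the same row-profile representation
    X <- m
    X[is.na(X)] <- 0
    diag(X) <- 0
    oracle <- oracle_ward(X)
    expect_equal(merge_member_sets(dend$merge), oracle$members)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-9)
  }
})

test_that("cophenetic coefficient equals the double-loop oracle", {
  set.seed(72)
  for (r in 1:5) {
    m <- random_weight_matrix(6)
    dend <- ward_dendrogram(m)
    cmat <- oracle_cophenetic(dend$merge, dend$height, 6)
    d <- as.matrix(dend$dist)
    ut <- upper.tri(d)
    expect_equal(cophenetic_coefficient(dend),
                 cor(cmat[ut], d[ut]), tolerance = 1e-9)
  }
})

test_that("an ultrametric-preserving tree scores a perfect fit", {
  # build an ultrametric distance, cluster it with a linkage that
  # reconstructs ultrametrics exactly, and check the coefficient is 1
  d <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(cophenetic_coefficient(hc, d), 1.0, tolerance = 1e-9)
  expect_equal(cophenetic_fit(0.8), "good")
  expect_equal(cophenetic_fit(0.79), "poor")
})

test_that("newick export round-trips the leaf set", {
  dend <- ward_dendrogram(block_rate_matrix())
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, sprintf("V%02d", 1:8))
})

test_that("two disconnected equal cliques give Q = 0.5 exactly", {
  n <- 8
  A <- matrix(0, n, n)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  dimnames(A) <- list(sprintf("V%02d", 1:n), sprintf("V%02d", 1:n))
  comm <- newman_communities(A)
  expect_equal(comm$q, 0.5, tolerance = 1e-12)
  expect_equal(unname(comm$membership), rep(1:2, each = 4))
})

test_that("a uniform complete graph stays one community", {
  A <- matrix(1, 6, 6)
  diag(A) <- 0
  comm <- newman_communities(A)
  expect_equal(comm$n_communities, 1)
  expect_equal(comm$q, 0, tolerance = 1e-12)
})

test_that("partitions reach the exhaustive optimum at small n", {
  set.seed(73)
  for (r in 1:8) {
    A <- random_weight_matrix(6)
    if (sum(A) == 0) next
    comm <- newman_communities(A)
    best <- oracle_best_partition_q(A)
    expect_equal(comm$q, best, tolerance = 1e-9)
    # and the package Q agrees with the oracle Q formula
    expect_equal(comm$q, oracle_q(A, unname(comm$membership)),
                 tolerance = 1e-12)
  }
})

test_that("partitions dominate every bipartition up to n = 8", {
  set.seed(74)
  for (r in 1:5) {
    A <- random_weight_matrix(8)
    if (sum(A) == 0) next
    comm <- newman_communities(A)
    expect_gte(comm$q, oracle_best_bipartition_q(A) - 1e-9)
  }
})

test_that("communities are invariant to relabelling and weight scaling", {
  set.seed(75)
  A <- random_weight_matrix(7)
  c0 <- newman_communities(A)
  expect_equal(newman_communities(A * 13.7)$membership, c0$membership)
  expect_equal(newman_communities(A * 13.7)$q, c0$q, tolerance = 1e-12)
  perm <- sample(7)
  Ap <- A[perm, perm]
  cp <- newman_communities(Ap)
  # same partition structure after mapping back
  back <- cp$membership[rownames(A)]
  expect_equal(length(unique(paste(back, c0$membership))),
               length(unique(back)))
  expect_equal(cp$q, c0$q, tolerance = 1e-12)
})

test_that("package Q never falls below igraph's leading-eigenvector Q", {
  set.seed(76)
  for (r in 1:5) {
    A <- random_weight_matrix(9)
    if (sum(A) == 0) next
    comm <- newman_communities(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    ig <- tryCatch(igraph::cluster_leading_eigen(g),
                   error = function(e) NULL)
    if (is.null(ig)) next
    expect_gte(comm$q + 1e-9, igraph::modularity(g, igraph::membership(ig),
                                                 weights = igraph::E(g)$weight))
  }
})

test_that("degenerate networks are rejected", {
  expect_error(newman_communities(matrix(0, 4, 4)), "empty network")
  expect_error(ward_dendrogram(matrix(0, 1, 1)), "at least 2")
})
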
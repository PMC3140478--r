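# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# --- David's Score: direct double-loop over the four sums -------------------
oracle_davids_score <- function(wins) {
  n <- nrow(wins)
  nij <- wins + t(wins)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && nij[i, j] > 0) P[i, j] <- wins[i, j] / nij[i, j]
  }
  ds <- numeric(n)
  for (i in seq_len(n)) {
    w <- 0; w2 <- 0; l <- 0; l2 <- 0
    for (j in seq_len(n)) {
      w <- w + P[i, j]
      l <- l + P[j, i]
      w2 <- w2 + P[i, j] * sum(P[j, ])
      l2 <- l2 + P[j, i] * sum(P[, j])
    }
    ds[i] <- w + w2 - l - l2
  }
  ds
}

# --- Ward agglomeration: evaluate every candidate merge per step ------------
oracle_ward <- function(X) {
  wss <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) if (a < b) {
      inc <- wss(c(clusters[[a]], clusters[[b]])) -
        wss(clusters[[a]]) - wss(clusters[[b]])
      if (inc < best_inc - 1e-12) {
        best_inc <- inc
        best <- c(a, b)
      }
    }
    merges[[length(merges) + 1]] <- sort(unlist(clusters[best]))
    heights <- c(heights, best_inc)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(members = merges, heights = heights)
}

# member sets of each merge of an hclust-style tree, sorted
merge_member_sets <- function(merge) {
  n <- nrow(merge) + 1
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(grab(merge[k, 1]), grab(merge[k, 2])))
  }
  sets
}

# --- cophenetic distances: double loop over pairs via merge sets ------------
oracle_cophenetic <- function(merge, heights, n) {
  sets <- merge_member_sets(merge)
  cmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (k in seq_along(sets)) {
      if (i %in% sets[[k]] && j %in% sets[[k]]) {
        cmat[i, j] <- cmat[j, i] <- heights[k]
        break
      }
    }
  }
  cmat
}

# --- exact Mantel p by enumerating all label permutations -------------------
oracle_mantel_exact <- function(A, B, mask = NULL) {
  n <- nrow(A)
  if (is.null(mask)) {
    mask <- matrix(1, n, n)
    diag(mask) <- 0
  }
  sel <- upper.tri(A) & mask == 1
  zstat <- function(Bp) sum(A[sel] * Bp[sel])
  perms <- all_permutations(n)
  z_obs <- zstat(B)
  zs <- vapply(perms, function(p) zstat(B[p, p]), numeric(1))
  mean(zs >= z_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  }
  out
}

# --- modularity: exhaustive search over set partitions ----------------------
oracle_q <- function(A, memb) {
  A <- unname(as.matrix(A))
  diag(A) <- 0
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_set_partitions(n - 1)
  out <- list()
  for (p in sub) {
    for (lab in seq_len(max(p) + 1)) {
      out[[length(out) + 1]] <- c(p, lab)
    }
  }
  out
}

oracle_best_partition_q <- function(A) {
  parts <- all_set_partitions(nrow(A))
  max(vapply(parts, function(p) oracle_q(A, p), numeric(1)))
}

oracle_best_bipartition_q <- function(A) {
  n <- nrow(A)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, 1L + as.integer(intToBits(code))[seq_len(n - 1)])
    best <- max(best, oracle_q(A, memb))
  }
  best
}
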
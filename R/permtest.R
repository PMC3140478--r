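#' Preferred / avoided association test
#'
#' Permutation test of the null hypothesis that individuals associate (or
#' cooperate) at random, constrained by daily presence: in each null
#' replicate, every sampling period's observed association slots are
#' reassigned by a random relabelling of the individuals present that
#' day. Individuals absent from the surroundings on a day never enter
#' that day's permuted data, and the number of associating individuals
#' per day is preserved — a "semi-random" shuffle.
#'
#' Two statistics of the dyadic index \eqn{x_{ij}/d_{ij}} are compared
#' with their null distributions:
#' \describe{
#'   \item{mean_index}{the mean dyadic index; p = P(null mean \eqn{\le}
#'     real mean). A small p with real mean below the null mean indicates
#'     events concentrated on fewer, stronger partners.}
#'   \item{sd_index}{the standard deviation of dyadic indices; p =
#'     P(null SD \eqn{\ge} real SD). A small p indicates more
#'     heterogeneous association than expected at random.}
#' }
#' For bout-count occurrences the index is bouts per joint period and can
#' exceed 1; the statistic is computed on whatever layer the occurrence
#' carries and named accordingly. p-values floor at
#' \eqn{1/(n_{perm}+1)}.
#'
#' An alternative null engine, \code{"swap"}, performs sequential
#' checkerboard swaps on the dyad x period occurrence matrix (preserving
#' dyad totals and per-period totals, in the spirit of the classical
#' sequential-swap null) and is provided for comparison; it applies to
#' binary occurrences only.
#'
#' @param occ a \code{vnet_occurrence}.
#' @param n_perm number of permutations (10000 in the field analysis).
#' @param seed RNG seed.
#' @param engine \code{"relabel"} (default, per-period relabelling of
#'   present individuals) or \code{"swap"}.
#' @param swap_burnin,swap_thin swaps before the first replicate and
#'   between replicates for the swap engine.
#' @return a \code{vnet_permtest}: a data.frame with one row per
#'   statistic and columns \code{statistic}, \code{stat_real},
#'   \code{stat_null_mean}, \code{stat_null_sd}, \code{p},
#'   \code{n_perm}; attribute \code{skipped_periods} lists days with
#'   fewer than two present individuals.
#' @export
preferred_association_test <- function(occ, n_perm = 10000, seed = NULL,
                                       engine = c("relabel", "swap"),
                                       swap_burnin = 1000, swap_thin = 10) {
  stopifnot(inherits(occ, "vnet_occurrence"))
  engine <- match.arg(engine)
  set_seed_if(seed)
  n <- length(occ$ids)
  np <- ncol(occ$presence)
  d <- ut_vec(occ$d)
  ok <- d > 0
  if (sum(ok) < 2) stop("need at least 2 dyads with joint observability")

  few <- which(colSums(occ$presence) < 2)
  if (length(few)) {
    warning("skipping ", length(few),
            " period(s) with fewer than 2 present individuals: ",
            paste(few, collapse = ", "))
  }
  active <- setdiff(seq_len(np), few)

  real <- index_stats(ut_vec(occ$x)[ok], d[ok])

  null_mat <- if (engine == "relabel") {
    null_counts_relabel(occ, active, n_perm)
  } else {
    null_counts_swap(occ, active, n_perm, swap_burnin, swap_thin)
  }
  # add back contributions from skipped periods unchanged
  if (length(few)) {
    fixed <- period_counts(occ, few)
    null_mat <- null_mat + fixed
  }
  null_mat <- null_mat[ok, , drop = FALSE]
  idx <- null_mat / d[ok]
  null_mean <- colMeans(idx)
  nm2 <- colMeans(idx^2)
  null_sd <- sqrt(pmax(0, (nm2 - null_mean^2) * nrow(idx) / (nrow(idx) - 1)))

  eps <- 1e-12
  p_mean <- (1 + sum(null_mean <= real[["mean"]] + eps)) / (n_perm + 1)
  p_sd <- (1 + sum(null_sd >= real[["sd"]] - eps)) / (n_perm + 1)

  res <- data.frame(
    statistic = c("mean_index", "sd_index"),
    stat_real = c(real[["mean"]], real[["sd"]]),
    stat_null_mean = c(mean(null_mean), mean(null_sd)),
    stat_null_sd = c(stats::sd(null_mean), stats::sd(null_sd)),
    p = c(p_mean, p_sd),
    n_perm = n_perm,
    stringsAsFactors = FALSE)
  attr(res, "skipped_periods") <- few
  attr(res, "engine") <- engine
  class(res) <- c("vnet_permtest", "data.frame")
  res
}

index_stats <- function(x, d) {
  a <- x / d
  c(mean = mean(a), sd = stats::sd(a))
}

# dyad-count vector (upper triangle order) summed over the given periods
period_counts <- function(occ, periods) {
  n <- length(occ$ids)
  nd <- n * (n - 1) / 2
  out <- numeric(nd)
  for (t in periods) {
    p <- occ$pairs[[t]]
    if (is.null(p) || nrow(p) == 0) next
    k <- dyad_index(p[, 1], p[, 2], n)
    cnt <- if (ncol(p) >= 3) p[, 3] else rep(1, nrow(p))
    out[k] <- out[k] + cnt
  }
  out
}

# Null engine: per period, relabel the present individuals uniformly at
# random and carry the period's observed dyads (and counts) across the
# relabelling. Returns a (n_dyads x n_perm) matrix of null counts.
null_counts_relabel <- function(occ, periods, n_perm) {
  n <- length(occ$ids)
  nd <- n * (n - 1) / 2
  keys <- integer(0)
  wts <- numeric(0)
  for (t in periods) {
    p <- occ$pairs[[t]]
    if (is.null(p) || nrow(p) == 0) next
    present <- which(occ$presence[, t] == 1L)
    k <- length(present)
    pos <- match(p[, 1:2, drop = FALSE], present)
    dim(pos) <- c(nrow(p), 2)
    cnt <- if (ncol(p) >= 3) p[, 3] else rep(1, nrow(p))
    # n_perm random permutations of the k present individuals at once:
    # order by (replicate, uniform) gives one permutation per block
    u <- stats::runif(k * n_perm)
    g <- rep(seq_len(n_perm), each = k)
    o <- order(g, u)
    pi_mat <- matrix(present[((o - 1L) %% k) + 1L], k, n_perm)
    A <- matrix(pi_mat[pos[, 1], ], nrow(p), n_perm)
    B <- matrix(pi_mat[pos[, 2], ], nrow(p), n_perm)
    dk <- dyad_index(A, B, n)  # n_events x n_perm dyad keys
    perm_of <- rep(seq_len(n_perm), each = nrow(p))
    keys <- c(keys, as.integer(dk) + nd * (perm_of - 1L))
    wts <- c(wts, rep(cnt, n_perm))
  }
  if (!length(keys)) return(matrix(0, nd, n_perm))
  s <- rowsum(wts, group = keys)
  out <- matrix(0, nd, n_perm)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Null engine: sequential swaps exchanging members between two observed
# dyads of the same period (preserving each individual's number of
# associations, each period's number of dyads, and presence), in the
# spirit of the classical group-membership swap null
null_counts_swap <- function(occ, periods, n_perm, burnin, thin) {
  if (!occ$binary) stop("the swap engine requires a binary occurrence")
  n <- length(occ$ids)
  nd <- n * (n - 1) / 2
  state <- lapply(periods, function(t) {
    p <- occ$pairs[[t]]
    if (is.null(p) || nrow(p) == 0) matrix(integer(0), 0, 2)
    else cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  })
  swappable <- which(vapply(state, nrow, integer(1)) >= 2)
  do_swaps <- function(nsw) {
    if (!length(swappable)) return(invisible(NULL))
    for (k in seq_len(nsw)) {
      s <- swappable[sample.int(length(swappable), 1)]
      p <- state[[s]]
      g <- sample.int(nrow(p), 2)
      a_side <- sample.int(2, 1)
      b_side <- sample.int(2, 1)
      a <- p[g[1], a_side]
      b <- p[g[2], b_side]
      if (a == b) next
      new1 <- sort(c(p[g[1], 3 - a_side], b))
      new2 <- sort(c(p[g[2], 3 - b_side], a))
      if (new1[1] == new1[2] || new2[1] == new2[2]) next
      cand <- p
      cand[g[1], ] <- new1
      cand[g[2], ] <- new2
      keys <- (cand[, 2] - 1L) * n + cand[, 1]
      if (anyDuplicated(keys)) next
      state[[s]] <<- cand
    }
    invisible(NULL)
  }
  counts <- function() {
    all_p <- do.call(rbind, state)
    out <- numeric(nd)
    if (nrow(all_p)) {
      k <- dyad_index(all_p[, 1], all_p[, 2], n)
      tab <- rowsum(rep(1, length(k)), k)
      out[as.integer(rownames(tab))] <- tab[, 1]
    }
    out
  }
  out <- matrix(0, nd, n_perm)
  do_swaps(burnin)
  for (b in seq_len(n_perm)) {
    do_swaps(thin)
    out[, b] <- counts()
  }
  out
}

#' @export
print.vnet_permtest <- function(x, ...) {
  cat("<preferred/avoided association test> ", attr(x, "engine"),
      " engine, ", x$n_perm[1], " permutations\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
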
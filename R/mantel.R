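#' Mantel Z-test with between-class masking and constrained permutations
#'
#' Tests the correlation between two dyadic matrices (e.g. cooperation
#' counts vs. an attribute-similarity matrix) by permuting the individual
#' labels of the second matrix. The statistic is the Mantel
#' cross-product \eqn{Z = \sum A_{ij} B_{ij}} over unmasked off-diagonal
#' cells; the matrix correlation coefficient (MCC) reported alongside is
#' the Pearson correlation over the same cells.
#'
#' When a between-class mask is supplied together with the class labels,
#' permutations exchange labels only within a cooperation class
#' (small-class labels move among small-class positions, large among
#' large), so the null preserves the matching-market structure of the
#' experiment and the mask is invariant under every permutation. Cells
#' where either matrix is missing are dropped. p-values floor at
#' \eqn{1/(n_{perm}+1)}.
#'
#' @param A,B square dyadic matrices (\code{vnet_dyadic} or plain
#'   symmetric matrices) over the same ids; B is the matrix whose labels
#'   are permuted (conventionally the attribute matrix).
#' @param mask optional 0/1 mask (\code{vnet_dyadic} or matrix), 1 =
#'   dyad included; defaults to the mask carried by A or B, else all
#'   off-diagonal dyads.
#' @param classes optional character vector (named by id, or in id
#'   order) restricting permutations to within-class exchanges.
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed.
#' @param tail \code{"greater"} (default): p = proportion of permuted Z
#'   at or above the observed; \code{"less"}; or \code{"two.sided"}.
#' @return a \code{vnet_mantel} list with \code{z}, \code{mcc}, \code{p},
#'   \code{n_perm}, \code{n_dyads} (unmasked dyads used), \code{tail} and
#'   \code{partial_controls}.
#' @export
mantel_test <- function(A, B, mask = NULL, classes = NULL, n_perm = 10000,
                        seed = NULL, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  prep <- mantel_prepare(A, B, mask, classes)
  set_seed_if(seed)
  res <- mantel_engine(prep, n_perm, tail)
  res$partial_controls <- character(0)
  class(res) <- "vnet_mantel"
  res
}

# shared set-up: align matrices, resolve mask, validate classes
mantel_prepare <- function(A, B, mask, classes) {
  mA <- if (inherits(A, "vnet_dyadic")) A$values else as.matrix(A)
  mB <- if (inherits(B, "vnet_dyadic")) B$values else as.matrix(B)
  if (is.null(mask)) {
    mask <- if (inherits(A, "vnet_dyadic") && !is.null(A$mask)) A$mask
            else if (inherits(B, "vnet_dyadic") && !is.null(B$mask)) B$mask
  }
  msk <- if (is.null(mask)) NULL
         else if (inherits(mask, "vnet_dyadic")) mask$values else as.matrix(mask)
  n <- nrow(mA)
  if (!all(dim(mB) == n) || (!is.null(msk) && !all(dim(msk) == n))) {
    stop("A, B and mask must be conformable square matrices")
  }
  ids <- rownames(mA) %||% paste0("id", seq_len(n))
  if (!is.null(rownames(mB)) && !identical(rownames(mB), ids)) {
    mB <- mB[ids, ids]
  }
  if (is.null(msk)) {
    msk <- matrix(1, n, n)
    diag(msk) <- 0
  }
  sel <- upper.tri(mA) & msk == 1 & !is.na(mA) & !is.na(mB)
  if (sum(sel) < 3) stop("fewer than 3 usable unmasked dyads")
  if (!is.null(classes)) {
    if (!is.null(names(classes))) classes <- classes[ids]
    if (length(classes) != n || anyNA(classes)) {
      stop("classes must label every individual")
    }
  }
  a <- mA[sel]
  b <- mB[sel]
  if (stats::sd(b) < 1e-12) stop("degenerate attribute matrix: B is constant ",
                                 "on the unmasked cells")
  if (stats::sd(a) < 1e-12) stop("degenerate matrix: A is constant on the ",
                                 "unmasked cells")
  list(A = mA, B = mB, sel = sel, na = is.na(mB), classes = classes,
       n = n, a = a, b = b)
}

mantel_engine <- function(prep, n_perm, tail) {
  z <- sum(prep$a * prep$b)
  mcc <- stats::cor(prep$a, prep$b)
  n <- prep$n
  zperm <- numeric(n_perm)
  Asel <- prep$A
  Asel[!prep$sel] <- NA  # restrict once; permuted B is re-read per draw
  for (k in seq_len(n_perm)) {
    pi_k <- class_permutation(n, prep$classes)
    Bp <- prep$B[pi_k, pi_k]
    zperm[k] <- sum(Asel * Bp, na.rm = TRUE)
  }
  eps <- 1e-12
  p <- switch(tail,
    greater = (1 + sum(zperm >= z - eps)) / (n_perm + 1),
    less = (1 + sum(zperm <= z + eps)) / (n_perm + 1),
    two.sided = {
      mu <- mean(zperm)
      (1 + sum(abs(zperm - mu) >= abs(z - mu) - eps)) / (n_perm + 1)
    })
  list(z = z, mcc = mcc, p = p, n_perm = n_perm, n_dyads = length(prep$a),
       tail = tail)
}

# a uniform random permutation, optionally restricted to within-class moves
class_permutation <- function(n, classes) {
  if (is.null(classes)) return(sample.int(n))
  pi_k <- seq_len(n)
  for (cl in unique(classes)) {
    pos <- which(classes == cl)
    if (length(pos) > 1) pi_k[pos] <- pos[sample.int(length(pos))]
  }
  pi_k
}

#' Partial Mantel test
#'
#' Residualises both matrices on one or more control matrices by
#' ordinary least squares over the unmasked cells (Smouse-style
#' regression residuals), then applies the [mantel_test()] machinery to
#' the residual matrices under the same constrained permutation scheme.
#' Used to test relatedness while controlling for matriline and sibling
#' co-membership.
#'
#' @inheritParams mantel_test
#' @param controls a list of control matrices (\code{vnet_dyadic} or
#'   plain), e.g. \code{list(matriline = ..., siblings = ...)}.
#' @return a \code{vnet_mantel} with \code{partial_controls} recording
#'   the control labels.
#' @export
partial_mantel_test <- function(A, B, controls, mask = NULL, classes = NULL,
                                n_perm = 10000, seed = NULL,
                                tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (!is.list(controls) || length(controls) == 0) {
    stop("controls must be a non-empty list of matrices")
  }
  prep <- mantel_prepare(A, B, mask, classes)
  cmats <- lapply(controls, function(ci) {
    m <- if (inherits(ci, "vnet_dyadic")) ci$values else as.matrix(ci)
    if (!all(dim(m) == prep$n)) stop("control matrix not conformable")
    m
  })
  X <- cbind(1, vapply(cmats, function(m) m[prep$sel], numeric(length(prep$a))))
  ra <- stats::lm.fit(X, prep$a)$residuals
  rb <- stats::lm.fit(X, prep$b)$residuals
  if (stats::sd(rb) < 1e-12) {
    stop("degenerate attribute matrix: B is collinear with the controls")
  }
  # rebuild full residual matrices so label permutation moves cells coherently
  Ares <- matrix(NA_real_, prep$n, prep$n, dimnames = dimnames(prep$A))
  Bres <- Ares
  Ares[prep$sel] <- ra
  Bres[prep$sel] <- rb
  Ares[t(prep$sel)] <- t(Ares)[t(prep$sel)]
  Bres[t(prep$sel)] <- t(Bres)[t(prep$sel)]
  mask01 <- matrix(0, prep$n, prep$n)
  mask01[prep$sel | t(prep$sel)] <- 1
  prep2 <- list(A = Ares, B = Bres, sel = prep$sel, classes = prep$classes,
                n = prep$n, a = ra, b = rb)
  set_seed_if(seed)
  res <- mantel_engine(prep2, n_perm, tail)
  res$partial_controls <- names(controls) %||%
    paste0("control", seq_along(controls))
  class(res) <- "vnet_mantel"
  res
}

#' @export
print.vnet_mantel <- function(x, ...) {
  cat("<Mantel test> Z = ", format(x$z), ", MCC = ", round(x$mcc, 3),
      ", p = ", format(x$p), " (", x$tail, ", ", x$n_perm,
      " permutations, ", x$n_dyads, " dyads",
      if (length(x$partial_controls)) paste0("; controlling for ",
        paste(x$partial_controls, collapse = ", ")),
      ")\n", sep = "")
  invisible(x)
}
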
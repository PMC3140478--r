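#' David's Score dominance index
#'
#' Computes David's Scores from a directed win-count matrix
#' (\code{wins[i, j]} = number of agonistic encounters i won against j;
#' in the field design these are aggression/submission bouts started
#' within 5 m of the feeders). For each dyad with \eqn{n_{ij} > 0}
#' encounters the win proportion is \eqn{P_{ij} = w_{ij}/n_{ij}}, or with
#' the dyadic correction (\code{method = "Dij"})
#' \eqn{D_{ij} = P_{ij} - (P_{ij} - 0.5)/(n_{ij} + 1)}, which shrinks
#' proportions from few encounters toward one half. Then
#' \deqn{DS_i = w_i + w_{2,i} - l_i - l_{2,i}} with \eqn{w_i = \sum_j
#' P_{ij}}, \eqn{w_{2,i} = \sum_j P_{ij} w_j}, \eqn{l_i = \sum_j P_{ji}}
#' and \eqn{l_{2,i} = \sum_j P_{ji} l_j}. Raw scores sum to zero over the
#' scored set; normalized scores are \eqn{(DS + n(n-1)/2)/n}.
#'
#' @param wins a square non-negative directed count matrix with zero
#'   diagonal and id dimnames.
#' @param method \code{"Pij"} (raw win proportions, default) or
#'   \code{"Dij"} (dyadic correction).
#' @return a \code{vnet_ds} list: \code{ds}, \code{normalized_ds} (both
#'   named), \code{n_interactions}, \code{method}.
#' @export
davids_score <- function(wins, method = c("Pij", "Dij")) {
  method <- match.arg(method)
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (n != ncol(wins)) stop("win matrix must be square")
  if (any(wins < 0)) stop("negative counts in win matrix")
  if (any(diag(wins) != 0)) stop("win matrix diagonal must be zero")
  ids <- rownames(wins) %||% paste0("id", seq_len(n))
  nij <- wins + t(wins)
  if (sum(wins) == 0) {
    warning("all-zero win matrix: all David's Scores are 0")
    z <- stats::setNames(numeric(n), ids)
    return(structure(list(ds = z,
                          normalized_ds = z + (n - 1) / 2,
                          n_interactions = 0, method = method),
                     class = "vnet_ds"))
  }
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  has <- nij > 0
  P[has] <- wins[has] / nij[has]
  if (method == "Dij") {
    P[has] <- P[has] - (P[has] - 0.5) / (nij[has] + 1)
  }
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  ds <- stats::setNames(w + w2 - l - l2, ids)
  structure(list(ds = ds,
                 normalized_ds = (ds + n * (n - 1) / 2) / n,
                 n_interactions = sum(nij) / 2,
                 method = method),
            class = "vnet_ds")
}

#' @export
print.vnet_ds <- function(x, ...) {
  cat("<David's Scores> (", x$method, ", ", x$n_interactions,
      " interactions)\n", sep = "")
  ord <- order(-x$ds)
  print(round(rbind(DS = x$ds[ord], normalized = x$normalized_ds[ord]), 2),
        ...)
  invisible(x)
}
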
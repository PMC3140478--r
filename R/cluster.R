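#' Ward-linkage dendrogram of a rate or association matrix
#'
#' Agglomerates individuals under Ward's minimum-variance objective: at
#' each step the pair of clusters whose merger least increases the total
#' within-cluster sum of squares (the sum of squared distances of the
#' cluster members to the cluster centroid) is joined, and the stored
#' height of the merge is exactly that increase. Because Ward's objective
#' assumes a Euclidean geometry, the rate matrix is converted to
#' Euclidean profile distances by default: each individual is represented
#' by its row of (optionally observability-normalised) rates, with the
#' self-cell set to zero. The direct \code{1 - rate/max} complement
#' distance is available but is not guaranteed Euclidean, so Ward's
#' interpretation is weaker there.
#'
#' @param rates a \code{vnet_dyadic} (interaction rates or association
#'   indices) or a plain symmetric matrix; \code{NA} cells are treated
#'   as 0 (never seen together).
#' @param distance \code{"profile"} (default, Euclidean row-profile
#'   distance) or \code{"complement"} (\code{1 - rate/max(rate)}).
#' @param normalise divide each dyad's rate by its joint observability
#'   before clustering; supply the occurrence \code{d} matrix to enable.
#' @return a \code{vnet_dendrogram}: \code{merge}, \code{height} (Ward
#'   SS increments, non-decreasing), \code{order}, \code{labels},
#'   \code{hclust} (an hclust object on the same scale) and
#'   \code{cophenetic_coefficient} against the clustering distances.
#' @export
ward_dendrogram <- function(rates, distance = c("profile", "complement"),
                            normalise = NULL) {
  distance <- match.arg(distance)
  m <- if (inherits(rates, "vnet_dyadic")) rates$values else as.matrix(rates)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 individuals to cluster")
  m[is.na(m)] <- 0
  if (!is.null(normalise)) {
    d_obs <- as.matrix(normalise)
    ok <- d_obs > 0
    m[ok] <- m[ok] / d_obs[ok]
    m[!ok] <- 0
  }
  diag(m) <- 0
  d <- switch(distance,
    profile = stats::dist(m),
    complement = {
      mx <- max(m)
      if (mx == 0) mx <- 1
      stats::as.dist(1 - m / mx)
    })
  hc <- stats::hclust(d, method = "ward.D2")
  heights <- hc$height^2 / 2  # ward.D2 merge distance -> SS increment
  hc2 <- hc
  hc2$height <- heights
  dend <- structure(list(merge = hc$merge, height = heights,
                         order = hc$order,
                         labels = hc$labels %||% rownames(m),
                         hclust = hc2, dist = d),
                    class = "vnet_dendrogram")
  dend$cophenetic_coefficient <- cophenetic_coefficient(dend, d)
  dend
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the dendrogram-implied distances (the
#' height of the lowest merge joining each pair) and the input
#' distances, over all dyads. A value of 1.0 means the tree fits the
#' data perfectly; 0.8 is conventionally taken as a good fit (see
#' [cophenetic_fit()]).
#'
#' @param dend a \code{vnet_dendrogram} or \code{hclust}.
#' @param d a \code{dist} or symmetric distance matrix over the same
#'   individuals; defaults to the distances the dendrogram was built
#'   from, when available.
#' @return the coefficient, a scalar in [-1, 1].
#' @export
cophenetic_coefficient <- function(dend, d = NULL) {
  hc <- if (inherits(dend, "vnet_dendrogram")) dend$hclust else dend
  stopifnot(inherits(hc, "hclust"))
  if (is.null(d)) {
    d <- if (inherits(dend, "vnet_dendrogram")) dend$dist
    if (is.null(d)) stop("no distances supplied or stored")
  }
  dv <- as.vector(stats::as.dist(d))
  cv <- as.vector(stats::cophenetic(hc))
  if (stats::sd(dv) < 1e-300) stop("constant distances: cophenetic ",
                                   "coefficient undefined")
  stats::cor(cv, dv)
}

#' @rdname cophenetic_coefficient
#' @param coefficient a cophenetic correlation coefficient.
#' @return \code{cophenetic_fit}: \code{"good"} for coefficients at or
#'   above 0.8, else \code{"poor"}.
#' @export
cophenetic_fit <- function(coefficient) {
  ifelse(coefficient >= 0.8, "good", "poor")
}

#' @export
print.vnet_dendrogram <- function(x, ...) {
  cat("<Ward dendrogram> ", length(x$labels), " individuals, cophenetic ",
      round(x$cophenetic_coefficient, 3), " (",
      cophenetic_fit(x$cophenetic_coefficient), ")\n", sep = "")
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the Ward merge heights.
#'
#' @param dend a \code{vnet_dendrogram}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "vnet_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
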
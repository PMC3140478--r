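#' Symmetric dyadic matrices
#'
#' A dyadic matrix stores one real value per unordered pair of individuals:
#' an association index, an interaction rate, an attribute similarity, a
#' relatedness coefficient or a distance. The diagonal is undefined and
#' ignored. An optional symmetric binary mask marks which dyads enter a
#' statistic (1 = included); the between-class mask used throughout the
#' cooperation analyses is built with [between_class_mask()].
#'
#' @param values a square symmetric numeric matrix with identical row and
#'   column names (individual ids).
#' @param kind one of \code{"association_index"}, \code{"interaction_rate"},
#'   \code{"similarity"}, \code{"relatedness"}, \code{"distance"}.
#' @param mask optional symmetric 0/1 matrix over the same ids, zero
#'   diagonal.
#' @param tol maximum absolute asymmetry tolerated before an error.
#' @return a \code{vnet_dyadic} object.
#' @export
dyadic_matrix <- function(values,
                          kind = c("association_index", "interaction_rate",
                                   "similarity", "relatedness", "distance"),
                          mask = NULL, tol = 1e-9) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("dyadic matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <-
      colnames(values) %||% paste0("id", seq_len(nrow(values)))
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column names of a dyadic matrix must match")
  }
  check_symmetric(values, tol, what = "values")
  values[] <- (values + t(values)) / 2  # remove numeric asymmetry
  rng <- switch(kind,
    association_index = c(0, 1),
    relatedness = c(-1, 1),
    NULL)
  if (!is.null(rng)) {
    v <- values[upper.tri(values)]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < rng[1] - tol || max(v) > rng[2] + tol)) {
      stop(kind, " values must lie in [", rng[1], ", ", rng[2], "]")
    }
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) stop("mask dimensions differ from values")
    check_symmetric(mask, tol, what = "mask")
    if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
    diag(mask) <- 0
    dimnames(mask) <- dimnames(values)
    storage.mode(mask) <- "double"
  }
  structure(list(values = values, kind = kind, mask = mask),
            class = "vnet_dyadic")
}

check_symmetric <- function(m, tol, what = "matrix") {
  asym <- abs(m - t(m))
  asym[is.na(asym)] <- 0
  if (max(asym) > tol) {
    w <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(what, " not symmetric: worst cell (", rownames(m)[w[1]] %||% w[1],
         ", ", colnames(m)[w[2]] %||% w[2], ") differs by ",
         format(max(asym)))
  }
  invisible(TRUE)
}

#' @export
print.vnet_dyadic <- function(x, ...) {
  cat("<dyadic matrix> kind=", x$kind, ", ", nrow(x$values), " individuals",
      if (!is.null(x$mask)) paste0(", ", sum(x$mask[upper.tri(x$mask)]),
                                   " unmasked dyads"),
      "\n", sep = "")
  print(x$values, ...)
  invisible(x)
}

#' Write / read a dyadic matrix as labelled CSV
#'
#' The matrix is stored with an id header row and an id first column. If a
#' mask is present it is written alongside with the suffix
#' \code{.mask.csv}; \code{read_dyadic_matrix} picks the mask file up
#' automatically. Reading enforces symmetry to within \code{tol} and
#' errors naming the worst cell otherwise, so a round trip reproduces the
#' matrix exactly at printed precision.
#'
#' @param m a \code{vnet_dyadic}.
#' @param path CSV file path.
#' @return \code{write_dyadic_matrix}: the path, invisibly;
#'   \code{read_dyadic_matrix}: a \code{vnet_dyadic}.
#' @export
write_dyadic_matrix <- function(m, path) {
  stopifnot(inherits(m, "vnet_dyadic"))
  df <- data.frame(id = rownames(m$values), m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(m$mask)) {
    mdf <- data.frame(id = rownames(m$mask), m$mask, check.names = FALSE)
    utils::write.csv(mdf, mask_path(path), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_dyadic_matrix
#' @param kind matrix kind, see [dyadic_matrix()].
#' @param tol symmetry tolerance on read.
#' @export
read_dyadic_matrix <- function(path, kind = "association_index", tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- ids
  if (!identical(colnames(vals), ids)) {
    stop("matrix file ", path, " is not square-labelled: header ids differ ",
         "from first-column ids")
  }
  mask <- NULL
  mp <- mask_path(path)
  if (file.exists(mp)) {
    mdf <- utils::read.csv(mp, check.names = FALSE, stringsAsFactors = FALSE)
    mask <- as.matrix(mdf[, -1, drop = FALSE])
    rownames(mask) <- as.character(mdf[[1]])
  }
  dyadic_matrix(vals, kind = kind, mask = mask, tol = tol)
}

mask_path <- function(path) sub("\\.csv$", ".mask.csv", path)

#' Export a dyadic matrix as a weighted GraphML network
#'
#' Writes an undirected weighted graph (edge attribute \code{weight}) for
#' external visualisation. Dyads with missing or zero values, and masked
#' dyads, carry no edge.
#'
#' @param m a \code{vnet_dyadic}.
#' @param path output GraphML file.
#' @return the path, invisibly.
#' @export
export_graphml <- function(m, path) {
  stopifnot(inherits(m, "vnet_dyadic"))
  w <- m$values
  w[is.na(w)] <- 0
  if (!is.null(m$mask)) w <- w * m$mask
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
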
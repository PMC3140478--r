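#' Attribute similarity matrices
#'
#' Encodes individual attributes as dyadic similarity matrices for the
#' partner-choice Mantel tests. Categorical attributes (sex, age class,
#' matriline) become same-class indicators (1 = same); dominance becomes
#' a rank-similarity matrix \eqn{1 - |DS_i - DS_j| / \max |DS|-gap}
#' rescaled to [0, 1]; sibling co-membership becomes a 0/1 indicator.
#' These are the minimal monotone encodings; each is exposed separately
#' so alternatives can be swapped in.
#'
#' @param roster a \code{vnet_roster}.
#' @param attribute column name of a categorical attribute
#'   (\code{"sex"}, \code{"age_class"}, \code{"matriline"}).
#' @return a \code{vnet_dyadic} of kind \code{"similarity"}.
#' @export
similarity_indicator <- function(roster, attribute) {
  v <- roster[[attribute]]
  if (is.null(v)) stop("no roster column called ", attribute)
  m <- outer(v, v, function(a, b) as.numeric(a == b))
  m[is.na(m)] <- 0
  dimnames(m) <- list(roster$id, roster$id)
  diag(m) <- 0
  dyadic_matrix(m, kind = "similarity")
}

#' @rdname similarity_indicator
#' @param ds a named numeric vector of dominance scores (e.g. David's
#'   Scores from [davids_score()]).
#' @export
rank_similarity <- function(ds) {
  stopifnot(!is.null(names(ds)))
  gap <- abs(outer(ds, ds, "-"))
  rng <- max(gap)
  m <- if (rng > 0) 1 - gap / rng else matrix(1, length(ds), length(ds))
  dimnames(m) <- list(names(ds), names(ds))
  diag(m) <- 0
  dyadic_matrix(m, kind = "similarity")
}

#' @rdname similarity_indicator
#' @export
sibling_indicator <- function(roster) {
  sets <- sibling_sets(roster)
  n <- nrow(roster)
  m <- matrix(0, n, n, dimnames = list(roster$id, roster$id))
  for (i in seq_len(n)) {
    sibs <- intersect(sets[[i]], roster$id)
    m[i, sibs] <- 1
  }
  m <- pmax(m, t(m))  # either direction declares the pair siblings
  diag(m) <- 0
  dyadic_matrix(m, kind = "similarity")
}

#' @rdname similarity_indicator
#' @export
matriline_indicator <- function(roster) {
  similarity_indicator(roster, "matriline")
}
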
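#' Per-period dyadic occurrence data
#'
#' The unit of repeated observation is the sampling period (one day).
#' For each period the object records which dyads were seen associated
#' (or how many interaction bouts they exchanged) and, through the
#' presence matrix, which individuals were observable in the surroundings
#' that day. A dyad's denominator \eqn{d_{ij}} is the number of periods in
#' which both members were present; its association index is
#' \eqn{\hat\alpha_{ij} = x_{ij} / d_{ij}}.
#'
#' @param presence an individuals x periods 0/1 matrix with row names
#'   (ids); 1 means the individual was observable in the surroundings
#'   that day.
#' @param pairs a list with one element per period; each element is an
#'   integer matrix with columns \code{i}, \code{j} (row indices into
#'   \code{presence}) and optionally \code{count} (bout counts; defaults
#'   to 1 per row). Dyads listed in a period must both be present that
#'   period.
#' @param binary TRUE when a period's dyad can occur at most once (periods
#'   together); FALSE for bout-count layers.
#' @return a \code{vnet_occurrence} object with components \code{ids},
#'   \code{presence}, \code{pairs}, \code{x} (periods-together or bout
#'   counts per dyad, symmetric), \code{d} (joint-presence counts) and
#'   \code{binary} (whether \code{x} counts periods, TRUE, or bouts).
#' @export
dyadic_occurrence <- function(presence, pairs, binary = TRUE) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (is.null(rownames(presence))) {
    rownames(presence) <- paste0("id", seq_len(nrow(presence)))
  }
  if (!all(presence %in% c(0L, 1L))) stop("presence entries must be 0 or 1")
  n <- nrow(presence)
  np <- ncol(presence)
  if (length(pairs) != np) {
    stop("pairs must have one element per sampling period (", np, ")")
  }
  ids <- rownames(presence)
  ii <- jj <- cc <- vector("list", np)
  for (t in seq_len(np)) {
    p <- pairs[[t]]
    if (is.null(p) || nrow(p) == 0) next
    p <- as.matrix(p)
    if (any(p[, 1] == p[, 2])) stop("self-dyad in period ", t)
    if (any(presence[p[, 1], t] == 0L | presence[p[, 2], t] == 0L)) {
      stop("period ", t, " lists a dyad with an absent member")
    }
    a <- pmin(p[, 1], p[, 2])
    b <- pmax(p[, 1], p[, 2])
    if (binary && anyDuplicated((b - 1L) * n + a)) {
      stop("period ", t, " lists the same dyad twice in binary occurrence")
    }
    ii[[t]] <- a
    jj[[t]] <- b
    cc[[t]] <- if (ncol(p) >= 3) p[, 3] else rep(1, nrow(p))
  }
  x <- accumulate_dyads(unlist(ii), unlist(jj), unlist(cc), n, ids)
  d <- tcrossprod(presence)  # joint presence counts
  diag(d) <- 0
  structure(list(ids = ids, presence = presence, pairs = pairs,
                 x = x, d = d, binary = binary),
            class = "vnet_occurrence")
}

# symmetric accumulation of dyad weights (i < j) into an n x n matrix
accumulate_dyads <- function(i, j, cnt, n, ids) {
  x <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(i)) {
    s <- rowsum(as.numeric(cnt), group = (j - 1L) * n + i)
    idx <- as.integer(rownames(s))
    x[idx] <- s[, 1]
    x <- x + t(x)
  }
  x
}

#' @export
print.vnet_occurrence <- function(x, ...) {
  cat("<dyadic occurrence> ", length(x$ids), " individuals x ",
      ncol(x$presence), " periods, ",
      if (x$binary) "binary periods-together" else "bout counts",
      ", total x = ", sum(x$x) / 2, "\n", sep = "")
  invisible(x)
}

#' Association indices of an occurrence object
#'
#' Simple-ratio index: periods together over periods jointly observable.
#' Dyads never jointly observable are \code{NA} and are excluded from all
#' downstream statistics.
#'
#' @param occ a \code{vnet_occurrence}.
#' @return a \code{vnet_dyadic} of kind \code{"association_index"} (or
#'   \code{"interaction_rate"} for bout-count occurrences, where the value
#'   is bouts per joint period and may exceed 1).
#' @export
association_index <- function(occ) {
  stopifnot(inherits(occ, "vnet_occurrence"))
  a <- occ$x / occ$d
  a[occ$d == 0] <- NA_real_
  diag(a) <- NA_real_
  dyadic_matrix(a, kind = if (occ$binary) "association_index"
                          else "interaction_rate")
}

# upper-triangle vectors (x, d) and the dyad grid, used by the estimators
occ_vectors <- function(occ) {
  list(x = ut_vec(occ$x), d = ut_vec(occ$d),
       dyads = dyad_grid(length(occ$ids)))
}

#' Build a presence matrix from an event log
#'
#' An individual counts as present in a sampling period if it appears in
#' any record that day, as actor, recipient or neighbour. Individuals on
#' the roster never seen in a period are scored absent for that period.
#'
#' @param log a \code{vnet_event_log}.
#' @param roster a \code{vnet_roster} giving the full set of individuals
#'   (rows of the matrix).
#' @return an individuals x periods 0/1 integer matrix.
#' @export
presence_from_log <- function(log, roster) {
  stopifnot(inherits(log, "vnet_event_log"))
  ids <- roster$id
  np <- max(log$sampling_period, 1L)
  pres <- matrix(0L, length(ids), np,
                 dimnames = list(ids, paste0("p", seq_len(np))))
  seen <- rbind(data.frame(id = log$actor, t = log$sampling_period),
                data.frame(id = log$recipient, t = log$sampling_period))
  seen <- seen[!is.na(seen$id) & seen$id %in% ids, ]
  pres[cbind(match(seen$id, ids), seen$t)] <- 1L
  pres
}
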
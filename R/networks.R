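#' Per-condition networks
#'
#' A condition network bundles, for one observation condition (proximity,
#' affiliative interactions, or cooperation at the feeders), the dyadic
#' matrix, the per-period occurrence layer behind it, and the bookkeeping
#' counts that enter the differentiation table.
#'
#' @name condition_network
NULL

condition_network <- function(condition, matrix, occurrence, n_events) {
  structure(list(condition = condition, matrix = matrix,
                 occurrence = occurrence,
                 n_periods = ncol(occurrence$presence),
                 n_events = n_events),
            class = "vnet_network")
}

#' @export
print.vnet_network <- function(x, ...) {
  cat("<condition network> ", x$condition, ": ", length(x$occurrence$ids),
      " individuals, ", x$n_periods, " periods, ", x$n_events,
      " contributing records\n", sep = "")
  invisible(x)
}

#' Proximity association network from scan samples
#'
#' A dyad counts as associated in a sampling period if any qualifying
#' scan that day records the two as nearest neighbours within
#' \code{max_nn_m} metres while away from the artificial feeders (record
#' feeder distance beyond \code{min_feeder_m}, or no feeders present).
#' The association index is the simple ratio: periods associated over
#' periods both individuals were present.
#'
#' @param log a \code{vnet_event_log} containing scan records.
#' @param presence an individuals x periods presence matrix (see
#'   [presence_from_log()]); its row names define the network's
#'   individuals.
#' @param max_nn_m nearest-neighbour distance threshold in metres.
#' @param min_feeder_m scans at or within this feeder radius are excluded
#'   to avoid scoring feeder-induced proximity.
#' @return a \code{vnet_network} of condition \code{"proximity"}.
#' @export
proximity_association <- function(log, presence, max_nn_m = 10,
                                  min_feeder_m = 10) {
  stopifnot(inherits(log, "vnet_event_log"))
  ids <- rownames(presence)
  sc <- log[log$kind == "scan" & !is.na(log$recipient), , drop = FALSE]
  ok <- !is.na(sc$neighbour_distance_m) & sc$neighbour_distance_m <= max_nn_m &
    (is.na(sc$feeder_distance_m) | sc$feeder_distance_m > min_feeder_m) &
    sc$actor %in% ids & sc$recipient %in% ids
  sc <- sc[ok, , drop = FALSE]
  np <- ncol(presence)
  pairs <- vector("list", np)
  for (t in seq_len(np)) {
    dt <- sc[sc$sampling_period == t, , drop = FALSE]
    if (!nrow(dt)) {
      pairs[[t]] <- matrix(integer(0), 0, 2)
      next
    }
    i <- match(dt$actor, ids)
    j <- match(dt$recipient, ids)
    keep <- presence[cbind(i, t)] == 1L & presence[cbind(j, t)] == 1L
    ij <- unique(cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE])
    pairs[[t]] <- ij
  }
  occ <- dyadic_occurrence(presence, pairs, binary = TRUE)
  condition_network("proximity", association_index(occ), occ, nrow(sc))
}

#' Interaction-rate network from behavioural bouts
#'
#' Counts bouts per dyad for a set of behaviours (frequency, not
#' duration), with direction collapsed, plus a binary periods-together
#' layer used by index-based statistics. Cooperation networks are
#' interaction-rate networks over \code{"coop_attempt"} bouts.
#'
#' @param log a \code{vnet_event_log} containing bout records.
#' @param behaviours non-empty character vector of behaviours to count,
#'   e.g. \code{c("allogroom", "contact_sit", "play")}.
#' @param presence presence matrix defining individuals and periods.
#' @param condition label stored on the resulting network.
#' @return a \code{vnet_network} whose \code{matrix} holds symmetric bout
#'   counts (kind \code{"interaction_rate"}) and whose \code{occurrence}
#'   carries per-period bout counts.
#' @export
interaction_rate <- function(log, behaviours, presence,
                             condition = "affiliative") {
  stopifnot(inherits(log, "vnet_event_log"))
  if (length(behaviours) == 0) stop("empty behaviour set")
  ids <- rownames(presence)
  b <- log[log$kind == "bout" & log$behaviour %in% behaviours &
             !is.na(log$recipient) &
             log$actor %in% ids & log$recipient %in% ids, , drop = FALSE]
  np <- ncol(presence)
  pairs <- vector("list", np)
  for (t in seq_len(np)) {
    dt <- b[b$sampling_period == t, , drop = FALSE]
    if (!nrow(dt)) {
      pairs[[t]] <- matrix(integer(0), 0, 3)
      next
    }
    i <- match(dt$actor, ids)
    j <- match(dt$recipient, ids)
    keep <- presence[cbind(i, t)] == 1L & presence[cbind(j, t)] == 1L
    ij <- cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE]
    if (!nrow(ij)) {
      pairs[[t]] <- matrix(integer(0), 0, 3)
      next
    }
    key <- paste(ij[, 1], ij[, 2])
    tab <- table(key)
    uk <- do.call(rbind, strsplit(names(tab), " "))
    pairs[[t]] <- cbind(as.integer(uk[, 1]), as.integer(uk[, 2]),
                        as.integer(tab))
  }
  occ <- dyadic_occurrence(presence, pairs, binary = FALSE)
  rates <- occ$x
  diag(rates) <- NA_real_
  condition_network(condition,
                    dyadic_matrix(rates, kind = "interaction_rate"),
                    occ, nrow(b))
}

#' Cooperation network
#'
#' @inheritParams interaction_rate
#' @return a \code{vnet_network} of condition \code{"cooperation"}
#'   counting \code{coop_attempt} bouts.
#' @export
cooperation_network <- function(log, presence) {
  interaction_rate(log, "coop_attempt", presence, condition = "cooperation")
}

#' Between-class mask
#'
#' Marks the dyads pairing a small-class member with a large-class
#' member. Restricting matrix statistics to these dyads keeps
#' same-class co-occurrences at the feeders (possible when more than two
#' individuals cooperate at once) from biasing the partner-choice tests.
#'
#' @param roster a \code{vnet_roster} with \code{coop_class} set for all
#'   individuals.
#' @return a \code{vnet_dyadic} of kind \code{"similarity"} whose values
#'   are the 0/1 mask (1 = between-class dyad), zero diagonal.
#' @export
between_class_mask <- function(roster) {
  if (anyNA(roster$coop_class)) stop("coop_class missing for some individuals")
  small <- roster$coop_class == "small"
  m <- outer(small, !small) | outer(!small, small)
  m <- matrix(as.numeric(m), nrow(roster),
              dimnames = list(roster$id, roster$id))
  diag(m) <- 0
  dyadic_matrix(m, kind = "similarity")
}
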
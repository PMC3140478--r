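#' Simulate a complete study bundle
#'
#' Generates one group's full synthetic dataset in the raw formats the
#' pipeline consumes: a roster, an event log holding proximity scans,
#' affiliative bouts, cooperation attempts and agonistic bouts, a
#' relatedness matrix, and a ground-truth record for recovery tests.
#'
#' The three observation conditions are generated as follows.
#' \describe{
#'   \item{proximity}{per-day dyadic association draws with planted mean
#'     and differentiation (\code{mu_proximity}, \code{s_proximity}),
#'     emitted as nearest-neighbour scan records away from the feeders;
#'     every present individual additionally gets a solo scan so daily
#'     presence is recoverable from the log.}
#'   \item{affiliative}{the same mechanism with its own mean and planted
#'     differentiation, emitted as allogrooming / contact-sitting / play
#'     bouts.}
#'   \item{cooperation}{either rank-assortative small-class x large-class
#'     attempts (\code{mechanism = "rank"}, strength
#'     \code{cfg$rank_assortment}) or planted-differentiation association
#'     draws restricted to between-class dyads (\code{mechanism =
#'     "planted"}, differentiation \code{s_cooperation}).}
#' }
#' Agonistic bouts (aggression near the feeders) realise the ground-truth
#' rank scores through logistic win probabilities.
#'
#' @param cfg a [sim_config()]; its \code{true_assoc_mean} /
#'   \code{true_assoc_cv} are overridden per condition by the arguments
#'   below.
#' @param mu_proximity,s_proximity mean and planted differentiation of
#'   the proximity condition.
#' @param mu_affiliative,s_affiliative same for the affiliative condition.
#' @param s_cooperation planted differentiation of the cooperation
#'   condition when \code{mechanism = "planted"}.
#' @param mechanism how cooperation events are generated, see Details.
#' @return a list with \code{roster}, \code{events} (one
#'   \code{vnet_event_log}), \code{relatedness}, \code{wins},
#'   \code{presence} and \code{truth}.
#' @export
simulate_study <- function(cfg,
                           mu_proximity = 0.2, s_proximity = 0.3,
                           mu_affiliative = 0.1, s_affiliative = 0.6,
                           s_cooperation = 1.2,
                           mechanism = c("rank", "planted")) {
  mechanism <- match.arg(mechanism)
  set_seed_if(cfg$seed)
  roster <- simulate_roster(cfg, seed = NA_seed_passthrough())
  presence <- simulate_presence(cfg, seed = NA_seed_passthrough())
  ids <- roster$id
  day0 <- as.Date("2008-07-01")

  cfg_prox <- utils::modifyList(cfg, list(true_assoc_mean = mu_proximity,
                                          true_assoc_cv = s_proximity))
  class(cfg_prox) <- class(cfg)
  prox <- simulate_association_data(cfg_prox, presence = presence,
                                    seed = NA_seed_passthrough())
  cfg_aff <- utils::modifyList(cfg, list(true_assoc_mean = mu_affiliative,
                                         true_assoc_cv = s_affiliative))
  class(cfg_aff) <- class(cfg)
  aff <- simulate_association_data(cfg_aff, presence = presence,
                                   seed = NA_seed_passthrough())

  rows <- list()
  for (t in seq_len(cfg$n_periods)) {
    stamp <- function(secs) format(as.POSIXct(day0 + (t - 1), tz = "UTC") + secs,
                                   "%Y-%m-%d %H:%M:%S", tz = "UTC")
    here <- which(presence[, t] == 1L)
    if (length(here)) {
      rows[[length(rows) + 1]] <- data.frame(
        timestamp = stamp(7 * 3600 + 10 * seq_along(here)),
        kind = "scan", behaviour = "proximity",
        actor = ids[here], recipient = NA_character_,
        neighbour_distance_m = NA_real_, feeder_distance_m = 20,
        stringsAsFactors = FALSE)
    }
    pp <- prox$occurrence$pairs[[t]]
    if (!is.null(pp) && nrow(pp)) {
      rows[[length(rows) + 1]] <- data.frame(
        timestamp = stamp(8 * 3600 + 10 * seq_len(nrow(pp))),
        kind = "scan", behaviour = "proximity",
        actor = ids[pp[, 1]], recipient = ids[pp[, 2]],
        neighbour_distance_m = 5, feeder_distance_m = 20,
        stringsAsFactors = FALSE)
    }
    ap <- aff$occurrence$pairs[[t]]
    if (!is.null(ap) && nrow(ap)) {
      beh <- AFFILIATIVE_BEHAVIOURS[1 + (seq_len(nrow(ap)) %% 3)]
      rows[[length(rows) + 1]] <- data.frame(
        timestamp = stamp(10 * 3600 + 30 * seq_len(nrow(ap))),
        kind = "bout", behaviour = beh,
        actor = ids[ap[, 1]], recipient = ids[ap[, 2]],
        neighbour_distance_m = 0.5, feeder_distance_m = 20,
        stringsAsFactors = FALSE)
    }
  }

  # cooperation condition
  if (mechanism == "rank") {
    coop_log <- simulate_cooperation_events(cfg, roster = roster,
                                            presence = presence,
                                            seed = NA_seed_passthrough())
    coop_rows <- as.data.frame(coop_log)[, names(empty_event_frame())]
  } else {
    mask <- between_class_mask(roster)
    cv_bound <- sqrt((1 - cfg$true_assoc_mean) / cfg$true_assoc_mean)
    s_coop <- min(s_cooperation, 0.99 * cv_bound)
    cfg_coop <- utils::modifyList(cfg, list(true_assoc_cv = s_coop))
    class(cfg_coop) <- class(cfg)
    coop <- simulate_association_data(cfg_coop, presence = presence,
                                      seed = NA_seed_passthrough())
    coop_rows <- list()
    for (t in seq_len(cfg$n_periods)) {
      cp <- coop$occurrence$pairs[[t]]
      if (is.null(cp) || !nrow(cp)) next
      keep <- mask$values[cp[, 1:2, drop = FALSE]] == 1
      cp <- cp[keep, , drop = FALSE]
      if (!nrow(cp)) next
      coop_rows[[length(coop_rows) + 1]] <- data.frame(
        timestamp = format(as.POSIXct(day0 + (t - 1), tz = "UTC") +
                             13 * 3600 + 60 * seq_len(nrow(cp)),
                           "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        kind = "bout", behaviour = "coop_attempt",
        actor = ids[cp[, 1]], recipient = ids[cp[, 2]],
        neighbour_distance_m = 0.5, feeder_distance_m = 0,
        stringsAsFactors = FALSE)
    }
    coop_rows <- if (length(coop_rows)) do.call(rbind, coop_rows)
                 else empty_event_frame()
  }

  # agonistic bouts near the feeders realising the rank scores; each
  # encounter lands on a day when both opponents were present (dyads
  # never jointly present contribute no logged bouts)
  wins <- simulate_agonistic_matrix(cfg, seed = NA_seed_passthrough())
  ag <- list(t = integer(0), a = integer(0), r = integer(0))
  nz <- which(wins > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1]; j <- nz[k, 2]
    days <- which(presence[i, ] == 1L & presence[j, ] == 1L)
    if (!length(days)) next
    tt <- rep_len(days, wins[i, j])
    ag$t <- c(ag$t, tt)
    ag$a <- c(ag$a, rep(i, length(tt)))
    ag$r <- c(ag$r, rep(j, length(tt)))
  }
  ag_rows <- if (length(ag$t)) {
    ord <- order(ag$t)
    within_day <- stats::ave(seq_along(ord), ag$t[ord],
                             FUN = seq_along)
    data.frame(
      timestamp = format(as.POSIXct(day0 + (ag$t[ord] - 1), tz = "UTC") +
                           14 * 3600 + 30 * within_day,
                         "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      kind = "bout", behaviour = "aggression",
      actor = ids[ag$a[ord]], recipient = ids[ag$r[ord]],
      neighbour_distance_m = 1, feeder_distance_m = 2,
      stringsAsFactors = FALSE)
  } else empty_event_frame()

  events <- as_event_log(rbind(do.call(rbind, rows), coop_rows, ag_rows))
  truth <- list(s_proximity = s_proximity, s_affiliative = s_affiliative,
                s_cooperation = if (mechanism == "planted") s_cooperation
                                else NA,
                mechanism = mechanism,
                rank_scores = as.list(stats::setNames(cfg$rank_scores, ids)),
                rank_assortment = cfg$rank_assortment,
                seed = cfg$seed)
  list(roster = roster, events = events,
       relatedness = simulate_relatedness(cfg, roster),
       wins = wins, presence = presence, truth = truth)
}

#' Write a simulated study bundle to a directory
#'
#' Writes \code{roster.csv}, \code{events.csv}, \code{relatedness.csv}
#' (with its mask file when present), \code{wins.csv}, \code{presence.csv}
#' and \code{truth.json}.
#'
#' @param bundle a list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roster(bundle$roster, file.path(dir, "roster.csv"))
  write_event_log(bundle$events, file.path(dir, "events.csv"))
  write_dyadic_matrix(bundle$relatedness, file.path(dir, "relatedness.csv"))
  utils::write.csv(data.frame(id = rownames(bundle$wins), bundle$wins,
                              check.names = FALSE),
                   file.path(dir, "wins.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = rownames(bundle$presence), bundle$presence,
                              check.names = FALSE),
                   file.path(dir, "presence.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
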
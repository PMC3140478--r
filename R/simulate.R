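#' Simulation configuration
#'
#' Defines the ground truth of a synthetic study: group size, the
#' two-member small cooperation class, per-day presence probability,
#' latent dyadic association probabilities with a controllable mean and
#' coefficient of variation (the planted social differentiation),
#' dominance scores and the strength of rank-assortative partner choice.
#' All generators are pure functions of the configuration and its seed.
#'
#' Defaults mirror a typical study group: 10 individuals observed over 30
#' daily sampling periods, each individual found in the surroundings on
#' about 90\% of days, dyads together on about 20\% of joint days with a
#' differentiation of 0.4 (a moderately differentiated society).
#'
#' @param n_individuals group size (infants excluded).
#' @param n_small_class size of the small cooperation class (2 in the
#'   field design: one male and one female, one adult and one juvenile).
#' @param n_periods number of daily sampling periods.
#' @param presence_prob per-individual probability of being observable in
#'   the surroundings on a given day (scalar or per-individual vector).
#' @param scans_per_period scan samples per day (10-minute intervals over
#'   an 8-hour observation day gives 48).
#' @param events_per_period cooperation attempts generated per day.
#' @param encounters_per_dyad agonistic encounters per dyad for the
#'   dominance generator.
#' @param true_assoc_mean mean latent association probability
#'   \eqn{\mu_\alpha \in (0,1)}.
#' @param true_assoc_cv planted social differentiation \eqn{S \ge 0}:
#'   the coefficient of variation of the latent association
#'   probabilities. Must satisfy \eqn{S < \sqrt{(1-\mu)/\mu}}, the CV
#'   bound of a Beta distribution with mean \eqn{\mu}.
#' @param rank_scores ground-truth dominance scores, one per individual
#'   (default: evenly spaced on \eqn{[-2, 2]}, high first).
#' @param rank_assortment \eqn{\beta \ge 0}: strength of preference for
#'   similar-rank cooperation partners; 0 gives uniform partner choice.
#' @param n_matrilines number of matrilines for the kin generator.
#' @param community_partition optional ground-truth community labels.
#' @param seed RNG seed.
#' @return a validated \code{vnet_sim_config} list.
#' @export
sim_config <- function(n_individuals = 10,
                       n_small_class = 2,
                       n_periods = 30,
                       presence_prob = 0.9,
                       scans_per_period = 48,
                       events_per_period = 10,
                       encounters_per_dyad = 10,
                       true_assoc_mean = 0.2,
                       true_assoc_cv = 0.4,
                       rank_scores = NULL,
                       rank_assortment = 0,
                       n_matrilines = 3,
                       community_partition = NULL,
                       seed = 1) {
  stopifnot(n_individuals >= 3, n_small_class >= 1,
            n_small_class < n_individuals,
            n_periods >= 1, scans_per_period >= 1,
            all(presence_prob > 0), all(presence_prob <= 1),
            true_assoc_mean > 0, true_assoc_mean < 1,
            true_assoc_cv >= 0, rank_assortment >= 0)
  cv_bound <- sqrt((1 - true_assoc_mean) / true_assoc_mean)
  if (true_assoc_cv > 0 && true_assoc_cv >= cv_bound) {
    stop("true_assoc_cv infeasible for a Beta distribution with mean ",
         true_assoc_mean, ": the CV must be below sqrt((1-mu)/mu) = ",
         format(cv_bound))
  }
  if (is.null(rank_scores)) {
    rank_scores <- seq(2, -2, length.out = n_individuals)
  }
  stopifnot(length(rank_scores) == n_individuals)
  cfg <- list(n_individuals = n_individuals, n_small_class = n_small_class,
              n_periods = n_periods,
              presence_prob = rep(presence_prob,
                                  length.out = n_individuals),
              scans_per_period = scans_per_period,
              events_per_period = events_per_period,
              encounters_per_dyad = encounters_per_dyad,
              true_assoc_mean = true_assoc_mean,
              true_assoc_cv = true_assoc_cv,
              rank_scores = rank_scores,
              rank_assortment = rank_assortment,
              n_matrilines = n_matrilines,
              community_partition = community_partition,
              seed = seed)
  class(cfg) <- "vnet_sim_config"
  cfg
}

sim_ids <- function(cfg) sprintf("M%02d", seq_len(cfg$n_individuals))

#' Simulate per-day presence
#'
#' Presence is independent Bernoulli per individual-day by default; a
#' sticky two-state Markov variant with the same marginal probability is
#' available for temporally clumped absences.
#'
#' @param cfg a [sim_config()].
#' @param model \code{"iid"} (default) or \code{"markov"}.
#' @param stickiness for the Markov variant, probability of repeating the
#'   previous day's state beyond the marginal rate.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return an individuals x periods 0/1 matrix.
#' @export
simulate_presence <- function(cfg, model = c("iid", "markov"),
                              stickiness = 0.5, seed = NULL) {
  model <- match.arg(model)
  set_seed_if(seed %||% cfg$seed)
  n <- cfg$n_individuals
  np <- cfg$n_periods
  p <- cfg$presence_prob
  pres <- matrix(0L, n, np, dimnames = list(sim_ids(cfg),
                                            paste0("p", seq_len(np))))
  if (model == "iid") {
    pres[] <- rbinom(n * np, 1, rep(p, np))
  } else {
    pres[, 1] <- rbinom(n, 1, p)
    for (t in 2:np) {
      stay <- rbinom(n, 1, stickiness)
      pres[, t] <- ifelse(stay == 1, pres[, t - 1], rbinom(n, 1, p))
    }
  }
  pres
}

# Beta parameters from mean mu and coefficient of variation cv
beta_moments <- function(mu, cv) {
  v <- (mu * cv)^2
  nu <- mu * (1 - mu) / v - 1
  c(shape1 = mu * nu, shape2 = (1 - mu) * nu)
}

#' Simulate association data with known differentiation
#'
#' Latent dyadic association probabilities \eqn{\alpha_{ij}} are drawn
#' from a Beta distribution with mean \code{true_assoc_mean} and CV
#' \code{true_assoc_cv} (the planted differentiation; CV 0 makes all
#' dyads share \eqn{\mu_\alpha} exactly). Each day, each jointly present
#' dyad associates with probability \eqn{\alpha_{ij}}.
#'
#' @param cfg a [sim_config()].
#' @param presence optional presence matrix (simulated from \code{cfg}
#'   when omitted).
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return a list with \code{presence}, \code{occurrence} (a
#'   \code{vnet_occurrence}) and \code{alpha} (the ground-truth
#'   probability matrix).
#' @export
simulate_association_data <- function(cfg, presence = NULL, seed = NULL) {
  set_seed_if(seed %||% cfg$seed)
  n <- cfg$n_individuals
  ids <- sim_ids(cfg)
  if (is.null(presence)) {
    presence <- simulate_presence(cfg, seed = NA_seed_passthrough())
  }
  dy <- dyad_grid(n)
  nd <- nrow(dy)
  if (cfg$true_assoc_cv == 0) {
    av <- rep(cfg$true_assoc_mean, nd)
  } else {
    sh <- beta_moments(cfg$true_assoc_mean, cfg$true_assoc_cv)
    av <- rbeta(nd, sh[1], sh[2])
  }
  alpha <- matrix(0, n, n, dimnames = list(ids, ids))
  alpha[dy] <- av
  alpha[dy[, 2:1, drop = FALSE]] <- av
  pairs <- vector("list", cfg$n_periods)
  for (t in seq_len(cfg$n_periods)) {
    joint <- presence[dy[, 1], t] == 1L & presence[dy[, 2], t] == 1L
    hit <- joint & (runif(nd) < av)
    pairs[[t]] <- dy[hit, , drop = FALSE]
  }
  list(presence = presence,
       occurrence = dyadic_occurrence(presence, pairs, binary = TRUE),
       alpha = alpha)
}

# sentinel: generator was already seeded by the caller
NA_seed_passthrough <- function() NULL

empty_event_frame <- function() {
  data.frame(timestamp = character(0), kind = character(0),
             behaviour = character(0), actor = character(0),
             recipient = character(0), neighbour_distance_m = numeric(0),
             feeder_distance_m = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate a roster with classes, matrilines and siblings
#'
#' The small class holds \code{n_small_class} individuals chosen to span
#' the group: one male and one female, one adult and one juvenile, one of
#' high and one of low rank (matching the field assignment rule).
#' Matrilines partition the group; within a matriline the first member is
#' the matriarch (relatedness 0.5 to her offspring) and the remaining
#' members are siblings of one another (relatedness 0.25).
#'
#' @inheritParams simulate_presence
#' @return a \code{vnet_roster}.
#' @export
simulate_roster <- function(cfg, seed = NULL) {
  set_seed_if(seed %||% cfg$seed)
  n <- cfg$n_individuals
  ids <- sim_ids(cfg)
  sex <- sample(rep(c("M", "F"), length.out = n))
  age <- sample(rep(c("adult", "juvenile"), length.out = n))
  # small class: the highest-rank individual and a low-rank one of the
  # other sex and age class, if available
  hi <- which.max(cfg$rank_scores)
  lo_pool <- setdiff(order(cfg$rank_scores), hi)
  pick <- lo_pool[sex[lo_pool] != sex[hi] & age[lo_pool] != age[hi]]
  lo <- if (length(pick)) pick[1] else lo_pool[1]
  small <- c(hi, lo)[seq_len(min(cfg$n_small_class, 2))]
  if (cfg$n_small_class > 2) {
    small <- c(small, setdiff(sample(n), small)[seq_len(cfg$n_small_class - 2)])
  }
  coop <- ifelse(seq_len(n) %in% small, "small", "large")
  mat <- sort(rep_len(paste0("mat", seq_len(cfg$n_matrilines)), n))
  mat <- sample(mat)
  # maternal pedigree: within each matriline the first member is the
  # matriarch and each later member descends from an earlier one
  parent <- rep(NA_integer_, n)
  for (m in unique(mat)) {
    members <- which(mat == m)
    if (length(members) < 2) next
    for (i in 2:length(members)) {
      parent[members[i]] <- members[sample.int(i - 1, 1)]
    }
  }
  sibs <- character(n)
  for (k in seq_len(n)) {
    sh <- which(!is.na(parent) & parent == parent[k] & seq_len(n) != k)
    if (!is.na(parent[k]) && length(sh)) {
      sibs[k] <- paste(ids[sh], collapse = ";")
    }
  }
  roster <- as_roster(data.frame(id = ids, sex = sex, age_class = age,
                                 coop_class = coop, matriline = mat,
                                 siblings = sibs, group = "sim",
                                 stringsAsFactors = FALSE))
  attr(roster, "pedigree") <- stats::setNames(
    ifelse(is.na(parent), NA_character_, ids[parent]), ids)
  roster
}

#' Relatedness matrix implied by a simulated roster
#'
#' Reads the maternal pedigree drawn by [simulate_roster()] (stored as
#' the roster's \code{"pedigree"} attribute: each individual's mother, or
#' \code{NA} for a matriarch) and sets the coefficient of a
#' within-matriline dyad to \eqn{0.5^d}, where d is the distance between
#' the two individuals in the maternal tree: 0.5 for mother-offspring,
#' 0.25 for grandmother-grandoffspring and for siblings, and so on.
#' Between-matriline dyads are unrelated (0). This is a synthetic
#' pedigree-decay surrogate for marker-estimated coefficients, not a
#' full kinship calculation.
#'
#' @param cfg a [sim_config()] (unused beyond interface symmetry).
#' @param roster a roster from [simulate_roster()].
#' @return a \code{vnet_dyadic} of kind \code{"relatedness"}.
#' @export
simulate_relatedness <- function(cfg, roster) {
  ped <- attr(roster, "pedigree")
  if (is.null(ped)) stop("roster carries no pedigree attribute; use a ",
                         "roster from simulate_roster()")
  ids <- roster$id
  n <- length(ids)
  chain_of <- function(id) {
    chain <- id
    while (!is.na(ped[[id]])) {
      id <- ped[[id]]
      chain <- c(chain, id)
    }
    chain
  }
  chains <- lapply(ids, chain_of)
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (roster$matriline[a] != roster$matriline[b]) next
    ca <- chains[[a]]; cb <- chains[[b]]
    anc <- intersect(ca, cb)[1]  # lowest common maternal ancestor
    if (is.na(anc)) next
    dist <- (match(anc, ca) - 1) + (match(anc, cb) - 1)
    r[a, b] <- r[b, a] <- 0.5^dist
  }
  diag(r) <- 0
  dyadic_matrix(r, kind = "relatedness")
}

#' Simulate cooperation attempts under rank-assortative partner choice
#'
#' Cooperation events pair one present small-class member s with one
#' present large-class member l, chosen with probability proportional to
#' \eqn{\exp(-\beta |r_s - r_l| / \mathrm{range}(r))}. With \eqn{\beta =
#' 0} partner choice is uniform among present large-class members; large
#' \eqn{\beta} makes the rank-nearest partner the modal choice. Days on
#' which no small-class (or no large-class) member is present yield no
#' events. Events are emitted as \code{coop_attempt} bouts at the feeders
#' (feeder distance 0), spaced so that bout segmentation leaves them
#' intact.
#'
#' @inheritParams simulate_association_data
#' @param roster optional roster (simulated from \code{cfg} when omitted).
#' @return a \code{vnet_event_log} with attributes \code{presence} and
#'   \code{roster}.
#' @export
simulate_cooperation_events <- function(cfg, roster = NULL, presence = NULL,
                                        seed = NULL) {
  set_seed_if(seed %||% cfg$seed)
  if (is.null(roster)) roster <- simulate_roster(cfg, seed = NA_seed_passthrough())
  if (is.null(presence)) presence <- simulate_presence(cfg, seed = NA_seed_passthrough())
  ids <- roster$id
  small <- which(roster$coop_class == "small")
  large <- which(roster$coop_class == "large")
  r <- cfg$rank_scores
  rr <- max(r) - min(r)
  if (rr == 0) rr <- 1
  beta <- cfg$rank_assortment
  rows <- vector("list", cfg$n_periods)
  day0 <- as.Date("2008-07-01")
  for (t in seq_len(cfg$n_periods)) {
    sp <- small[presence[small, t] == 1L]
    lp <- large[presence[large, t] == 1L]
    if (length(sp) == 0 || length(lp) == 0) next
    s_pick <- sp[sample.int(length(sp), cfg$events_per_period, replace = TRUE)]
    l_pick <- vapply(s_pick, function(s) {
      w <- exp(-beta * abs(r[s] - r[lp]) / rr)
      lp[sample.int(length(lp), 1, prob = w)]
    }, integer(1))
    times <- 7 * 3600 + seq_len(length(s_pick)) * 60  # one event a minute
    rows[[t]] <- data.frame(
      timestamp = format(as.POSIXct(day0 + (t - 1), tz = "UTC") + times,
                         "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      kind = "bout", behaviour = "coop_attempt",
      actor = ids[s_pick], recipient = ids[l_pick],
      neighbour_distance_m = 0.5, feeder_distance_m = 0,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else empty_event_frame()
  log <- as_event_log(df)
  attr(log, "presence") <- presence
  attr(log, "roster") <- roster
  log
}

#' Simulate a directed agonistic win-count matrix
#'
#' Each dyad meets \code{encounters_per_dyad} times; in each encounter
#' individual i beats j with probability
#' \eqn{\mathrm{logit}^{-1}(r_i - r_j)}. Equal ranks give 50/50 outcomes;
#' an infinite rank gap makes the upper individual win every encounter.
#'
#' @inheritParams simulate_presence
#' @return a directed integer matrix \code{wins} with \code{wins[i, j]} =
#'   number of times i beat j.
#' @export
simulate_agonistic_matrix <- function(cfg, seed = NULL) {
  set_seed_if(seed %||% cfg$seed)
  n <- cfg$n_individuals
  ids <- sim_ids(cfg)
  r <- cfg$rank_scores
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  dy <- dyad_grid(n)
  for (k in seq_len(nrow(dy))) {
    i <- dy[k, 1]; j <- dy[k, 2]
    pij <- stats::plogis(r[i] - r[j])
    wij <- rbinom(1, cfg$encounters_per_dyad, pij)
    wins[i, j] <- wij
    wins[j, i] <- cfg$encounters_per_dyad - wij
  }
  wins
}
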
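#' Run the full analysis pipeline
#'
#' One-command reproduction of the analysis shape of the induced-
#' cooperation study on any dataset in the package's raw formats:
#' per-condition networks, differentiation estimates with bootstrap SEs
#' (the differentiation table), presence-constrained preferred/avoided
#' association tests, the partner-choice Mantel grid (sex, age, rank,
#' relatedness, and relatedness controlling for matriline and siblings,
#' each against feeding proximity and cooperation), David's Scores, and
#' Ward dendrograms with Newman communities for the proximity and
#' cooperation networks. Runs each group found in the roster; a stage
#' failure in one group is recorded and the remaining groups still run,
#' but the call errors at the end if any stage failed.
#'
#' @param config a YAML file path or a list with elements:
#'   \describe{
#'     \item{roster}{path to roster.csv (required)}
#'     \item{events}{path to events.csv (required)}
#'     \item{relatedness}{optional path to a relatedness matrix CSV}
#'     \item{wins}{optional path to a directed agonistic count matrix
#'       CSV; when absent, wins are tallied from aggression/submission
#'       bouts near the feeders}
#'     \item{thresholds}{optional list: \code{max_nn_m} (10),
#'       \code{min_feeder_m} (10), \code{max_feeder_agonistic_m} (5)}
#'     \item{n_perm, n_boot}{replicate counts (default 10000)}
#'     \item{seed}{master seed; stage seeds derive from it}
#'   }
#' @param out_dir output directory; when non-NULL, writes
#'   \code{report.json}, \code{table1.csv}, \code{table2.csv}, Newick
#'   dendrograms, community CSVs and GraphML networks.
#' @param seed overrides \code{config$seed}.
#' @return the report (a list), invisibly when \code{out_dir} is set.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  seed <- cfg$seed %||% 1
  th <- cfg$thresholds
  n_perm <- cfg$n_perm %||% 10000
  n_boot <- cfg$n_boot %||% 10000

  roster_all <- read_roster(cfg$roster)
  events_all <- read_event_log(cfg$events, roster = roster_all)
  relatedness <- if (!is.null(cfg$relatedness)) {
    read_dyadic_matrix(cfg$relatedness, kind = "relatedness")
  }
  wins_all <- if (!is.null(cfg$wins)) read_counts_csv(cfg$wins)

  report <- list(meta = list(seed = seed, n_perm = n_perm, n_boot = n_boot,
                             config_hash = config_hash(cfg),
                             thresholds = th))
  failures <- character(0)
  for (grp in unique(roster_all$group)) {
    res <- tryCatch(
      run_group(grp, roster_all, events_all, relatedness, wins_all,
                th, n_perm, n_boot, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(grp, ": ", conditionMessage(res)))
      report$groups[[grp]] <- list(error = conditionMessage(res))
    } else {
      report$groups[[grp]] <- res
    }
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  if (length(failures)) {
    stop("pipeline stage failure(s):\n  ", paste(failures, collapse = "\n  "))
  }
  if (is.null(out_dir)) report else invisible(report)
}

load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg), !is.null(cfg$roster), !is.null(cfg$events))
  cfg$thresholds <- utils::modifyList(
    list(max_nn_m = 10, min_feeder_m = 10, max_feeder_agonistic_m = 5),
    cfg$thresholds %||% list())
  cfg
}

read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

# one group: networks -> differentiation -> permutation tests ->
# Mantel grid -> dominance -> clustering
run_group <- function(grp, roster_all, events_all, relatedness, wins_all,
                      th, n_perm, n_boot, seed) {
  roster <- roster_all[roster_all$group == grp, , drop = FALSE]
  class(roster) <- class(roster_all)
  ids <- roster$id
  keep <- events_all$actor %in% ids &
    (is.na(events_all$recipient) | events_all$recipient %in% ids)
  log <- events_all[keep, , drop = FALSE]
  class(log) <- class(events_all)
  if (!nrow(log)) stop("no events for group ", grp)
  presence <- presence_from_log(log, roster)

  nets <- list(
    proximity = proximity_association(log, presence,
                                      max_nn_m = th$max_nn_m,
                                      min_feeder_m = th$min_feeder_m),
    affiliative = interaction_rate(log, AFFILIATIVE_BEHAVIOURS, presence),
    cooperation = cooperation_network(log, presence))

  table1 <- do.call(rbind, lapply(seq_along(nets), function(i) {
    tryCatch(
      estimate_differentiation(nets[[i]], n_boot = n_boot,
                               seed = derive_seed(seed, i)),
      error = function(e) {
        pres <- nets[[i]]$occurrence$presence
        data.frame(condition = nets[[i]]$condition,
                   individuals = sum(rowSums(pres) > 0),
                   mean_identified_per_period = mean(colSums(pres)),
                   sampling_periods = ncol(pres),
                   n_events = nets[[i]]$n_events,
                   social_differentiation = NA_real_, se = NA_real_,
                   classification = NA_character_, n_boot = n_boot,
                   stringsAsFactors = FALSE)
      })
  }))
  table1 <- cbind(group = grp, table1)

  permtests <- lapply(seq_along(nets), function(i) {
    pt <- tryCatch(
      withCallingHandlers(
        preferred_association_test(nets[[i]]$occurrence, n_perm = n_perm,
                                   seed = derive_seed(seed, 10 + i)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) data.frame(statistic = NA_character_,
                                     stat_real = NA_real_,
                                     stat_null_mean = NA_real_,
                                     stat_null_sd = NA_real_, p = NA_real_,
                                     n_perm = n_perm,
                                     stringsAsFactors = FALSE))
    as.data.frame(pt)
  })
  names(permtests) <- names(nets)

  # dominance
  wins <- if (!is.null(wins_all)) {
    wins_all[intersect(rownames(wins_all), ids),
             intersect(colnames(wins_all), ids), drop = FALSE]
  } else {
    wins_from_log(log, roster, max_feeder_m = th$max_feeder_agonistic_m)
  }
  dominance <- davids_score(wins)

  # Mantel grid
  mask <- between_class_mask(roster)
  classes <- stats::setNames(roster$coop_class, ids)
  cond_mats <- list(
    feeding_proximity = nets$proximity$matrix$values,
    cooperation = nets$cooperation$matrix$values)
  ds_full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  ds_full[names(dominance$ds)] <- dominance$ds
  ds_full[is.na(ds_full)] <- 0
  attr_mats <- list(
    sex = similarity_indicator(roster, "sex")$values,
    age = similarity_indicator(roster, "age_class")$values,
    rank = rank_similarity(ds_full)$values)
  rel_mat <- NULL
  rel_mask <- mask$values
  if (!is.null(relatedness)) {
    rel_mat <- matrix(NA_real_, length(ids), length(ids),
                      dimnames = list(ids, ids))
    common <- intersect(ids, rownames(relatedness$values))
    rel_mat[common, common] <- relatedness$values[common, common]
    missing_ids <- setdiff(ids, common)
    if (length(missing_ids)) {
      rel_mask[missing_ids, ] <- 0
      rel_mask[, missing_ids] <- 0
    }
  }
  grid <- list()
  for (cond in names(cond_mats)) {
    A <- cond_mats[[cond]]
    for (att in names(attr_mats)) {
      grid[[length(grid) + 1]] <- mantel_row(
        grp, cond, att, A, attr_mats[[att]], mask$values, classes,
        n_perm, derive_seed(seed, 100 + length(grid)))
    }
    if (!is.null(rel_mat)) {
      grid[[length(grid) + 1]] <- mantel_row(
        grp, cond, "relatedness", A, rel_mat, rel_mask, classes,
        n_perm, derive_seed(seed, 100 + length(grid)))
      controls <- list(matriline = matriline_indicator(roster)$values,
                       siblings = sibling_indicator(roster)$values)
      grid[[length(grid) + 1]] <- mantel_row(
        grp, cond, "relatedness_ctrl_matriline_siblings", A, rel_mat,
        rel_mask, classes, n_perm, derive_seed(seed, 100 + length(grid)),
        controls = controls)
    }
  }
  table2 <- do.call(rbind, grid)

  # structure: dendrograms + communities for proximity and cooperation
  structure_out <- lapply(c("proximity", "cooperation"), function(cond) {
    net <- nets[[cond]]
    vals <- net$matrix$values
    if (all(is.na(vals) | vals == 0)) return(list(skipped = "empty network"))
    dend <- ward_dendrogram(net$matrix, normalise = net$occurrence$d)
    comm <- newman_communities(net$matrix)
    list(dendrogram = dend, communities = comm)
  })
  names(structure_out) <- c("proximity", "cooperation")

  list(roster_n = nrow(roster),
       small_class = ids[roster$coop_class == "small"],
       table1 = table1, permtests = permtests, table2 = table2,
       dominance = dominance, networks = nets, structure = structure_out)
}

mantel_row <- function(grp, cond, identity, A, B, mask, classes, n_perm,
                       seed, controls = NULL) {
  n_small <- sum(classes == "small")
  n_large <- sum(classes == "large")
  res <- tryCatch({
    if (is.null(controls)) {
      mantel_test(A, B, mask = mask, classes = classes, n_perm = n_perm,
                  seed = seed)
    } else {
      partial_mantel_test(A, B, controls = controls, mask = mask,
                          classes = classes, n_perm = n_perm, seed = seed)
    }
  }, error = function(e) e)
  if (inherits(res, "error")) {
    data.frame(group = grp, condition = cond, identity = identity,
               class_sizes = paste0(n_small, "/", n_large),
               p = NA_real_, mcc = NA_real_, n_dyads = NA_integer_,
               note = conditionMessage(res), stringsAsFactors = FALSE)
  } else {
    data.frame(group = grp, condition = cond, identity = identity,
               class_sizes = paste0(n_small, "/", n_large),
               p = res$p, mcc = res$mcc, n_dyads = res$n_dyads,
               note = "", stringsAsFactors = FALSE)
  }
}

#' Tally a directed win matrix from agonistic bouts
#'
#' Aggression bouts score a win for the actor; submission bouts score a
#' win for the recipient. Only bouts started within
#' \code{max_feeder_m} of the feeders are used (records with no feeder
#' distance are excluded).
#'
#' @param log a \code{vnet_event_log}.
#' @param roster a \code{vnet_roster}.
#' @param max_feeder_m feeder radius in metres.
#' @return a directed count matrix over the roster ids.
#' @export
wins_from_log <- function(log, roster, max_feeder_m = 5) {
  ids <- roster$id
  ag <- log[log$behaviour %in% c("aggression", "submission") &
              !is.na(log$recipient) &
              !is.na(log$feeder_distance_m) &
              log$feeder_distance_m <= max_feeder_m, , drop = FALSE]
  wins <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(ag)) {
    winner <- ifelse(ag$behaviour == "aggression", ag$actor, ag$recipient)
    loser <- ifelse(ag$behaviour == "aggression", ag$recipient, ag$actor)
    tab <- table(factor(winner, ids), factor(loser, ids))
    wins[] <- as.integer(tab)
  }
  wins
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- do.call(rbind, lapply(report$groups, function(g) g$table1))
  t2 <- do.call(rbind, lapply(report$groups, function(g) g$table2))
  if (!is.null(t1)) utils::write.csv(t1, file.path(out_dir, "table1.csv"),
                                     row.names = FALSE)
  if (!is.null(t2)) utils::write.csv(t2, file.path(out_dir, "table2.csv"),
                                     row.names = FALSE)
  for (grp in names(report$groups)) {
    g <- report$groups[[grp]]
    if (!is.null(g$error)) next
    for (cond in names(g$structure)) {
      s <- g$structure[[cond]]
      if (!is.null(s$dendrogram)) {
        write_dendrogram_newick(
          s$dendrogram,
          file.path(out_dir, paste0("dendrogram_", grp, "_", cond, ".nwk")))
        write_communities(
          s$communities,
          file.path(out_dir, paste0("communities_", grp, "_", cond, ".csv")))
      }
      net <- g$networks[[cond]]
      export_graphml(net$matrix,
                     file.path(out_dir, paste0("network_", grp, "_", cond,
                                               ".graphml")))
    }
  }
  jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# reduce the report to JSON-friendly pieces (drop heavy S3 internals)
report_json <- function(report) {
  out <- list(meta = report$meta)
  for (grp in names(report$groups)) {
    g <- report$groups[[grp]]
    if (!is.null(g$error)) {
      out$groups[[grp]] <- list(error = g$error)
      next
    }
    out$groups[[grp]] <- list(
      n_individuals = g$roster_n,
      small_class = g$small_class,
      differentiation = g$table1,
      permutation_tests = g$permtests,
      mantel = g$table2,
      davids_score = as.list(round(g$dominance$ds, 10)),
      structure = lapply(g$structure, function(s) {
        if (!is.null(s$skipped)) return(list(skipped = s$skipped))
        list(cophenetic = s$dendrogram$cophenetic_coefficient,
             cophenetic_fit = cophenetic_fit(
               s$dendrogram$cophenetic_coefficient),
             modularity = s$communities$q,
             communities = as.list(s$communities$membership))
      }))
  }
  out
}

#' Validate pipeline inputs
#'
#' Cross-checks the roster against the event log and optional matrices
#' before a run: duplicated ids are fatal; other findings (event ids not
#' on the roster, groups without exactly two small-class members,
#' individuals missing from the relatedness matrix — whose dyads will be
#' masked from the relatedness tests) are warnings.
#'
#' @param config as in [run_pipeline()].
#' @return a \code{vnet_validation} list with \code{errors} and
#'   \code{warnings} character vectors.
#' @export
validate_inputs <- function(config) {
  cfg <- load_pipeline_config(config)
  errors <- character(0)
  warnings <- character(0)

  roster_df <- utils::read.csv(cfg$roster, stringsAsFactors = FALSE)
  dup <- unique(roster_df$id[duplicated(roster_df$id)])
  if (length(dup)) {
    errors <- c(errors, paste0("duplicated roster ids: ",
                               paste(dup, collapse = ", ")))
  }
  roster <- if (!length(dup)) as_roster(roster_df)
  if (!is.null(roster)) {
    for (grp in unique(roster$group)) {
      ns <- sum(roster$coop_class[roster$group == grp] == "small")
      if (ns != 2) {
        warnings <- c(warnings, paste0(
          "group ", grp, " has ", ns, " small-class members (the design ",
          "uses 2); cooperation analyses will still run"))
      }
    }
    log <- suppressMessages(read_event_log(cfg$events))
    ev_ids <- unique(c(log$actor, log$recipient[!is.na(log$recipient)]))
    unknown <- setdiff(ev_ids, roster$id)
    if (length(unknown)) {
      warnings <- c(warnings, paste0("event ids not on roster (records ",
                                     "will be dropped): ",
                                     paste(unknown, collapse = ", ")))
    }
    if (!is.null(cfg$relatedness)) {
      rel <- read_dyadic_matrix(cfg$relatedness, kind = "relatedness")
      missing_ids <- setdiff(roster$id, rownames(rel$values))
      if (length(missing_ids)) {
        warnings <- c(warnings, paste0(
          "relatedness coefficients missing for: ",
          paste(missing_ids, collapse = ", "),
          "; their dyads are masked from the relatedness tests"))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings),
            class = "vnet_validation")
}

#' @export
print.vnet_validation <- function(x, ...) {
  cat("<input validation> ", length(x$errors), " error(s), ",
      length(x$warnings), " warning(s)\n", sep = "")
  for (e in x$errors) cat("  ERROR: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
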
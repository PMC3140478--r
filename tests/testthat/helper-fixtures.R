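# Small fixtures built in code.

tiny_roster <- function(n = 7, n_small = 2, group = "g1") {
  ids <- sprintf("V%02d", seq_len(n))
  as_roster(data.frame(
    id = ids,
    sex = rep(c("F", "M"), length.out = n),
    age_class = rep(c("adult", "juvenile"), length.out = n),
    coop_class = c(rep("small", n_small), rep("large", n - n_small)),
    matriline = rep(c("A", "B"), length.out = n),
    siblings = "",
    group = group,
    stringsAsFactors = FALSE))
}

event_csv_lines <- function(rows) {
  header <- "timestamp,kind,behaviour,actor,recipient,neighbour_distance_m,feeder_distance_m"
  c(header, rows)
}

write_event_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(event_csv_lines(rows), path)
  path
}

# occurrence with explicit per-period dyads over n individuals
occ_from_lists <- function(n, n_periods, dyads_by_period,
                           presence = NULL, binary = TRUE) {
  if (is.null(presence)) {
    presence <- matrix(1L, n, n_periods,
                       dimnames = list(sprintf("V%02d", seq_len(n)), NULL))
  }
  pairs <- lapply(seq_len(n_periods), function(t) {
    p <- dyads_by_period[[t]]
    if (is.null(p)) matrix(integer(0), 0, 2) else p
  })
  dyadic_occurrence(presence, pairs, binary = binary)
}

# a random symmetric non-negative weight matrix with zero diagonal
random_weight_matrix <- function(n, density = 0.6) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  w <- stats::runif(sum(ut))
  w[stats::runif(sum(ut)) > density] <- 0
  m[ut] <- w
  m <- m + t(m)
  dimnames(m) <- list(sprintf("V%02d", seq_len(n)), sprintf("V%02d", seq_len(n)))
  m
}
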
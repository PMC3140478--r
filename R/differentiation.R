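#' Social differentiation
#'
#' Estimates the coefficient of variation of the latent dyadic
#' association probabilities — how varied the social system is — by
#' removing an estimate of the binomial sampling variance from the
#' coefficient of variation of the observed association indices
#' (method-of-moments estimator in the style of Whitehead's appendix).
#'
#' With \eqn{\hat\alpha_{ij} = x_{ij}/d_{ij}} and \eqn{\bar\alpha}
#' the \eqn{d_{ij}}-weighted mean,
#' \deqn{S^2 = \max\!\left(0,\;
#'   \frac{\mathrm{var}_w(\hat\alpha) - \overline{\hat\alpha(1-\hat\alpha)/d}}
#'        {\bar\alpha^2}\right), \qquad S = \sqrt{S^2}.}
#' Dyads never jointly observable (\eqn{d_{ij} = 0}) are excluded.
#'
#' As a rule of thumb, S below 0.3 describes a rather homogeneous
#' society, 0.5 to 2.0 a well differentiated one, and above 2.0 an
#' extremely differentiated one.
#'
#' @param occ a \code{vnet_occurrence}. For bout-count occurrences the
#'   per-period layer is first reduced to binary periods-together, so the
#'   index stays a proportion.
#' @return the estimate S (non-negative scalar).
#' @export
social_differentiation <- function(occ) {
  stopifnot(inherits(occ, "vnet_occurrence"))
  x <- ut_vec(binary_x(occ))
  d <- ut_vec(occ$d)
  ok <- d > 0
  if (sum(ok) < 2) stop("need at least 2 dyads with joint observability")
  x <- x[ok]; d <- d[ok]
  if (sum(x) == 0) stop("no associations observed: differentiation undefined")
  a <- x / d
  abar <- sum(x) / sum(d)
  wvar <- sum(d * (a - abar)^2) / sum(d)
  samp <- mean(a * (1 - a) / d)
  sqrt(max(0, wvar - samp)) / abar
}

# periods-together counts regardless of the occurrence's count layer
binary_x <- function(occ) {
  if (occ$binary) return(occ$x)
  n <- length(occ$ids)
  ii <- jj <- vector("list", length(occ$pairs))
  for (t in seq_along(occ$pairs)) {
    p <- occ$pairs[[t]]
    if (is.null(p) || nrow(p) == 0) next
    ii[[t]] <- pmin(p[, 1], p[, 2])
    jj[[t]] <- pmax(p[, 1], p[, 2])
  }
  i <- unlist(ii); j <- unlist(jj)
  accumulate_dyads(i, j, rep(1, length(i)), n, occ$ids)
}

#' Interpret a social differentiation value
#'
#' Rule-of-thumb classification: below 0.3 homogeneous (all individuals
#' on average well connected to all others), 0.3 to 0.5 intermediate,
#' 0.5 to 2.0 well differentiated (sub-units of individuals clump
#' together), above 2.0 extremely differentiated.
#'
#' @param S a differentiation estimate.
#' @return one of \code{"homogeneous"}, \code{"intermediate"},
#'   \code{"well_differentiated"}, \code{"extreme"}.
#' @export
classify_differentiation <- function(S) {
  stopifnot(is.numeric(S), all(S >= 0))
  # below 0.3 homogeneous; 0.5 up to and including 2.0 well
  # differentiated; only values beyond 2.0 are extreme
  ifelse(S < 0.3, "homogeneous",
         ifelse(S < 0.5, "intermediate",
                ifelse(S <= 2.0, "well_differentiated", "extreme")))
}

#' Bootstrap standard error over sampling periods
#'
#' Resamples sampling periods (days) with replacement, recomputes the
#' statistic on each replicate, and reports the standard deviation across
#' replicates. Replicates on which the statistic is undefined (an error
#' or \code{NA}) are dropped and counted; more than half undefined is an
#' error advising more data.
#'
#' @param occ a \code{vnet_occurrence}.
#' @param statistic a function of a \code{vnet_occurrence} returning a
#'   scalar, e.g. [social_differentiation()].
#' @param n_boot number of bootstrap replicates (10000 in the field
#'   analysis).
#' @param seed RNG seed.
#' @return the bootstrap SE, with attributes \code{n_boot} and
#'   \code{n_undefined}.
#' @export
bootstrap_se <- function(occ, statistic, n_boot = 10000, seed = NULL) {
  stopifnot(inherits(occ, "vnet_occurrence"))
  np <- ncol(occ$presence)
  if (np < 2) stop("need at least 2 sampling periods to bootstrap")
  set_seed_if(seed)
  draws <- matrix(sample.int(np, np * n_boot, replace = TRUE), np, n_boot)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- draws[, b]
    rocc <- resample_periods(occ, idx)
    tryCatch(as.numeric(statistic(rocc)), error = function(e) NA_real_)
  }, numeric(1))
  bad <- sum(is.na(vals))
  if (bad > n_boot / 2) {
    stop("statistic undefined on ", bad, "/", n_boot,
         " bootstrap replicates; more data are needed")
  }
  se <- stats::sd(vals[!is.na(vals)])
  structure(se, n_boot = n_boot, n_undefined = bad)
}

# occurrence restricted to a resampled vector of period indices
resample_periods <- function(occ, idx) {
  dyadic_occurrence(occ$presence[, idx, drop = FALSE],
                    occ$pairs[idx], binary = occ$binary)
}

#' Differentiation estimate with bootstrap SE for one condition network
#'
#' Produces one row of the differentiation table: individuals seen, mean
#' identified per period, periods, number of associations or
#' interactions, S and its bootstrap SE.
#'
#' @param net a \code{vnet_network}.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return a one-row data.frame.
#' @export
estimate_differentiation <- function(net, n_boot = 10000, seed = NULL) {
  stopifnot(inherits(net, "vnet_network"))
  occ <- net$occurrence
  S <- social_differentiation(occ)
  se <- bootstrap_se(occ, social_differentiation, n_boot = n_boot,
                     seed = seed)
  pres <- occ$presence
  data.frame(condition = net$condition,
             individuals = sum(rowSums(pres) > 0),
             mean_identified_per_period = mean(colSums(pres)),
             sampling_periods = ncol(pres),
             n_events = net$n_events,
             social_differentiation = S,
             se = as.numeric(se),
             classification = classify_differentiation(S),
             n_boot = n_boot,
             stringsAsFactors = FALSE)
}
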
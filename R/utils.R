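#' @keywords internal
"_PACKAGE"

# linear index of the unordered dyad (i, j) in upper-triangle
# column-major order, i.e. the position of cell (min, max) in
# m[upper.tri(m)] — every dyad-vector in the package uses this order
dyad_index <- function(i, j, n) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  ((b - 1L) * (b - 2L)) %/% 2L + a
}

# all unordered dyads over n individuals, as a 2-column integer matrix,
# in the same upper-triangle column-major order as dyad_index()
dyad_grid <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  j <- rep.int(2:n, 1:(n - 1L))
  i <- sequence(1:(n - 1L))
  cbind(i = i, j = j)
}

# upper-triangle vector of a square matrix
ut_vec <- function(m) m[upper.tri(m)]

# deterministic polynomial hash of an R object's deparsed form,
# used to stamp reports with a config fingerprint
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# seed handling: every stochastic entry point calls this once
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  invisible(NULL)
}

# derive a stage seed from a master seed, staying inside 32-bit range
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1000003 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
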
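# Internal helpers shared across modules.

# Deterministic sub-seed for a (subject, modality, run) unit, derived from the
# master seed by a multiplicative integer hash of the identifying strings.
# Stable under re-ordering of generation; result always in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (part in unlist(list(...))) {
    for (code in utf8ToInt(as.character(part))) {
      # 48271: minimal-standard Lehmer multiplier; all arithmetic < 2^53
      h <- (h * 48271 + code) %% m
    }
    h <- (h * 48271 + 7919) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_square_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop2(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop2(what, " must be symmetric")
  invisible(m)
}
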
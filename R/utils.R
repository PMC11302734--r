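# Internal helpers: validation and seeded RNG streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

stop_validation <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a sub-stream seed from a global seed
#'
#' All randomized operations in the package draw from streams derived from a
#' single user-facing seed, so that the whole simulation/analysis is
#' reproducible from one integer while independent stages do not share or
#' disturb each other's draws. The derivation is a fixed multiplicative hash
#' modulo the Mersenne prime 2^31 - 1, so the result is always a valid
#' 32-bit seed.
#'
#' @param seed integer global seed.
#' @param stream integer stream index (each randomized operation uses its own
#'   documented index).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("'seed' must be a single non-missing integer")
  }
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  # two LCG-style mixing rounds keep nearby (seed, stream) pairs decorrelated
  s <- (s * 48271 + as.numeric(stream) * 1299721 + 12345) %% m
  s <- (s * 69621 + 331) %% m
  as.integer(s + 1)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Check a length-2 numeric range with min < max.
check_range <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] >= x[2]) {
    stop_config(field, "must be a numeric [min, max] range with min < max")
  }
  invisible(x)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}
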
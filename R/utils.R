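# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Keeps every generator a pure function of its seed
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and a stream label, so the separate
# random components of a world (field, smoke, noise, ...) are independent but
# all reproducible from the one user-facing seed.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
  }
}

# Day-of-year / month helpers (365-day phase convention, see encode_time()).
date_doy <- function(date) as.POSIXlt(date)$yday + 1L
date_month <- function(date) as.POSIXlt(date)$mon + 1L
date_year <- function(date) as.POSIXlt(date)$year + 1900L
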
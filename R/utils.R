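# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All package randomness flows through this so that no
# function leaves global RNG side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %s", name, min)
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x))
    stopf("'%s' must be a single number", name)
  if (strict && x <= min) stopf("'%s' must be > %s", name, min)
  if (!strict && x < min) stopf("'%s' must be >= %s", name, min)
  as.numeric(x)
}

# Polynomial rolling hash (mod 2^31-1) of a serialized R object. Used to
# stamp output tables with a provenance hash of the run configuration;
# stable within an R version, not a cryptographic digest.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}
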
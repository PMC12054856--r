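# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject substream: keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483629) + 1L
}

format_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

parse_iso <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable timestamp at row %d: '%s'", bad[1], x[bad[1]]),
         call. = FALSE)
  }
  t
}

# "23:00" -> minutes since midnight
clock_to_minutes <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

stopifnot_scalar_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
}
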
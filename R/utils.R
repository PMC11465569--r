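# Set the RNG seed for the duration of the calling function, restoring the
# caller's RNG state when it exits. Keeps package functions deterministic
# given their `seed` argument without clobbering the user's stream.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call("on.exit", list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# Deterministic child seed for a keyed sub-task (e.g. one temporal cell), so
# per-cell results do not depend on iteration order. Linear-congruential hash
# kept below 2^31 - 1.
child_seed <- function(master_seed, ...) {
  key <- c(as.integer(master_seed), as.integer(c(...)))
  m <- 2147483647
  h <- 0
  for (k in key) h <- (h * 69069 + (as.double(k) %% m) + 1) %% m
  as.integer(h)
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a == -pi, pi, a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse ISO-8601 / space-separated UTC timestamps
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
}
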
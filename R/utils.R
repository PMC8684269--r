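# internal helpers shared across modules

# run code under a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic stage seeds derived from a master seed; stays inside the
# 32-bit integer range R requires of set.seed()
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483629)
}

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
}

format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
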
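`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed from a master seed plus mixed-type labels.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    pv <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 48271 + pv) %% 2147483647
  }
  as.integer(h)
}

as_utc_time <- function(time) {
  if (is.character(time)) {
    time <- as.POSIXct(time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                      "%Y-%m-%d"))
  }
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct or an ISO 8601 string")
  if (anyNA(time)) stop("invalid timestamp")
  attr(time, "tzone") <- "UTC"
  time
}

time_year <- function(time) as.integer(format(time, "%Y", tz = "UTC"))
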
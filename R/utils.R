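# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seed derivation: every generator draws from its own
# seed so adding a stream never perturbs another. Kept below 2^31 - 1.
substream <- function(seed, k) {
  ((seed %% 1000000L) * 2099 + k * 131 + 7) %% 2147483647
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# Hours of [from, to] falling inside the nightly window [night_start, 24) U
# [0, night_end). Exact interval arithmetic, iterated per calendar night.
night_hours <- function(from, to, night_start = 18, night_end = 6) {
  from <- as_utc(from); to <- as_utc(to)
  if (to <= from) return(0)
  day0 <- as.POSIXct(trunc(from - 86400, units = "days"), tz = "UTC")
  total <- 0
  d <- day0
  while (d < to) {
    ns <- d + night_start * 3600
    ne <- d + (24 + night_end) * 3600
    ov <- min(as.numeric(to), as.numeric(ne)) - max(as.numeric(from), as.numeric(ns))
    if (ov > 0) total <- total + ov
    d <- d + 86400
  }
  total / 3600
}

is_night_hour <- function(hour, night_start = 18, night_end = 6) {
  hour >= night_start | hour < night_end
}
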
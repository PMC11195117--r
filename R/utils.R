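# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Poisson process on [0, duration) thinned so consecutive points are at
# least min_gap apart (earlier point wins). Used for simulated event trains
# so that downstream peak matching is unambiguous.
rpoisson_train <- function(rate, duration, min_gap = 1) {
  if (rate <= 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * duration)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, 0, duration))
  if (min_gap > 0 && length(t) > 1L) {
    keep <- rep(TRUE, length(t))
    last <- t[1L]
    for (i in seq_along(t)[-1L]) {
      if (t[i] - last < min_gap) keep[i] <- FALSE else last <- t[i]
    }
    t <- t[keep]
  }
  t
}

# deterministic substream seeds derived from one master seed (kept < 2^31)
substream_seed <- function(seed, stream) {
  offsets <- c(behavior = 101L, fluorescence = 211L, structure = 307L,
               analysis = 401L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 2000000000L) + offsets[[stream]]
}
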
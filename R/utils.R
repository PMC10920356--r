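# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Count rise-fall excursions of a rate trace
#'
#' Counts the number of contiguous excursions of a (population) firing-rate
#' trace above the mid-line between its minimum and maximum, after a light
#' moving-average smoothing.  Used to check that a raster phase-locked to a
#' k-petal target produces exactly k rise-fall excursions of the population
#' rate per trial.
#'
#' @param rate numeric vector of rate samples (Hz), evenly spaced in time.
#' @param smooth width (in samples) of the centered moving average applied
#'   before counting; 1 disables smoothing.
#' @param frac threshold position between the trace minimum (0) and maximum
#'   (1); an excursion is a maximal run of samples above the threshold.
#' @return integer number of excursions (0 for a flat trace).
#' @export
count_rate_peaks <- function(rate, smooth = 3, frac = 0.5) {
  stopifnot(is.numeric(rate), length(rate) >= 3, smooth >= 1)
  x <- as.numeric(rate)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    xs <- stats::filter(x, k, sides = 2)
    x <- as.numeric(xs)
    x <- x[!is.na(x)]
  }
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(0L)
  thr <- rng[1] + frac * diff(rng)
  above <- x > thr
  sum(diff(c(FALSE, above)) == 1L)
}
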
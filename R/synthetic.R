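# Surrogate spike rasters with the statistical structure of the trained
# networks: per-neuron rates in a 20-80 Hz band and phase-locked "petal"
# modulation with k distinct active phases per 1 s trial.

#' Specification of a surrogate petal-modulated raster
#'
#' Each neuron is assigned to one of `k` petals and fires as an
#' inhomogeneous Poisson process whose rate is a baseline plus a smooth
#' bump centered on its petal's time window:
#' `lambda_i(t) = base + depth * max(0, cos(2 pi (t - c_i)/T))^c`,
#' where `c_i` is the petal center plus a small phase jitter and the
#' concentration exponent `c` narrows the bump so that the k petal
#' populations are active in distinct phases.  `depth` is scaled so the
#' population-averaged rate peaks at the top of `rate_band` while the
#' baseline sits at its bottom; the population rate therefore makes exactly
#' `k` rise-fall excursions per trial.
#'
#' @param n_neurons number of neurons.
#' @param duration trial length T (s).
#' @param petals number of petals k (1-4; 1 with `modulation = 0` gives a
#'   homogeneous raster at the mid-band rate).
#' @param rate_band `(low, high)` population rate band in Hz (baseline and
#'   population peak).
#' @param phase_concentration bump sharpening exponent `c`; default `2 k^2`
#'   (wider than a petal window for small k, clearly separated phases for
#'   k >= 2).
#' @param phase_jitter standard deviation of the per-neuron phase jitter,
#'   in radians on the trial circle.
#' @param modulation 0 disables the petal modulation (homogeneous Poisson
#'   at the mid-band rate); 1 (default) full modulation.
#' @param seed RNG seed.
#' @export
synth_spec <- function(n_neurons = 300, duration = 1, petals = 2,
                       rate_band = c(20, 80), phase_concentration = NULL,
                       phase_jitter = 0.2, modulation = 1, seed = NULL) {
  stopifnot(n_neurons >= 1, duration > 0, petals >= 1, petals <= 4,
            length(rate_band) == 2, rate_band[1] >= 0,
            rate_band[2] > rate_band[1], modulation >= 0, modulation <= 1,
            phase_jitter >= 0)
  if (is.null(phase_concentration)) phase_concentration <- 2 * petals^2
  stopifnot(phase_concentration > 0)
  structure(list(n_neurons = as.integer(n_neurons), duration = duration,
                 petals = as.integer(petals), rate_band = rate_band,
                 phase_concentration = phase_concentration,
                 phase_jitter = phase_jitter, modulation = modulation,
                 seed = seed),
            class = "synth_spec")
}

#' Homogeneous Poisson raster
#'
#' Independent exponential inter-spike intervals per neuron; an optional
#' absolute refractory period is enforced by thinning (spikes closer than
#' `refractory` to the previous accepted spike are discarded).
#'
#' @param n number of neurons.
#' @param rate firing rate (Hz).
#' @param T trial duration (s).
#' @param seed RNG seed.
#' @param refractory refractory period (s); 0 disables thinning.
#' @return a [spike_raster()].
#' @export
homogeneous_poisson <- function(n, rate, T, seed = NULL, refractory = 0) {
  stopifnot(n >= 1, rate >= 0, T > 0, refractory >= 0)
  with_seed(seed, {
    times <- lapply(seq_len(n), function(i) {
      if (rate == 0) return(numeric(0))
      # draw enough intervals to cover T with margin
      m <- max(10, ceiling(rate * T + 5 * sqrt(rate * T)))
      t <- cumsum(rexp(m, rate))
      while (length(t) && t[length(t)] < T)
        t <- c(t, t[length(t)] + cumsum(rexp(m, rate)))
      t <- t[t < T]
      if (refractory > 0 && length(t) > 1) {
        keep <- logical(length(t))
        last <- -Inf
        for (k in seq_along(t)) {
          if (t[k] - last >= refractory) {
            keep[k] <- TRUE
            last <- t[k]
          }
        }
        t <- t[keep]
      }
      t
    })
    spike_raster(times, T)
  })
}

# Per-neuron rate profile for a synth_spec; centers is the vector of petal
# centers (s) per neuron.  Returns an n x length(tt) matrix of rates.
petal_lambda <- function(spec, centers, depth, tt) {
  base <- spec$rate_band[1]
  ph <- outer(centers, tt, function(ci, t)
    cos(2 * pi * (t - ci) / spec$duration))
  base + depth * pmax(ph, 0)^spec$phase_concentration
}

#' Petal-modulated surrogate raster
#'
#' @param spec a [synth_spec()].
#' @return a [spike_raster()] with attributes `centers` (per-neuron petal
#'   center times), `petal` (per-neuron petal assignment), and `depth` (the
#'   modulation depth used), so the analytic rate profile can be
#'   reconstructed with the spec.
#' @export
petal_modulated_raster <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_neurons
  T <- spec$duration
  k <- spec$petals
  if (spec$modulation == 0)
    return(homogeneous_poisson(n, mean(spec$rate_band), T, seed = spec$seed))
  with_seed(spec$seed, {
    petal <- rep(seq_len(k), length.out = n)
    jit <- rnorm(n, 0, spec$phase_jitter) * T / (2 * pi)
    centers <- ((petal - 0.5) / k) * T + jit
    # scale the depth so the population-average rate peaks at the top of
    # the band (the baseline sits at the bottom)
    tt <- seq(0, T, length.out = 512)
    pop1 <- colMeans(petal_lambda(spec, centers, 1, tt)) - spec$rate_band[1]
    depth <- spec$modulation * (spec$rate_band[2] - spec$rate_band[1]) /
      max(pop1)
    lam_max <- spec$rate_band[1] + depth
    times <- lapply(seq_len(n), function(i) {
      m <- rpois(1, lam_max * T)
      if (m == 0) return(numeric(0))
      cand <- sort(runif(m, 0, T))
      lam <- petal_lambda(spec, centers[i], depth, cand)[1, ]
      cand[runif(m) < lam / lam_max]
    })
    r <- spike_raster(times, T)
    attr(r, "centers") <- centers
    attr(r, "petal") <- petal
    attr(r, "depth") <- depth
    r
  })
}

#' Jittered copies of a spike train
#'
#' Each copy shifts every spike by independent zero-mean Gaussian noise of
#' standard deviation `sigma`, clips to `[0, T]` and re-sorts.  Spike
#' counts are preserved.  Used as a Victor-Purpura validation fixture: the
#' expected VP distance to the original grows with `sigma`.
#'
#' @param train sorted spike times (s).
#' @param sigma jitter standard deviation (s).
#' @param n number of copies.
#' @param seed RNG seed.
#' @param T clipping bound (default: no upper clipping).
#' @return list of `n` sorted spike-time vectors.
#' @export
jittered_copies <- function(train, sigma, n, seed = NULL, T = Inf) {
  train <- check_train(train)
  stopifnot(sigma >= 0, n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      t <- train + rnorm(length(train), 0, sigma)
      sort(pmin(pmax(t, 0), T))
    })
  })
}
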
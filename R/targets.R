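# Closed planar target curves: a circle and two-, three-, and four-petal
# polar roses, sampled as teacher signals z(t) = (x(t), y(t)).

#' Specify a closed planar target curve
#'
#' The four supported shapes are a circle and polar roses with two, three and
#' four petals.  The time parameterization is rescaled so that one full
#' closed traversal of the curve occupies exactly `duration / (base_frequency
#' * duration)` = one period; with the default `base_frequency = 1/duration`
#' the curve is traversed exactly once per trial.
#'
#' In polar form (angle `phi`, radius `r`):
#' * `circle`: `r = R`, one revolution of `phi`.
#' * `rose2`: `r = R sin(2 phi)` restricted to `phi` in `[0, pi/2]` union
#'   `[pi, 3 pi/2]` (the two positive lobes along the diagonals); the
#'   excluded angular intervals are skipped by a continuous time mapping, so
#'   the curve passes through the origin between the two petals.
#' * `rose3`: `r = R sin(3 phi / 2)` over one revolution; the trace starts
#'   and ends at the origin and draws three petals.
#' * `rose4`: `r = R sin(2 phi)` over one revolution (four petals).
#'
#' @param shape one of `"circle"`, `"rose2"`, `"rose3"`, `"rose4"`.
#' @param amplitude radius scale R (output units, dimensionless by default).
#' @param duration trial length T in seconds.
#' @param dt sample step in seconds (defaults to the simulator step).
#' @param base_frequency traversal frequency f1 in Hz; `base_frequency *
#'   duration` must be a positive integer so the curve closes at `duration`.
#'   Default `1/duration` (one traversal per trial).
#' @return an object of class `target_spec`.
#' @seealso [generate_target()], [petal_count()]
#' @export
target_spec <- function(shape = c("circle", "rose2", "rose3", "rose4"),
                        amplitude = 1, duration = 1, dt = 5e-5,
                        base_frequency = 1 / duration) {
  shape <- match.arg(shape)
  stopifnot(amplitude > 0, duration > 0, dt > 0, dt < duration,
            base_frequency > 0)
  n_trav <- base_frequency * duration
  if (abs(n_trav - round(n_trav)) > 1e-9 || round(n_trav) < 1)
    stop("base_frequency * duration must be a positive integer so the ",
         "curve closes at t = duration")
  structure(list(shape = shape, amplitude = amplitude, duration = duration,
                 dt = dt, base_frequency = base_frequency,
                 n_traversals = as.integer(round(n_trav))),
            class = "target_spec")
}

#' Number of petals of a target shape
#'
#' Cross-check quantity for the phase structure of spike rasters: a trained
#' network's population rate makes one rise-fall excursion per petal.
#'
#' @param shape shape identifier as in [target_spec()] (a `target_spec` is
#'   also accepted).
#' @return 1 for the circle, k for the k-petal rose.
#' @export
petal_count <- function(shape) {
  if (inherits(shape, "target_spec")) shape <- shape$shape
  switch(shape,
         circle = 1L, rose2 = 2L, rose3 = 3L, rose4 = 4L,
         stop("unknown shape id: ", shape))
}

# Evaluate the curve at traversal phase u in [0, 1] (u = 0 and u = 1 are the
# same point).  Returns a list with x and y.
eval_target_phase <- function(shape, amplitude, u) {
  R <- amplitude
  switch(shape,
         circle = {
           phi <- 2 * pi * u
           list(x = R * cos(phi), y = R * sin(phi))
         },
         rose4 = {
           phi <- 2 * pi * u
           s <- sin(2 * phi)
           list(x = R * s * cos(phi), y = R * s * sin(phi))
         },
         rose3 = {
           phi <- 2 * pi * u
           s <- sin(1.5 * phi)
           list(x = R * s * cos(phi), y = R * s * sin(phi))
         },
         rose2 = {
           # traverse only phi in [0, pi/2] U [pi, 3 pi/2]; total length pi
           w <- pi * u
           phi <- ifelse(w <= pi / 2, w, w + pi / 2)
           s <- sin(2 * phi)
           list(x = R * s * cos(phi), y = R * s * sin(phi))
         },
         stop("unknown shape id: ", shape))
}

#' Sample a target curve as a time series
#'
#' @param spec a [target_spec()].
#' @return an object of class `trajectory`: a data.frame with columns
#'   `time`, `x`, `y` sampled at `spec$dt`, including both endpoints, so the
#'   first and last points coincide (the curve is closed).
#' @export
generate_target <- function(spec) {
  stopifnot(inherits(spec, "target_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  u <- (times / spec$duration * spec$n_traversals) %% 1
  u[length(u)] <- 1  # exact closure at t = duration
  p <- eval_target_phase(spec$shape, spec$amplitude, u)
  structure(data.frame(time = times, x = p$x, y = p$y),
            class = c("trajectory", "data.frame"),
            spec = spec)
}

# M-column teacher matrix sampled at the n_steps simulator instants
# t = 0, dt, ..., (n_steps - 1) dt, tiling the curve periodically.
target_teacher <- function(spec, n_steps, dt) {
  t <- (seq_len(n_steps) - 1) * dt
  u <- (t / spec$duration * spec$n_traversals) %% 1
  p <- eval_target_phase(spec$shape, spec$amplitude, u)
  cbind(p$x, p$y)
}

#' Write / read a trajectory as CSV (columns time,x,y)
#'
#' @param traj a `trajectory` as returned by [generate_target()].
#' @param path file path.
#' @return `read_trajectory_csv` returns a data.frame with columns
#'   `time`, `x`, `y`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(all(c("time", "x", "y") %in% names(traj)))
  write.csv(as.data.frame(traj)[, c("time", "x", "y")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time", "x", "y") %in% names(d)))
  d
}
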
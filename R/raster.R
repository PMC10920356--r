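# Spike rasters: per-neuron sorted spike times over a trial.

#' Construct a spike raster
#'
#' @param times list of numeric vectors, one per neuron, each sorted
#'   strictly increasing, spike times in seconds.
#' @param duration trial duration in seconds (spikes must lie in
#'   `[0, duration]`).
#' @param validate check the invariants (sorted, non-negative, in range).
#' @return an object of class `spike_raster`.
#' @export
spike_raster <- function(times, duration, validate = TRUE) {
  stopifnot(is.list(times), duration > 0)
  times <- lapply(times, as.numeric)
  if (validate) {
    for (i in seq_along(times)) {
      ti <- times[[i]]
      if (length(ti) == 0) next
      if (any(!is.finite(ti)) || any(ti < 0) || any(ti > duration))
        stop("neuron ", i, ": spike times must be finite, >= 0 and <= ",
             duration)
      if (is.unsorted(ti, strictly = TRUE))
        stop("neuron ", i, ": spike times must be strictly increasing")
    }
  }
  structure(list(times = times, n_neurons = length(times),
                 duration = duration),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ns <- lengths(x$times)
  cat("<spike_raster> ", x$n_neurons, " neurons, ", sum(ns),
      " spikes over ", x$duration, " s (mean rate ",
      round(sum(ns) / x$n_neurons / x$duration, 2), " Hz)\n", sep = "")
  invisible(x)
}

# Build a raster from parallel (neuron id, spike time) vectors (1-based ids).
raster_from_events <- function(id, t, n_neurons, duration) {
  times <- split(t, factor(id, levels = seq_len(n_neurons)))
  times <- lapply(times, function(v) sort(as.numeric(v)))
  names(times) <- NULL
  spike_raster(times, duration)
}

#' Population firing-rate trace
#'
#' Counts the spikes of all neurons in windows of length `window` and divides
#' by `window * n_neurons`, giving the instantaneous population rate in Hz
#' per neuron (the quantity plotted as "instant firing rate of the full
#' network averaged over `window`").
#'
#' @param raster a [spike_raster()].
#' @param window window length in seconds (default 20 ms).
#' @param step spacing of window centers in seconds; the default
#'   (`step = window`) gives non-overlapping windows, a smaller value a
#'   sliding window.
#' @return data.frame with columns `time` (window centers) and `rate` (Hz).
#' @export
mean_rate_trace <- function(raster, window = 0.02, step = window) {
  stopifnot(inherits(raster, "spike_raster"), window > 0, step > 0)
  all_t <- sort(unlist(raster$times, use.names = FALSE))
  centers <- seq(window / 2, raster$duration - window / 2 + 1e-12, by = step)
  if (length(all_t) == 0)
    return(data.frame(time = centers, rate = rep(0, length(centers))))
  # count spikes in [c - w/2, c + w/2)
  lo <- findInterval(centers - window / 2, all_t, left.open = TRUE)
  hi <- findInterval(centers + window / 2, all_t, left.open = TRUE)
  data.frame(time = centers,
             rate = (hi - lo) / (window * raster$n_neurons))
}

#' Spike raster CSV input/output
#'
#' Two-column CSV with header `neuron_id,spike_time_s`; neuron ids are
#' 0-based integers, rows sorted by neuron then time.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @param n_neurons number of neurons (for reading; default: max id + 1).
#' @param duration trial duration in seconds (for reading; default: max
#'   spike time).
#' @return `read_raster_csv` returns a [spike_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  id <- rep(seq_along(raster$times) - 1L, lengths(raster$times))
  t <- unlist(raster$times, use.names = FALSE)
  if (is.null(t)) t <- numeric(0)
  # %.17g guarantees exact double round-trip, so re-analysis of a stored
  # raster reproduces the distance ranks bit for bit
  writeLines(c("neuron_id,spike_time_s",
               sprintf("%d,%.17g", id, t)), path)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, n_neurons = NULL, duration = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty raster file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("raster CSV needs columns neuron_id,spike_time_s")
  id <- numeric(length(lines) - 1)
  tm <- numeric(length(lines) - 1)
  for (k in seq_along(id)) {
    f <- strsplit(lines[k + 1], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 2 || any(is.na(v)))
      stop("malformed raster row at line ", k + 1, ": '", lines[k + 1], "'")
    id[k] <- v[1]
    tm[k] <- v[2]
  }
  if (any(id != round(id)) || any(id < 0))
    stop("neuron_id must be a non-negative integer")
  if (is.null(n_neurons)) n_neurons <- if (length(id)) max(id) + 1 else 0
  if (is.null(duration)) duration <- if (length(tm)) max(tm) else 1
  raster_from_events(id + 1L, tm, as.integer(n_neurons), duration)
}
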
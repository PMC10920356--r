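# Victor-Purpura spike-train metric, distance matrices, and the normalized
# rank-ordered matrix M.

check_train <- function(x, label = "spike train") {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 0))
    stop(label, " must contain finite, non-negative times")
  if (is.unsorted(x, strictly = FALSE))
    stop(label, " must be sorted in increasing order")
  x
}

#' Victor-Purpura distance between two spike trains
#'
#' Minimum total cost of editing one train into the other, where inserting
#' or deleting a spike costs 1 and shifting a spike by `t` seconds costs
#' `q * t`.  Computed by the standard dynamic program; `q` sets the
#' timescale `1/q` below which shifting is cheaper than delete-plus-insert.
#' At `q = 0` the distance reduces to the spike-count difference.
#'
#' @param a,b numeric vectors of sorted spike times (seconds).
#' @param q cost per second of spike shift (1/s); default 1.
#' @return non-negative distance.
#' @export
vp_distance <- function(a, b, q = 1) {
  stopifnot(q >= 0)
  cpp_vp_distance(check_train(a, "first train"),
                  check_train(b, "second train"), q)
}

#' Victor-Purpura distance matrix
#'
#' @param trains a [spike_raster()] or a list of sorted spike-time vectors
#'   (at least 2).
#' @param q shift cost (1/s).
#' @return symmetric N x N matrix with zero diagonal and attribute `q`.
#' @export
vp_distance_matrix <- function(trains, q = 1) {
  if (inherits(trains, "spike_raster")) trains <- trains$times
  stopifnot(is.list(trains), length(trains) >= 2, q >= 0)
  trains <- lapply(seq_along(trains), function(i)
    check_train(trains[[i]], paste("train", i)))
  D <- cpp_vp_matrix(trains, q)
  attr(D, "q") <- q
  D
}

#' Mean firing rate of a spike train
#'
#' @param train sorted spike times (seconds).
#' @param T trial duration (s).
#' @return rate in Hz (`length(train) / T`).
#' @export
firing_rate <- function(train, T) {
  stopifnot(T > 0)
  length(check_train(train)) / T
}

#' Per-neuron firing rates of a raster
#'
#' @param raster a [spike_raster()].
#' @return numeric vector of rates (Hz).
#' @export
firing_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  lengths(raster$times) / raster$duration
}

#' Indices of the k most active neurons
#'
#' @param rates per-neuron firing rates (Hz).
#' @param k how many to keep; ties are broken in favor of the lower neuron
#'   index.
#' @return integer indices of the `k` largest rates, most active first.
#' @export
select_top_active <- function(rates, k) {
  stopifnot(k >= 1, k <= length(rates))
  order(-rates, seq_along(rates))[seq_len(k)]
}

#' Rank-order transform of a distance matrix
#'
#' The above-diagonal entries of `D` are replaced by their ranks
#' `0, 1, ..., N(N-1)/2 - 1`, mirrored below the diagonal, and normalized by
#' `N(N-1)/2`; rows and columns are then permuted so that neurons appear in
#' descending order of firing rate.  Under the default `"descending"`
#' convention the largest distance receives rank 0, i.e. the larger the VP
#' distance the smaller the entry of `M`; `"ascending"` assigns rank 0 to
#' the smallest distance instead.  The result is invariant under strictly
#' monotone transforms of the distances.
#'
#' Exact ties in `D` are broken by lexicographic `(i, j)` pair order.  The
#' diagonal (self-distance 0) is excluded from ranking and set to the
#' convention-consistent extreme: 1 under `"descending"`, 0 under
#' `"ascending"`.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param rates per-neuron firing rates used for the reindexing.
#' @param convention rank convention, see above.
#' @return object of class `rank_matrix`: list with `M` (the normalized
#'   rank-ordered matrix, reindexed), `neuron_order` (permutation applied:
#'   original indices in descending-rate order), `convention`, `n_pairs`.
#' @export
rank_order <- function(D, rates, convention = c("descending", "ascending")) {
  convention <- match.arg(convention)
  N <- nrow(D)
  stopifnot(ncol(D) == N, N >= 2, length(rates) == N)
  if (any(is.na(D))) stop("NaN/NA in distance matrix")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  K <- N * (N - 1) / 2
  ut <- which(upper.tri(D))
  i <- row(D)[ut]
  j <- col(D)[ut]
  d <- D[ut]
  ord <- if (convention == "descending") order(-d, i, j) else order(d, i, j)
  M <- matrix(0, N, N)
  M[ut[ord]] <- (seq_len(K) - 1) / K
  M <- M + t(M)
  diag(M) <- if (convention == "descending") 1 else 0
  perm <- order(-rates, seq_len(N))
  M <- M[perm, perm]
  structure(list(M = M, neuron_order = perm, convention = convention,
                 n_pairs = K),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat("<rank_matrix> ", nrow(x$M), " neurons, convention '", x$convention,
      "' (diagonal = ", x$M[1, 1], ")\n", sep = "")
  invisible(x)
}

#' Square matrix CSV input/output
#'
#' Writes a square symmetric matrix with a header row of neuron ids; the
#' reader validates squareness and symmetry.
#'
#' @param M square matrix (a `rank_matrix` is also accepted).
#' @param path file path.
#' @param ids column ids (default `n1..nN`).
#' @export
write_matrix_csv <- function(M, path, ids = NULL) {
  if (inherits(M, "rank_matrix")) M <- M$M
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(M)))
  colnames(M) <- ids
  write.csv(M, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  d <- as.matrix(read.csv(path, check.names = FALSE))
  if (nrow(d) != ncol(d)) stop("matrix in ", path, " is not square")
  storage.mode(d) <- "double"
  if (max(abs(d - t(d))) > 1e-9) stop("matrix in ", path, " is not symmetric")
  d
}
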
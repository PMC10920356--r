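# Vietoris-Rips persistent homology (dimensions 0 and 1) of a symmetric
# dissimilarity matrix, persistence barcodes and Betti curves.

#' Vietoris-Rips persistence barcode of a dissimilarity matrix
#'
#' Vertices `i` and `j` are joined once the filtration parameter `rho`
#' reaches `M[i, j]`; a triangle enters when its largest edge does.
#' Dimension-0 bars (connected components) are computed by union-find over
#' the sorted edges: all `n` bars are born at 0, one is infinite, and the
#' finite deaths are the minimum-spanning-tree edge values (zero-length
#' dim-0 bars are kept, so there are always exactly `n`).  Dimension-1 bars
#' (independent cycles) come from GF(2) column reduction of the triangle
#' boundary matrix; zero-persistence dim-1 pairs are dropped.
#'
#' @param M symmetric finite matrix (a [rank_order()] result is accepted);
#'   the diagonal is ignored.
#' @param max_dim 0 or 1.
#' @return object of class `persistence_barcode`: data.frame with columns
#'   `dim`, `birth`, `death` (`Inf` for the essential component), and
#'   attribute `n_points`.
#' @export
rips_persistence <- function(M, max_dim = 1) {
  if (inherits(M, "rank_matrix")) M <- M$M
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) >= 1,
            max_dim %in% c(0, 1))
  M2 <- M
  diag(M2) <- 0
  res <- cpp_rips_ph(M2, as.integer(max_dim))
  bars <- data.frame(dim = res$dim, birth = res$birth, death = res$death)
  bars <- bars[order(bars$dim, bars$birth, bars$death), ]
  rownames(bars) <- NULL
  structure(bars, class = c("persistence_barcode", "data.frame"),
            n_points = nrow(M))
}

#' Betti curve from a barcode
#'
#' Counts, at each grid value `rho`, the bars of dimension `dim` alive at
#' `rho` under the half-open convention `birth <= rho < death`.
#'
#' @param bars a [rips_persistence()] barcode (or any data.frame with
#'   columns `dim`, `birth`, `death`).
#' @param dim homology dimension to count.
#' @param grid ascending vector of filtration values.
#' @return data.frame with columns `rho` and `beta`.
#' @export
betti_curve <- function(bars, dim, grid = seq(0, 1, length.out = 512)) {
  stopifnot(!is.unsorted(grid))
  b <- bars[bars$dim == dim, , drop = FALSE]
  beta <- vapply(grid, function(rho)
    sum(b$birth <= rho & rho < b$death), numeric(1))
  data.frame(rho = grid, beta = as.integer(beta))
}

#' Betti curves for dimensions 0 and 1
#'
#' @inheritParams betti_curve
#' @return data.frame with columns `rho`, `beta0`, `beta1`.
#' @export
betti_curves <- function(bars, grid = seq(0, 1, length.out = 512)) {
  data.frame(rho = grid,
             beta0 = betti_curve(bars, 0, grid)$beta,
             beta1 = betti_curve(bars, 1, grid)$beta)
}

#' Number of connected components at a filtration value
#'
#' Union-find over the edges with `M[i, j] <= rho`; equals the dimension-0
#' Betti number `beta0(rho)` obtained from the barcode (up to the treatment
#' of bars dying exactly at `rho`: an edge with value exactly `rho` is
#' included here, matching the half-open bar convention).
#'
#' @param M symmetric dissimilarity matrix (diagonal ignored).
#' @param rho filtration value.
#' @return integer component count.
#' @export
connected_components_at <- function(M, rho) {
  if (inherits(M, "rank_matrix")) M <- M$M
  n <- nrow(M)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (M[i, j] <= rho) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Barcode CSV input/output
#'
#' Columns `dim,birth,death`; infinite deaths are written as the sentinel
#' string `inf`.
#'
#' @param bars a [rips_persistence()] barcode.
#' @param path file path.
#' @export
write_barcode_csv <- function(bars, path) {
  d <- data.frame(dim = bars$dim, birth = bars$birth,
                  death = ifelse(is.infinite(bars$death), "inf",
                                 as.character(bars$death)))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_barcode_csv
#' @export
read_barcode_csv <- function(path) {
  d <- read.csv(path, colClasses = c("integer", "numeric", "character"))
  d$death <- ifelse(d$death == "inf", Inf, suppressWarnings(as.numeric(d$death)))
  if (any(is.na(d$death))) stop("malformed death column in ", path)
  structure(d, class = c("persistence_barcode", "data.frame"))
}

#' Betti-curve CSV input/output
#'
#' Columns `rho,beta0,beta1`.
#'
#' @param bc a [betti_curves()] data.frame.
#' @param path file path.
#' @export
write_betti_csv <- function(bc, path) {
  write.csv(bc[, c("rho", "beta0", "beta1")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_betti_csv
#' @export
read_betti_csv <- function(path) read.csv(path)

#' Plot a persistence barcode
#'
#' Bars of each dimension in its own panel; infinite bars are drawn to the
#' right edge with an arrowhead.
#'
#' @param bars a [rips_persistence()] barcode.
#' @param dims dimensions to draw.
#' @param xlim filtration range (default from the finite deaths).
#' @export
plot_barcode <- function(bars, dims = c(0, 1), xlim = NULL) {
  finite <- bars$death[is.finite(bars$death)]
  if (is.null(xlim))
    xlim <- c(0, if (length(finite)) max(finite) * 1.05 else 1)
  old <- graphics::par(mfrow = c(length(dims), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in dims) {
    b <- bars[bars$dim == d, , drop = FALSE]
    n <- nrow(b)
    graphics::plot(NA, xlim = xlim, ylim = c(0, max(n, 1) + 1),
                   xlab = expression(rho), ylab = "bar",
                   main = paste0("dimension ", d), yaxt = "n")
    if (n == 0) next
    b <- b[order(b$death - b$birth), ]
    dd <- pmin(b$death, xlim[2])
    graphics::segments(b$birth, seq_len(n), dd, seq_len(n), lwd = 2)
    inf <- is.infinite(b$death)
    if (any(inf))
      graphics::points(dd[inf], which(inf), pch = ">", cex = 0.8)
  }
  invisible(bars)
}

#' Plot Betti curves
#'
#' @param bc a [betti_curves()] data.frame.
#' @export
plot_betti <- function(bc) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(bc$rho, bc$beta0, type = "s", xlab = expression(rho),
                 ylab = expression(beta[0]), main = "components")
  graphics::plot(bc$rho, bc$beta1, type = "s", xlab = expression(rho),
                 ylab = expression(beta[1]), main = "cycles")
  invisible(bc)
}
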
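# Independent oracles used by the tests.  These deliberately avoid the code
# paths of the package implementation: the VP oracle enumerates all edit
# sequences, the RLS oracle inverts the regularized correlation matrix
# directly, and the persistence oracle reduces the full boundary matrix of
# the clique complex in plain R.

# ---- Victor-Purpura: exhaustive enumeration ------------------------------
# Minimum edit cost over ALL injective matchings (crossing ones included)
# between the two trains; unmatched spikes are deleted/inserted at cost 1.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

vp_brute <- function(a, b, q) {
  n <- length(a)
  m <- length(b)
  best <- n + m  # delete and insert everything
  for (s in seq_len(min(n, m))) {
    sub_a <- utils::combn(n, s, simplify = FALSE)
    sub_b <- utils::combn(m, s, simplify = FALSE)
    for (ia in sub_a) for (ib in sub_b) for (pb in all_perms(ib)) {
      cost <- (n - s) + (m - s) + q * sum(abs(a[ia] - b[pb]))
      if (cost < best) best <- cost
    }
  }
  best
}

random_train <- function(n_spikes, T = 1) sort(runif(n_spikes, 0, T))

# ---- RLS: closed-form regularized inverse --------------------------------
rls_closed_form <- function(alpha, rs) {
  n <- length(rs[[1]])
  S <- diag(n) * alpha
  for (r in rs) S <- S + tcrossprod(r)
  solve(S)
}

# ---- persistent homology: full boundary-matrix reduction in R ------------
# Columns are stored as packed 30-bit integer words; low() is the highest
# set row bit.  Standard reduction over GF(2) of the boundary matrix of the
# full clique filtration (vertices, edges, triangles) sorted by
# (value, dim, lexicographic vertices).  Independent of the union-find /
# triangle-only reduction used by the package.
pack_rows <- function(rows, n_words) {
  col <- integer(n_words)
  for (r in rows) {
    w <- (r - 1) %/% 30L + 1L
    col[w] <- bitwOr(col[w], bitwShiftL(1L, (r - 1) %% 30L))
  }
  col
}

high_row <- function(col) {
  for (w in rev(seq_along(col))) {
    if (col[w] != 0L)
      return((w - 1L) * 30L + floor(log2(col[w])) + 1L)
  }
  0L
}

ph_oracle <- function(Md, drop_zero_dim1 = TRUE) {
  n <- nrow(Md)
  # enumerate simplices
  dim <- integer(0); val <- numeric(0); verts <- list()
  for (i in seq_len(n)) {
    dim <- c(dim, 0L); val <- c(val, 0); verts[[length(verts) + 1]] <- i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dim <- c(dim, 1L); val <- c(val, Md[i, j])
    verts[[length(verts) + 1]] <- c(i, j)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      dim <- c(dim, 2L)
      val <- c(val, max(Md[i, j], Md[i, k], Md[j, k]))
      verts[[length(verts) + 1]] <- c(i, j, k)
    }
  }
  v1 <- vapply(verts, `[`, numeric(1), 1)
  v2 <- vapply(verts, function(v) if (length(v) > 1) v[2] else 0, numeric(1))
  v3 <- vapply(verts, function(v) if (length(v) > 2) v[3] else 0, numeric(1))
  ord <- order(val, dim, v1, v2, v3)
  pos <- integer(length(ord))  # filtration position of simplex id
  pos[ord] <- seq_along(ord)

  # lookups for boundary rows
  vpos <- pos[seq_len(n)]
  epos <- matrix(0L, n, n)
  eidx <- n
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    eidx <- eidx + 1L
    epos[i, j] <- pos[eidx]
  }

  S <- length(ord)
  n_words <- (S + 29L) %/% 30L
  cols <- vector("list", S)
  owner <- integer(S)
  paired_with <- integer(S)  # for positive simplex at position p: killer position
  is_positive <- logical(S)

  for (p in seq_len(S)) {
    id <- ord[p]
    vv <- verts[[id]]
    rows <- if (dim[id] == 0L) integer(0)
            else if (dim[id] == 1L) c(vpos[vv[1]], vpos[vv[2]])
            else c(epos[vv[1], vv[2]], epos[vv[1], vv[3]],
                   epos[vv[2], vv[3]])
    col <- pack_rows(rows, n_words)
    repeat {
      l <- high_row(col)
      if (l == 0L || owner[l] == 0L) break
      col <- bitwXor(col, cols[[owner[l]]])
    }
    if (l == 0L) {
      is_positive[p] <- TRUE
    } else {
      owner[l] <- p
      cols[[p]] <- col
      paired_with[l] <- p
    }
  }

  dims <- integer(0); births <- numeric(0); deaths <- numeric(0)
  for (p in seq_len(S)) {
    if (!is_positive[p]) next
    id <- ord[p]
    if (dim[id] > 1L) next
    b <- val[id]
    d <- if (paired_with[p] > 0L) val[ord[paired_with[p]]] else Inf
    if (dim[id] == 1L && drop_zero_dim1 && d <= b) next
    dims <- c(dims, dim[id]); births <- c(births, b); deaths <- c(deaths, d)
  }
  out <- data.frame(dim = dims, birth = births, death = deaths)
  out[order(out$dim, out$birth, out$death), ]
}

# GF(2) rank of the triangle boundary matrix restricted to simplices with
# value <= rho; used for the rank-based Betti-1 cross-check
# beta1(rho) = E(rho) - n + beta0(rho) - rank(d2 restricted).
rank_d2_at <- function(Md, rho) {
  n <- nrow(Md)
  epos <- matrix(0L, n, n)
  ne <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (Md[i, j] <= rho) {
      ne <- ne + 1L
      epos[i, j] <- ne
    }
  }
  n_words <- max(1L, (ne + 29L) %/% 30L)
  pivots <- list()
  rank <- 0L
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (max(Md[i, j], Md[i, k], Md[j, k]) > rho) next
      col <- pack_rows(c(epos[i, j], epos[i, k], epos[j, k]), n_words)
      repeat {
        l <- high_row(col)
        if (l == 0L || is.null(pivots[[as.character(l)]])) break
        col <- bitwXor(col, pivots[[as.character(l)]])
      }
      if (l != 0L) {
        pivots[[as.character(l)]] <- col
        rank <- rank + 1L
      }
    }
  }
  list(rank = rank, n_edges = ne)
}

betti1_rank_oracle <- function(Md, rho) {
  n <- nrow(Md)
  rk <- rank_d2_at(Md, rho)
  b0 <- connected_components_at(Md, rho)
  rk$n_edges - n + b0 - rk$rank
}

random_symmetric_matrix <- function(n, max_val = 1) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0, max_val)
  M + t(M)
}
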
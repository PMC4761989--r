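# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / direct definitions and share no code
# with the implementation paths they check.

# All Δ-feasible surfaces of a 2D cost matrix (nx columns x nz rows, 0-based
# heights), by exhaustive enumeration; returns the minimum cost and the
# lexicographically smallest argmin.
enumerate_surface <- function(cost, delta, lo = NULL, hi = NULL) {
  nx <- nrow(cost); nz <- ncol(cost)
  lo <- lo %||% rep(0L, nx); hi <- hi %||% rep(nz - 1L, nx)
  grid <- do.call(expand.grid, lapply(seq_len(nx), function(i) lo[i]:hi[i]))
  grid <- as.matrix(grid)[, seq_len(nx), drop = FALSE]
  if (nx > 1) {
    ok <- rep(TRUE, nrow(grid))
    for (i in 1:(nx - 1)) ok <- ok & abs(grid[, i + 1] - grid[, i]) <= delta
    grid <- grid[ok, , drop = FALSE]
  }
  stopifnot(nrow(grid) > 0)
  costs <- rowSums(matrix(cost[cbind(rep(seq_len(nx), each = nrow(grid)),
                                     as.vector(grid) + 1L)],
                          nrow(grid), nx))
  best <- min(costs)
  cand <- grid[abs(costs - best) < 1e-9, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  list(cost = best, surface = cand[ord[1], ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lower hull (maximal z) of a trace by brute force over all chords.
brute_lower_hull <- function(z) {
  n <- length(z)
  out <- z
  for (x in seq_len(n)) {
    best <- z[x]
    for (i in 1:x) for (j in x:n) {
      if (i == j) next
      v <- z[i] + (z[j] - z[i]) * (x - i) / (j - i)
      best <- max(best, v)
    }
    out[x] <- best
  }
  out
}

# Brute-force ball morphology on 3D logical arrays (outside = background).
ball_offsets <- function(r) {
  if (r <= 0) return(matrix(0L, 1, 3))
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= r^2, ])
}

brute_erode <- function(mask, r) {
  d <- dim(mask); off <- ball_offsets(r)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    co <- arrayInd(v, d)
    pts <- sweep(off, 2, as.integer(co), `+`)
    inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
      pts[, 3] >= 1 & pts[, 3] <= d[3]
    out[v] <- all(inside) &&
      all(mask[cbind(pts[, 1], pts[, 2], pts[, 3])])
  }
  out
}

brute_dilate <- function(mask, r) {
  d <- dim(mask); off <- ball_offsets(r)
  out <- array(FALSE, d)
  for (v in which(mask)) {
    co <- arrayInd(v, d)
    pts <- sweep(off, 2, as.integer(co), `+`)
    keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
      pts[, 3] >= 1 & pts[, 3] <= d[3]
    out[pts[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# Scalar (pixel-by-pixel loop) reference of one MCDE step; mirrors the
# documented discretization directly from its definition.
mcde_step_scalar <- function(u, K, dt, eps = 1e-12) {
  nx <- nrow(u); nz <- ncol(u)
  at <- function(i, j) u[min(max(i, 1), nx), min(max(j, 1), nz)]
  out <- u
  cfun <- function(g) exp(-(g / K)^2)
  for (i in 1:nx) for (j in 1:nz) {
    flux <- function(di, dj) {
      d_n <- at(i + di, j + dj) - at(i, j)
      if (di != 0) {
        d_t <- ((at(i, j + 1) - at(i, j - 1)) +
                (at(i + di, j + 1) - at(i + di, j - 1))) / 4
      } else {
        d_t <- ((at(i + 1, j) - at(i - 1, j)) +
                (at(i + 1, j + dj) - at(i - 1, j + dj))) / 4
      }
      g <- sqrt(d_n^2 + d_t^2)
      cfun(g) / max(g, eps) * d_n
    }
    total <- flux(1, 0) + flux(-1, 0) + flux(0, 1) + flux(0, -1)
    gmag <- sqrt(((at(i + 1, j) - at(i - 1, j)) / 2)^2 +
                 ((at(i, j + 1) - at(i, j - 1)) / 2)^2)
    out[i, j] <- u[i, j] + dt * gmag * total
  }
  out
}

# Exhaustive minimum of a two-label energy over all labelings honoring the
# seed constraints (n <= ~14 free voxels).
brute_min_energy <- function(unary, edges, fixed) {
  n <- nrow(unary)
  free <- which(fixed == 0L)
  base <- fixed > 0L
  nf <- length(free)
  best <- Inf
  for (m in 0:(2^nf - 1)) {
    lab <- base
    if (nf > 0) lab[free] <- bitwAnd(m, 2^(seq_len(nf) - 1)) > 0
    e <- cut_energy(unary, edges, lab)
    if (e < best) best <- e
  }
  best
}

# Small phantom parameters for fast tests.
tiny_phantom <- function(seed = 1L, ...) {
  phantom_params(nx = 48L, nB = 8L, nz = 96L,
                 peds = list(list(cx = 24, cB = 4, a = 10, b = 2.5, h = 8)),
                 seed = seed, ...)
}
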
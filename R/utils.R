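# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Squared Euclidean distance transform to the nearest TRUE voxel of a 2D or
# 3D logical array (voxel metric). Returns an array of the same shape; Inf
# where the input has no TRUE voxel.
sq_edt <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  if (length(d) == 1) d <- c(d, 1L, 1L)
  if (length(d) == 2) d <- c(d, 1L)
  out <- .sq_edt3d(as.logical(mask), as.integer(d))
  array(out, dim = dim(mask) %||% length(mask))
}

# Connected-component labelling of a logical array.
# 2D: connectivity 4 or 8; 3D: 6 or 26. Labels follow column-major first
# encounter order; background is 0.
label_components <- function(mask, connectivity) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  if (length(d) == 2) d3 <- c(d, 1L) else d3 <- d
  assert_that(length(d3) == 3, "label_components: mask must be 2D or 3D")
  lab <- .label_cc(as.logical(mask), as.integer(d3), as.integer(connectivity))
  array(lab, dim = d)
}

# Otsu threshold of a numeric vector: exhaustive maximisation of
# between-class variance over nbins histogram bin edges.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) == 0) return(suppressWarnings(max(x, -Inf)))
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  bc <- rep(-Inf, nbins)
  bc[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  mids[which.max(bc)]
}

# Replicate-padding 1D convolution operator as a dense banded matrix, so that
# separable 2D filtering is T_x %*% img %*% t(T_z). kernel taps are indexed
# -r..r; row i of the matrix gathers clamp(i + k) for tap offset k.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- clamp(seq_len(n) + off, 1L, n)
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + kernel[k]
  }
  M
}

# Separable 2D convolution with replicate boundary. img is nx x nz; kx along
# rows (x), kz along columns (z).
conv_sep2d <- function(img, kx, kz) {
  Tx <- conv_matrix(nrow(img), kx)
  Tz <- conv_matrix(ncol(img), kz)
  Tx %*% img %*% t(Tz)
}

# Smooth random field on an nx x nB grid: iid Gaussian noise filtered with a
# Gaussian kernel of standard deviation `corr` voxels per axis, rescaled to
# standard deviation `amplitude`. Degenerate amplitude 0 returns zeros.
smooth_field <- function(nx, nB, amplitude, corr) {
  if (amplitude <= 0) return(matrix(0, nx, nB))
  g <- function(s) {
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  }
  z <- matrix(rnorm(nx * nB), nx, nB)
  k1 <- g(corr)
  f <- conv_matrix(nx, k1) %*% z
  if (nB > 1) f <- f %*% t(conv_matrix(nB, g(max(corr / 4, 1))))
  s <- sd(as.vector(f))
  if (s == 0) return(matrix(0, nx, nB))
  f * (amplitude / s)
}

# Minimum s-t cut of a directed capacitated graph (Dinic max-flow in C++),
# returning the *minimal* source side (residual reachability from s), which
# makes tie-breaking deterministic. edges: 2-column matrix (from, to),
# caps: forward capacities (reverse 0). Nodes are 1..n; s, t are node ids.
st_mincut_source_side <- function(n, edges, caps, s, t, rcaps = NULL) {
  res <- .maxflow_mincut(as.integer(n), as.integer(edges[, 1]),
                         as.integer(edges[, 2]), as.numeric(caps),
                         as.numeric(rcaps %||% numeric(0)),
                         as.integer(s), as.integer(t))
  res$side
}
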
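# Retinal layer segmentation by optimal single-surface graph search.
#
# A surface picks exactly one z per (x, B) column; smoothness constraints
# bound the axial jump between adjacent columns (delta_x within a B-scan,
# delta_b across B-scans); per-column feasibility bands restrict the search
# range. The optimum (minimum total cost) is found either by per-B-scan
# dynamic programming (delta_b decoupled; exact, fast) or by the minimum
# closed set / s-t min-cut construction on the full 3D column graph, which
# enforces the cross-B-scan constraint. Both return, among equal-cost
# optima, the surface with the smallest heights (the optimal surfaces form a
# lattice under pointwise min, so the pointwise-minimal optimum exists and
# equals the lexicographically smallest one).

#' Surface search specification
#'
#' @param polarity `"dark_to_bright"` (cost favours a positive downward
#'   intensity step: ILM, EZ roof) or `"bright_to_dark"` (RPE floor).
#' @param delta_x maximum axial jump (voxels, >= 0) between columns adjacent
#'   along x.
#' @param delta_b maximum jump across adjacent B-scans; `NULL` decouples
#'   B-scans (solved independently by dynamic programming).
#' @param band `NULL` or `list(lo=, hi=)` of 0-based inclusive per-column
#'   z bounds (`nx x nB` matrices, or scalars).
#' @param scales number of factor-2 axial down-samplings for
#'   [multiscale_search] (default 2: three scales).
#' @export
surface_search_spec <- function(polarity = c("dark_to_bright", "bright_to_dark"),
                                delta_x = 1L, delta_b = NULL, band = NULL,
                                scales = 2L) {
  polarity <- match.arg(polarity)
  if (delta_x < 0 || (!is.null(delta_b) && delta_b < 0))
    stop_param("surface_search_spec: smoothness constraints must be >= 0")
  if (scales < 0) stop_param("surface_search_spec: scales must be >= 0")
  list(polarity = polarity, delta_x = as.integer(delta_x),
       delta_b = if (is.null(delta_b)) NULL else as.integer(delta_b),
       band = band, scales = as.integer(scales))
}

#' Edge cost raster for a surface polarity
#'
#' Cost at voxel z is the negated (dark-to-bright) or raw (bright-to-dark)
#' symmetric axial difference `I(z+1) - I(z-1)` (replicated at the ends), so
#' the minimum straddles the matching transition with the full edge contrast
#' regardless of how a down-sampled grid aligns with the edge; exact ties
#' resolve to the shallower voxel through the search's tie rule.
#'
#' @param volume [oct_volume] or 3D array.
#' @param polarity as in [surface_search_spec].
#' @return numeric array of the same shape.
#' @export
surface_cost <- function(volume, polarity = c("dark_to_bright", "bright_to_dark")) {
  polarity <- match.arg(polarity)
  a <- as_volume_array(volume)
  nz <- dim(a)[3]
  d <- array(0, dim(a))
  if (nz > 1) {
    up <- a[, , c(1, 1:(nz - 1)), drop = FALSE]
    dn <- a[, , c(2:nz, nz), drop = FALSE]
    d <- dn - up
  }
  if (polarity == "dark_to_bright") -d else d
}

expand_band <- function(band, nx, nB, nz) {
  lo <- band$lo %||% 0
  hi <- band$hi %||% (nz - 1)
  if (length(lo) == 1) lo <- matrix(lo, nx, nB)
  if (length(hi) == 1) hi <- matrix(hi, nx, nB)
  lo <- pmax(as.matrix(lo), 0)
  hi <- pmin(as.matrix(hi), nz - 1)
  if (any(lo > hi)) stop_param("surface search: empty feasibility band")
  list(lo = lo, hi = hi)
}

# Tighten per-column bands so |z_i - z_j| <= delta is satisfiable, sweeping
# until a fixed point; errors if some column becomes empty.
propagate_bands <- function(lo, hi, dx, dB) {
  nx <- nrow(lo); nB <- ncol(lo)
  repeat {
    lo0 <- lo; hi0 <- hi
    if (nx > 1) {
      for (i in 2:nx) { hi[i, ] <- pmin(hi[i, ], hi[i - 1, ] + dx); lo[i, ] <- pmax(lo[i, ], lo[i - 1, ] - dx) }
      for (i in (nx - 1):1) { hi[i, ] <- pmin(hi[i, ], hi[i + 1, ] + dx); lo[i, ] <- pmax(lo[i, ], lo[i + 1, ] - dx) }
    }
    if (!is.null(dB) && nB > 1) {
      for (j in 2:nB) { hi[, j] <- pmin(hi[, j], hi[, j - 1] + dB); lo[, j] <- pmax(lo[, j], lo[, j - 1] - dB) }
      for (j in (nB - 1):1) { hi[, j] <- pmin(hi[, j], hi[, j + 1] + dB); lo[, j] <- pmax(lo[, j], lo[, j + 1] - dB) }
    }
    if (any(lo > hi))
      stop_param("surface search: infeasible bands (no surface satisfies the smoothness constraints)")
    if (identical(lo, lo0) && identical(hi, hi0)) break
  }
  list(lo = lo, hi = hi)
}

# Exact 2D DP for one B-scan. cost: nx x nz matrix; lo, hi: 0-based bounds.
# Returns 0-based heights; lexicographically smallest optimal surface.
dp_surface_2d <- function(cost, lo, hi, delta) {
  nx <- nrow(cost); nz <- ncol(cost)
  INF <- Inf
  colcost <- function(i) {
    v <- rep(INF, nz)
    idx <- (lo[i]:hi[i]) + 1L
    v[idx] <- cost[i, idx]
    v
  }
  wmin <- function(v, d) {
    # windowed min over |shift| <= d
    out <- v
    if (d > 0) for (s in 1:d) {
      out <- pmin(out, c(v[-(1:s)], rep(INF, s)), c(rep(INF, s), v[1:(nz - s)]))
    }
    out
  }
  # backward suffix DP: G[i, z] = cost(i, z) + min window G[i+1, .]
  G <- matrix(INF, nx, nz)
  G[nx, ] <- colcost(nx)
  if (nx > 1) for (i in (nx - 1):1) G[i, ] <- colcost(i) + wmin(G[i + 1, ], delta)
  heights <- integer(nx)
  # greedy left-to-right reconstruction, ties to the smallest z
  z <- which.min(G[1, ])  # 1-based
  heights[1] <- z - 1L
  if (nx > 1) for (i in 2:nx) {
    w <- max(1L, z - delta):min(nz, z + delta)
    z <- w[which.min(G[i, w])]
    heights[i] <- z - 1L
  }
  heights
}

# Li-style minimum closed set via s-t min-cut on the full column graph.
mincut_surface <- function(cost, lo, hi, dx, dB) {
  d <- dim(cost); nx <- d[1]; nB <- d[2]; nz <- d[3]
  nC <- nx * nB
  lov <- as.vector(lo); hiv <- as.vector(hi)
  size <- hiv - lov + 1L
  off <- c(0L, cumsum(size))
  N <- off[nC + 1]
  cs <- rep(seq_len(nC), size)
  zs <- sequence(size) - 1L + lov[cs]
  xs <- (cs - 1L) %% nx + 1L
  Bs <- (cs - 1L) %/% nx + 1L
  Cv <- cost[cbind(xs, Bs, zs + 1L)]
  base <- zs == lov[cs]
  M <- sum(abs(Cv)) + 1
  w <- Cv
  w[!base] <- Cv[!base] - cost[cbind(xs[!base], Bs[!base], zs[!base])]  # zs, i.e. z-1 in 0-based
  w[base] <- Cv[base] - M
  HUGE <- sum(abs(w)) + 1
  ids <- seq_len(N)
  s <- N + 1L; t <- N + 2L

  e_from <- ids[!base]; e_to <- ids[!base] - 1L  # intra-column chain (z -> z-1)
  ef <- list(e_from); et <- list(e_to); n_inter <- 1L
  add_dir <- function(cond, c2, dlt) {
    sel <- which(cond[cs])
    if (!length(sel)) return(invisible(NULL))
    c2s <- c2[cs[sel]]
    zt <- pmax(lov[c2s], zs[sel] - dlt)
    n_inter <<- n_inter + 1L
    ef[[n_inter]] <<- ids[sel]
    et[[n_inter]] <<- off[c2s] + (zt - lov[c2s]) + 1L
    invisible(NULL)
  }
  colx <- (seq_len(nC) - 1L) %% nx + 1L
  colB <- (seq_len(nC) - 1L) %/% nx + 1L
  add_dir(colx > 1, seq_len(nC) - 1L, dx)
  add_dir(colx < nx, seq_len(nC) + 1L, dx)
  if (!is.null(dB) && nB > 1) {
    add_dir(colB > 1, seq_len(nC) - nx, dB)
    add_dir(colB < nB, seq_len(nC) + nx, dB)
  }
  inter_from <- unlist(ef); inter_to <- unlist(et)
  neg <- which(w < 0); pos <- which(w > 0)
  edges <- rbind(cbind(inter_from, inter_to),
                 cbind(rep(s, length(neg)), neg),
                 cbind(pos, rep(t, length(pos))))
  caps <- c(rep(HUGE, length(inter_from)), -w[neg], w[pos])
  side <- st_mincut_source_side(t, edges, caps, s, t)
  insel <- which(side[seq_len(N)])
  hmax <- vapply(split(zs[insel], cs[insel]), max, numeric(1))
  heights <- integer(nC)
  heights[as.integer(names(hmax))] <- as.integer(hmax)
  matrix(heights, nx, nB)
}

#' Optimal single-surface search
#'
#' Finds the surface (one z per column) minimizing the total cost subject to
#' the smoothness constraints and feasibility bands of `spec`. Among
#' equal-cost optima the surface with the smallest heights is returned.
#'
#' @param cost 3D cost raster (`nx x nB x nz`; use a `nx x 1 x nz` array or
#'   an `nx x nz` matrix for a single B-scan).
#' @param spec [surface_search_spec].
#' @param method `"dp"` (per-B-scan dynamic programming; requires
#'   `delta_b = NULL`), `"mincut"` (minimum closed set via s-t min-cut), or
#'   `"auto"` (dp when B-scans are decoupled, else mincut).
#' @return integer matrix `nx x nB` of 0-based surface heights.
#' @export
single_surface_search <- function(cost, spec, method = c("auto", "dp", "mincut")) {
  method <- match.arg(method)
  if (length(dim(cost)) == 2) cost <- array(cost, c(nrow(cost), 1L, ncol(cost)))
  d <- dim(cost); nx <- d[1]; nB <- d[2]; nz <- d[3]
  b <- expand_band(spec$band %||% list(), nx, nB, nz)
  b <- propagate_bands(b$lo, b$hi, spec$delta_x, spec$delta_b)
  if (method == "auto") method <- if (is.null(spec$delta_b) || nB == 1) "dp" else "mincut"
  if (method == "dp") {
    if (!is.null(spec$delta_b) && nB > 1)
      stop_param("single_surface_search: dp solver decouples B-scans; use method='mincut' for finite delta_b")
    h <- matrix(0L, nx, nB)
    for (j in seq_len(nB))
      h[, j] <- dp_surface_2d(cost[, j, , drop = TRUE], b$lo[, j], b$hi[, j], spec$delta_x)
    h
  } else {
    mincut_surface(cost, b$lo, b$hi, spec$delta_x, spec$delta_b %||% spec$delta_x)
  }
}

pool_z <- function(a) {
  nz2 <- dim(a)[3] %/% 2L
  (a[, , 2 * seq_len(nz2) - 1, drop = FALSE] + a[, , 2 * seq_len(nz2), drop = FALSE]) / 2
}

#' Multi-scale surface search
#'
#' The full-resolution cost raster is mean-pooled axially by factor 2
#' `spec$scales` times; the coarsest scale is searched over the full band
#' and each finer scale inside a band of `margin` voxels around the
#' up-sampled coarser surface (intersected with `spec$band`). Pooling the
#' cost (rather than re-deriving it from a pooled volume) keeps each edge's
#' response localized, so closely stacked boundaries do not merge at coarse
#' scales; the smoothness constraint is divided by the pooling factor
#' (rounded up) to match the halved height units.
#'
#' @param volume [oct_volume] or 3D array.
#' @param spec [surface_search_spec].
#' @param margin half-width (voxels) of the refinement band at each scale.
#' @param method solver passed to [single_surface_search].
#' @return integer matrix `nx x nB` of 0-based heights.
#' @export
multiscale_search <- function(volume, spec, margin = 8L, method = "auto") {
  a <- as_volume_array(volume)
  nz <- dim(a)[3]
  if (nz < 4 * 2^spec$scales)
    stop_param("multiscale_search: volume too shallow for %d scales (nz = %d)", spec$scales, nz)
  cost <- surface_cost(a, spec$polarity)
  ms_refine(cost, spec, spec$scales, as.integer(margin), method)
}

scaled_spec <- function(spec, s) {
  out <- spec
  out$delta_x <- as.integer(ceiling(spec$delta_x / 2^s))
  if (!is.null(spec$delta_b)) out$delta_b <- as.integer(ceiling(spec$delta_b / 2^s))
  out
}

ms_refine <- function(cost, spec, scale, margin, method) {
  d <- dim(cost); nz <- d[3]
  b <- expand_band(spec$band %||% list(), d[1], d[2], nz)
  if (scale == 0) {
    sp <- scaled_spec(spec, spec$scales)  # coarsest level: scales poolings
    sp$band <- b
    return(single_surface_search(cost, sp, method))
  }
  # round the band inward so no coarse voxel pools out-of-band cost
  clo <- (b$lo + 1L) %/% 2L
  chi <- pmax((b$hi - 1L) %/% 2L, clo)
  coarse_spec <- spec
  coarse_spec$band <- list(lo = clo, hi = chi)
  h_coarse <- ms_refine(pool_z(cost), coarse_spec, scale - 1L, margin, method)
  lo <- pmax(b$lo, 2L * h_coarse - margin)
  hi <- pmin(b$hi, 2L * h_coarse + 1L + margin)
  # if the coarser surface drifted outside the caller band, fall back to it
  bad <- lo > hi
  lo[bad] <- b$lo[bad]; hi[bad] <- b$hi[bad]
  sp <- scaled_spec(spec, spec$scales - scale)
  sp$band <- list(lo = lo, hi = hi)
  single_surface_search(cost, sp, method)
}

#' Layer segmentation parameters
#'
#' @param delta_ilm smoothness constraint for the ILM (voxels per column).
#' @param delta_rpe larger constraint for the EZ roof and RPE floor, which
#'   must follow the abrupt arch of a PED.
#' @param delta_b cross-B-scan constraint (`NULL` = decoupled; finite values
#'   use the min-cut solver).
#' @param min_gap minimum axial gap (voxels) enforced between consecutive
#'   surfaces.
#' @param scales,margin multi-scale settings (see [multiscale_search]).
#' @export
layer_params <- function(delta_ilm = 1L, delta_rpe = 4L, delta_b = NULL,
                         min_gap = 2L, scales = 2L, margin = 8L) {
  list(delta_ilm = as.integer(delta_ilm), delta_rpe = as.integer(delta_rpe),
       delta_b = delta_b, min_gap = as.integer(min_gap),
       scales = as.integer(scales), margin = as.integer(margin))
}

#' Segment the ILM, EZ roof and RPE floor
#'
#' Three sequential multi-scale single-surface searches: the ILM first (the
#' most prominent dark-to-bright edge), then the photoreceptor EZ roof
#' (dark-to-bright) below `ILM + min_gap`, then the RPE floor
#' (bright-to-dark) below `EZ roof + min_gap`. The banded searches guarantee
#' the column-wise ordering ILM < EZ roof < RPE floor.
#'
#' @param volume denoised [oct_volume] or 3D array.
#' @param params [layer_params].
#' @return named list of [oct_surface]: `ILM`, `EZ_ROOF`, `RPE_FLOOR`.
#' @export
segment_layers <- function(volume, params = layer_params()) {
  a <- as_volume_array(volume)
  nz <- dim(a)[3]
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("segment_layers [%s]: %s", name, conditionMessage(e)), call. = FALSE))
  ilm <- stage("ILM", multiscale_search(a, surface_search_spec(
    "dark_to_bright", delta_x = params$delta_ilm, delta_b = params$delta_b,
    scales = params$scales), params$margin))
  ez <- stage("EZ_ROOF", multiscale_search(a, surface_search_spec(
    "dark_to_bright", delta_x = params$delta_rpe, delta_b = params$delta_b,
    band = list(lo = ilm + params$min_gap, hi = nz - 1),
    scales = params$scales), params$margin))
  rpe <- stage("RPE_FLOOR", multiscale_search(a, surface_search_spec(
    "bright_to_dark", delta_x = params$delta_rpe, delta_b = params$delta_b,
    band = list(lo = ez + params$min_gap, hi = nz - 1),
    scales = params$scales), params$margin))
  list(ILM = oct_surface("ILM", ilm, nz),
       EZ_ROOF = oct_surface("EZ_ROOF", ez, nz),
       RPE_FLOOR = oct_surface("RPE_FLOOR", rpe, nz))
}

#' Estimate Bruch's membrane from the RPE floor
#'
#' Per B-scan, BM is the maximal-z boundary of the convex hull of the trace
#' points `(x, z_RPE(x))` — the straight baseline beneath the PED arches;
#' equivalently the pointwise maximum over all chords between trace points.
#' BM >= RPE floor in z everywhere and may take fractional (sub-voxel)
#' values between hull vertices.
#'
#' @param rpe_floor [oct_surface] or `nx x nB` height matrix.
#' @return [oct_surface] named `"BM"` (numeric heights).
#' @export
estimate_bm <- function(rpe_floor) {
  h <- surface_heights(rpe_floor)
  nx <- nrow(h); nB <- ncol(h)
  out <- matrix(0, nx, nB)
  for (j in seq_len(nB)) out[, j] <- lower_hull_envelope(h[, j])
  oct_surface("BM", out, integer = FALSE)
}

# Maximal-z convex chain of the points (0:(n-1), z) via Andrew's monotone
# chain, evaluated at every integer x.
lower_hull_envelope <- function(z) {
  n <- length(z)
  if (n <= 2) return(z)
  x <- 0:(n - 1)
  hx <- c(x[1]); hz <- c(z[1])
  for (i in 2:n) {
    while (length(hx) >= 2) {
      k <- length(hx)
      # keep the chain bending toward smaller z (hull side of maximal z):
      # drop the middle point if it lies at or above (<=) the chord
      cross <- (hx[k] - hx[k - 1]) * (z[i] - hz[k - 1]) -
               (hz[k] - hz[k - 1]) * (x[i] - hx[k - 1])
      if (cross >= 0) { hx <- hx[-k]; hz <- hz[-k] } else break
    }
    hx <- c(hx, x[i]); hz <- c(hz, z[i])
  }
  approx(hx, hz, xout = x)$y
}

#' Initial PED mask from the RPE floor and BM
#'
#' The half-open slab `z in (z_RPE, z_BM]` per column; empty where the
#' surfaces coincide.
#'
#' @param rpe_floor,bm [oct_surface] or height matrices (BM may be
#'   fractional).
#' @return logical `nx x nB x nz` array.
#' @param nz axial extent of the target grid.
#' @export
initial_ped_mask <- function(rpe_floor, bm, nz) {
  hr <- surface_heights(rpe_floor)
  hb <- surface_heights(bm)
  if (any(hb < hr - 1e-9))
    stop_param("initial_ped_mask: BM must lie at or below the RPE floor everywhere")
  nx <- nrow(hr); nB <- ncol(hr)
  zg <- array(rep(0:(nz - 1), each = nx * nB), c(nx, nB, nz))
  zg > array(hr, c(nx, nB, nz)) & zg <= array(hb, c(nx, nB, nz)) + 1e-9
}
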
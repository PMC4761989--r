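# Final PED segmentation: automatic seeds by adaptive ball morphology, a
# layer-guided brightness normalization, a three-term shape-constrained
# graph cut solved by s-t min-cut, and adaptive morphological refinement.

# ---- adaptive ball morphology -------------------------------------------

#' Adaptive structuring-element radius
#'
#' Ball radius `r = round(c * V^(1/3))` from a region volume `V` (voxels):
#' dimensionally consistent (a length from a volume), monotone in `V`, and 0
#' for empty regions. The stage coefficients are c = 0.143 (foreground-seed
#' erosion), 1.143 (background-seed dilation), 0.200 (reconstruction) and
#' 0.700 (closing).
#'
#' @param V region volume in voxels (>= 0).
#' @param c positive coefficient.
#' @return integer radius >= 0.
#' @examples se_radius(1331, 0.143) # 2
#' @export
se_radius <- function(V, c) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stop_param("se_radius: c must be > 0")
  if (any(V < 0)) stop_param("se_radius: V must be >= 0")
  as.integer(round(c * V^(1 / 3)))
}

pad3 <- function(mask, w, value = FALSE) {
  d <- dim(mask)
  out <- array(value, d + 2L * w)
  out[w + seq_len(d[1]), w + seq_len(d[2]), w + seq_len(d[3])] <- mask
  out
}

unpad3 <- function(mask, w, d) mask[w + seq_len(d[1]), w + seq_len(d[2]), w + seq_len(d[3])]

# Erosion by the Euclidean ball {v: ||v|| <= r}; voxels outside the array
# count as background. Exact via the squared distance transform.
ball_erode <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  p <- pad3(mask, 1L)
  d2 <- sq_edt(!p)
  unpad3(p & d2 > r^2, 1L, d)
}

# Dilation by the same ball (clipped to the array).
ball_dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  if (!any(mask)) return(mask)
  sq_edt(mask) <= r^2
}

# Closing = dilation then erosion, computed on an r+1 pad so the volume
# border does not act as background during the erosion.
ball_close <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  d <- dim(mask)
  p <- pad3(mask, r + 1L)
  unpad3(ball_erode(ball_dilate(p, r), r), r + 1L, d)
}

# Geodesic reconstruction by dilation: grow `marker` inside `mask` with the
# 6-neighbourhood until stable.
reconstruct_6 <- function(marker, mask) {
  cur <- marker & mask
  if (!any(cur)) return(cur)
  d <- dim(cur)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  repeat {
    grown <- cur
    for (ax in 1:3) if (d[ax] > 1) grown <- grown | shift(cur, ax, 1) | shift(cur, ax, -1)
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

region_bbox <- function(vox_idx, d) {
  co <- arrayInd(vox_idx, d)
  rbind(lo = apply(co, 2, min), hi = apply(co, 2, max))
}

expand_bbox <- function(bb, d, factor = 3) {
  ctr <- (bb["lo", ] + bb["hi", ]) / 2
  half <- pmax((bb["hi", ] - bb["lo", ] + 1) * factor / 2, 1)
  lo <- pmax(1L, floor(ctr - half))
  hi <- pmin(d, ceiling(ctr + half))
  rbind(lo = as.integer(lo), hi = as.integer(hi))
}

crop3 <- function(a, bb) a[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2],
                          bb["lo", 3]:bb["hi", 3], drop = FALSE]

# ---- automatic seeds -----------------------------------------------------

#' Automatic foreground / background seeds from the refined mask
#'
#' Per 26-connected region of the refined initial segmentation: foreground
#' seeds are the ball erosion with radius `se_radius(V, c_fg)` (falling back
#' to the innermost voxel — the distance-transform maximum — when the
#' erosion would empty a small region); background seeds are the complement
#' of the ball dilation with radius `se_radius(V, c_bg)`, restricted to a
#' working box of 3x the dilated extent. Background seeds exclude the
#' dilation of *every* region, so the global seed sets are disjoint.
#'
#' @param mask logical 3D refined mask.
#' @param c_fg,c_bg structuring-element coefficients.
#' @return `seed_set`: global `fg` / `bg` logical arrays plus per-region
#'   detail (`vox`, `fg_vox`, `box`, `V`, `r_fg`, `r_bg`).
#' @export
make_seeds <- function(mask, c_fg = 0.143, c_bg = 1.143) {
  d <- dim(mask)
  fg <- array(FALSE, d); bg <- array(FALSE, d)
  regions <- list()
  if (any(mask)) {
    lab <- label_components(mask, connectivity = 26L)
    nreg <- max(lab)
    per <- list()
    dils <- list()
    for (i in seq_len(nreg)) {
      vox <- which(lab == i)
      V <- length(vox)
      rmask <- array(FALSE, d); rmask[vox] <- TRUE
      r_fg <- se_radius(V, c_fg); r_bg <- se_radius(V, c_bg)
      f <- ball_erode(rmask, r_fg)
      if (!any(f)) {
        d2 <- sq_edt(!pad3(rmask, 1L))
        inner <- which.max(unpad3(d2, 1L, d) * rmask)
        f <- array(FALSE, d); f[inner] <- TRUE
      }
      dils[[i]] <- ball_dilate(rmask, r_bg)
      per[[i]] <- list(vox = vox, fg_vox = which(f), V = V,
                       r_fg = r_fg, r_bg = r_bg,
                       box = expand_bbox(region_bbox(which(dils[[i]]), d), d))
      fg <- fg | f
    }
    for (i in seq_len(nreg)) {
      bb <- per[[i]]$box
      sel <- array(FALSE, d)
      sel[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3]] <- TRUE
      # background = working box outside this region's dilation; foreground
      # seeds of any region are excluded so the global sets stay disjoint
      bgm <- sel & !dils[[i]] & !fg
      bg <- bg | bgm
      per[[i]]$bg_vox <- which(bgm)
      regions[[i]] <- per[[i]]
    }
  }
  structure(list(fg = fg, bg = bg, regions = regions), class = "seed_set")
}

#' Shape prior of the refined regions
#'
#' Per 26-connected region: its voxel set, the radius `r` of an enclosing
#' sphere of the voxel centres (Ritter's deterministic bounding sphere), and
#' — computed on demand per crop — the Euclidean distance field `d(p)`
#' (voxel metric, 0 inside the region).
#'
#' @param mask logical 3D refined mask.
#' @return `shape_prior`: list of regions with `vox` and `r`.
#' @export
build_shape_prior <- function(mask) {
  d <- dim(mask)
  regions <- list()
  if (any(mask)) {
    lab <- label_components(mask, connectivity = 26L)
    for (i in seq_len(max(lab))) {
      vox <- which(lab == i)
      co <- arrayInd(vox, d)
      regions[[i]] <- list(vox = vox, r = ritter_radius(co))
    }
  }
  structure(list(regions = regions, dim = d), class = "shape_prior")
}

# Ritter's bounding sphere (two farthest-point passes + growth), on voxel
# centre coordinates. Always encloses; within a few percent of minimal.
ritter_radius <- function(co) {
  if (nrow(co) == 1) return(0.5)
  p0 <- co[1, ]
  d2 <- rowSums(sweep(co, 2, p0)^2)
  p1 <- co[which.max(d2), ]
  d2 <- rowSums(sweep(co, 2, p1)^2)
  p2 <- co[which.max(d2), ]
  ctr <- (p1 + p2) / 2
  r <- sqrt(max(d2)) / 2
  repeat {
    dd <- sqrt(rowSums(sweep(co, 2, ctr)^2))
    k <- which.max(dd)
    if (dd[k] <= r + 1e-9) break
    r <- (r + dd[k]) / 2
    ctr <- ctr + (dd[k] - r) / dd[k] * (co[k, ] - ctr)
  }
  max(r, 0.5)
}

# ---- brightness normalization -------------------------------------------

#' Layer-guided brightness transform
#'
#' Per column, an affine monotone remap anchored on two layer statistics:
#' the median of the RPE band slab (EZ roof, RPE floor] maps to
#' `targets["rpe"]` and the median of the vitreous background (z <= ILM)
#' maps to `targets["bg"]`; output clipped to 0..255. Columns with a
#' degenerate slab (zero thickness or non-increasing medians) are left
#' unchanged.
#'
#' @param volume [oct_volume] or 3D array.
#' @param surfaces named list with `ILM`, `EZ_ROOF`, `RPE_FLOOR` surfaces.
#' @param targets named levels for `bg` and `rpe`.
#' @return [oct_volume].
#' @export
brightness_transform <- function(volume, surfaces,
                                 targets = c(bg = 30, rpe = 200)) {
  a <- as_volume_array(volume)
  sp <- if (inherits(volume, "oct_volume")) volume$spacing else c(1, 1, 1)
  d <- dim(a)
  ilm <- surface_heights(surfaces$ILM)
  ez <- surface_heights(surfaces$EZ_ROOF)
  rpe <- surface_heights(surfaces$RPE_FLOOR)
  out <- a
  for (b in seq_len(d[2])) for (x in seq_len(d[1])) {
    zi <- ilm[x, b]; ze <- ez[x, b]; zr <- rpe[x, b]
    if (zr <= ze || zi < 0) next
    col <- a[x, b, ]
    m_bg <- median(col[seq_len(min(zi + 1L, d[3]))])
    m_rpe <- median(col[(ze + 2L):min(zr + 1L, d[3])])
    if (!is.finite(m_bg) || !is.finite(m_rpe) || m_rpe <= m_bg) next
    s <- (targets[["rpe"]] - targets[["bg"]]) / (m_rpe - m_bg)
    out[x, b, ] <- clamp(targets[["bg"]] + (col - m_bg) * s, 0, 255)
  }
  oct_volume(out, sp)
}

# ---- energy and min-cut --------------------------------------------------

#' Energy weights of the three-term graph-cut cost
#'
#' Non-negative weights for the region (intensity likelihood), shape and
#' boundary terms, constrained to sum to one.
#'
#' @param lambda_r,lambda_s,lambda_b weights.
#' @export
energy_weights <- function(lambda_r = 0.4, lambda_s = 0.2, lambda_b = 0.4) {
  w <- c(lambda_r = lambda_r, lambda_s = lambda_s, lambda_b = lambda_b)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_param("energy_weights: weights must be >= 0 and sum to 1")
  as.list(w)
}

#' Unary and pairwise cost tables of the shape-constrained energy
#'
#' Region term: Boykov-Jolly negative log-likelihoods from smoothed
#' histograms of the seed intensities. Shape term: `S_p(obj) =
#' min(d(p)/r, 1)` and its complement, with `d` the Euclidean distance to
#' the prior region and `r` its enclosing radius. Boundary term (6-
#' neighbourhood): `B_pq = exp(-(I_p - I_q)^2 / (2 sigma^2)) / dist(p, q)`
#' with `sigma` the standard deviation of neighbouring intensity
#' differences. Seed voxels carry effectively infinite opposite-label costs.
#'
#' @param vol numeric 3D array (crop) of intensities.
#' @param fg,bg logical arrays of seed voxels (same shape).
#' @param dist_field numeric array: distance to the prior region (0 inside).
#' @param r enclosing radius of the prior region (> 0).
#' @param weights [energy_weights].
#' @param nbins histogram bins for the region term.
#' @return list `unary` (N x 2 matrix, columns obj/bg), `edges`
#'   (data.frame p, q, w), `huge` (the hard-constraint cost).
#' @export
energy_terms <- function(vol, fg, bg, dist_field, r, weights, nbins = 32L) {
  d <- dim(vol); n <- prod(d)
  iv <- as.vector(vol)
  if (!any(fg) || !any(bg))
    stop_param("energy_terms: empty seed histogram; regenerate seeds")
  rng <- range(iv)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  binof <- function(x) clamp(findInterval(x, br, rightmost.closed = TRUE), 1L, nbins)
  lik <- function(seed) {
    # small-count floor: intensities never seen among the seeds must stay
    # far less likely than rare-but-seen ones, or the negative-log margin
    # collapses and flat far-field structures can flip label wholesale
    eps <- 0.01
    h <- tabulate(binof(iv[as.vector(seed)]), nbins)
    p <- (h + eps) / (sum(h) + eps * nbins)
    -log(p)
  }
  R_obj <- lik(fg)[binof(iv)]
  R_bg <- lik(bg)[binof(iv)]
  S_obj <- pmin(as.vector(dist_field) / max(r, 1e-9), 1)
  S_bg <- 1 - S_obj
  unary <- cbind(obj = weights$lambda_r * R_obj + weights$lambda_s * S_obj,
                 bg = weights$lambda_r * R_bg + weights$lambda_s * S_bg)
  # 6-neighbourhood edges (each unordered pair once)
  id <- array(seq_len(n), d)
  pe <- list(); k <- 0
  for (ax in 1:3) if (d[ax] > 1) {
    sl_a <- lapply(d, seq_len); sl_b <- sl_a
    sl_a[[ax]] <- 1:(d[ax] - 1); sl_b[[ax]] <- 2:d[ax]
    k <- k + 1
    pe[[k]] <- cbind(as.vector(id[sl_a[[1]], sl_a[[2]], sl_a[[3]]]),
                     as.vector(id[sl_b[[1]], sl_b[[2]], sl_b[[3]]]))
  }
  pq <- do.call(rbind, pe)
  dI <- iv[pq[, 1]] - iv[pq[, 2]]
  sigma <- max(sd(dI), 1e-9)
  Bw <- exp(-dI^2 / (2 * sigma^2))  # dist(p,q) = 1 for the 6-neighbourhood
  edges <- data.frame(p = pq[, 1], q = pq[, 2], w = weights$lambda_b * Bw)
  huge <- sum(unary[is.finite(unary)]) + sum(edges$w) + 1
  unary[as.vector(fg), "bg"] <- huge
  unary[as.vector(bg), "obj"] <- huge
  list(unary = unary, edges = edges, huge = huge)
}

#' Solve a two-label submodular energy by s-t min-cut
#'
#' Voxels with a known label (`fixed` +1 object / -1 background — seed hard
#' constraints) are contracted into the terminals: their pairwise costs fold
#' into the terminal capacities of their free neighbours, so the flow
#' problem only spans the free voxels.
#'
#' @param unary N x 2 matrix of label costs (columns obj, bg).
#' @param edges data.frame `p`, `q`, `w` of symmetric pairwise costs
#'   (`w >= 0`, paid when the labels differ).
#' @param fixed optional integer vector: +1 forced object, -1 forced
#'   background, 0 free.
#' @return logical vector of length N, TRUE = object label; attribute
#'   `"energy"` carries the attained energy.
#' @export
solve_binary_cut <- function(unary, edges, fixed = NULL) {
  n <- nrow(unary)
  fixed <- fixed %||% rep(0L, n)
  free <- which(fixed == 0L)
  lab <- fixed > 0L
  if (length(free)) {
    id <- integer(n); id[free] <- seq_along(free)
    cap_s <- unary[free, "bg"]   # cut when labeled bg
    cap_t <- unary[free, "obj"]  # cut when labeled obj
    pf <- fixed[edges$p]; qf <- fixed[edges$q]
    # fold edges touching fixed voxels into terminal capacities
    sel <- pf == 0L & qf != 0L
    if (any(sel)) {
      i <- id[edges$p[sel]]; wv <- edges$w[sel]; obj <- qf[sel] > 0
      add_s <- tapply(wv[obj], i[obj], sum)
      add_t <- tapply(wv[!obj], i[!obj], sum)
      if (length(add_s)) cap_s[as.integer(names(add_s))] <- cap_s[as.integer(names(add_s))] + add_s
      if (length(add_t)) cap_t[as.integer(names(add_t))] <- cap_t[as.integer(names(add_t))] + add_t
    }
    sel <- qf == 0L & pf != 0L
    if (any(sel)) {
      i <- id[edges$q[sel]]; wv <- edges$w[sel]; obj <- pf[sel] > 0
      add_s <- tapply(wv[obj], i[obj], sum)
      add_t <- tapply(wv[!obj], i[!obj], sum)
      if (length(add_s)) cap_s[as.integer(names(add_s))] <- cap_s[as.integer(names(add_s))] + add_s
      if (length(add_t)) cap_t[as.integer(names(add_t))] <- cap_t[as.integer(names(add_t))] + add_t
    }
    ff <- pf == 0L & qf == 0L
    nf <- length(free)
    s <- nf + 1L; t <- nf + 2L
    em <- rbind(cbind(rep(s, nf), seq_len(nf)),
                cbind(seq_len(nf), rep(t, nf)),
                cbind(id[edges$p[ff]], id[edges$q[ff]]))
    caps <- c(cap_s, cap_t, edges$w[ff])
    rcaps <- c(rep(0, 2L * nf), edges$w[ff])
    side <- st_mincut_source_side(t, em, caps, s, t, rcaps = rcaps)
    lab[free] <- side[seq_len(nf)]
  }
  structure(lab, energy = cut_energy(unary, edges, lab))
}

#' @rdname solve_binary_cut
#' @param labels logical labeling to score.
#' @export
cut_energy <- function(unary, edges, labels) {
  sum(ifelse(labels, unary[, "obj"], unary[, "bg"])) +
    sum(edges$w[labels[edges$p] != labels[edges$q]])
}

#' Shape-constrained graph cut segmentation
#'
#' Runs the three-term min-cut independently in each region's working box
#' (3x the dilated region extent) and unions the object labels. With no
#' refined regions the result is empty.
#'
#' @param volume [oct_volume] or 3D array (brightness-normalized).
#' @param seeds [make_seeds] output.
#' @param prior [build_shape_prior] output (same refined mask).
#' @param weights [energy_weights].
#' @return logical 3D mask.
#' @export
graph_cut <- function(volume, seeds, prior, weights = energy_weights()) {
  a <- as_volume_array(volume)
  d <- dim(a)
  out <- array(FALSE, d)
  for (i in seq_along(seeds$regions)) {
    reg <- seeds$regions[[i]]
    if (!length(reg$bg_vox)) { out[prior$regions[[i]]$vox] <- TRUE; next }
    bb <- reg$box
    vol_c <- crop3(a, bb)
    mk <- function(vox) { m <- array(FALSE, d); m[vox] <- TRUE; crop3(m, bb) }
    fg_c <- mk(reg$fg_vox)
    bg_c <- mk(reg$bg_vox)
    rmask_c <- mk(prior$regions[[i]]$vox)
    dist_c <- sqrt(sq_edt(rmask_c))
    et <- energy_terms(vol_c, fg_c, bg_c, dist_c, prior$regions[[i]]$r, weights)
    fixed <- as.integer(fg_c) - as.integer(bg_c)
    lab <- solve_binary_cut(et$unary, et$edges, fixed = fixed)
    sub <- array(FALSE, dim(vol_c)); sub[lab] <- TRUE
    out[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3]] <-
      out[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3]] | sub
  }
  out
}

#' Estimate the energy weights by projected gradient ascent
#'
#' Finite-difference ascent of the mean Dice coefficient over training
#' cases on `(lambda_r, lambda_s)`, with `lambda_b = 1 - lambda_r -
#' lambda_s`, projected onto the simplex. Monotone: the returned weights
#' never score below the initialization.
#'
#' @param cases list of `list(volume=, refined=, truth=)`: the (normalized)
#'   intensity volume, refined initial mask and truth PED mask.
#' @param init starting [energy_weights].
#' @param step initial step size; halved on failure to improve.
#' @param maxit ascent iterations.
#' @param fd finite-difference probe size.
#' @return [energy_weights] with attribute `"objective"` (mean DSC).
#' @export
estimate_weights <- function(cases, init = energy_weights(), step = 0.1,
                             maxit = 8L, fd = 0.05) {
  if (!length(cases)) stop_param("estimate_weights: need at least one training case")
  if (all(vapply(cases, function(cs) !any(cs$truth), logical(1))))
    stop_param("estimate_weights: all truth masks are empty")
  prep <- lapply(cases, function(cs) {
    list(a = as_volume_array(cs$volume), seeds = make_seeds(cs$refined),
         prior = build_shape_prior(cs$refined), truth = cs$truth)
  })
  objective <- function(v) {  # v = c(lambda_r, lambda_s)
    w <- list(lambda_r = v[1], lambda_s = v[2], lambda_b = 1 - v[1] - v[2])
    mean(vapply(prep, function(p) {
      m <- graph_cut(p$a, p$seeds, p$prior, w)
      inter <- sum(m & p$truth)
      denom <- sum(m) + sum(p$truth)
      if (denom == 0) 1 else 2 * inter / denom
    }, numeric(1)))
  }
  proj <- function(v) {
    v <- pmax(v, 0)
    if (sum(v) > 1) v <- v / sum(v)
    v
  }
  v <- c(init$lambda_r, init$lambda_s)
  f <- objective(v)
  for (it in seq_len(maxit)) {
    g <- vapply(1:2, function(k) {
      e <- c(0, 0); e[k] <- fd
      (objective(proj(v + e)) - objective(proj(v - e))) / (2 * fd)
    }, numeric(1))
    if (all(abs(g) < 1e-9)) break
    improved <- FALSE
    st <- step
    while (st > 1e-3) {
      v2 <- proj(v + st * g)
      f2 <- objective(v2)
      if (f2 > f + 1e-12) { v <- v2; f <- f2; improved <- TRUE; break }
      st <- st / 2
    }
    if (!improved) break
  }
  out <- energy_weights(v[1], v[2], 1 - v[1] - v[2])
  attr(out, "objective") <- f
  out
}

# ---- morphological refinement -------------------------------------------

#' Morphological post-processing of the segmentation
#'
#' Per 26-connected region of volume `V`: (1) geodesic reconstruction
#' (6-neighbourhood) of the ball-eroded marker (radius
#' `se_radius(V, c_recon)`) inside the region — removes isolated specks and
#' diagonally attached spurs while restoring the 6-connected body; regions
#' whose erosion is empty are dropped; (2) ball closing with radius
#' `se_radius(V, c_close)` — fills grooves and interior holes. The
#' 26-connected region count never increases.
#'
#' @param mask logical 3D mask.
#' @param c_recon,c_close structuring-element coefficients.
#' @return logical 3D mask.
#' @export
postprocess_mask <- function(mask, c_recon = 0.200, c_close = 0.700) {
  d <- dim(mask)
  out <- array(FALSE, d)
  if (!any(mask)) return(out)
  lab <- label_components(mask, connectivity = 26L)
  for (i in seq_len(max(lab))) {
    vox <- which(lab == i)
    V <- length(vox)
    bb <- expand_bbox(region_bbox(vox, d), d, factor = 1.0)
    r2 <- se_radius(V, c_close)
    # pad the working box enough for the closing
    bb["lo", ] <- pmax(1L, bb["lo", ] - r2 - 1L)
    bb["hi", ] <- pmin(d, bb["hi", ] + r2 + 1L)
    rmask <- array(FALSE, d); rmask[vox] <- TRUE
    rc <- crop3(rmask, bb)
    marker <- ball_erode(rc, se_radius(V, c_recon))
    if (!any(marker)) next
    rec <- reconstruct_6(marker, rc)
    res <- ball_close(rec, r2)
    out[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3]] <-
      out[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2], bb["lo", 3]:bb["hi", 3]] | res
  }
  out
}
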
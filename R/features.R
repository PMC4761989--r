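# Per-region feature extraction on 2D B-scan slices.
#
# Each 8-connected component of the initial PED mask on one B-scan yields a
# 62-dimensional feature vector:
#   f1-f17  shape / intensity: area, perimeter, major axis length, minor
#           axis length, major/minor, perimeter/area, eccentricity,
#           orientation, Euler number, number of bright pixels (above the
#           B-scan's Otsu threshold), equivalent diameter, solidity, extent,
#           convex hull area, max / min / mean intensity
#   f18-f21 centroid distance (z, voxels, signed downward) to ILM, EZ roof,
#           RPE floor, BM
#   f22-f28 centroid x, z, intensity; axis-aligned bounding box x, z,
#           width, height
#   f29-f52 extremum point in each of 8 compass directions: x, z, intensity
#   f53-f62 regional means of the two Hessian eigenvalues (|l1| <= |l2|) of
#           Gaussian-derivative filters at scales 1, 3, 6, 9, 14
# All coordinates are 0-based voxel units; the ellipse features follow the
# normalized-second-central-moment (regionprops) convention with the 1/12
# pixel-variance term.

HESSIAN_SCALES <- c(1, 3, 6, 9, 14)

#' 2D connected components of a mask slice
#'
#' 8-connected components; labels are deterministic, ordered by each
#' component's first pixel in raster-scan order (z row by row, then x).
#'
#' @param slice logical `nx x nz` matrix (one B-scan of a mask).
#' @param bscan 0-based B-scan index recorded on each region.
#' @return list of `candidate_region`: `list(bscan=, label=, pixels=)` with
#'   `pixels` an n x 2 matrix of 0-based (x, z) coordinates.
#' @export
components_2d <- function(slice, bscan = 0L) {
  slice <- as.matrix(slice) != 0
  if (!any(slice)) return(list())
  lab <- label_components(slice, connectivity = 8L)
  idx <- which(lab > 0, arr.ind = TRUE)
  px <- idx[, 1] - 1L; pz <- idx[, 2] - 1L
  l <- lab[idx]
  # raster order: scan rows of constant z, x increasing
  first <- vapply(split(pz * nrow(slice) + px, l), min, numeric(1))
  ord <- order(first)
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    sel <- l == as.integer(names(first))[ord[k]]
    out[[k]] <- structure(list(bscan = as.integer(bscan), label = k,
                               pixels = cbind(x = px[sel], z = pz[sel])),
                          class = "candidate_region")
  }
  out
}

# calibrated discrete Gaussian-derivative kernels: g integrates to 1,
# g' reproduces slope 1 on a ramp, g'' reproduces curvature 2 on z^2.
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  t <- -r:r
  g0 <- exp(-t^2 / (2 * sigma^2)); g0 <- g0 / sum(g0)
  g1 <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  g1 <- g1 - mean(g1)
  s1 <- sum(-t * g1); if (s1 != 0) g1 <- g1 / s1
  g2 <- (t^2 - sigma^2) / sigma^4 * exp(-t^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)
  s2 <- sum(t^2 * g2) / 2; if (s2 != 0) g2 <- g2 / s2
  list(g0 = g0, g1 = g1, g2 = g2)
}

# Hessian eigenvalue images of a B-scan (rows x, cols z) at one scale.
hessian_eigen_images <- function(image, sigma) {
  k <- gauss_kernels(sigma)
  hxx <- conv_sep2d(image, k$g2, k$g0)
  hzz <- conv_sep2d(image, k$g0, k$g2)
  hxz <- conv_sep2d(image, k$g1, k$g1)
  tr <- (hxx + hzz) / 2
  dlt <- sqrt(((hxx - hzz) / 2)^2 + hxz^2)
  ea <- tr + dlt; eb <- tr - dlt
  swap <- abs(ea) > abs(eb)  # order |l1| <= |l2|
  l1 <- ifelse(swap, eb, ea)
  l2 <- ifelse(swap, ea, eb)
  list(l1 = l1, l2 = l2)
}

#' Regional Hessian-eigenvalue means at multiple scales
#'
#' For each scale sigma, the Gaussian-derivative Hessian is computed over the
#' whole B-scan and the two eigenvalues (ordered `|l1| <= |l2|`) are averaged
#' over the region pixels.
#'
#' @param region `candidate_region` (see [components_2d]).
#' @param image `nx x nz` B-scan intensity matrix.
#' @param scales positive filter scales (voxels).
#' @param cache optional precomputed result of [hessian_cache] for this
#'   image (used by [build_feature_table] to share filter work).
#' @return numeric vector of `2 * length(scales)` values
#'   (l1 then l2 per scale).
#' @export
hessian_features <- function(region, image, scales = HESSIAN_SCALES, cache = NULL) {
  if (any(scales <= 0)) stop_param("hessian_features: scales must be positive")
  if (is.null(cache)) cache <- hessian_cache(image, scales)
  idx <- cbind(region$pixels[, 1] + 1L, region$pixels[, 2] + 1L)
  out <- numeric(0)
  for (s in seq_along(scales)) {
    ei <- cache[[s]]
    out <- c(out, mean(ei$l1[idx]), mean(ei$l2[idx]))
  }
  names(out) <- paste0(rep(c("hess_l1_s", "hess_l2_s"), length(scales)),
                       rep(scales, each = 2))
  out
}

#' @rdname hessian_features
#' @export
hessian_cache <- function(image, scales = HESSIAN_SCALES) {
  lapply(scales, function(s) hessian_eigen_images(image, s))
}

# area of the convex hull of the pixel set, counted as the number of pixels
# whose centre lies inside or on the hull polygon of the pixel centres
convex_pixel_area <- function(px, pz) {
  pts <- unique(cbind(px, pz))
  if (nrow(pts) < 3) return(nrow(unique(cbind(px, pz))))
  h <- chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hz <- pts[h, 2]
  if (length(unique(hx)) == 1 || length(unique(hz)) == 1 ||
      abs(pracma::polyarea(hx, hz)) < 1e-12) return(nrow(pts))
  gx <- min(px):max(px); gz <- min(pz):max(pz)
  gg <- expand.grid(x = gx, z = gz)
  inside <- pracma::inpolygon(gg$x, gg$z, hx, hz, boundary = TRUE)
  sum(inside)
}

#' Extract the 62-dimensional feature vector of one region
#'
#' @param region `candidate_region` from [components_2d].
#' @param image `nx x nz` intensity matrix of the region's B-scan.
#' @param surfaces named list with `ILM`, `EZ_ROOF`, `RPE_FLOOR`, `BM`
#'   heights on this B-scan: numeric vectors of length nx (or
#'   [oct_surface]s, from which the column is taken).
#' @param bscan 0-based B-scan index used to slice [oct_surface] inputs.
#' @param hessians optional [hessian_cache] for `image`.
#' @return named numeric vector of exactly 62 finite values.
#' @export
extract_features <- function(region, image, surfaces, bscan = region$bscan,
                             hessians = NULL) {
  px <- region$pixels[, 1]; pz <- region$pixels[, 2]
  nx <- nrow(image); nz <- ncol(image)
  if (any(px < 0 | px >= nx | pz < 0 | pz >= nz))
    stop_param("extract_features: region pixels outside the image")
  n <- length(px)
  idx <- cbind(px + 1L, pz + 1L)
  ints <- image[idx]

  # --- shape moments (regionprops convention) ---
  mx <- mean(px); mz <- mean(pz)
  mxx <- mean((px - mx)^2) + 1 / 12
  mzz <- mean((pz - mz)^2) + 1 / 12
  mxz <- mean((px - mx) * (pz - mz))
  tr <- (mxx + mzz) / 2
  dlt <- sqrt(((mxx - mzz) / 2)^2 + mxz^2)
  l_major <- tr + dlt; l_minor <- pmax(tr - dlt, 0)
  major <- 4 * sqrt(l_major); minor <- 4 * sqrt(l_minor)
  ecc <- sqrt(pmax(1 - l_minor / l_major, 0))
  orient <- 0.5 * atan2(2 * mxz, mxx - mzz)

  # perimeter: exposed 4-neighbour pixel faces
  occ <- matrix(FALSE, nx + 2, nz + 2)
  occ[cbind(px + 2L, pz + 2L)] <- TRUE
  nb4 <- occ[cbind(px + 1L, pz + 2L)] + occ[cbind(px + 3L, pz + 2L)] +
         occ[cbind(px + 2L, pz + 1L)] + occ[cbind(px + 2L, pz + 3L)]
  perim <- sum(4 - nb4)

  # Euler number: 1 component minus enclosed holes (4-connected background)
  bb <- occ[(min(px) + 1L):(max(px) + 3L), (min(pz) + 1L):(max(pz) + 3L)]
  bglab <- label_components(!bb, connectivity = 4L)
  border_labs <- unique(c(bglab[1, ], bglab[nrow(bglab), ], bglab[, 1], bglab[, ncol(bglab)]))
  holes <- length(setdiff(unique(bglab[bglab > 0]), border_labs))
  euler <- 1 - holes

  bright_thr <- otsu_threshold(as.vector(image))
  conv_area <- convex_pixel_area(px, pz)
  bw <- max(px) - min(px) + 1L; bh <- max(pz) - min(pz) + 1L

  surf_z <- function(nm) {
    s <- surfaces[[nm]]
    if (is.null(s)) stop_param("extract_features: surface %s missing", nm)
    h <- surface_heights(s)
    v <- if (is.matrix(h) && ncol(h) > 1) h[, bscan + 1L] else as.numeric(h)
    v[clamp(round(mx), 0, nx - 1) + 1L]
  }

  # directional extrema: max projection on each compass direction; ties by
  # raster-scan order (z, then x)
  ang <- (0:7) * pi / 4
  ord <- order(pz, px)
  ext <- numeric(0)
  for (a in ang) {
    proj <- px[ord] * cos(a) + pz[ord] * sin(a)
    k <- ord[which.max(proj)]
    ext <- c(ext, px[k], pz[k], image[px[k] + 1L, pz[k] + 1L])
  }

  cx <- clamp(round(mx), 0, nx - 1); cz <- clamp(round(mz), 0, nz - 1)
  fv <- c(
    area = n,
    perimeter = perim,
    major_axis = major,
    minor_axis = minor,
    axis_ratio = major / minor,
    perim_over_area = perim / n,
    eccentricity = ecc,
    orientation = orient,
    euler = euler,
    n_bright = sum(ints > bright_thr),
    equiv_diameter = sqrt(4 * n / pi),
    solidity = n / conv_area,
    extent = n / (bw * bh),
    convex_area = conv_area,
    max_intensity = max(ints),
    min_intensity = min(ints),
    mean_intensity = mean(ints),
    dist_ilm = mz - surf_z("ILM"),
    dist_ez = mz - surf_z("EZ_ROOF"),
    dist_rpe = mz - surf_z("RPE_FLOOR"),
    dist_bm = mz - surf_z("BM"),
    centroid_x = mx,
    centroid_z = mz,
    centroid_intensity = image[cx + 1L, cz + 1L],
    bbox_x = min(px),
    bbox_z = min(pz),
    bbox_w = bw,
    bbox_h = bh
  )
  names(ext) <- paste0(rep(c("ext_x_d", "ext_z_d", "ext_i_d"), 8),
                       rep(1:8, each = 3))
  hv <- hessian_features(region, image, HESSIAN_SCALES, cache = hessians)
  out <- c(fv, ext, hv)
  stopifnot(length(out) == 62L, all(is.finite(out)))
  out
}

#' Build the per-region feature table of a volume
#'
#' Runs [components_2d] on every B-scan of `mask` and extracts the 62
#' features of each region; optionally labels regions against a truth mask
#' (see [make_labels]).
#'
#' @param volume [oct_volume] or 3D array (intensities the features are
#'   measured on — typically the denoised volume).
#' @param mask logical 3D array of candidate regions (initial PED mask).
#' @param surfaces named list of the four [oct_surface]s.
#' @param truth optional truth PED mask; adds a `label` column (+1 / -1).
#' @param volume_id identifier recorded in the first column.
#' @return `data.frame`: volume id, bscan, label id, 62 feature columns and
#'   (with truth) the class label; plus attribute `"regions"` holding the
#'   region list.
#' @export
build_feature_table <- function(volume, mask, surfaces, truth = NULL,
                                volume_id = "vol") {
  a <- as_volume_array(volume)
  nB <- dim(a)[2]
  rows <- list(); regions <- list(); k <- 0L
  for (b in seq_len(nB) - 1L) {
    slice <- mask[, b + 1L, ]
    if (!any(slice)) next
    regs <- components_2d(slice, bscan = b)
    img <- a[, b + 1L, ]
    hc <- hessian_cache(img)
    surf_b <- lapply(surfaces, function(s) surface_heights(s)[, b + 1L])
    for (r in regs) {
      k <- k + 1L
      fv <- extract_features(r, img, surf_b, bscan = 0L, hessians = hc)
      rows[[k]] <- data.frame(volume_id = volume_id, bscan = b,
                              region = r$label, t(fv),
                              check.names = FALSE)
      regions[[k]] <- r
    }
  }
  if (k == 0L) {
    df <- data.frame()
    attr(df, "regions") <- list()
    return(df)
  }
  df <- do.call(rbind, rows)
  if (!is.null(truth)) df$label <- make_labels(regions, truth)
  attr(df, "regions") <- regions
  df
}

#' Names of the 62 feature columns of a feature table
#' @param df data frame from [build_feature_table].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(df) {
  setdiff(names(df), c("volume_id", "bscan", "region", "label"))
}
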
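# Synthetic SD-OCT phantoms with known surfaces and PED masks.
#
# The phantom paints flat-ish intensity bands between four smooth surfaces
# (ILM, EZ roof, RPE floor, BM; z increases with depth), lifts the RPE floor
# above a near-convex BM baseline by half-ellipsoid "caps" to create serous
# PED domes with dark interiors, optionally carves dark fluid pockets into
# the bright band just above the RPE floor (confounders for classifier
# training), and can add unit-mean multiplicative gamma speckle.

#' Phantom parameters
#'
#' @param nx,nB,nz voxel counts (each >= 8). Default 128 x 16 x 160, a desk
#'   scale that exercises the whole pipeline in minutes.
#' @param levels named grey levels (0..255): `background` (vitreous),
#'   `nfl` (retinal nerve fibre layer band), `onl` (outer nuclear layer),
#'   `ez` (photoreceptor ellipsoid zone), `rpe` (RPE band), `fluid`
#'   (PED / pocket interior, darker than the RPE band) and `choroid`
#'   (below Bruch's membrane). Defaults keep the vitreous-to-NFL step the
#'   strongest dark-to-bright transition — including composites of stacked
#'   deeper edges — matching the ILM's role as the most prominent OCT edge.
#' @param smooth `list(amplitude=, corr=)`: standard deviation (voxels) and
#'   correlation length (voxels) of the low-frequency undulation added to
#'   the ILM.
#' @param bm_smooth undulation of the BM baseline; much stiffer than the
#'   inner retina (BM is nearly planar), keeping the baseline near-convex.
#' @param peds list of PED caps, each `list(cx=, cB=, a=, b=, h=)`: centre
#'   (x, B-scan), half-width along x, half-depth along B (voxels) and apex
#'   height (voxels, >= 1). The RPE floor is lifted above BM by the
#'   half-ellipsoid `h * sqrt(1 - ((x-cx)/a)^2 - ((B-cB)/b)^2)`.
#' @param confounders list of fluid pockets with the same cap
#'   parameterization, carved into the bright band directly above the RPE
#'   floor (the floor itself stays on the BM baseline there).
#' @param speckle `list(family="gamma", scale=)`: multiplicative unit-mean
#'   noise standard deviation (0 disables).
#' @param seed integer RNG seed; the phantom is a pure function of
#'   (params, seed).
#' @param ilm_frac,bm_frac fractional depth of the ILM and BM baselines.
#' @param nfl_thickness,band_thickness thickness (voxels) of the bright NFL
#'   band below the ILM and of the EZ+RPE bright band above the RPE floor.
#' @return Validated parameter list of class `phantom_params`.
#' @export
phantom_params <- function(nx = 128L, nB = 16L, nz = 160L,
                           levels = c(background = 20, nfl = 170, onl = 55,
                                      ez = 140, rpe = 200, fluid = 40, choroid = 90),
                           smooth = list(amplitude = 0.8, corr = 24),
                           bm_smooth = list(amplitude = 0.4, corr = 40),
                           peds = list(list(cx = 64, cB = 8, a = 24, b = 5, h = 15)),
                           confounders = list(),
                           speckle = list(family = "gamma", scale = 0),
                           seed = 1L,
                           ilm_frac = 0.25, bm_frac = 0.72,
                           nfl_thickness = 6L, band_thickness = 12L) {
  p <- list(nx = as.integer(nx), nB = as.integer(nB), nz = as.integer(nz),
            levels = levels, smooth = smooth, bm_smooth = bm_smooth, peds = peds,
            confounders = confounders, speckle = speckle, seed = as.integer(seed),
            ilm_frac = ilm_frac, bm_frac = bm_frac,
            nfl_thickness = as.integer(nfl_thickness),
            band_thickness = as.integer(band_thickness))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (any(c(p$nx, p$nB, p$nz) < 8)) stop_param("phantom: all voxel counts must be >= 8")
  need <- c("background", "nfl", "onl", "ez", "rpe", "fluid", "choroid")
  if (!all(need %in% names(p$levels)))
    stop_param("phantom: levels must name %s", paste(need, collapse = ", "))
  if (any(p$levels < 0 | p$levels > 255)) stop_param("phantom: levels must lie in 0..255")
  for (cap in c(p$peds, p$confounders)) {
    if (!all(c("cx", "cB", "a", "b", "h") %in% names(cap)))
      stop_param("phantom: each cap needs cx, cB, a, b, h")
    if (cap$h < 1) stop_param("phantom: cap apex height must be >= 1 voxel")
    if (cap$a <= 0 || cap$b <= 0) stop_param("phantom: cap half-extents must be positive")
  }
  if (!is.null(p$speckle$scale) && p$speckle$scale < 0)
    stop_param("phantom: speckle scale must be >= 0")
  invisible(p)
}

# Half-ellipsoid lift field of a list of caps on the (x, B) grid.
cap_lift <- function(caps, nx, nB) {
  lift <- matrix(0, nx, nB)
  for (cap in caps) {
    x <- matrix(0:(nx - 1), nx, nB)
    B <- matrix(rep(0:(nB - 1), each = nx), nx, nB)
    u <- 1 - ((x - cap$cx) / cap$a)^2 - ((B - cap$cB) / cap$b)^2
    lift <- lift + cap$h * sqrt(pmax(u, 0))
  }
  lift
}

cap_footprints_overlap <- function(caps, nx, nB) {
  if (length(caps) < 2) return(FALSE)
  hit <- matrix(0L, nx, nB)
  for (cap in caps) {
    x <- matrix(0:(nx - 1), nx, nB)
    B <- matrix(rep(0:(nB - 1), each = nx), nx, nB)
    inside <- (((x - cap$cx) / cap$a)^2 + ((B - cap$cB) / cap$b)^2) < 1
    hit <- hit + inside
  }
  any(hit > 1L)
}

#' Generate a synthetic SD-OCT phantom
#'
#' Deterministic for a fixed `params$seed`. Overlapping cap footprints (which
#' would force surface crossings) are rejected.
#'
#' @param params [phantom_params].
#' @return `list(volume=, truth=)` where `volume` is a noise-free
#'   [oct_volume] (apply [add_speckle] separately) and `truth` is a
#'   `phantom_truth` list with `surfaces` (named list of [oct_surface]),
#'   `ped_mask`, `retina_mask` and `confounder_mask` logical arrays.
#' @examples
#' ph <- generate_phantom(phantom_params(nx = 32, nB = 8, nz = 64,
#'   peds = list(list(cx = 16, cB = 4, a = 8, b = 2, h = 6))))
#' sum(ph$truth$ped_mask)
#' @export
generate_phantom <- function(params) {
  p <- validate_phantom_params(params)
  nx <- p$nx; nB <- p$nB; nz <- p$nz
  if (cap_footprints_overlap(c(p$peds, p$confounders), nx, nB))
    stop_param("generate_phantom: cap footprints overlap; surfaces would cross")

  set.seed(p$seed, kind = "Mersenne-Twister")
  u_ilm <- smooth_field(nx, nB, p$smooth$amplitude, p$smooth$corr)
  bs <- p$bm_smooth %||% list(amplitude = 0.4, corr = 40)
  u_bm  <- smooth_field(nx, nB, bs$amplitude, bs$corr)

  z_ilm <- round(p$ilm_frac * nz + u_ilm)
  z_bm  <- round(p$bm_frac * nz + u_bm)
  lift  <- round(cap_lift(p$peds, nx, nB))
  z_rpe <- z_bm - lift
  z_ez  <- z_rpe - p$band_thickness
  z_nfl <- z_ilm + p$nfl_thickness

  if (any(z_ez <= z_nfl + 1))
    stop_param("generate_phantom: PED apex too tall for the grid; surfaces would cross")
  if (any(z_ilm < 1) || any(z_bm >= nz - 1))
    stop_param("generate_phantom: surfaces leave the axial range; adjust fractions")

  lev <- p$levels
  vol <- array(lev[["background"]], c(nx, nB, nz))
  zg <- array(rep(0:(nz - 1), each = nx * nB), c(nx, nB, nz))
  rep3 <- function(m) array(m, c(nx, nB, nz))  # broadcast height map over z
  Zilm <- rep3(z_ilm); Znfl <- rep3(z_nfl); Zez <- rep3(z_ez)
  Zrpe <- rep3(z_rpe); Zbm <- rep3(z_bm)
  zmid <- rep3(z_rpe - floor(p$band_thickness / 2))

  vol[zg > Zilm & zg <= Znfl] <- lev[["nfl"]]
  vol[zg > Znfl & zg <= Zez]  <- lev[["onl"]]
  vol[zg > Zez & zg <= zmid]  <- lev[["ez"]]
  vol[zg > zmid & zg <= Zrpe] <- lev[["rpe"]]
  ped_mask <- zg > Zrpe & zg <= Zbm
  vol[ped_mask] <- lev[["fluid"]]
  vol[zg > Zbm] <- lev[["choroid"]]

  conf_mask <- array(FALSE, c(nx, nB, nz))
  if (length(p$confounders)) {
    clift <- round(cap_lift(p$confounders, nx, nB))
    Ctop <- rep3(z_rpe - clift)
    conf_mask <- zg > Ctop & zg <= Zrpe & rep3(clift) > 0
    vol[conf_mask] <- lev[["fluid"]]
  }

  retina_mask <- zg > Zilm & zg <= Zbm
  surfaces <- list(ILM = oct_surface("ILM", z_ilm, nz),
                   EZ_ROOF = oct_surface("EZ_ROOF", z_ez, nz),
                   RPE_FLOOR = oct_surface("RPE_FLOOR", z_rpe, nz),
                   BM = oct_surface("BM", z_bm, nz))
  truth <- structure(list(surfaces = surfaces, ped_mask = ped_mask,
                          retina_mask = retina_mask, confounder_mask = conf_mask),
                     class = "phantom_truth")
  list(volume = oct_volume(vol, c(11.72, 93.75, 3.50)), truth = truth)
}

#' Add multiplicative speckle noise
#'
#' Voxelwise multiplication by unit-mean gamma noise with standard deviation
#' `scale` (shape `1/scale^2`, scale `scale^2`), a standard surrogate for the
#' multiplicative speckle of coherent imaging. Output is clipped to 0..255.
#'
#' @param volume [oct_volume] or 3D array.
#' @param scale noise standard deviation (>= 0; 0 returns the input).
#' @param seed integer RNG seed (same seed, same noise field).
#' @param family noise family; only `"gamma"` is implemented.
#' @return [oct_volume].
#' @export
add_speckle <- function(volume, scale, seed = 1L, family = "gamma") {
  if (!is.numeric(scale) || length(scale) != 1 || scale < 0)
    stop_param("add_speckle: scale must be a single value >= 0")
  family <- match.arg(family, "gamma")
  a <- as_volume_array(volume)
  sp <- if (inherits(volume, "oct_volume")) volume$spacing else c(1, 1, 1)
  if (scale == 0) return(oct_volume(a, sp))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  shape <- 1 / scale^2
  noise <- rgamma(length(a), shape = shape, scale = 1 / shape)
  oct_volume(array(clamp(a * noise, 0, 255), dim(a)), sp)
}

#' Sample randomized phantom parameter sets for an experiment
#'
#' Draws `n` parameter sets with one PED cap each (half-width 18..30 voxels,
#' apex 10..18 voxels) and, optionally, one small confounding fluid pocket
#' (half-width 5..9, apex 3..6) placed with a disjoint footprint. These are
#' the study conditions used by the package's phantom experiments.
#'
#' @param n number of parameter sets.
#' @param seed integer seed; set `i` uses seed `seed + i`.
#' @param confounder add one fluid pocket per phantom?
#' @param speckle_scale multiplicative noise standard deviation.
#' @param ... overrides forwarded to [phantom_params].
#' @return list of [phantom_params].
#' @export
sample_phantom_params <- function(n, seed = 1L, confounder = TRUE,
                                  speckle_scale = 0.25, ...) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + i, kind = "Mersenne-Twister")
    a <- runif(1, 18, 30); b <- runif(1, 4, 6.5); h <- runif(1, 10, 18)
    cx <- runif(1, 34, 94); cB <- runif(1, 6.5, 9.5)
    peds <- list(list(cx = cx, cB = cB, a = a, b = b, h = h))
    confs <- list()
    if (confounder) {
      ca <- runif(1, 5, 9); cb <- runif(1, 2, 3.5); ch <- runif(1, 3, 6)
      # place on the far side of the scan, footprint disjoint from the PED cap
      ccx <- if (cx < 64) cx + a + ca + runif(1, 6, 14) else cx - a - ca - runif(1, 6, 14)
      ccx <- clamp(ccx, 12, 115)
      confs <- list(list(cx = ccx, cB = runif(1, 5, 11), a = ca, b = cb, h = ch))
    }
    out[[i]] <- phantom_params(peds = peds, confounders = confs,
                               speckle = list(family = "gamma", scale = speckle_scale),
                               seed = as.integer(seed) + i, ...)
  }
  out
}
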
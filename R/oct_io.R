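# Core rasters and file I/O.
#
# Conventions used throughout the package:
#  * A volume is an nx x nB x nz array indexed [x, B, z]: x = lateral position
#    within a B-scan, B = B-scan index, z = axial depth increasing downward.
#  * All coordinates and surface heights in the public API are 0-based voxel
#    indices (array access adds 1 internally).
#  * A surface "height" z(x, B) is the z index of the boundary voxel itself —
#    the deepest voxel of the tissue above the interface — and the slab
#    "between surfaces A and B" is the half-open axial range (z_A, z_B], so
#    adjacent slabs partition the retina without overlap.

#' OCT volume container
#'
#' Wraps a 3D intensity raster with its anisotropic voxel spacing.
#'
#' @param intensities numeric 3D array, `nx x nB x nz`, non-negative finite
#'   grey levels (nominal range 0..255).
#' @param spacing numeric length-3, micrometres per voxel along x, B, z.
#' @return An object of class `oct_volume` with elements `intensities` and
#'   `spacing`.
#' @examples
#' v <- oct_volume(array(100, c(8, 2, 8)))
#' dim(v$intensities)
#' @export
oct_volume <- function(intensities, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3)
    stop_param("oct_volume: intensities must be a 3D array, got %s dims",
               length(dim(intensities)))
  if (any(dim(intensities) < 1)) stop_param("oct_volume: all dimensions must be >= 1")
  if (!all(is.finite(intensities))) stop_param("oct_volume: intensities must be finite")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_param("oct_volume: spacing must be 3 strictly positive values")
  structure(list(intensities = intensities, spacing = as.numeric(spacing)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<oct_volume> %d x %d x %d voxels (x, B-scan, z), spacing %.2f x %.2f x %.2f um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

as_volume_array <- function(volume) {
  if (inherits(volume, "oct_volume")) volume$intensities else volume
}

#' Retinal surface container
#'
#' A per-(x, B-scan) axial height map for one retinal boundary.
#'
#' @param name one of `"ILM"`, `"EZ_ROOF"`, `"RPE_FLOOR"`, `"BM"`.
#' @param heights integer matrix `nx x nB` of 0-based axial (z) indices.
#' @param nz optional z extent used to validate `0 <= height < nz`.
#' @param integer require integer heights (searched surfaces); the
#'   hull-estimated BM may carry sub-voxel heights (`integer = FALSE`).
#' @return Object of class `oct_surface`.
#' @export
oct_surface <- function(name, heights, nz = NULL, integer = TRUE) {
  name <- match.arg(name, c("ILM", "EZ_ROOF", "RPE_FLOOR", "BM"))
  heights <- as.matrix(heights)
  if (any(!is.finite(heights)))
    stop_param("oct_surface: heights must be finite")
  if (integer && any(heights != round(heights)))
    stop_param("oct_surface: heights must be integers")
  if (any(heights < 0)) stop_param("oct_surface: heights must be >= 0")
  if (!is.null(nz) && any(heights >= nz))
    stop_param("oct_surface: heights must be < nz = %d", nz)
  structure(list(name = name, heights = heights), class = "oct_surface")
}

#' Height matrix of a surface (or pass a matrix through)
#' @param s [oct_surface] or height matrix.
#' @return numeric `nx x nB` matrix of 0-based heights.
#' @export
surface_heights <- function(s) if (inherits(s, "oct_surface")) s$heights else as.matrix(s)

#' Read an OCT volume from multi-page TIFF or NIfTI
#'
#' TIFF stacks are read as one page per B-scan with rows = z and columns = x,
#' with grey values rescaled to 0..255. NIfTI rasters are read as stored,
#' with spacing taken from the header `pixdim` when present.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @param spacing optional spacing override (micrometres per voxel, x/B/z).
#' @return [oct_volume].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop_param("read_volume: file not found: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2)
      stop_param("read_volume: %s: pages must be single-channel 2D images", path)
    nzv <- nrow(pages[[1]]); nxv <- ncol(pages[[1]])
    arr <- array(0, c(nxv, length(pages), nzv))
    for (b in seq_along(pages)) arr[, b, ] <- t(pages[[b]]) * 255
    oct_volume(arr, spacing %||% c(1, 1, 1))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3)
      stop_param("read_volume: %s: expected a 3D raster, got %dD", path, length(dim(a)))
    sp <- spacing
    if (is.null(sp)) {
      pd <- attr(RNifti::niftiHeader(img), "pixdim") %||% RNifti::pixdim(img)
      sp <- if (!is.null(pd) && length(pd) >= 3 && all(pd[1:3] > 0)) pd[1:3] * 1000 else c(1, 1, 1)
    }
    oct_volume(a, sp)
  } else stop_param("read_volume: unrecognized format (need TIFF or NIfTI): %s", path)
}

#' Write an OCT volume
#'
#' NIfTI (`.nii`/`.nii.gz`) stores the raster losslessly as float64 with the
#' spacing in the header (converted to millimetres, the NIfTI convention).
#' TIFF stores one 32-bit float page per B-scan, intensities divided by 255.
#'
#' @param volume [oct_volume].
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  a <- volume$intensities
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(a)[2]), function(b) t(a[, b, ]) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(a, reference = list(pixdim = c(1, volume$spacing / 1000, 1, 1, 1, 1)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
  } else stop_param("write_volume: unrecognized extension: %s", path)
  invisible(path)
}

#' Write / read a binary region mask
#'
#' Masks are stored as 8-bit rasters (0 background, 255 foreground): one TIFF
#' page per B-scan (rows z, columns x) or a NIfTI volume of 0/1.
#'
#' @param mask logical `nx x nB x nz` array.
#' @param path destination (TIFF or NIfTI).
#' @param volume optional [oct_volume] whose grid the mask must match.
#' @return `path` invisibly; `read_mask()` returns the logical array.
#' @export
write_mask <- function(mask, path, volume = NULL) {
  if (length(dim(mask)) != 3) stop_param("write_mask: mask must be a 3D array")
  if (!is.null(volume) && !identical(dim(mask), dim(as_volume_array(volume))))
    stop_param("write_mask: mask shape %s does not match volume shape %s",
               paste(dim(mask), collapse = "x"),
               paste(dim(as_volume_array(volume)), collapse = "x"))
  m <- array(as.numeric(mask != 0), dim(mask))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(dim(m)[2]), function(b) t(m[, b, ]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  } else stop_param("write_mask: unrecognized extension: %s", path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_param("read_mask: file not found: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nzv <- nrow(pages[[1]]); nxv <- ncol(pages[[1]])
    arr <- array(FALSE, c(nxv, length(pages), nzv))
    for (b in seq_along(pages)) arr[, b, ] <- t(pages[[b]]) > 0.5
    arr
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    as.array(RNifti::readNifti(path)) > 0.5
  } else stop_param("read_mask: unrecognized extension: %s", path)
}

#' Write / read retinal surfaces as CSV
#'
#' Long-format CSV with 0-based columns `x`, `bscan`, and one `z_*` column per
#' surface (`z_ilm`, `z_ez`, `z_rpe`, `z_bm` for the standard set).
#'
#' @param surfaces named list of [oct_surface] (or plain height matrices);
#'   names among ILM, EZ_ROOF, RPE_FLOOR, BM.
#' @param path CSV destination.
#' @return `path` invisibly; `read_surfaces()` returns the named list of
#'   [oct_surface] objects.
#' @export
write_surfaces <- function(surfaces, path) {
  cols <- c(ILM = "z_ilm", EZ_ROOF = "z_ez", RPE_FLOOR = "z_rpe", BM = "z_bm")
  hs <- lapply(surfaces, surface_heights)
  d <- dim(hs[[1]])
  for (h in hs) if (!identical(dim(h), d))
    stop_param("write_surfaces: inconsistent height map shapes")
  df <- data.frame(x = rep(0:(d[1] - 1), d[2]),
                   bscan = rep(0:(d[2] - 1), each = d[1]))
  for (nm in names(hs)) df[[cols[[nm]] %||% paste0("z_", tolower(nm))]] <- as.vector(hs[[nm]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  df <- read.csv(path)
  nx <- max(df$x) + 1L
  nB <- max(df$bscan) + 1L
  ord <- order(df$bscan, df$x)
  df <- df[ord, ]
  back <- c(z_ilm = "ILM", z_ez = "EZ_ROOF", z_rpe = "RPE_FLOOR", z_bm = "BM")
  out <- list()
  for (cn in setdiff(names(df), c("x", "bscan"))) {
    nm <- back[[cn]] %||% toupper(sub("^z_", "", cn))
    out[[nm]] <- oct_surface(nm, matrix(df[[cn]], nx, nB),
                             integer = all(df[[cn]] == round(df[[cn]])))
  }
  out
}

#' Read / write a run configuration
#'
#' Key-value configuration serialized as YAML or JSON, used by the pipeline
#' and the command-line driver.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @param config named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_param("read_config: unrecognized extension: %s", path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(config, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  else stop_param("write_config: unrecognized extension: %s", path)
  invisible(path)
}
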
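make_region <- function(px, pz, bscan = 0L)
  structure(list(bscan = bscan, label = 1L, pixels = cbind(x = px, z = pz)),
            class = "candidate_region")

flat_surfaces <- function(nx, ilm = 10, ez = 20, rpe = 30, bm = 35)
  list(ILM = rep(ilm, nx), EZ_ROOF = rep(ez, nx),
       RPE_FLOOR = rep(rpe, nx), BM = rep(bm, nx))

test_that("2D components use 8-connectivity with deterministic labels", {
  sl <- matrix(FALSE, 6, 6)
  sl[2, 2] <- TRUE; sl[3, 3] <- TRUE          # diagonal touch: one component
  regs <- components_2d(sl)
  expect_length(regs, 1)
  expect_equal(nrow(regs[[1]]$pixels), 2)
  expect_length(components_2d(matrix(FALSE, 4, 4)), 0)
  cb <- matrix(FALSE, 4, 4)
  cb[1, 1] <- TRUE; cb[2, 2] <- TRUE; cb[1, 3] <- TRUE; cb[2, 4] <- TRUE
  expect_length(components_2d(cb), 1)          # checkerboard chain, 8-connected
  two <- matrix(FALSE, 8, 8); two[1:2, 1:2] <- TRUE; two[6:7, 6:7] <- TRUE
  regs2 <- components_2d(two)
  expect_length(regs2, 2)
  expect_equal(regs2[[1]]$label, 1L)
  expect_lt(min(regs2[[1]]$pixels[, 2]), min(regs2[[2]]$pixels[, 2]))
})

test_that("a solid square reproduces its closed-form features", {
  nx <- 20; nz <- 20
  img <- matrix(0, nx, nz)
  px <- rep(5:14, 10); pz <- rep(5:14, each = 10)
  img[cbind(px + 1, pz + 1)] <- 100
  fv <- extract_features(make_region(px, pz), img, flat_surfaces(nx))
  expect_length(fv, 62)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["area"]), 100)
  expect_equal(unname(fv["perimeter"]), 40)
  expect_equal(unname(fv["eccentricity"]), 0, tolerance = 1e-9)
  expect_equal(unname(fv["equiv_diameter"]), sqrt(400 / pi), tolerance = 1e-9)
  expect_equal(unname(fv["solidity"]), 1.0)
  expect_equal(unname(fv["extent"]), 1.0)
  expect_equal(unname(fv["euler"]), 1)
  expect_equal(unname(fv[c("max_intensity", "min_intensity", "mean_intensity")]),
               c(100, 100, 100))
  expect_equal(unname(fv["major_axis"]), 4 * sqrt(mean((0:9 - 4.5)^2) + 1 / 12),
               tolerance = 1e-9)
  # centroid at z = 9.5; distance features are signed downward offsets
  expect_equal(unname(fv["dist_ilm"]), 9.5 - 10)
  expect_equal(unname(fv["dist_bm"]), 9.5 - 35)
  # identities among derived features
  expect_equal(unname(fv["axis_ratio"]), unname(fv["major_axis"] / fv["minor_axis"]),
               tolerance = 1e-9)
  expect_equal(unname(fv["perim_over_area"]), unname(fv["perimeter"] / fv["area"]),
               tolerance = 1e-9)
})

test_that("Euler number counts enclosed holes", {
  nx <- 12; nz <- 12
  img <- matrix(0, nx, nz)
  coords <- expand.grid(x = 2:8, z = 2:8)
  coords <- coords[!(coords$x == 5 & coords$z == 5), ]   # one interior hole
  fv <- extract_features(make_region(coords$x, coords$z), img, flat_surfaces(nx))
  expect_equal(unname(fv["euler"]), 0)
})

test_that("translation invariance of shape and Hessian features", {
  nx <- 40; nz <- 40
  img <- matrix(0, nx, nz)
  px <- c(5:9, 5:9, 5:7); pz <- c(rep(5, 5), rep(6, 5), rep(7, 3))
  img[cbind(px + 1, pz + 1)] <- 50
  img2 <- matrix(0, nx, nz)
  img2[cbind(px + 8, pz + 11)] <- 50
  fv1 <- extract_features(make_region(px, pz), img, flat_surfaces(nx))
  fv2 <- extract_features(make_region(px + 7, pz + 10), img2, flat_surfaces(nx))
  shape <- c("area", "perimeter", "major_axis", "minor_axis", "axis_ratio",
             "perim_over_area", "eccentricity", "euler", "equiv_diameter",
             "solidity", "extent", "convex_area",
             "max_intensity", "min_intensity", "mean_intensity")
  expect_equal(fv1[shape], fv2[shape], tolerance = 1e-9)
  hess <- grep("^hess", names(fv1), value = TRUE)
  expect_equal(fv1[hess], fv2[hess], tolerance = 1e-6)
  expect_equal(unname(fv2["centroid_x"] - fv1["centroid_x"]), 7)
  expect_equal(unname(fv2["centroid_z"] - fv1["centroid_z"]), 10)
  expect_equal(unname(fv2["bbox_x"] - fv1["bbox_x"]), 7)
})

test_that("Hessian eigenvalues recover analytic curvature and rotation invariance", {
  nx <- 48; nz <- 48
  zs <- matrix(rep(0:(nz - 1), each = nx), nx, nz)
  img <- zs^2
  px <- rep(20:27, 8); pz <- rep(20:27, each = 8)
  hv <- hessian_features(make_region(px, pz), img, scales = c(1, 2))
  expect_equal(unname(hv[1]), 0, tolerance = 1e-6)   # |l1| (lateral) ~ 0
  expect_equal(unname(hv[2]), 2, tolerance = 1e-6)   # |l2| (axial) = 2
  # 90-degree rotation: eigenvalues invariant
  set.seed(3)
  img_r <- matrix(runif(24 * 24), 24, 24)
  px2 <- c(8:12, 8:12); pz2 <- c(rep(10, 5), rep(11, 5))
  h1 <- hessian_features(make_region(px2, pz2), img_r, scales = c(1, 3))
  rot <- t(img_r)[, ncol(img_r):1]   # rotate 90 degrees
  # pixel (x, z) maps to (z, n-1-x)
  px3 <- pz2; pz3 <- 23 - px2
  h2 <- hessian_features(make_region(px3, pz3), rot, scales = c(1, 3))
  expect_equal(unname(h1), unname(h2), tolerance = 1e-3)
  # single-pixel region mean equals that pixel's eigenvalues
  h_one <- hessian_features(make_region(10L, 12L), img_r, scales = 2)
  cache <- hessian_cache(img_r, 2)
  expect_equal(unname(h_one), c(cache[[1]]$l1[11, 13], cache[[1]]$l2[11, 13]))
  # constant region on constant image: zero curvature
  hc <- hessian_features(make_region(px2, pz2), matrix(5, 24, 24), scales = c(1, 3))
  expect_equal(unname(hc), rep(0, 4), tolerance = 1e-9)
})

test_that("feature tables have one row of 62 features per region", {
  ph <- generate_phantom(tiny_phantom(seed = 13))
  surf <- ph$truth$surfaces
  init <- ph$truth$ped_mask
  tab <- build_feature_table(ph$volume, init, surf, truth = ph$truth$ped_mask)
  expect_equal(length(feature_columns(tab)), 62)
  expect_true(all(tab$label == 1))
  expect_true(all(is.finite(as.matrix(tab[feature_columns(tab)]))))
  regs <- attr(tab, "regions")
  expect_equal(nrow(tab), length(regs))
  expect_error(extract_features(make_region(50L, 2L), matrix(0, 10, 10),
                                flat_surfaces(10)), "outside")
})
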
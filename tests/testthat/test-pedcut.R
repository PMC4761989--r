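test_that("adaptive SE radius follows the cube-root rule", {
  expect_equal(se_radius(0, 0.143), 0L)
  expect_equal(se_radius(1000, 0.143), 1L)
  expect_equal(se_radius(1000, 1.143), 11L)
  expect_equal(se_radius(1331, 0.143), 2L)
  expect_true(all(diff(se_radius(c(10, 100, 1000, 10000), 0.7)) >= 0))
  expect_error(se_radius(10, 0), "c")
  expect_error(se_radius(-1, 0.2), "V")
})

test_that("ball morphology matches the brute-force discrete-ball oracle", {
  set.seed(31)
  for (trial in 1:6) {
    d <- c(9, 8, 9)
    m <- array(runif(prod(d)) < 0.35, d)
    for (r in 1:3) {
      expect_identical(pedseg:::ball_erode(m, r), brute_erode(m, r),
                       info = sprintf("erode trial %d r %d", trial, r))
      expect_identical(pedseg:::ball_dilate(m, r), brute_dilate(m, r),
                       info = sprintf("dilate trial %d r %d", trial, r))
    }
  }
})

test_that("seeds honor the morphology containment chain on the 11-cube", {
  d <- c(45, 45, 45)
  mask <- array(FALSE, d); mask[17:27, 17:27, 17:27] <- TRUE
  seeds <- make_seeds(mask)
  expect_equal(sum(seeds$fg), 343)                 # inner 7^3 after r = 2 erosion
  expect_true(all(mask[seeds$fg]))                 # fg subset of region
  expect_false(any(seeds$fg & seeds$bg))           # disjoint
  dil <- pedseg:::ball_dilate(mask, seeds$regions[[1]]$r_bg)
  expect_false(any(seeds$bg & dil))                # bg outside the dilation
  expect_true(all(dil[mask]))
})

test_that("small regions fall back to their innermost voxel; empty masks are empty", {
  d <- c(20, 6, 20)
  mask2 <- array(FALSE, d); mask2[5:12, 2:4, 5:12] <- TRUE  # 192 voxels, r_fg 1
  seeds <- make_seeds(mask2)
  expect_gt(sum(seeds$fg), 0)
  expect_true(all(mask2[seeds$fg]))
  s0 <- make_seeds(array(FALSE, d))
  expect_equal(sum(s0$fg) + sum(s0$bg), 0)
  expect_length(s0$regions, 0)
  expect_equal(sum(graph_cut(array(50, d), s0, build_shape_prior(array(FALSE, d)))), 0)
})

test_that("Ritter sphere encloses every region voxel", {
  set.seed(13)
  for (trial in 1:10) {
    co <- matrix(sample(0:15, 30, replace = TRUE), ncol = 3)
    r <- pedseg:::ritter_radius(co)
    # some centre must exist within r of all points; verify via the midpoint
    # property: max pairwise distance <= 2 r
    dmax <- max(dist(co))
    expect_gte(2 * r + 1e-9, dmax / 1)
  }
  expect_equal(pedseg:::ritter_radius(matrix(c(1, 1, 1), 1, 3)), 0.5)
})

test_that("brightness transform anchors layer medians and preserves ordering", {
  ph <- generate_phantom(tiny_phantom(seed = 41))
  surf <- ph$truth$surfaces
  # anchored at the volume's own medians (vitreous 20, band slab median 170):
  # the transform is the identity up to interpolation error
  bt0 <- brightness_transform(ph$volume, surf, targets = c(bg = 20, rpe = 170))
  expect_lt(max(abs(bt0$intensities - ph$volume$intensities)), 1 + 1e-9)
  # uniformly dimmed volume recovers the target slab median
  dim_vol <- ph$volume
  dim_vol$intensities <- dim_vol$intensities * 0.5
  bt <- brightness_transform(dim_vol, surf, targets = c(bg = 20, rpe = 170))
  ez <- surface_heights(surf$EZ_ROOF); rpe <- surface_heights(surf$RPE_FLOOR)
  d <- dim(bt$intensities)
  meds <- c()
  for (b in seq_len(d[2])) for (x in seq_len(d[1])) {
    sl <- (ez[x, b] + 2):(rpe[x, b] + 1)
    meds <- c(meds, median(bt$intensities[x, b, sl]))
  }
  expect_lt(max(abs(meds - 170)), 1 + 1e-9)
  # monotone within every column
  for (x in c(1, 10)) {
    col_in <- dim_vol$intensities[x, 1, ]
    col_out <- bt$intensities[x, 1, ]
    ord <- order(col_in)
    expect_true(all(diff(col_out[ord]) >= -1e-9))
  }
})

test_that("energy terms satisfy their defining anchor values", {
  set.seed(17)
  vol <- array(runif(5 * 1 * 6, 0, 255), c(5, 1, 6))
  fg <- array(FALSE, dim(vol)); fg[3, 1, 3] <- TRUE
  bg <- array(FALSE, dim(vol)); bg[1, 1, 1] <- TRUE; bg[5, 1, 6] <- TRUE
  region <- array(FALSE, dim(vol)); region[3, 1, 3:4] <- TRUE
  dist_field <- sqrt(pedseg:::sq_edt(region))
  r <- 2
  et <- energy_terms(vol, fg, bg, dist_field, r, energy_weights(0.4, 0.2, 0.4))
  # inside the prior region d = 0 so S(obj) = 0; at d >= r it saturates at 1
  S <- pmin(as.vector(dist_field) / r, 1)
  expect_equal(S[as.vector(region)], rep(0, sum(region)))
  far <- which(as.vector(dist_field) >= r & !as.vector(bg) & !as.vector(fg))
  expect_equal(S[far[1]], 1)
  expect_true(all(is.finite(et$unary[as.vector(!fg & !bg), ])))
  # equal intensities give the maximal boundary weight lambda_b * 1
  vol2 <- array(100, c(3, 1, 3))
  fg2 <- array(FALSE, dim(vol2)); fg2[1, 1, 1] <- TRUE
  bg2 <- array(FALSE, dim(vol2)); bg2[3, 1, 3] <- TRUE
  et2 <- energy_terms(vol2, fg2, bg2, array(0, dim(vol2)), 1,
                      energy_weights(0.4, 0.2, 0.4))
  expect_true(all(abs(et2$edges$w - 0.4) < 1e-12))
  expect_error(energy_terms(vol2, array(FALSE, dim(vol2)), bg2,
                            array(0, dim(vol2)), 1, energy_weights()),
               "seed")
})

test_that("min-cut labeling attains the exhaustive minimum energy", {
  set.seed(23)
  for (trial in 1:12) {
    n <- 10
    unary <- cbind(obj = runif(n, 0, 3), bg = runif(n, 0, 3))
    pq <- t(combn(n, 2))
    pq <- pq[runif(nrow(pq)) < 0.3, , drop = FALSE]
    edges <- data.frame(p = pq[, 1], q = pq[, 2], w = runif(nrow(pq), 0, 1))
    fixed <- integer(n); fixed[1] <- 1L; fixed[n] <- -1L
    lab <- solve_binary_cut(unary, edges, fixed)
    expect_true(lab[1]); expect_false(lab[n])
    expect_equal(attr(lab, "energy"), brute_min_energy(unary, edges, fixed),
                 tolerance = 1e-9, info = paste("trial", trial))
  }
})

test_that("decoupled weights reduce the cut to per-voxel thresholds", {
  ph <- generate_phantom(tiny_phantom(seed = 51))
  vol <- ph$volume$intensities
  refined <- ph$truth$ped_mask
  seeds <- make_seeds(refined)
  prior <- build_shape_prior(refined)
  # lambda_S = lambda_B = 0: labeling equals the per-voxel argmin of R
  cutR <- graph_cut(vol, seeds, prior, energy_weights(1, 0, 0))
  reg <- seeds$regions[[1]]
  bb <- reg$box
  mk <- function(vox) { m <- array(FALSE, dim(vol)); m[vox] <- TRUE; pedseg:::crop3(m, bb) }
  vc <- pedseg:::crop3(vol, bb)
  et <- energy_terms(vc, mk(reg$fg_vox), mk(reg$bg_vox),
                     sqrt(pedseg:::sq_edt(mk(prior$regions[[1]]$vox))),
                     prior$regions[[1]]$r, energy_weights(1, 0, 0))
  fixed <- as.integer(mk(reg$fg_vox)) - as.integer(mk(reg$bg_vox))
  manual <- et$unary[, "obj"] < et$unary[, "bg"]
  manual[fixed == 1] <- TRUE; manual[fixed == -1] <- FALSE
  expect_equal(as.vector(pedseg:::crop3(cutR, bb)), unname(manual))
})

test_that("a pure shape energy thresholds distance at half the enclosing radius", {
  d <- c(14, 3, 14)
  vol <- array(runif(prod(d), 0, 255), d)
  refined <- array(FALSE, d); refined[7:8, 2, 7] <- TRUE  # tiny: r = 0.5
  seeds <- make_seeds(refined)
  prior <- build_shape_prior(refined)
  cutS <- graph_cut(vol, seeds, prior, energy_weights(0, 1, 0))
  expect_identical(cutS, refined)   # r/2 < 1: no outside voxel qualifies
  # output always contains all fg seeds and no bg seeds
  expect_true(all(cutS[seeds$fg]))
  expect_false(any(cutS & seeds$bg))
})

test_that("graph-cut output respects seed hard constraints on phantoms", {
  ph <- generate_phantom(tiny_phantom(seed = 61))
  noisy <- add_speckle(ph$volume, 0.2, seed = 61)
  den <- mcde_filter(noisy, diffusion_params(K = 25, iterations = 3))
  refined <- ph$truth$ped_mask
  seeds <- make_seeds(refined)
  cutm <- graph_cut(den, seeds, build_shape_prior(refined), energy_weights())
  expect_true(all(cutm[seeds$fg]))
  expect_false(any(cutm & seeds$bg))
  m <- compute_metrics(cutm, ph$truth$ped_mask, ph$truth$retina_mask)
  expect_gte(m$dsc, 0.85)
})

test_that("weight estimation stays on the simplex and never degrades the objective", {
  # controlled experiment: PED fluid painted at the choroid level makes the
  # intensity term uninformative below BM, so the shape prior (built from
  # the truth mask) carries real signal
  mkcase <- function(s) {
    lev <- c(background = 20, nfl = 170, onl = 55, ez = 140, rpe = 200,
             fluid = 90, choroid = 90)
    ph <- generate_phantom(tiny_phantom(seed = s, levels = lev))
    noisy <- add_speckle(ph$volume, 0.15, seed = s)
    list(volume = mcde_filter(noisy, diffusion_params(K = 25, iterations = 3)),
         refined = ph$truth$ped_mask, truth = ph$truth$ped_mask)
  }
  cases <- lapply(c(71, 72), mkcase)
  init <- energy_weights(0.5, 0.1, 0.4)
  w <- estimate_weights(cases, init = init, maxit = 3)
  expect_equal(w$lambda_r + w$lambda_s + w$lambda_b, 1, tolerance = 1e-12)
  expect_true(all(unlist(w) >= 0))
  obj_init <- attr(estimate_weights(cases, init = init, maxit = 0), "objective")
  expect_gte(attr(w, "objective"), obj_init)
  # the informative shape weight must not decrease from a small start
  expect_gte(w$lambda_s, init$lambda_s - 1e-9)
  expect_error(estimate_weights(list()), "at least one")
})

test_that("postprocess removes diagonal spurs, fills holes, and is idempotent", {
  d <- c(24, 10, 24)
  mask <- array(FALSE, d)
  mask[6:15, 3:7, 6:15] <- TRUE          # 500-voxel block: r_recon 2, r_close 6
  mask[10, 5, 10] <- FALSE               # interior 1-voxel hole
  mask[16, 8, 16] <- TRUE                # diagonal 1-voxel spur (26- not 6-connected)
  out <- postprocess_mask(mask)
  expect_false(out[16, 8, 16])           # spur removed
  expect_true(out[10, 5, 10])            # hole filled
  block <- array(FALSE, d); block[6:15, 3:7, 6:15] <- TRUE
  expect_true(all(out[block]))           # main body restored
  expect_identical(postprocess_mask(out), out)
  expect_equal(sum(postprocess_mask(array(FALSE, d))), 0)
  # region count never increases; idempotence on random blob masks
  set.seed(19)
  for (trial in 1:5) {
    m <- array(FALSE, c(20, 8, 20))
    for (k in 1:3) {
      c0 <- c(sample(4:16, 1), sample(2:6, 1), sample(4:16, 1))
      r0 <- sample(2:3, 1)
      idx <- which(array(TRUE, dim(m)))
      co <- arrayInd(idx, dim(m))
      m[idx[rowSums(sweep(co, 2, c0)^2) <= r0^2]] <- TRUE
    }
    p1 <- postprocess_mask(m)
    n_in <- max(pedseg:::label_components(m, 26L))
    n_out <- if (any(p1)) max(pedseg:::label_components(p1, 26L)) else 0L
    expect_lte(n_out, n_in)
    expect_identical(postprocess_mask(p1), p1, info = paste("trial", trial))
  }
})
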
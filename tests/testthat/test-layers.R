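test_that("surface cost tracks polarity on a two-band image", {
  # dark (10) above bright (100); boundary voxel = last dark row z = 4
  a <- array(10, c(6, 1, 10)); a[, , 6:10] <- 100
  co <- surface_cost(a, "dark_to_bright")
  for (x in 1:6) expect_equal(which.min(co[x, 1, ]) - 1L, 4L)
  cb <- surface_cost(a, "bright_to_dark")
  for (x in 1:6) expect_false(which.min(cb[x, 1, ]) - 1L == 4L)
  cc <- surface_cost(array(7, c(3, 1, 5)), "dark_to_bright")
  expect_true(all(cc == 0))
})

test_that("single-surface search solves the worked 4-column example", {
  cost <- array(0, c(4, 1, 3))
  cost[1, 1, ] <- c(5, 1, 5); cost[2, 1, ] <- c(5, 1, 5)
  cost[3, 1, ] <- c(5, 5, 1); cost[4, 1, ] <- c(5, 5, 1)
  sp <- surface_search_spec("dark_to_bright", delta_x = 1)
  for (m in c("dp", "mincut")) {
    h <- single_surface_search(cost, sp, method = m)
    expect_equal(as.vector(h), c(1, 1, 2, 2))
    expect_equal(sum(cost[cbind(1:4, 1, h + 1)]), 4)
  }
})

test_that("both solvers equal exhaustive enumeration on random rasters", {
  set.seed(101)
  for (trial in 1:30) {
    nx <- sample(2:5, 1); nz <- sample(3:6, 1); delta <- sample(0:2, 1)
    cost2 <- matrix(sample(0:9, nx * nz, replace = TRUE), nx, nz)
    ref <- enumerate_surface(cost2, delta)
    sp <- surface_search_spec("dark_to_bright", delta_x = delta)
    cost3 <- array(cost2, c(nx, 1, nz))
    for (m in c("dp", "mincut")) {
      h <- single_surface_search(cost3, sp, method = m)
      expect_equal(sum(cost2[cbind(1:nx, as.vector(h) + 1)]), ref$cost,
                   info = sprintf("trial %d method %s", trial, m))
      expect_equal(as.vector(h), unname(ref$surface),
                   info = sprintf("trial %d method %s tie rule", trial, m))
    }
  }
})

test_that("the min-cut solver honors the cross-B-scan constraint", {
  set.seed(7)
  for (trial in 1:10) {
    cost <- array(sample(0:9, 2 * 2 * 4, replace = TRUE), c(2, 2, 4))
    sp <- surface_search_spec("dark_to_bright", delta_x = 1, delta_b = 1)
    h <- single_surface_search(cost, sp, method = "mincut")
    # enumerate all 4 columns jointly
    grid <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3))
    ok <- abs(grid[, 1] - grid[, 2]) <= 1 & abs(grid[, 3] - grid[, 4]) <= 1 &
      abs(grid[, 1] - grid[, 3]) <= 1 & abs(grid[, 2] - grid[, 4]) <= 1
    grid <- grid[ok, , drop = FALSE]
    cols <- rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
    costs <- apply(grid, 1, function(zs)
      sum(cost[cbind(cols[, 1], cols[, 2], zs + 1)]))
    expect_equal(sum(cost[cbind(cols[, 1], cols[, 2], as.vector(h) + 1)]),
                 min(costs), info = paste("trial", trial))
  }
})

test_that("delta 0 reduces to the best constant surface and ties break shallow", {
  cost2 <- matrix(c(3, 1, 2,
                    2, 1, 3,
                    4, 1, 1), 3, 3, byrow = TRUE)
  sp0 <- surface_search_spec("dark_to_bright", delta_x = 0)
  h <- single_surface_search(array(cost2, c(3, 1, 3)), sp0, "dp")
  expect_equal(as.vector(h), rep(which.min(colSums(cost2)) - 1L, 3))
  hu <- single_surface_search(array(5, c(4, 1, 6)),
                              surface_search_spec("dark_to_bright", delta_x = 2))
  expect_equal(as.vector(hu), rep(0L, 4))
})

test_that("infeasible bands raise an explicit error", {
  cost <- array(1, c(3, 1, 6))
  sp <- surface_search_spec("dark_to_bright", delta_x = 0,
                            band = list(lo = matrix(c(0, 5, 0), 3, 1),
                                        hi = matrix(c(1, 5, 1), 3, 1)))
  expect_error(single_surface_search(cost, sp), "infeasible")
})

test_that("multiscale equals single-scale on a smooth phantom and degenerates cleanly", {
  ph <- generate_phantom(tiny_phantom(seed = 21))
  a <- ph$volume$intensities
  sp2 <- surface_search_spec("dark_to_bright", delta_x = 1, scales = 2)
  sp0 <- surface_search_spec("dark_to_bright", delta_x = 1, scales = 0)
  h2 <- multiscale_search(a, sp2, margin = 8)
  h0 <- multiscale_search(a, sp0)
  hf <- single_surface_search(surface_cost(a, "dark_to_bright"),
                              surface_search_spec("dark_to_bright", delta_x = 1))
  expect_identical(h0, hf)
  expect_identical(h2, hf)
  expect_error(multiscale_search(array(1, c(4, 1, 8)),
                                 surface_search_spec("dark_to_bright", scales = 2)),
               "shallow")
})

test_that("a coarse surface outside the band clamps to the band edge", {
  # bright edge near the bottom, but the caller band confines the search to
  # the top rows: the fine result must stay inside the band
  a <- array(10, c(6, 1, 32)); a[, , 25:32] <- 200
  sp <- surface_search_spec("dark_to_bright", delta_x = 1,
                            band = list(lo = 0, hi = 6), scales = 1)
  h <- multiscale_search(a, sp, margin = 2)
  expect_true(all(h <= 6))
})

test_that("segment_layers recovers phantom surfaces and never crosses", {
  ph <- generate_phantom(tiny_phantom(seed = 31))
  surf <- segment_layers(ph$volume)
  for (nm in names(surf)) {
    err <- abs(surface_heights(surf[[nm]]) -
               surface_heights(ph$truth$surfaces[[nm]]))
    expect_lte(mean(err), 1)
  }
  # PED arch followed at the apex
  p20 <- tiny_phantom(seed = 32)
  p20$peds <- list(list(cx = 24, cB = 4, a = 14, b = 3, h = 16))
  ph2 <- generate_phantom(p20)
  # the arch rim jumps up to 6 voxels per column; the smoothness constraint
  # must be at least the apex slope for the floor to follow the arch
  surf2 <- segment_layers(ph2$volume, layer_params(delta_rpe = 8))
  err_rpe <- abs(surface_heights(surf2$RPE_FLOOR) -
                 surface_heights(ph2$truth$surfaces$RPE_FLOOR))
  expect_lte(max(err_rpe), 2)
  for (seed in 1:10) {
    phr <- generate_phantom(tiny_phantom(seed = 100 + seed))
    noisy <- add_speckle(phr$volume, 0.2, seed = seed)
    s <- segment_layers(mcde_filter(noisy, diffusion_params(K = 25, iterations = 3)))
    expect_true(all(surface_heights(s$ILM) < surface_heights(s$EZ_ROOF)))
    expect_true(all(surface_heights(s$EZ_ROOF) < surface_heights(s$RPE_FLOOR)))
  }
})

test_that("estimate_bm matches the brute-force chord hull", {
  expect_equal(as.vector(surface_heights(estimate_bm(matrix(10, 5, 1)))), rep(10, 5))
  expect_equal(as.vector(surface_heights(estimate_bm(matrix(c(10, 10, 6, 10, 10), 5, 1)))),
               rep(10, 5))
  expect_equal(as.vector(surface_heights(estimate_bm(matrix(1:4, 4, 1)))), 1:4)
  set.seed(55)
  for (trial in 1:40) {
    n <- sample(4:16, 1)
    z <- sample(0:20, n, replace = TRUE)
    bm <- as.vector(surface_heights(estimate_bm(matrix(z, n, 1))))
    ref <- brute_lower_hull(z)
    expect_equal(bm, ref, tolerance = 1e-9, info = paste("trial", trial))
    expect_true(all(bm >= z - 1e-9))
    d2 <- diff(diff(bm))
    expect_true(all(d2 <= 1e-9))             # hull chain: slopes non-increasing
    expect_gte(sum(abs(bm - z) < 1e-9), 2)   # touches the trace at >= 2 columns
  }
})

test_that("initial PED mask follows the half-open slab convention", {
  rpe <- matrix(5, 1, 1); bm <- matrix(8, 1, 1)
  m <- initial_ped_mask(rpe, bm, 12)
  expect_equal(which(m[1, 1, ]) - 1L, c(6L, 7L, 8L))
  expect_equal(sum(initial_ped_mask(rpe, rpe, 12)), 0)
  expect_error(initial_ped_mask(matrix(9, 1, 1), matrix(5, 1, 1), 12), "below")
  ph <- generate_phantom(tiny_phantom(seed = 77))
  surf <- segment_layers(ph$volume)
  bmS <- estimate_bm(surf$RPE_FLOOR)
  init <- initial_ped_mask(surf$RPE_FLOOR, bmS, dim(ph$volume$intensities)[3])
  expect_lt(abs(sum(init) - sum(ph$truth$ped_mask)) / sum(ph$truth$ped_mask), 0.15)
})
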
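test_that("3D Sobel matches a direct convolution oracle", {
  a <- withr::with_seed(21, array(runif(9^3), c(9, 9, 9)))
  g <- sobel3d(volume(a, 100))
  expect_lt(max(abs(g$gz - oracle_sobel(a, 1))), 1e-10)
  expect_lt(max(abs(g$gy - oracle_sobel(a, 2))), 1e-10)
  expect_lt(max(abs(g$gx - oracle_sobel(a, 3))), 1e-10)
})

test_that("Sobel of constant and ramp volumes behaves analytically", {
  g0 <- sobel3d(volume(array(0.5, c(8, 8, 8)), 100))
  expect_true(all(g0$gx == 0) && all(g0$gy == 0) && all(g0$gz == 0))

  ramp <- volume(array(rep(1:10, each = 64) / 10, c(8, 8, 10)), 100)
  g <- sobel3d(ramp)
  interior <- g$gx[3:6, 3:6, 3:8]
  expect_true(all(abs(interior - 0.1) < 1e-12))
  expect_true(all(abs(g$gy[3:6, 3:6, 3:8]) < 1e-12))
  expect_true(all(abs(g$gz[3:6, 3:6, 3:8]) < 1e-12))

  expect_error(sobel3d(volume(array(0, c(2, 8, 8)), 100)), "smaller")
})

test_that("GVF of a zero field is zero with zero energy", {
  g <- sobel3d(volume(array(0.5, c(8, 8, 8)), 100))
  gvf <- compute_gvf(g, mu = 0.2, n_iter = 10)
  expect_true(all(gvf$vx == 0) && all(gvf$vy == 0) && all(gvf$vz == 0))
  expect_true(all(gvf$energy == 0))
})

test_that("GVF energy is non-increasing and the field diffuses outward", {
  a <- withr::with_seed(8, array(runif(16^3), c(16, 16, 16)))
  gvf <- compute_gvf(sobel3d(volume(a, 100)), mu = 0.2, n_iter = 40)
  expect_true(all(diff(gvf$energy) <= 1e-10))
  expect_lt(gvf$energy[41], gvf$energy[1])

  # single bright voxel: after many iterations the field reaches 3 voxels out
  b <- array(0, c(17, 17, 17)); b[9, 9, 9] <- 1
  gv <- compute_gvf(sobel3d(volume(b, 100)), mu = 0.2, n_iter = 150)
  mag_far <- sqrt(gv$vx[9, 9, 13]^2 + gv$vy[9, 9, 13]^2 + gv$vz[9, 9, 13]^2)
  expect_gt(mag_far, 1e-6)
})

test_that("seed detection finds tube axes and is reproducible", {
  blank <- normalize_volume(volume(
    withr::with_seed(2, array(runif(16^3, 0.45, 0.55), c(16, 16, 16))), 100))
  gvf_b <- compute_gvf(sobel3d(blank$volume), n_iter = 10)
  expect_equal(nrow(detect_seeds(blank$volume, gvf_b)), 0)

  ph <- tube_phantom(radius_vox = 3, shape = c(48, 48, 48))
  nv <- normalize_volume(ph$volume)$volume
  gvf <- compute_gvf(sobel3d(nv))
  s1 <- detect_seeds(nv, gvf)
  expect_gt(nrow(s1), 0)
  # strongest interior seed lies within 1 voxel of the true axis (y = z = 24)
  interior <- s1[s1$x > 4 & s1$x < 44, ]
  expect_lt(sqrt((interior$y[1] - 24)^2 + (interior$z[1] - 24)^2), 1 + 1e-9)
  expect_identical(s1, detect_seeds(nv, gvf))
})

test_that("straight tubes trace to sub-voxel centerline accuracy", {
  for (noise in c(0, 0.05 * 0.7)) {
    ph <- tube_phantom(radius_vox = 3, shape = c(48, 48, 48),
                       noise_sd = noise, seed = 17)
    nv <- normalize_volume(ph$volume)$volume
    model <- trace_model(nv)
    gt <- geometry_table(model)
    expect_gte(nrow(gt), 1)
    main <- which.max(gt$length_um)
    nd <- model$constituents[[which(vapply(model$constituents,
                                           function(cc) cc$id, "") ==
                                      gt$constituent_id[main])]]$nodes
    dev <- sqrt((nd$y - ph$axis_y)^2 + (nd$z - ph$axis_z)^2) / ph$vox
    expect_lt(sqrt(mean(dev^2)), 0.5)
    expect_lt(abs(gt$mean_radius[main] - ph$radius_um) / ph$radius_um, 0.12)
  }
})

test_that("radius estimation is accurate and rotation-invariant", {
  ph <- tube_phantom(radius_vox = 4, shape = c(48, 48, 48))
  nv <- normalize_volume(ph$volume)$volume
  r <- estimate_radius(nv, c(2.4, ph$axis_y, ph$axis_z), c(1, 0, 0))
  expect_gte(r / ph$vox, 3.5)
  expect_lte(r / ph$vox, 4.5)

  # the same tube laid along y instead of x: estimate within 2%
  vox <- ph$vox
  tube_y <- make_parametric_curve("line", list(
    start = c(2.35, 0.4, 2.35), direction = c(0, 1, 0), length = 3.9,
    radius = 4 * vox), 50)
  ph2 <- render_volume(phantom_spec(shape = c(48, 48, 48),
                                    voxel_size_nm = 100,
                                    curves = list(list(polyline = tube_y))))
  nv2 <- normalize_volume(ph2$volume)$volume
  r2 <- estimate_radius(nv2, c(2.35, 2.4, 2.35), c(0, 1, 0))
  expect_lt(abs(r2 - r) / r, 0.02)

  expect_error(estimate_radius(nv, c(0.4, 0.4, 0.4), c(1, 0, 0)),
               "below the stop threshold")
})

test_that("seeds inside the visited mask are rejected", {
  ph <- tube_phantom(radius_vox = 3, shape = c(32, 32, 32))
  nv <- normalize_volume(ph$volume)$volume
  grad <- sobel3d(nv)
  gvf <- compute_gvf(grad)
  seeds <- detect_seeds(nv, gvf)
  visited <- array(TRUE, dim(nv))
  expect_null(trace_constituent(nv, grad, gvf,
                                c(seeds$z[1], seeds$y[1], seeds$x[1]),
                                visited = visited))
})

test_that("tracing is equivariant under integer-voxel translation", {
  vox <- 0.1
  mk <- function(shift_vox) {
    tube <- make_parametric_curve("line", list(
      start = c(0.5, 2.0 + shift_vox * vox, 2.0), direction = c(1, 0, 0),
      length = 3.6, radius = 0.3), 40)
    ph <- render_volume(phantom_spec(shape = c(48, 48, 48),
                                     voxel_size_nm = 100,
                                     curves = list(list(polyline = tube))))
    trace_model(normalize_volume(ph$volume)$volume)
  }
  m0 <- mk(0); m3 <- mk(3)
  n0 <- m0$constituents[[1]]$nodes
  n3 <- m3$constituents[[1]]$nodes
  expect_equal(mean(n3$y) - mean(n0$y), 3 * vox, tolerance = 0.02)
  expect_equal(mean(n3$z), mean(n0$z), tolerance = 0.01)
})

test_that("well-separated parallel tubes give two neurites and no spines", {
  vox <- 0.1
  t1 <- make_parametric_curve("line", list(start = c(0.5, 1.5, 2.3),
                                           direction = c(1, 0, 0),
                                           length = 3.6, radius = 0.3), 40)
  t2 <- make_parametric_curve("line", list(start = c(0.5, 3.2, 2.3),
                                           direction = c(1, 0, 0),
                                           length = 3.6, radius = 0.3), 40)
  ph <- render_volume(phantom_spec(shape = c(48, 48, 48), voxel_size_nm = 100,
                                   curves = list(list(polyline = t1),
                                                 list(polyline = t2))))
  m <- trace_model(normalize_volume(ph$volume)$volume)
  types <- vapply(m$constituents, function(cc) cc$type, "")
  expect_equal(sum(types == "neurite"), 2)
  expect_equal(sum(types == "spine"), 0)
})

test_that("a blank volume yields an empty model", {
  blank <- volume(withr::with_seed(4, array(runif(24^3, 0.49, 0.51),
                                            c(24, 24, 24))), 100)
  m <- trace_model(blank)
  expect_equal(length(m$constituents), 0)
})

test_that("a spiny neurite phantom is recovered with high spine recall", {
  ph <- spiny_phantom(n_spine_seed = 4)
  m <- trace_model(normalize_volume(ph$volume)$volume)
  types <- vapply(m$constituents, function(cc) cc$type, "")
  expect_equal(sum(types == "neurite"), 1)
  expect_gte(sum(types == "spine"), ceiling(0.8 * ph$n_true_spines))
  # every spine is attached to the single neurite
  for (cc in m$constituents) {
    if (cc$type == "spine") {
      expect_equal(cc$attachment$parent_id, "N001")
    }
  }
})
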
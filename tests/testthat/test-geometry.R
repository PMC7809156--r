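test_that("Menger curvature is exact on circles and zero on lines", {
  circ <- make_parametric_curve("circle", list(a = 2), 100)
  k <- curvature_profile(circ)
  expect_true(all(abs(k - 0.5) < 1e-3))

  line <- polyline(cbind(seq(0, 5, by = 0.5), 0, 0))
  expect_true(all(curvature_profile(line) == 0))

  expect_error(curvature_profile(polyline(cbind(c(0, 1), 0, 0))), ">= 3")
})

test_that("Menger curvature matches an independent circumradius solver", {
  for (seed in 1:25) {
    pts <- withr::with_seed(seed, matrix(runif(18, 0, 10), ncol = 3))
    pl <- polyline(pts)
    k <- curvature_profile(pl)
    for (i in 2:(nrow(pts) - 1)) {
      r <- oracle_circumradius(pts[i - 1, ], pts[i, ], pts[i + 1, ])
      expect_lt(abs(k[i - 1] - 1 / r), 1e-10)
    }
  }
})

test_that("torsion is signed by chirality and zero for planar curves", {
  h <- make_parametric_curve("helix", list(a = 1, b = 0.5, turns = 3), 600)
  expect_equal(mean(torsion_profile(h)), 0.4, tolerance = 0.01)

  hl <- make_parametric_curve("helix",
                              list(a = 1, b = 0.5, turns = 3,
                                   handedness = -1), 600)
  expect_equal(mean(torsion_profile(hl)), -0.4, tolerance = 0.01)

  zig <- polyline(cbind(0:6, c(0, 1, 0, 1, 0, 1, 0), 0))
  expect_true(all(torsion_profile(zig) == 0))

  expect_error(torsion_profile(polyline(cbind(0:2, 0, 0))), ">= 4")
})

test_that("profile lengths follow the n-2 / n-3 / n-1 count rule", {
  pl <- withr::with_seed(5, polyline(matrix(runif(30, 0, 10), ncol = 3)))
  g <- curve_geometry(pl)
  expect_length(g$curvature, 8)
  expect_length(g$torsion, 7)
  expect_length(g$edge_length, 9)
})

test_that("constituent summaries recover closed forms and spine lengths", {
  circ <- make_parametric_curve("circle", list(a = 2, radius = 0.33), 100)
  g <- constituent_geometry(circ)
  expect_equal(g$mean_radius, 0.33)
  expect_equal(g$mean_curvature, 0.5, tolerance = 1e-4)

  h <- make_parametric_curve("helix", list(a = 1, b = 0.5, turns = 3), 600)
  gh <- constituent_geometry(h)
  expect_equal(gh$mean_curvature, 0.8, tolerance = 0.008)
  expect_equal(gh$mean_torsion, 0.4, tolerance = 0.004)

  # 3-node spine with unit edges attached 0.5 um from the parent node
  spine <- list(id = "s", type = "spine",
                nodes = polyline(cbind(c(0.5, 1.5, 2.5), 0, 0), 0.1))
  gs <- constituent_geometry(spine, parent_node = c(0, 0, 0))
  expect_equal(gs$spine_length_um, 2.5)
  expect_equal(gs$length_um, 2)
})

test_that("curvature and |torsion| are rigid-motion invariant; reflection flips torsion sign", {
  pl <- withr::with_seed(9, polyline(matrix(runif(36, 0, 10), ncol = 3)))
  theta <- 0.7; phi <- 1.2
  rz <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  rx <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)), c(0, sin(phi), cos(phi)))
  rot <- rz %*% rx
  moved <- polyline(t(rot %*% t(as.matrix(pl[, c("x", "y", "z")]))) +
                      matrix(c(3, -2, 7), nrow(pl), 3, byrow = TRUE))
  expect_equal(curvature_profile(moved), curvature_profile(pl),
               tolerance = 1e-9)
  expect_equal(torsion_profile(moved), torsion_profile(pl), tolerance = 1e-9)
  refl <- polyline(as.matrix(pl[, c("x", "y", "z")]) %*% diag(c(1, 1, -1)))
  expect_equal(torsion_profile(refl), -torsion_profile(pl), tolerance = 1e-9)
})

test_that("scaling coordinates by s scales curvature and torsion by 1/s", {
  pl <- withr::with_seed(13, polyline(matrix(runif(30, 0, 10), ncol = 3)))
  s <- 2.5
  scaled <- polyline(as.matrix(pl[, c("x", "y", "z")]) * s)
  expect_equal(curvature_profile(scaled), curvature_profile(pl) / s)
  expect_equal(torsion_profile(scaled), torsion_profile(pl) / s)
  expect_equal(polyline_length(scaled), polyline_length(pl) * s)
})

test_that("helix curvature error shrinks at least linearly with sampling step", {
  errs <- vapply(c(50, 100, 200, 400), function(n) {
    h <- make_parametric_curve("helix", list(a = 1, b = 0.5, turns = 2), n)
    max(abs(curvature_profile(h) - 0.8))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # halving the step should at least halve the error (observed order >= 1)
  expect_lt(errs[4], errs[2] / 2)
})

test_that("torsion of an achiral curve family is zero-centred", {
  taus <- unlist(lapply(1:10, function(s) {
    cv <- make_parametric_curve("smooth_random",
                                list(seed = s, length = 20,
                                     curvature_scale = 0.5), 120)
    mir <- polyline(as.matrix(cv[, c("x", "y", "z")]) %*% diag(c(1, 1, -1)))
    c(mean(torsion_profile(cv), na.rm = TRUE),
      mean(torsion_profile(mir), na.rm = TRUE))
  }))
  expect_lt(abs(mean(taus)), 2 * sd(taus) / sqrt(length(taus)) + 1e-12)
})

test_that("geometry tables carry labels, order, and phantom ground truth", {
  m <- node_model(list(
    list(id = "n1", type = "neurite", nodes = polyline(cbind(0:5, 0, 0), 0.4)),
    list(id = "n2", type = "neurite", nodes = polyline(cbind(0:5, 2, 0), 0.4)),
    list(id = "s1", type = "spine",
         nodes = polyline(cbind(c(2, 2, 2), c(0.4, 0.8, 1.2), 0), 0.1),
         attachment = list(parent_id = "n1", parent_node = 3)),
    list(id = "s2", type = "spine",
         nodes = polyline(cbind(c(3, 3, 3), c(0.4, 0.8, 1.2), 0), 0.1),
         attachment = list(parent_id = "n1", parent_node = 4)),
    list(id = "s3", type = "spine",
         nodes = polyline(cbind(c(4, 4), c(0.4, 0.9), 0), 0.1),
         attachment = list(parent_id = "n2", parent_node = 5))),
    metadata = list(dataset = "S1A", case = "S1", group = "schizophrenia",
                    area = "BA22"))
  gt <- geometry_table(m)
  expect_equal(nrow(gt), 5)
  expect_equal(sum(gt$type == "neurite"), 2)
  expect_equal(sum(gt$type == "spine"), 3)
  expect_equal(gt$constituent_id, sort(gt$constituent_id))
  expect_true(all(gt$dataset == "S1A" & gt$case == "S1"))
  # spine length includes the attachment segment
  expect_equal(gt$spine_length_um[gt$constituent_id == "s1"], 0.8 + 0.4)

  expect_equal(nrow(geometry_table(node_model())), 0)

  ph <- helix_phantom(shape = c(112, 64, 64))
  gt2 <- geometry_table(ph$model)
  expect_equal(gt2$mean_curvature[1], ph$kappa_true, tolerance = 0.02)
})
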
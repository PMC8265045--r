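# Synthetic specimens: analytic deformations, contour sampling, planted
# cells, recovery metrics.

test_that("trivial deformations act as expected on nodal parameters", {
  m <- make_identity_cube()
  # identity affine: unchanged
  m1 <- deform_mesh(m, deformation_affine())
  expect_identical(get_node_params(m1, "reference", 3),
    get_node_params(m, "reference", 3))
  # pure translation: values shift, derivatives unchanged
  m2 <- deform_mesh(m, deformation_affine(b = c(1, -2, 3)))
  p0 <- get_node_params(m, "reference", 5); p2 <- get_node_params(m2, "reference", 5)
  expect_equal(p2[, 1], p0[, 1] + c(1, -2, 3))
  expect_identical(p2[, 2:8], p0[, 2:8])
})

test_that("chain-rule parameter updates match finite differences of the map", {
  tube <- make_straight_tube(n_segments = 2)
  defs <- list(
    bend = deformation_bend(0.06, center = c(0, 0, 2)),
    bulge = deformation_bulge(center = c(0, 0, 2), amplitude = 0.3, sigma = 2),
    composite = compose_deformations(
      deformation_bend(0.04, center = c(0, 0, 2)),
      deformation_bulge(center = c(0.5, 0, 1), amplitude = 0.2, sigma = 2)))
  h <- 1e-5
  for (nm in names(defs)) {
    def <- defs[[nm]]
    md <- deform_mesh(tube, def)
    for (nd in c(1, 10, 25)) {
      p0 <- get_node_params(tube, "reference", nd)
      p1 <- get_node_params(md, "reference", nd)
      v <- p0[, 1]
      # first-derivative slots: directional FD of the map along d
      for (slot in c(2, 3, 5)) {
        d <- p0[, slot]
        num <- (def$value(v + h * d) - def$value(v - h * d)) / (2 * h)
        expect_close(p1[, slot], num, 1e-6 * max(1, max(abs(num))))
      }
      # cross slot d12 = d/du d/dv phi(v + u d1 + v d2) + J d12 term
      d1 <- p0[, 2]; d2 <- p0[, 3]; d12 <- p0[, 4]
      num <- (def$value(v + h * d1 + h * d2) - def$value(v + h * d1 - h * d2) -
              def$value(v - h * d1 + h * d2) + def$value(v - h * d1 - h * d2)) / (4 * h^2)
      J <- def$jacobian(v)
      expect_close(p1[, 4], num + J %*% d12, 1e-4)
    }
  }
})

test_that("contour sampling hits the truth surface with the advertised counts", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 3, points_per_ring = 7)
  pts <- dataset_points(ds)
  expect_equal(nrow(pts), 21L)
  expect_true(all(pts$term == "outer surface"))
  prs <- project_dataset(tube, "reference", ds)
  expect_lt(max(vapply(prs, `[[`, 0, "distance")), 1e-9)
})

test_that("noisy sampling reproduces the half-normal surface-distance law", {
  # straight cylinder: the distance from a noised sample to the sampled
  # surface is the |surface-normal noise component|, a half-normal with
  # mean sigma*sqrt(2/pi); the cylinder gives it in closed form
  tube <- make_straight_tube(r = 20, w = 2, n_around = 8, n_segments = 2, len = 40)
  sigma <- 0.25
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 14, points_per_ring = 100, noise_sd = sigma, seed = 99)
  pts <- dataset_points(ds)
  expect_equal(nrow(pts), 1400L)
  dist <- abs(sqrt(pts$x^2 + pts$y^2) - 21)   # outer surface radius r + w/2
  expect_lt(abs(mean(dist) / (sigma * sqrt(2 / pi)) - 1), 0.05)
  # points noised outward carry the same offset as their mesh projection
  out_idx <- which(sqrt(pts$x^2 + pts$y^2) > 21 + 0.1)[1:20]
  sub <- contour_dataset(contours = list(list(name = "outer surface",
    ontology_id = "", closed = FALSE,
    points = as.matrix(pts[out_idx, c("x", "y", "z")]))))
  prs <- project_dataset(tube, "reference", sub)
  # the 8-around Hermite ring deviates from the true circle by ~0.1% of the
  # radius between nodes; allow for that interpolation sag
  expect_close(vapply(prs, `[[`, 0, "distance"), dist[out_idx], 0.05)
})

test_that("cell scattering is reproducible, group-restricted, and invertible", {
  atria <- make_atria("rat-atria")
  c1 <- scatter_cells(atria, "reference", n = 10, seed = 42, groups = "left atrium")
  c2 <- scatter_cells(atria, "reference", n = 10, seed = 42, groups = "left atrium")
  expect_identical(c1, c2)
  la <- get_annotation(atria, "left atrium")
  expect_true(all(c1$element %in% la$elements))
  expect_error(scatter_cells(atria, "reference", n = 5, seed = 1, groups = "no such group"),
    "group")
  # zero-noise observations invert to the true material coordinates
  emb <- embed_points(atria, "reference",
    data.frame(x = c1$x, y = c1$y, z = c1$z, label = c1$label))
  same <- emb$element == c1$element
  expect_close(as.matrix(emb[same, c("xi1", "xi2", "xi3")]),
    as.matrix(c1[same, c("xi1", "xi2", "xi3")]), 1e-6)
  expect_gt(mean(same), 0.89)  # cells at internal faces may land in a neighbour
})

test_that("registration metrics agree with a direct recomputation", {
  truth <- data.frame(label = c("a", "b", "c"), x = c(0, 1, 2), y = 0, z = 0)
  rec <- truth
  m0 <- registration_error(truth, rec)
  expect_equal(m0$physical_rms, 0)
  expect_equal(m0$worst, 0)
  rec$x[2] <- 2  # one point off by 1 mm
  m1 <- registration_error(truth[2, ], rec[2, ])
  expect_equal(m1$physical_rms, 1)
  m2 <- registration_error(truth, rec)
  d <- sqrt(rowSums((as.matrix(truth[, 2:4]) - as.matrix(rec[, 2:4]))^2))
  expect_equal(m2$physical_rms, sqrt(mean(d^2)))
  expect_equal(m2$worst, max(d))
  expect_error(registration_error(truth, data.frame(label = "z", x = 0, y = 0, z = 0)),
    "common labels")
  m3 <- registration_error(truth, rbind(rec, data.frame(label = "d", x = 0, y = 0, z = 0)))
  expect_equal(m3$missing, "d")
})

test_that("deformations that fold the mesh are rejected with advice", {
  m <- make_identity_cube()
  expect_error(deform_mesh(m, deformation_bulge(center = c(0.5, 0.5, 0.5),
    amplitude = -2, sigma = 0.4)), "amplitude")
})
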
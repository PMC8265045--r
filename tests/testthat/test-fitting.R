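# Closest-point projection and regularized linear fitting.

test_that("projection recovers exact points and distances on a flat element", {
  m <- make_flat_quad()
  pr <- project_point(m, "reference", c(0.5, 0.5, 1))
  expect_close(pr$mp$xi, c(0.5, 0.5), 1e-8)
  expect_equal(pr$distance, 1, tolerance = 1e-10)
  # a node of the mesh projects to itself
  pr0 <- project_point(m, "reference", c(0, 0, 0))
  expect_equal(pr0$distance, 0, tolerance = 1e-12)
  expect_close(pr0$mp$xi, c(0, 0), 1e-10)
  # boundary clamp
  pr2 <- project_point(m, "reference", c(0.3, -0.4, 0.2))
  expect_close(pr2$mp$xi, c(0.3, 0), 1e-8)
  expect_equal(pr2$distance, sqrt(0.16 + 0.04), tolerance = 1e-8)
})

test_that("projection matches a dense grid oracle on a curved element", {
  m <- make_curved_quad()
  P <- anatscaffold:::.element_params(m, "reference", m$elements[["1"]])
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(3, -0.3, 1.3)
    pr <- project_point(m, "reference", p)
    or <- grid_project_oracle(P, 2, p)
    expect_lte(pr$distance, or$dist + 1e-9)
    expect_lt(or$dist - pr$distance, 0.05)
  }
})

test_that("equidistant ties resolve to the lowest element id", {
  m <- hermite_mesh()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (off in 0:1) for (i in 1:8) {
    v <- corners[i, ] + c(off * 2, 0, 0)   # cubes [0,1] and [2,3] in x
    m <- set_node_params(m, "reference", off * 8 + i,
      cbind(v, c(1, 0, 0), c(0, 1, 0), 0, c(0, 0, 1), 0, 0, 0))
  }
  m <- add_element(m, 1, 3, 1:8)
  m <- add_element(m, 2, 3, 9:16)
  pr <- project_point(m, "reference", c(1.5, 0.5, 0.5))
  expect_equal(pr$mp$element, 1L)
  expect_equal(pr$distance, 0.5, tolerance = 1e-9)
})

test_that("term-annotated points project only onto their group", {
  atria <- make_atria("rat-atria")
  ra <- get_annotation(atria, "right atrium")
  # a point in the middle of the right atrium, labelled left atrium
  p <- eval_field(atria, "reference", material_point(ra$elements[1], c(0.5, 0.5, 0.5)))
  ds <- contour_dataset(contours = list(list(name = "left atrium",
    ontology_id = "UBERON:0002079", closed = FALSE,
    points = rbind(p, p + c(0.01, 0, 0)))))
  prs <- project_dataset(atria, "reference", ds)
  la <- get_annotation(atria, "left atrium")
  for (pr in prs) expect_true(pr$mp$element %in% la$elements)
  # points sampled on the mesh surface project at ~zero distance
  ds2 <- sample_contours(atria, "reference", groups = "left atrium",
    rings = 2, points_per_ring = 4)
  prs2 <- project_dataset(atria, "reference", ds2)
  for (pr in prs2) expect_lt(pr$distance, 1e-8)
})

test_that("self-projections leave the solution unchanged", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 4, points_per_ring = 8)
  prs <- project_dataset(tube, "reference", ds)
  for (cfg in list(fit_config(), fit_config(lambda_strain = 1, beta_smooth = 0.1))) {
    s <- solve_linear_fit(tube, "reference", prs, cfg)
    expect_lt(s$objective, 1e-16)
    for (nd in tube$node_ids)
      expect_close(get_node_params(s$mesh, "reference", nd),
        get_node_params(tube, "reference", nd), 1e-9)
  }
})

test_that("the linear solve recovers a pure translation exactly", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 4, points_per_ring = 8)
  prs <- project_dataset(tube, "reference", ds)
  t_vec <- c(1, -2, 0.5)
  prs_t <- lapply(prs, function(pr) { pr$target <- pr$target + t_vec; pr })
  for (cfg in list(fit_config(), fit_config(lambda_strain = 3, beta_smooth = 0.5))) {
    s <- solve_linear_fit(tube, "reference", prs_t, cfg)
    for (nd in tube$node_ids) {
      p0 <- get_node_params(tube, "reference", nd)
      p1 <- get_node_params(s$mesh, "reference", nd)
      expect_close(p1[, 1], p0[, 1] + t_vec, 1e-8)      # values translated
      expect_close(p1[, 2:8], p0[, 2:8], 1e-8)          # derivatives kept
    }
  }
})

test_that("dense volume data with zero penalties recovers an affine map", {
  tube <- make_straight_tube(n_around = 4, n_segments = 2)
  A <- diag(3) + matrix(c(0, 0.05, -0.03, 0.04, 0.02, 0, -0.02, 0.03, 0.05), 3, 3)
  b <- c(2, -1, 3)
  # true-correspondence projections on a 4^3 grid per element
  g <- seq(0.1, 0.9, length.out = 4)
  grid <- as.matrix(expand.grid(g, g, g))
  prs <- list()
  for (el in tube$elements) for (r in seq_len(nrow(grid))) {
    mp <- material_point(el$id, grid[r, ])
    x <- eval_field(tube, "reference", mp)
    prs[[length(prs) + 1L]] <- structure(list(mp = mp, distance = 0,
      point = x, weight = 1, data_index = NA, target = as.vector(A %*% x + b)),
      class = "projection")
  }
  s <- solve_linear_fit(tube, "reference", prs,
    fit_config(lambda_strain = 0, beta_smooth = 0))
  for (nd in tube$node_ids) {
    p0 <- get_node_params(tube, "reference", nd)
    p1 <- get_node_params(s$mesh, "reference", nd)
    expect_close(p1[, 1], as.vector(A %*% p0[, 1] + b), 1e-6 * max(1, abs(p0[, 1])))
    expect_close(p1[, 2:8], A %*% p0[, 2:8], 1e-6)
  }
})

test_that("insufficient data with zero penalties reports a singular system", {
  tube <- make_straight_tube(n_segments = 1)
  pr <- project_point(tube, "reference",
    eval_field(tube, "reference", material_point(1, c(0.5, 0.5, 1))))
  pr$target <- pr$point + c(0, 0, 1)
  expect_error(solve_linear_fit(tube, "reference", list(pr),
    fit_config(lambda_strain = 0, beta_smooth = 0)), "lambda_strain")
})

test_that("hard landmark constraints are honored exactly", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 3, points_per_ring = 6)
  prs <- project_dataset(tube, "reference", ds)
  lm_mp <- material_point(1, c(0.5, 0.5, 1))
  lm_target <- eval_field(tube, "reference", lm_mp) + c(0.2, 0, 0)
  s <- solve_linear_fit(tube, "reference", prs,
    fit_config(fixed_landmarks = list(list(mp = lm_mp, point = lm_target))))
  expect_close(eval_field(s$mesh, "reference", lm_mp), lm_target, 1e-8)
})

test_that("a huge strain penalty pins the Jacobian to the reference", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 3, points_per_ring = 8)
  prs <- project_dataset(tube, "reference", ds)
  set.seed(9)
  prs <- lapply(prs, function(pr) { pr$target <- pr$target + c(2, 1, -1) + rnorm(3, 0, 0.1); pr })
  s <- solve_linear_fit(tube, "reference", prs, fit_config(lambda_strain = 1e8, beta_smooth = 0))
  mp <- material_point(3, c(0.4, 0.6, 0.2))
  expect_close(element_jacobian(s$mesh, "reference", mp)$matrix,
    element_jacobian(tube, "reference", mp)$matrix, 1e-5)
})

test_that("the outer fit loop converges on self-data and decreases its objective", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 4, points_per_ring = 8)
  r <- fit_scaffold(tube, ds, fit_config(outer_iterations = 3))
  expect_lt(r$diagnostics$rms[1], 1e-8)
  expect_true(attr(r$diagnostics, "converged"))
  expect_true("fitted" %in% mesh_fields(r$mesh))
  # reference untouched
  expect_equal(get_node_params(r$mesh, "reference", 1),
    get_node_params(tube, "reference", 1))
  # deformed data: objective non-increasing across iterations
  def <- deformation_bend(0.04, center = c(0, 0, 2))
  truth <- deform_mesh(tube, def)
  ds2 <- sample_contours(truth, "reference", groups = "outer surface",
    rings = 4, points_per_ring = 8)
  r2 <- fit_scaffold(tube, ds2, fit_config(outer_iterations = 4, rms_tol = 1e-12))
  expect_true(all(diff(r2$diagnostics$objective) <= 1e-10))
  expect_lt(r2$diagnostics$rms[nrow(r2$diagnostics)], r2$diagnostics$rms[1])
})

test_that("solve_linear_fit is translation-equivariant", {
  tube <- make_straight_tube(n_segments = 2)
  ds <- sample_contours(tube, "reference", groups = "outer surface",
    rings = 3, points_per_ring = 6)
  prs <- project_dataset(tube, "reference", ds)
  set.seed(13)
  prs <- lapply(prs, function(pr) { pr$target <- pr$target + rnorm(3, 0, 0.05); pr })
  t_vec <- c(4, -7, 2)
  prs_t <- lapply(prs, function(pr) { pr$target <- pr$target + t_vec; pr })
  s0 <- solve_linear_fit(tube, "reference", prs, fit_config())
  s1 <- solve_linear_fit(tube, "reference", prs_t, fit_config())
  for (nd in c(1, 5, 9)) {
    p0 <- get_node_params(s0$mesh, "reference", nd)
    p1 <- get_node_params(s1$mesh, "reference", nd)
    expect_close(p1[, 1], p0[, 1] + t_vec, 5e-8)
    expect_close(p1[, 2:8], p0[, 2:8], 5e-8)
  }
})
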
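# Scaffold generation: tubes, species presets, body, refinement.

test_that("a straight circular tube has exact surface radii and counts", {
  tube <- make_straight_tube(r = 1, w = 0.2, n_around = 8, n_segments = 4)
  expect_equal(length(tube$elements), 32L)
  outer <- get_annotation(tube, "outer surface")
  for (nd in outer$nodes) {
    v <- get_node_params(tube, "reference", nd)[, 1]
    expect_lt(abs(sqrt(v[1]^2 + v[2]^2) - 1.1), 1e-9)
  }
  inner <- get_annotation(tube, "inner surface")
  v <- get_node_params(tube, "reference", inner$nodes[1])[, 1]
  expect_lt(abs(sqrt(v[1]^2 + v[2]^2) - 0.9), 1e-9)
})

test_that("ring centroids of a curved tube lie on the centerline", {
  R <- 10
  th <- seq(0, pi / 2, length.out = 65)
  cl <- centerline(cbind(R * cos(th), R * sin(th), 0))
  tube <- build_tube(cross_section_spec(1, 0.2, n_around = 8), cl, 6)
  blk <- tube$metadata$blocks[[1]]
  nsta <- blk$n_segments + 1
  nid <- function(j, k, l) ((j - 1) %% 8) + 8 * ((k - 1) + nsta * (l - 1)) + 1
  for (k in seq_len(nsta)) {
    ring <- t(vapply(1:8, function(j) {
      (get_node_params(tube, "reference", nid(j, k, 1))[, 1] +
       get_node_params(tube, "reference", nid(j, k, 2))[, 1]) / 2
    }, numeric(3)))
    centroid <- colMeans(ring)
    # distance from the analytic quarter-circle arc
    expect_lt(abs(sqrt(centroid[1]^2 + centroid[2]^2) - R), 1e-6)
    expect_lt(abs(centroid[3]), 1e-6)
  }
})

test_that("tight centerline curvature raises a generation error", {
  th <- seq(0, pi / 2, length.out = 17)
  cl <- centerline(cbind(1.5 * cos(th), 1.5 * sin(th), 0))
  expect_error(build_tube(cross_section_spec(2, 0.4), cl, 6), "curvature")
})

test_that("colon presets expose the species taenia coli groups", {
  counts <- c("human-colon" = 3L, "pig-colon" = 2L, "mouse-colon" = 0L)
  for (p in names(counts)) {
    m <- make_colon(p)
    tg <- grep("taenia coli", annotation_terms(m), value = TRUE)
    expect_length(tg, counts[[p]])
    if (counts[[p]] > 0) {
      for (t in tg) expect_gt(length(get_annotation(m, t)$elements), 0)
    }
  }
})

test_that("atrial presets expose the species pulmonary-vein topology", {
  counts <- c("human-atria" = 4L, "pig-atria" = 2L, "rat-atria" = 3L)
  for (p in names(counts)) {
    m <- make_atria(p)
    pv <- grep("pulmonary vein", annotation_terms(m), value = TRUE)
    expect_length(pv, counts[[p]])
  }
  rat <- make_atria("rat-atria")
  expect_setequal(annotation_terms(rat),
    c("left atrium", "left atrial auricle", "left pulmonary vein",
      "middle pulmonary vein", "right pulmonary vein", "right atrium",
      "right atrial auricle", "inferior vena cava", "superior vena cava"))
  expect_error(make_atria(n_pulmonary_veins = 7), "1..6")
})

test_that("the body scaffold partitions its core at the diaphragm", {
  m <- make_body(length = 200, core_radius = 15, n_axial_segments = 4,
    n_around = 8, diaphragm_position = 0.5)
  expect_equal(length(m$elements), 64L)
  core <- m$metadata$blocks$body$elems[, , 1]
  thorax <- get_annotation(m, "thorax")$elements
  abdomen <- get_annotation(m, "abdomen")$elements
  expect_setequal(c(thorax, abdomen), as.integer(core))
  expect_length(intersect(thorax, abdomen), 0)
  dia <- get_annotation(m, "diaphragm")
  expect_equal(dia$kind, "landmark")
  for (nd in dia$nodes)
    expect_lt(abs(get_node_params(m, "reference", nd)[3, 1] - 100), 1e-9)
  # off-grid diaphragm positions still land exactly on a node ring
  m2 <- make_body(length = 150, n_axial_segments = 5, diaphragm_position = 0.37)
  for (nd in get_annotation(m2, "diaphragm")$nodes)
    expect_lt(abs(get_node_params(m2, "reference", nd)[3, 1] - 0.37 * 150), 1e-9)
  expect_error(make_body(n_axial_segments = 1), "at least 2")
  expect_error(make_body(diaphragm_position = 1.2), "between 0 and 1")
})

test_that("generated scaffolds are C1-conforming with positive Jacobians", {
  for (p in c("human-colon", "rat-atria")) {
    m <- make_scaffold(p)
    expect_true(validate_mesh(m))
    expect_equal(nrow(continuity_report(m, tol = 1e-8)), 0L)
  }
})

test_that("generation is deterministic", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_mesh(make_scaffold("mouse-colon"), f1)
  write_mesh(make_scaffold("mouse-colon"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("refinement preserves geometry and annotation groups", {
  m <- make_identity_cube()
  r <- refine_mesh(m, c(2, 2, 2))
  expect_equal(length(r$elements), 8L)
  set.seed(3)
  for (rep in 1:50) {
    xi <- runif(3)
    cell <- pmin(floor(xi * 2), 1)
    cidx <- 1 + cell[1] + 2 * cell[2] + 4 * cell[3]
    expect_close(eval_field(m, "reference", material_point(1, xi)),
      eval_field(r, "reference", material_point(cidx, xi * 2 - cell)), 1e-9)
  }
  expect_equal(nrow(continuity_report(r)), 0L)
  # identity refinement keeps counts and values
  r1 <- refine_mesh(m, c(1, 1, 1))
  expect_equal(length(r1$elements), 1L)
  expect_equal(length(r1$node_ids), 8L)
  expect_equal(eval_field(r1, "reference", material_point(1, c(0.3, 0.7, 0.2))),
    eval_field(m, "reference", material_point(1, c(0.3, 0.7, 0.2))))
  # annotation propagation on a real scaffold
  colon <- make_colon("human-colon")
  rc <- refine_mesh(colon, c(2, 1, 1))
  expect_length(grep("taenia coli", annotation_terms(rc)), 3L)
  tg <- get_annotation(rc, "taenia coli 1")
  expect_equal(length(tg$elements), 2L * length(get_annotation(colon, "taenia coli 1")$elements))
})
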
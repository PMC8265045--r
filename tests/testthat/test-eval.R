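# Field evaluation, Jacobians and the continuity report.

test_that("evaluation reproduces nodal parameters at corners", {
  m <- make_identity_cube()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in 1:8) {
    mp <- material_point(1, corners[i, ])
    expect_equal(eval_field(m, "reference", mp), as.numeric(corners[i, ]))
    expect_equal(eval_field(m, "reference", mp, deriv = c(1, 0, 0)), c(1, 0, 0))
    expect_equal(eval_field(m, "reference", mp, deriv = c(0, 0, 1)), c(0, 0, 1))
  }
  expect_equal(eval_field(m, "reference", material_point(1, c(0.5, 0.5, 0.5))),
    c(0.5, 0.5, 0.5))
})

test_that("an affine element reproduces its affine map exactly", {
  A <- matrix(c(2, 0.3, -0.1, 0.2, 1.5, 0.4, -0.3, 0.1, 0.8), 3, 3)
  b <- c(5, -2, 1)
  m <- make_affine_cube(A, b)
  set.seed(11)
  for (rep in 1:100) {
    xi <- runif(3)
    expect_close(eval_field(m, "reference", material_point(1, xi)),
      as.vector(A %*% xi + b), 1e-12)
  }
})

test_that("element Jacobian matches a finite-difference oracle", {
  A <- matrix(c(2, 0.3, -0.1, 0.2, 1.5, 0.4, -0.3, 0.1, 0.8), 3, 3)
  m <- make_affine_cube(A, c(0, 0, 0))
  j <- element_jacobian(m, "reference", material_point(1, c(0.3, 0.6, 0.9)))
  expect_close(j$matrix, A, 1e-12)
  expect_equal(j$det, det(A), tolerance = 1e-12)
  # scaled cube
  m2 <- make_affine_cube(diag(c(2, 1, 1)), c(0, 0, 0))
  j2 <- element_jacobian(m2, "reference", material_point(1, c(0.5, 0.5, 0.5)))
  expect_equal(j2$det, 2)
  # curved geometry: central differences of the interpolated position
  mt <- make_straight_tube(n_segments = 2)
  mp <- material_point(3, c(0.4, 0.3, 0.7))
  J <- element_jacobian(mt, "reference", mp)$matrix
  h <- 1e-6
  for (i in 1:3) {
    e <- numeric(3); e[i] <- h
    num <- (eval_field(mt, "reference", material_point(3, mp$xi + e)) -
            eval_field(mt, "reference", material_point(3, mp$xi - e))) / (2 * h)
    expect_close(J[, i], num, 1e-6 * max(1, abs(num)))
  }
  # dimension guard
  expect_error(element_jacobian(make_flat_quad(), "reference",
    material_point(1, c(0.5, 0.5))), "3-D")
})

test_that("continuity report is empty for conforming meshes", {
  expect_equal(nrow(continuity_report(make_identity_cube())), 0L)
  expect_equal(nrow(continuity_report(make_two_cubes())), 0L)
})

test_that("a doubled derivative version flags exactly one face", {
  m <- make_two_cubes()
  # give the shared-face node 2 (x=1 corner) a second version with a doubled
  # face-tangential derivative and make element 2 select it
  p <- get_node_params(m, "reference", 2)
  p[, 3] <- 2 * p[, 3]
  m <- set_node_params(m, "reference", 2, p, version = 2)
  el <- m$elements[["2"]]
  el$versions[el$nodes == 2] <- 2L
  m$elements[["2"]] <- el
  rep <- continuity_report(m)
  expect_equal(nrow(rep), 1L)
  expect_setequal(c(rep$element_a, rep$element_b), c(1L, 2L))
  expect_gt(rep$max_value_mismatch + rep$max_deriv_mismatch, 1e-9)
})
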
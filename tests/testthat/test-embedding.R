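# Material embedding, transfer, and fiducial placement.

test_that("volume embedding inverts the identity map exactly", {
  m <- make_identity_cube()
  emb <- embed_points(m, "reference", rbind(c(0.25, 0.5, 0.75), c(0, 0, 0)))
  expect_close(as.numeric(emb[1, c("xi1", "xi2", "xi3")]), c(0.25, 0.5, 0.75), 1e-9)
  expect_lt(emb$residual[1], 1e-9)
  expect_false(any(emb$off_mesh))
  expect_close(as.numeric(emb[2, c("xi1", "xi2", "xi3")]), c(0, 0, 0), 1e-9)
})

test_that("embedding inverts a smoothly deformed cube against a grid oracle", {
  m <- make_identity_cube()
  def <- deformation_bulge(center = c(0.5, 0.5, 0.5), amplitude = 0.25, sigma = 0.6)
  md <- deform_mesh(m, def)
  set.seed(21)
  xis <- matrix(runif(30, 0.05, 0.95), 10, 3)
  pts <- t(apply(xis, 1, function(xi) eval_field(md, "reference", material_point(1, xi))))
  emb <- embed_points(md, "reference", pts)
  expect_lt(max(emb$residual), 1e-8)
  expect_close(as.matrix(emb[, c("xi1", "xi2", "xi3")]), xis, 1e-6)
})

test_that("embed-then-transfer on the same mesh and field is the identity", {
  tube <- make_straight_tube(n_segments = 2)
  set.seed(2)
  cells <- scatter_cells(tube, "reference", n = 20, seed = 2)
  emb <- embed_points(tube, "reference", data.frame(x = cells$x, y = cells$y,
    z = cells$z, label = cells$label))
  back <- transfer_points(emb, tube, "reference")
  expect_true(all(back$ok))
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
    as.matrix(cells[, c("x", "y", "z")]))), 1e-9)
})

test_that("material points survive a deform-fit-free round trip between fields", {
  tube <- make_straight_tube(n_segments = 2)
  def <- deformation_bend(0.05, center = c(0, 0, 2))
  truth <- deform_mesh(copy_field(tube, "reference", "fitted"), def, field = "fitted")
  cells <- scatter_cells(truth, "fitted", n = 15, seed = 4)
  emb <- embed_points(truth, "fitted", data.frame(x = cells$x, y = cells$y,
    z = cells$z, label = cells$label))
  # transfer to the generic (reference) configuration and re-embed there
  generic_pos <- transfer_points(emb, truth, "reference")
  emb2 <- embed_points(truth, "reference", data.frame(x = generic_pos$x,
    y = generic_pos$y, z = generic_pos$z, label = generic_pos$label))
  expect_close(as.matrix(emb2[, c("xi1", "xi2", "xi3")]),
    as.matrix(emb[, c("xi1", "xi2", "xi3")]), 1e-6)
  expect_equal(emb2$element, emb$element)
})

test_that("points outside the mesh are flagged off_mesh with a boundary address", {
  m <- make_identity_cube()
  emb <- embed_points(m, "reference", rbind(c(2, 0.5, 0.5)))
  expect_true(emb$off_mesh[1])
  expect_equal(emb$residual[1], 1, tolerance = 1e-7)
  expect_close(as.numeric(emb[1, c("xi1", "xi2", "xi3")]), c(1, 0.5, 0.5), 1e-6)
})

test_that("fiducial transforms recover exact similarity maps", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.4, 1))
  tr <- fiducial_transform(src, 2 * src + matrix(c(1, 0, 0), 4, 3, byrow = TRUE))
  expect_equal(tr$scale, 2, tolerance = 1e-12)
  expect_close(tr$rotation, diag(3), 1e-12)
  expect_close(tr$translation, c(1, 0, 0), 1e-12)
  expect_lt(tr$rms, 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- fiducial_transform(src, src %*% t(R))
  expect_equal(tr2$scale, 1, tolerance = 1e-12)
  expect_close(tr2$rotation, R, 1e-12)
  expect_lt(tr2$rms, 1e-12)
  expect_error(fiducial_transform(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0))), "collinear")
})

test_that("noisy fiducial pairs match a brute-force search", {
  th0 <- 0.35; s0 <- 1.4; t0 <- c(2, -1, 0.5)
  Rz <- function(th) matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  src <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0), c(1, 1, 1))
  set.seed(8)
  dst <- s0 * src %*% t(Rz(th0)) + matrix(t0, 4, 3, byrow = TRUE) +
    matrix(rnorm(12, 0, 0.02), 4, 3)
  tr <- fiducial_transform(src, dst)
  # grid search restricted to z-rotations (the generating family)
  obj <- function(th, s) {
    M <- s * src %*% t(Rz(th))
    tt <- colMeans(dst) - colMeans(M)
    sum((sweep(M, 2, -tt) - dst)^2)
  }
  best <- Inf; best_par <- NULL
  for (th in seq(th0 - 0.1, th0 + 0.1, by = 0.0005))
    for (s in seq(s0 - 0.1, s0 + 0.1, by = 0.0005)) {
      v <- obj(th, s)
      if (v < best) { best <- v; best_par <- c(th, s) }
    }
  ang <- atan2(tr$rotation[2, 1], tr$rotation[1, 1])
  expect_lt(abs(ang - best_par[1]), 1e-3)
  expect_lt(abs(tr$scale - best_par[2]), 1e-3)
})

test_that("organ placement applies the similarity to values and Jacobians", {
  organ <- make_straight_tube(n_segments = 2)
  pairs <- list(
    list(organ = material_point(1, c(0, 0, 0)), body = material_point(1, c(0, 0, 0))),
    list(organ = material_point(5, c(0.5, 0.5, 1)), body = material_point(5, c(0.5, 0.5, 1))),
    list(organ = material_point(12, c(1, 1, 0)), body = material_point(12, c(1, 1, 0))))
  # identity placement: organ unchanged
  placed0 <- place_organ(organ, organ, pairs)
  expect_close(get_node_params(placed0, "reference", 1),
    get_node_params(organ, "reference", 1), 1e-9)
  # translated body: organ translated identically
  body <- organ
  f <- body$fields$reference
  for (k in names(f$params)) f$params[[k]][[1]][, 1] <- f$params[[k]][[1]][, 1] + c(5, 0, 0)
  body$fields$reference <- f
  placed <- place_organ(organ, body, pairs)
  expect_close(get_node_params(placed, "reference", 3)[, 1],
    get_node_params(organ, "reference", 3)[, 1] + c(5, 0, 0), 1e-8)
  tr <- attr(placed, "transform")
  expect_equal(tr$scale, 1, tolerance = 1e-9)
  # scaled/rotated body: element Jacobians transform by s R
  th <- 0.5
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  body2 <- organ
  f <- body2$fields$reference
  for (k in names(f$params)) {
    m <- f$params[[k]][[1]]
    m[, 1] <- as.vector(1.7 * R %*% m[, 1]) + c(1, 2, 3)
    m[, 2:8] <- 1.7 * R %*% m[, 2:8]
    f$params[[k]][[1]] <- m
  }
  body2$fields$reference <- f
  placed2 <- place_organ(organ, body2, pairs)
  mp <- material_point(4, c(0.3, 0.7, 0.5))
  J0 <- element_jacobian(organ, "reference", mp)$matrix
  J1 <- element_jacobian(placed2, "reference", mp)$matrix
  expect_close(J1, 1.7 * R %*% J0, 1e-8)
  expect_error(place_organ(organ, organ, pairs[1:2]), ">= 3")
})
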
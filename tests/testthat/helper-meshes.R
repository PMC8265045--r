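# Small meshes built in code for the unit tests.

# unit cube element whose reference field is the identity map
make_identity_cube <- function() {
  m <- hermite_mesh()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in 1:8)
    m <- set_node_params(m, "reference", i,
      cbind(corners[i, ], c(1, 0, 0), c(0, 1, 0), 0, c(0, 0, 1), 0, 0, 0))
  add_element(m, 1, 3, 1:8)
}

# an element encoding an arbitrary affine map x -> A xi + b
make_affine_cube <- function(A, b) {
  m <- hermite_mesh()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in 1:8)
    m <- set_node_params(m, "reference", i,
      cbind(A %*% corners[i, ] + b, A[, 1], A[, 2], 0, A[, 3], 0, 0, 0))
  add_element(m, 1, 3, 1:8)
}

# two unit cubes sharing the x = 1 face, conforming derivatives
make_two_cubes <- function() {
  m <- hermite_mesh()
  corners <- as.matrix(expand.grid(0:2, 0:1, 0:1))
  for (i in seq_len(nrow(corners)))
    m <- set_node_params(m, "reference", i,
      cbind(corners[i, ], c(1, 0, 0), c(0, 1, 0), 0, c(0, 0, 1), 0, 0, 0))
  nid <- function(i, j, k) i + 3 * (j - 1) + 6 * (k - 1)
  el_nodes <- function(i0) c(nid(i0, 1, 1), nid(i0 + 1, 1, 1), nid(i0, 2, 1), nid(i0 + 1, 2, 1),
                             nid(i0, 1, 2), nid(i0 + 1, 1, 2), nid(i0, 2, 2), nid(i0 + 1, 2, 2))
  m <- add_element(m, 1, 3, el_nodes(1))
  add_element(m, 2, 3, el_nodes(2))
}

# flat unit-square 2-D element in the z = 0 plane
make_flat_quad <- function() {
  m <- hermite_mesh()
  c2 <- as.matrix(expand.grid(0:1, 0:1))
  for (i in 1:4)
    m <- set_node_params(m, "reference", i,
      cbind(c(c2[i, 1], c2[i, 2], 0), c(1, 0, 0), c(0, 1, 0), 0))
  add_element(m, 1, 2, 1:4)
}

# gently curved 2-D element (cubic bump out of plane)
make_curved_quad <- function() {
  m <- hermite_mesh()
  c2 <- as.matrix(expand.grid(0:1, 0:1))
  slopes <- c(0.6, -0.4, 0.5, -0.3)
  for (i in 1:4)
    m <- set_node_params(m, "reference", i,
      cbind(c(c2[i, 1], c2[i, 2], 0), c(1, 0, slopes[i]), c(0, 1, slopes[5 - i]), 0))
  add_element(m, 1, 2, 1:4)
}

# short straight tube along z: circular section, radius r, wall w
make_straight_tube <- function(r = 1, w = 0.2, n_around = 8, n_segments = 4, len = 4) {
  build_tube(cross_section_spec(r, w, n_around = n_around),
    centerline(cbind(0, 0, seq(0, len, length.out = max(3, n_segments + 1)))),
    n_segments)
}

# dense xi-grid projection oracle over one element's parameter matrix
grid_project_oracle <- function(P, d, p, n = 201) {
  pts <- seq(0, 1, length.out = n)
  xis <- t(as.matrix(expand.grid(rep(list(pts), d))))
  W <- anatscaffold:::.tensor_weights_batch(xis)
  pos <- P %*% W
  d2 <- colSums((pos - p)^2)
  k <- which.min(d2)
  list(dist = sqrt(d2[k]), xi = xis[, k])
}

expect_close <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
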
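# Cubic Hermite basis functions and tensor-product weights.

test_that("1-D basis interpolates endpoint values and derivatives", {
  expect_equal(basis_1d(0, 0), c(1, 0, 0, 0))
  expect_equal(basis_1d(1, 0), c(0, 0, 1, 0))
  expect_equal(basis_1d(0, 1), c(0, 1, 0, 0))
  expect_equal(basis_1d(1, 1), c(0, 0, 0, 1))
  expect_equal(basis_1d(0.5, 0), c(0.5, 0.125, 0.5, -0.125))
  expect_error(basis_1d(1.2), "domain")
  expect_error(basis_1d(0.5, deriv = 3), "deriv")
})

test_that("value-slot tensor weights form a partition of unity", {
  set.seed(42)
  for (d in 1:3) {
    for (rep in 1:25) {
      xi <- runif(d)
      w <- tensor_basis(xi)
      expect_lt(abs(sum(w[, "value"]) - 1), 1e-12)
    }
  }
})

test_that("tensor weights at corners and midpoints match closed forms", {
  w <- tensor_basis(c(0, 0, 0))
  expect_equal(unname(w["c000", "value"]), 1)
  expect_equal(sum(abs(w)) - 1, 0)  # all other weights vanish at a corner
  w2 <- tensor_basis(c(0.5, 0.5))
  expect_equal(unname(w2[, "value"]), rep(0.25, 4))
})

test_that("analytic derivative weights agree with central finite differences", {
  h <- 1e-5
  set.seed(7)
  for (rep in 1:10) {
    xi <- runif(1, h, 1 - h)
    expect_close(basis_1d(xi, 1), (basis_1d(xi + h, 0) - basis_1d(xi - h, 0)) / (2 * h), 1e-6)
    expect_close(basis_1d(xi, 2), (basis_1d(xi + h, 1) - basis_1d(xi - h, 1)) / (2 * h), 1e-6)
  }
  # tensor: d/dxi1 of a 2-D weight table
  xi <- c(0.37, 0.81)
  num <- (tensor_basis(c(xi[1] + h, xi[2])) - tensor_basis(c(xi[1] - h, xi[2]))) / (2 * h)
  expect_close(tensor_basis(xi, c(1, 0)), num, 1e-6)
})
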
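# Cubic Hermite basis functions and tensor-product weight tables.
#
# Every element direction uses the four cubic Hermite polynomials on [0,1]:
# two interpolate values at the interval ends, two interpolate first
# derivatives. A d-dimensional element takes tensor products, so each of the
# 2^d corner nodes carries 2^d parameter slots (value and mixed partials).

# corner/slot bit tables, one per element dimension: row k gives, for corner
# (or slot) k, which directions are "high side" (or "derivative taking").
.hermite_bits <- lapply(1:3, function(d) {
  n <- 2L^d
  m <- matrix(0L, n, d)
  for (i in seq_len(d)) m[, i] <- bitwAnd(seq_len(n) - 1L, bitwShiftL(1L, i - 1L)) %/% bitwShiftL(1L, i - 1L)
  m
})

# canonical per-node slot order; 1D elements use slots 1:2, 2D 1:4, 3D 1:8
.slot_names <- c("value", "d1", "d2", "d12", "d3", "d13", "d23", "d123")

#' One-dimensional cubic Hermite basis
#'
#' Evaluates the four cubic Hermite basis polynomials (or their first or
#' second derivatives) at local coordinates in \eqn{[0,1]}. The weights are
#' ordered (value at 0, derivative at 0, value at 1, derivative at 1), i.e.
#' they multiply the nodal value and first-derivative parameters of the two
#' interval-end nodes.
#'
#' @param xi numeric vector of local coordinates in \eqn{[0,1]}.
#' @param deriv derivative order: 0, 1 or 2.
#' @return For a single `xi`, a numeric vector of 4 weights; for a vector,
#'   a 4 x length(xi) matrix (one column per coordinate).
#' @examples
#' basis_1d(0.5)          # c(0.5, 0.125, 0.5, -0.125)
#' basis_1d(c(0, 1))      # endpoint interpolation
#' @export
basis_1d <- function(xi, deriv = 0L) {
  if (!is.numeric(xi) || length(xi) < 1L) stop("`xi` must be numeric", call. = FALSE)
  if (any(!is.finite(xi)) || any(xi < -1e-9) || any(xi > 1 + 1e-9))
    stop("`xi` outside the element domain [0, 1]", call. = FALSE)
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2", call. = FALSE)
  t <- pmin(pmax(xi, 0), 1)
  t2 <- t * t
  w <- switch(as.character(deriv),
    "0" = rbind(1 - 3 * t2 + 2 * t2 * t, t - 2 * t2 + t2 * t, 3 * t2 - 2 * t2 * t, -t2 + t2 * t),
    "1" = rbind(-6 * t + 6 * t2, 1 - 4 * t + 3 * t2, 6 * t - 6 * t2, -2 * t + 3 * t2),
    "2" = rbind(-6 + 12 * t, -4 + 6 * t, 6 - 12 * t, -2 + 6 * t)
  )
  if (length(t) == 1L) as.vector(w) else w
}

#' Tensor-product Hermite weight table
#'
#' Weights of all corner-node parameter slots of a d-dimensional cubic
#' Hermite element at one local coordinate. Corners are ordered from the
#' lowest-\eqn{\xi} corner with \eqn{\xi_1} varying fastest; slots follow the
#' canonical order (value, d1, d2, d12, d3, d13, d23, d123) truncated to the
#' element dimension.
#'
#' @param xi numeric d-vector (d = 1, 2 or 3) of local coordinates in [0,1].
#' @param deriv integer d-vector of per-direction derivative orders (each
#'   0, 1 or 2); `NULL` means plain interpolation.
#' @return a 2^d x 2^d numeric matrix, rows = corners, columns = slots.
#' @examples
#' tensor_basis(c(0.5, 0.5))["c00", "value"]  # 0.25
#' @export
tensor_basis <- function(xi, deriv = NULL) {
  d <- length(xi)
  if (!d %in% 1:3) stop("`xi` must have 1, 2 or 3 components", call. = FALSE)
  if (is.null(deriv)) deriv <- rep(0L, d)
  if (length(deriv) != d || !all(deriv %in% 0:2))
    stop("`deriv` must give one order in 0:2 per xi direction", call. = FALSE)
  bits <- .hermite_bits[[d]]
  n <- 2L^d
  w <- matrix(1, n, n)
  for (i in seq_len(d)) {
    b <- basis_1d(xi[i], deriv[i])
    # weight index within direction i: 2*side + deriv_flag + 1
    w <- w * b[outer(2L * bits[, i], bits[, i], "+") + 1L]
  }
  rownames(w) <- paste0("c", apply(bits, 1, paste, collapse = ""))
  colnames(w) <- .slot_names[seq_len(n)]
  w
}

# precomputed per-dimension index tables for the flat weight layout
# (corner-major, slots fastest within a corner)
.tw_idx <- lapply(1:3, function(d) {
  bits <- .hermite_bits[[d]]
  n <- 2L^d
  corner <- rep(seq_len(n), each = n)
  slot <- rep(seq_len(n), times = n)
  lapply(seq_len(d), function(i) 2L * bits[corner, i] + bits[slot, i] + 1L)
})

# raw 1-D basis without argument checking (hot path)
.b1 <- function(t, deriv) {
  t2 <- t * t
  if (deriv == 0L) c(1 - 3 * t2 + 2 * t2 * t, t - 2 * t2 + t2 * t, 3 * t2 - 2 * t2 * t, -t2 + t2 * t)
  else if (deriv == 1L) c(-6 * t + 6 * t2, 1 - 4 * t + 3 * t2, 6 * t - 6 * t2, -2 * t + 3 * t2)
  else c(-6 + 12 * t, -4 + 6 * t, 6 - 12 * t, -2 + 6 * t)
}

# Flat weight vector: corner-major, slots fastest within a corner. This is
# the layout element parameter matrices use (see .element_params).
.tensor_weights_flat <- function(xi, deriv = NULL) {
  d <- length(xi)
  idx <- .tw_idx[[d]]
  dv <- if (is.null(deriv)) integer(d) else deriv
  w <- .b1(xi[1], dv[1])[idx[[1]]]
  if (d >= 2L) w <- w * .b1(xi[2], dv[2])[idx[[2]]]
  if (d == 3L) w <- w * .b1(xi[3], dv[3])[idx[[3]]]
  w
}

# Batch version: xis is a d x n matrix, one deriv spec for all columns.
# Returns a (2^d * 2^d) x n matrix of flat weight vectors.
.tensor_weights_batch <- function(xis, deriv = NULL) {
  d <- nrow(xis)
  if (is.null(deriv)) deriv <- rep(0L, d)
  bits <- .hermite_bits[[d]]
  n <- 2L^d
  # flat index k = (corner-1)*n + slot: corner bits vary slowest
  corner <- rep(seq_len(n), each = n)
  slot <- rep(seq_len(n), times = n)
  w <- matrix(1, n * n, ncol(xis))
  for (i in seq_len(d)) {
    b <- basis_1d(xis[i, ], deriv[i])
    if (is.null(dim(b))) b <- matrix(b, 4, 1)
    sel <- 2L * bits[corner, i] + bits[slot, i] + 1L
    w <- w * b[sel, , drop = FALSE]
  }
  w
}
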
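# Field evaluation on cubic Hermite elements.

# Gather the element's nodal parameters into a components x (2^d * 2^d)
# matrix whose columns follow the flat weight layout (corner-major, slots
# fastest), honouring per-local-node derivative-version selectors.
.element_params <- function(mesh, field, el) {
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("unknown field '%s'", field), call. = FALSE)
  ns <- 2L^el$dim
  P <- matrix(0, f$components, length(el$nodes) * ns)
  for (j in seq_along(el$nodes)) {
    vers <- f$params[[as.character(el$nodes[j])]]
    if (is.null(vers)) stop(sprintf("field '%s' undefined at node %d", field, el$nodes[j]), call. = FALSE)
    v <- el$versions[j]
    if (v > length(vers)) stop(sprintf("node %d has no derivative version %d", el$nodes[j], v), call. = FALSE)
    P[, ((j - 1L) * ns + 1L):(j * ns)] <- vers[[v]][, seq_len(ns), drop = FALSE]
  }
  P
}

# Cache of gathered parameter matrices for all elements of one field:
# list keyed by element id (character).
.field_params_all <- function(mesh, field, elements = mesh$elements) {
  lapply(elements, function(el) .element_params(mesh, field, el))
}

#' Evaluate a field at a material point
#'
#' Tensor-product cubic Hermite interpolation of the element's nodal
#' parameters. With a derivative spec, returns the corresponding partial
#' derivative with respect to the local coordinates (e.g. `deriv = c(1,0,0)`
#' gives \eqn{\partial x/\partial \xi_1}).
#'
#' @param mesh a `hermite_mesh`.
#' @param field field name.
#' @param mp a [material_point()], or a list/vector `(element, xi...)`.
#' @param deriv integer per-direction derivative orders (0/1/2), or `NULL`
#'   for the field value.
#' @return numeric vector of field components.
#' @export
eval_field <- function(mesh, field, mp, deriv = NULL) {
  mp <- .as_material_point(mp)
  el <- mesh$elements[[as.character(mp$element)]]
  if (is.null(el)) stop(sprintf("unknown element %s", mp$element), call. = FALSE)
  if (length(mp$xi) != el$dim)
    stop(sprintf("material point has %d coordinates; element %d is %d-D",
      length(mp$xi), el$id, el$dim), call. = FALSE)
  P <- .element_params(mesh, field, el)
  as.vector(P %*% .tensor_weights_flat(mp$xi, deriv))
}

.as_material_point <- function(mp) {
  if (inherits(mp, "material_point")) return(mp)
  if (is.list(mp)) return(material_point(mp$element %||% mp[[1]], mp$xi %||% mp[[2]]))
  stop("`mp` must be a material_point", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jacobian d(x)/d(xi) from a gathered parameter matrix at one xi.
# Returns a components x d matrix.
.jacobian_at <- function(P, xi) {
  d <- length(xi)
  J <- matrix(0, nrow(P), d)
  for (i in seq_len(d)) {
    dv <- integer(d); dv[i] <- 1L
    J[, i] <- P %*% .tensor_weights_flat(xi, dv)
  }
  J
}

#' Element Jacobian of a coordinate field
#'
#' The 3 x 3 matrix of partial derivatives \eqn{\partial x/\partial \xi} of
#' a 3-component coordinate field on a 3-D element, and its determinant.
#'
#' @inheritParams eval_field
#' @return list with `matrix` (3 x 3, columns \eqn{\partial x/\partial
#'   \xi_i}) and `det`.
#' @export
element_jacobian <- function(mesh, field, mp) {
  mp <- .as_material_point(mp)
  el <- mesh$elements[[as.character(mp$element)]]
  if (is.null(el)) stop(sprintf("unknown element %s", mp$element), call. = FALSE)
  if (el$dim != 3L) stop(sprintf("element %d is %d-D; Jacobian needs a 3-D element", el$id, el$dim), call. = FALSE)
  P <- .element_params(mesh, field, el)
  J <- .jacobian_at(P, mp$xi)
  list(matrix = J, det = det(J))
}

# ---- shared faces and continuity ------------------------------------------

# Enumerate faces (dim-1 entities) of an element: for each direction i and
# side a, the local corner indices with bit i == a, in face-lattice order
# (remaining directions ascending, first remaining direction fastest).
.element_faces <- function(el) {
  d <- el$dim
  bits <- .hermite_bits[[d]]
  out <- list()
  for (i in seq_len(d)) for (a in 0:1) {
    loc <- which(bits[, i] == a)
    # order by remaining directions, lowest direction fastest: bits order
    # already has xi1 fastest, so `which` preserves the face-lattice order
    out[[length(out) + 1L]] <- list(dir = i, side = a, local = loc,
      nodes = el$nodes[loc])
  }
  out
}

# All square symmetries mapping face coordinates u (length k = d-1) of face A
# to face coordinates of face B; returns list of (perm, flip) candidates.
.face_symmetries <- function(k) {
  if (k == 0L) return(list(list(perm = integer(0), flip = logical(0))))
  perms <- if (k == 1L) list(1L) else list(c(1L, 2L), c(2L, 1L))
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  out <- list()
  for (p in perms) for (r in seq_len(nrow(flips)))
    out[[length(out) + 1L]] <- list(perm = p, flip = as.logical(flips[r, ]))
  out
}

# Corner of a face lattice for coordinates u in {0,1}^k -> local index into
# face$local ordering (u1 fastest).
.face_corner_index <- function(u) {
  if (!length(u)) return(1L)
  sum(u * 2L^(seq_along(u) - 1L)) + 1L
}

# Find the symmetry mapping face A's corners onto face B's equal node ids.
.match_faces <- function(faceA, faceB, k) {
  for (s in .face_symmetries(k)) {
    ok <- TRUE
    if (k > 0L) {
      grid <- as.matrix(expand.grid(rep(list(0:1), k)))
      for (r in seq_len(nrow(grid))) {
        u <- as.integer(grid[r, ])
        v <- integer(k)
        for (j in seq_len(k)) {
          uj <- u[s$perm[j]]
          v[j] <- if (s$flip[j]) 1L - uj else uj
        }
        if (faceA$nodes[.face_corner_index(u)] != faceB$nodes[.face_corner_index(v)]) { ok <- FALSE; break }
      }
    } else ok <- faceA$nodes[1] == faceB$nodes[1]
    if (ok) return(s)
  }
  NULL
}

# Build full element xi from face coordinates u for a given face.
.face_to_xi <- function(face, u, d) {
  xi <- numeric(d)
  xi[face$dir] <- face$side
  xi[setdiff(seq_len(d), face$dir)] <- u
  xi
}

#' Report continuity violations across shared element faces
#'
#' Finds every face shared by two elements (identified by equal corner node
#' ids) and compares cross-boundary interpolation: field values (C0) always,
#' and first derivatives (C1) whenever both elements select the same
#' derivative versions on all shared nodes. Faces where a mismatch exceeds
#' `tol` are reported.
#'
#' @param mesh a `hermite_mesh`.
#' @param field field name.
#' @param tol mismatch tolerance (same units as the field).
#' @return a data frame with one row per offending face: the two element
#'   ids, the shared corner node ids, and the maximum value and derivative
#'   mismatches found. Zero rows means the field is C0 (and, where versions
#'   agree, C1) across all shared faces.
#' @export
continuity_report <- function(mesh, field = "reference", tol = 1e-9) {
  faces <- list()
  for (el in mesh$elements) {
    if (el$dim < 2L) next
    for (fc in .element_faces(el)) {
      key <- paste(sort(fc$nodes), collapse = "_")
      faces[[key]] <- c(faces[[key]], list(list(el = el, face = fc)))
    }
  }
  rows <- list()
  ts <- c(0, 0.5, 1)
  for (key in names(faces)) {
    grp <- faces[[key]]
    if (length(grp) < 2L) next
    for (a in seq_len(length(grp) - 1L)) for (b in (a + 1L):length(grp)) {
      elA <- grp[[a]]$el; fA <- grp[[a]]$face
      elB <- grp[[b]]$el; fB <- grp[[b]]$face
      if (elA$id == elB$id) next
      d <- elA$dim
      if (elB$dim != d) next
      k <- d - 1L
      if (anyDuplicated(fA$nodes)) next  # collapsed face: skip
      sym <- .match_faces(fA, fB, k)
      if (is.null(sym)) next
      PA <- .element_params(mesh, field, elA)
      PB <- .element_params(mesh, field, elB)
      # compare derivatives only if shared nodes pick identical versions
      vA <- elA$versions[fA$local][order(fA$nodes)]
      vB <- elB$versions[fB$local][order(fB$nodes)]
      same_versions <- all(vA == vB)
      grid <- as.matrix(expand.grid(rep(list(ts), max(k, 1))))[, seq_len(k), drop = FALSE]
      maxval <- 0; maxder <- 0
      for (r in seq_len(nrow(grid))) {
        u <- as.numeric(grid[r, ])
        v <- numeric(k)
        for (j in seq_len(k)) {
          uj <- u[sym$perm[j]]
          v[j] <- if (sym$flip[j]) 1 - uj else uj
        }
        xiA <- .face_to_xi(fA, u, d)
        xiB <- .face_to_xi(fB, v, d)
        pA <- PA %*% .tensor_weights_flat(xiA)
        pB <- PB %*% .tensor_weights_flat(xiB)
        maxval <- max(maxval, max(abs(pA - pB)))
        if (same_versions) {
          JA <- .jacobian_at(PA, xiA)
          JB <- .jacobian_at(PB, xiB)
          freeA <- setdiff(seq_len(d), fA$dir)
          freeB <- setdiff(seq_len(d), fB$dir)
          # tangential: dx/du_j must agree through the symmetry map
          for (j in seq_len(k)) {
            sgn <- if (sym$flip[j]) -1 else 1
            maxder <- max(maxder, max(abs(JA[, freeA[sym$perm[j]]] - sgn * JB[, freeB[j]])))
          }
          # transverse: continuing parameterization iff sides differ
          sgn <- if (fA$side != fB$side) 1 else -1
          maxder <- max(maxder, max(abs(JA[, fA$dir] - sgn * JB[, fB$dir])))
        }
      }
      if (maxval > tol || maxder > tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_a = elA$id, element_b = elB$id, face_nodes = key,
          max_value_mismatch = maxval, max_deriv_mismatch = maxder,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    data.frame(element_a = integer(0), element_b = integer(0),
      face_nodes = character(0), max_value_mismatch = numeric(0),
      max_deriv_mismatch = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
}
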
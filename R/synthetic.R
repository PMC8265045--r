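# Synthetic ground-truth specimens: analytic deformations of generated
# scaffolds, noisy surface-contour sampling, and cells planted at known
# material coordinates. These emulate the distortions experimental
# preparations impose on an organ, with exact ground truth so fitting and
# embedding can be validated end to end.
#
# Deformations are analytic maps with closed-form first, second and third
# derivatives, so nodal derivative slots are updated by the exact chain
# rule (no numerical differentiation enters the ground truth).

#' Affine deformation
#' @param A 3 x 3 matrix.
#' @param b translation 3-vector.
#' @return object of class `deformation`.
#' @export
deformation_affine <- function(A = diag(3), b = c(0, 0, 0)) {
  A <- as.matrix(A)
  structure(list(
    value = function(x) as.vector(A %*% x) + b,
    jacobian = function(x) A,
    hessian = function(x) array(0, c(3, 3, 3)),
    third = function(x) array(0, c(3, 3, 3, 3)),
    kind = "affine"), class = "deformation")
}

#' Circular bend deformation
#'
#' Bends the z axis into a circular arc of curvature `curvature` (deflecting
#' in +x), about the given center; `orientation` pre-rotates coordinates so
#' the bend can act in any plane. The identity at curvature 0.
#'
#' @param curvature 1/mm.
#' @param center point held fixed by the bend, mm.
#' @param orientation 3 x 3 rotation applied to coordinates before bending
#'   (and undone after).
#' @return object of class `deformation`.
#' @export
deformation_bend <- function(curvature, center = c(0, 0, 0), orientation = diag(3)) {
  k <- curvature
  Q <- as.matrix(orientation)
  base <- if (abs(k) < 1e-15) deformation_affine() else {
    # x' = (1/k + x) cos(kz) - 1/k, y' = y, z' = (1/k + x) sin(kz);
    # tends to the identity as k -> 0, det J = 1 + kx > 0 while |x| < 1/k
    structure(list(
      value = function(x) {
        u <- 1 / k + x[1]; s <- sin(k * x[3]); c_ <- cos(k * x[3])
        c(u * c_ - 1 / k, x[2], u * s)
      },
      jacobian = function(x) {
        u <- 1 / k + x[1]; s <- sin(k * x[3]); c_ <- cos(k * x[3])
        matrix(c(c_, 0, s, 0, 1, 0, -u * k * s, 0, u * k * c_), 3, 3)
      },
      hessian = function(x) {
        u <- 1 / k + x[1]; s <- sin(k * x[3]); c_ <- cos(k * x[3])
        H <- array(0, c(3, 3, 3))
        H[1, 1, 3] <- H[1, 3, 1] <- -k * s
        H[1, 3, 3] <- -u * k^2 * c_
        H[3, 1, 3] <- H[3, 3, 1] <- k * c_
        H[3, 3, 3] <- -u * k^2 * s
        H
      },
      third = function(x) {
        u <- 1 / k + x[1]; s <- sin(k * x[3]); c_ <- cos(k * x[3])
        T <- array(0, c(3, 3, 3, 3))
        T[1, 1, 3, 3] <- T[1, 3, 1, 3] <- T[1, 3, 3, 1] <- -k^2 * c_
        T[1, 3, 3, 3] <- u * k^3 * s
        T[3, 1, 3, 3] <- T[3, 3, 1, 3] <- T[3, 3, 3, 1] <- -k^2 * s
        T[3, 3, 3, 3] <- -u * k^3 * c_
        T
      },
      kind = "bend"), class = "deformation")
  }
  .conjugate_deformation(base, Q, center)
}

#' Gaussian radial bulge deformation
#'
#' Pushes material radially away from `center` by
#' \eqn{a\,\exp(-\|x-c\|^2 / 2\sigma^2)\,(x-c)}.
#'
#' @param center bulge center, mm.
#' @param amplitude dimensionless gain `a` (|a| < 1 keeps the map
#'   invertible near the center).
#' @param sigma Gaussian width, mm.
#' @return object of class `deformation`.
#' @export
deformation_bulge <- function(center, amplitude, sigma) {
  cc <- as.numeric(center); a <- amplitude; s2 <- sigma^2
  g_of <- function(q) exp(-q / (2 * s2))
  structure(list(
    value = function(x) { d <- x - cc; x + a * g_of(sum(d^2)) * d },
    jacobian = function(x) {
      d <- x - cc; q <- sum(d^2); g <- g_of(q); gq <- -g / (2 * s2)
      diag(3) + a * g * diag(3) + 2 * a * gq * outer(d, d)
    },
    hessian = function(x) {
      d <- x - cc; q <- sum(d^2); g <- g_of(q)
      gq <- -g / (2 * s2); gqq <- g / (4 * s2^2)
      H <- array(0, c(3, 3, 3))
      I <- diag(3)
      for (i in 1:3) for (j in 1:3) for (kk in 1:3)
        H[i, j, kk] <- 2 * a * gq * (d[kk] * I[i, j] + I[i, kk] * d[j] + d[i] * I[j, kk]) +
          4 * a * gqq * d[i] * d[j] * d[kk]
      H
    },
    third = function(x) {
      d <- x - cc; q <- sum(d^2); g <- g_of(q)
      gq <- -g / (2 * s2); gqq <- g / (4 * s2^2); gqqq <- -g / (8 * s2^3)
      T <- array(0, c(3, 3, 3, 3))
      I <- diag(3)
      for (i in 1:3) for (j in 1:3) for (kk in 1:3) for (l in 1:3) {
        T[i, j, kk, l] <- 2 * a * gq * (I[kk, l] * I[i, j] + I[i, kk] * I[j, l] + I[i, l] * I[j, kk]) +
          4 * a * gqq * (d[l] * (d[kk] * I[i, j] + I[i, kk] * d[j] + d[i] * I[j, kk]) +
                         I[i, l] * d[j] * d[kk] + d[i] * I[j, l] * d[kk] + d[i] * d[j] * I[kk, l]) +
          8 * a * gqqq * d[i] * d[j] * d[kk] * d[l]
      }
      T
    },
    kind = "bulge"), class = "deformation")
}

# y = c + Q^T f(Q (x - c)): conjugation by a rotation about a center, with
# exact derivative transforms.
.conjugate_deformation <- function(f, Q, center) {
  if (all(Q == diag(3)) && all(center == 0)) return(f)
  Qt <- t(Q); cc <- as.numeric(center)
  structure(list(
    value = function(x) cc + as.vector(Qt %*% f$value(as.vector(Q %*% (x - cc)))),
    jacobian = function(x) Qt %*% f$jacobian(as.vector(Q %*% (x - cc))) %*% Q,
    hessian = function(x) {
      H <- f$hessian(as.vector(Q %*% (x - cc)))
      Hn <- array(0, c(3, 3, 3))
      for (i in 1:3) {
        Mi <- matrix(0, 3, 3)
        for (a in 1:3) Mi <- Mi + Qt[i, a] * (t(Q) %*% H[a, , ] %*% Q)
        Hn[i, , ] <- Mi
      }
      Hn
    },
    third = function(x) {
      T <- f$third(as.vector(Q %*% (x - cc)))
      Tn <- array(0, c(3, 3, 3, 3))
      for (i in 1:3) for (a in 1:3) {
        if (Qt[i, a] == 0) next
        # contract the three trailing indices with Q
        Ta <- T[a, , , ]
        tmp <- array(0, c(3, 3, 3))
        for (j in 1:3) for (kk in 1:3) for (l in 1:3)
          tmp[j, kk, l] <- sum(Ta * outer(Q[, j], outer(Q[, kk], Q[, l])))
        Tn[i, , , ] <- Tn[i, , , ] + Qt[i, a] * tmp
      }
      Tn
    },
    kind = paste0(f$kind, "+conjugated")), class = "deformation")
}

#' Compose deformations
#'
#' `compose_deformations(g, f)` applies `f` first, then `g`
#' (\eqn{x \mapsto g(f(x))}), with exact chain-rule derivatives.
#'
#' @param g,f `deformation` objects.
#' @return a `deformation`.
#' @export
compose_deformations <- function(g, f) {
  structure(list(
    value = function(x) g$value(f$value(x)),
    jacobian = function(x) g$jacobian(f$value(x)) %*% f$jacobian(x),
    hessian = function(x) {
      y <- f$value(x); Jg <- g$jacobian(y); Hg <- g$hessian(y)
      Jf <- f$jacobian(x); Hf <- f$hessian(x)
      H <- array(0, c(3, 3, 3))
      for (i in 1:3) {
        M <- t(Jf) %*% Hg[i, , ] %*% Jf
        for (a in 1:3) M <- M + Jg[i, a] * Hf[a, , ]
        H[i, , ] <- M
      }
      H
    },
    third = function(x) {
      y <- f$value(x)
      Jg <- g$jacobian(y); Hg <- g$hessian(y); Tg <- g$third(y)
      Jf <- f$jacobian(x); Hf <- f$hessian(x); Tf <- f$third(x)
      T <- array(0, c(3, 3, 3, 3))
      # Faa di Bruno for third-order mixed partials of g(f(x))
      for (i in 1:3) for (j in 1:3) for (kk in 1:3) for (l in 1:3) {
        acc <- 0
        for (a in 1:3) {
          acc <- acc + Jg[i, a] * Tf[a, j, kk, l]
          for (b in 1:3) {
            acc <- acc + Hg[i, a, b] * (Hf[a, j, kk] * Jf[b, l] +
                                        Hf[a, j, l] * Jf[b, kk] +
                                        Hf[a, kk, l] * Jf[b, j])
            for (cq in 1:3)
              acc <- acc + Tg[i, a, b, cq] * Jf[a, j] * Jf[b, kk] * Jf[cq, l]
          }
        }
        T[i, j, kk, l] <- acc
      }
      T
    },
    kind = paste(g$kind, f$kind, sep = "*")), class = "deformation")
}

# chain-rule update of one node's parameter matrix (3 x 8) under a
# deformation: value, first, second-cross and third-cross slots.
.deform_params <- function(def, m) {
  v <- m[, 1]
  J <- def$jacobian(v); H <- def$hessian(v); Tt <- def$third(v)
  hc <- function(a, b) {  # H contracted with two vectors -> 3-vector
    out <- numeric(3)
    for (i in 1:3) out[i] <- as.numeric(t(a) %*% H[i, , ] %*% b)
    out
  }
  tc <- function(a, b, c_) {
    out <- numeric(3)
    for (i in 1:3) for (j in 1:3) out[i] <- out[i] + a[j] * as.numeric(t(b) %*% Tt[i, j, , ] %*% c_)
    out
  }
  d1 <- m[, 2]; d2 <- m[, 3]; d12 <- m[, 4]
  d3 <- m[, 5]; d13 <- m[, 6]; d23 <- m[, 7]; d123 <- m[, 8]
  out <- matrix(0, 3, 8)
  out[, 1] <- def$value(v)
  out[, 2] <- J %*% d1
  out[, 3] <- J %*% d2
  out[, 5] <- J %*% d3
  out[, 4] <- J %*% d12 + hc(d1, d2)
  out[, 6] <- J %*% d13 + hc(d1, d3)
  out[, 7] <- J %*% d23 + hc(d2, d3)
  out[, 8] <- J %*% d123 + hc(d12, d3) + hc(d13, d2) + hc(d23, d1) + tc(d1, d2, d3)
  out
}

#' Deform a mesh field analytically
#'
#' Applies a smooth analytic deformation to all nodal values and, by the
#' exact chain rule, to all derivative slots of the given field. Errors if
#' the deformed field has non-positive Jacobians at quadrature points.
#'
#' @param mesh a `hermite_mesh`.
#' @param def a `deformation`.
#' @param field field to deform (in place).
#' @param check check Jacobian positivity afterwards.
#' @return the deformed mesh.
#' @export
deform_mesh <- function(mesh, def, field = "reference", check = TRUE) {
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("unknown field '%s'", field), call. = FALSE)
  for (key in names(f$params)) for (v in seq_along(f$params[[key]]))
    f$params[[key]][[v]] <- .deform_params(def, f$params[[key]][[v]])
  mesh$fields[[field]] <- f
  if (check) {
    ok <- tryCatch({ validate_mesh(mesh, field); TRUE }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("deformation folds the mesh (reduce its amplitude/curvature): ", ok, call. = FALSE)
  }
  mesh
}

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample noisy surface contours from a scaffold
#'
#' Samples rings of points on the outward (\eqn{\xi_3 = 1}) surface of the
#' elements of each requested annotation group, using the generator's block
#' grid to lay `rings` rings evenly along the group and `points_per_ring`
#' points around each, then adds isotropic Gaussian noise. Contour terms
#' are inherited from the groups.
#'
#' @param mesh a `hermite_mesh` built by the package generators (block
#'   metadata present).
#' @param field coordinate field to sample (the "truth" geometry).
#' @param groups character vector of annotation-group terms; default: all
#'   groups that own elements.
#' @param rings rings per group (per surface side).
#' @param points_per_ring points around each ring.
#' @param noise_sd isotropic Gaussian noise SD, mm.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param sides which wall surfaces to sample: `"outer"` (\eqn{\xi_3 = 1}),
#'   `"inner"` (\eqn{\xi_3 = 0}), or both (as when endocardial and
#'   epicardial contours are both segmented).
#' @return a `contour_dataset`.
#' @export
sample_contours <- function(mesh, field = "reference", groups = NULL,
                            rings = 4L, points_per_ring = 12L, noise_sd = 0,
                            seed = NULL, sides = "outer") {
  stopifnot(all(sides %in% c("outer", "inner")))
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when sampling with noise", call. = FALSE)
  if (is.null(groups)) {
    groups <- annotation_terms(mesh)[vapply(mesh$annotations, function(g)
      length(g$elements) > 0 && g$kind == "region", TRUE)]
    groups <- setdiff(groups, c("inner surface", "outer surface"))
    if (!length(groups)) groups <- intersect(annotation_terms(mesh), "outer surface")
  }
  blocks <- mesh$metadata$blocks
  if (is.null(blocks)) stop("mesh has no block metadata; sample per element instead", call. = FALSE)
  contours <- list()
  for (term in groups) {
    g <- get_annotation(mesh, term)
    if (is.null(g) || !length(g$elements)) stop(sprintf("no element group '%s' to sample", term), call. = FALSE)
    blk <- NULL
    for (b in blocks) if (all(g$elements %in% b$elems)) { blk <- b; break }
    if (is.null(blk)) stop(sprintf("group '%s' spans no single generator block", term), call. = FALSE)
    # columns (v) and layers (w) of the block covered by this group
    hit <- array(blk$elems %in% g$elements, dim = dim(blk$elems))
    for (side in sides) {
      wlay <- if (side == "outer") max(which(apply(hit, 3, any)))
              else min(which(apply(hit, 3, any)))
      xi3 <- if (side == "outer") 1 else 0
      vcols <- which(apply(hit[, , wlay, drop = FALSE], 2, any))
      ucols <- which(apply(hit[, vcols, wlay, drop = FALSE], 1, any))
      nu <- length(ucols); nv <- length(vcols)
      wrap <- isTRUE(blk$wrap_u) && nu == dim(blk$elems)[1]
      for (r in seq_len(rings)) {
        vg <- (r - 0.5) / rings * nv              # global v in covered columns
        jv <- min(nv, floor(vg) + 1L); xi2 <- vg - (jv - 1L)
        pts <- matrix(0, points_per_ring, 3)
        mps <- matrix(0, points_per_ring, 4)   # true material address per point
        for (q in seq_len(points_per_ring)) {
          ug <- if (wrap) (q - 1) / points_per_ring * nu else (q - 0.5) / points_per_ring * nu
          ju <- min(nu, floor(ug) + 1L); xi1 <- ug - (ju - 1L)
          eid <- blk$elems[ucols[ju], vcols[jv], wlay]
          pts[q, ] <- eval_field(mesh, field, material_point(eid, c(xi1, xi2, xi3)))
          mps[q, ] <- c(eid, xi1, xi2, xi3)
        }
        if (noise_sd > 0)
          pts <- pts + .with_seed(seed + 7919L * length(contours),
            matrix(stats::rnorm(length(pts), 0, noise_sd), nrow(pts), 3))
        contours[[length(contours) + 1L]] <- list(name = term,
          ontology_id = g$ontology_id, closed = wrap, points = pts, mps = mps)
      }
    }
  }
  contour_dataset(contours = contours, markers = list(),
    metadata = list(source = "sample_contours", units = "mm"))
}

#' Scatter cells at random material points
#'
#' Draws material points uniformly over (element, \eqn{\xi}) in the chosen
#' groups and records both the true material coordinates and the observed
#' physical positions (truth-field evaluation plus optional noise).
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field giving observed positions.
#' @param n number of cells (>= 1).
#' @param seed RNG seed.
#' @param groups character vector of annotation terms to restrict the
#'   elements (default: all 3-D elements).
#' @param noise_sd observation noise SD, mm.
#' @return data frame with label, term, element, xi1..xi3, x, y, z.
#' @export
scatter_cells <- function(mesh, field = "reference", n = 50L, seed = 1L,
                          groups = NULL, noise_sd = 0) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(groups)) {
    elems <- vapply(mesh$elements, `[[`, 0L, "id")[vapply(mesh$elements, `[[`, 0L, "dim") == 3L]
    terms <- rep("", length(elems))
  } else {
    elems <- integer(0); terms <- character(0)
    for (term in groups) {
      g <- get_annotation(mesh, term)
      if (is.null(g) || !length(g$elements)) stop(sprintf("empty group filter '%s'", term), call. = FALSE)
      elems <- c(elems, g$elements); terms <- c(terms, rep(term, length(g$elements)))
    }
  }
  if (!length(elems)) stop("no elements to scatter cells in", call. = FALSE)
  .with_seed(seed, {
    pick <- sample.int(length(elems), n, replace = TRUE)
    xi <- matrix(stats::runif(3 * n), n, 3)
    obs <- t(vapply(seq_len(n), function(i)
      eval_field(mesh, field, material_point(elems[pick[i]], xi[i, ])), numeric(3)))
    if (noise_sd > 0) obs <- obs + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
    data.frame(label = sprintf("cell_%04d", seq_len(n)), term = terms[pick],
      element = elems[pick], xi1 = xi[, 1], xi2 = xi[, 2], xi3 = xi[, 3],
      x = obs[, 1], y = obs[, 2], z = obs[, 3])
  })
}

#' Registration-error metrics between true and recovered cell positions
#'
#' @param truth data frame with label, x, y, z (and optionally element,
#'   xi1..xi3).
#' @param recovered data frame with label, x, y, z (e.g. from
#'   [transfer_points()]); may carry element/xi and off_mesh columns.
#' @return list with `n`, `physical_rms` (mm), `worst` (mm), `xi_rms`
#'   (element-normalized, over pairs sharing an element; NA otherwise),
#'   `off_mesh` count and `missing` labels.
#' @export
registration_error <- function(truth, recovered) {
  common <- intersect(truth$label, recovered$label)
  if (!length(common)) stop("no common labels between truth and recovered sets", call. = FALSE)
  missing <- setdiff(union(truth$label, recovered$label), common)
  a <- truth[match(common, truth$label), ]
  b <- recovered[match(common, recovered$label), ]
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  xi_rms <- NA_real_
  if (all(c("element", "xi1") %in% names(a)) && all(c("element", "xi1") %in% names(b))) {
    same <- which(a$element == b$element)
    if (length(same)) {
      dx <- as.matrix(a[same, c("xi1", "xi2", "xi3")]) - as.matrix(b[same, c("xi1", "xi2", "xi3")])
      xi_rms <- sqrt(mean(rowSums(dx^2, na.rm = TRUE)))
    }
  }
  list(n = length(common), physical_rms = sqrt(mean(d^2)), worst = max(d),
    xi_rms = xi_rms,
    off_mesh = if (!is.null(b$off_mesh)) sum(b$off_mesh) else 0L,
    missing = missing)
}
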
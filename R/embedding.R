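# Material embedding and transfer of point data, and fiducial-based organ
# placement.
#
# Embedding stores each datum as (element, xi): the same material address
# evaluates to corresponding locations in any configuration (field) of the
# scaffold, giving the one-to-one mapping that lets cells measured in
# different specimens be compared on one generic scaffold.

#' Embed points as material coordinates
#'
#' `volume` mode Newton-solves \eqn{x(\xi) = p} inside candidate elements
#' (seeded on a 3-per-direction grid); points for which no interior
#' solution exists fall back to surface projection and are flagged
#' `off_mesh` when the residual exceeds the tolerance. `surface` mode uses
#' closest-point projection directly.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field to embed against (typically `"fitted"`).
#' @param points numeric n x 3 matrix, or data frame with columns
#'   `x`, `y`, `z` and optionally `label` and `term`.
#' @param mode `"volume"` or `"surface"`.
#' @param tol off-mesh residual tolerance, mm; default 1e-6 x the mesh
#'   bounding-box diagonal.
#' @return data frame with columns label, term, element, xi1..xi3,
#'   residual (mm) and off_mesh.
#' @export
embed_points <- function(mesh, field, points, mode = c("volume", "surface"),
                         tol = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3])
  if (is.null(points$label)) points$label <- sprintf("point_%04d", seq_len(nrow(points)))
  if (is.null(points$term)) points$term <- ""
  if (is.null(tol)) tol <- 1e-6 * .bbox_diag(mesh, field)
  ctx <- .projection_context(mesh, field)
  el_list <- ctx$els
  # element bounding boxes (seed-grid positions, padded) to shortlist
  # candidate elements for interior inversion
  bb <- lapply(seq_along(el_list), function(k) {
    r <- apply(ctx$seedpos[[k]], 1, range)
    pad <- ctx$margin[k] + 1e-9
    list(lo = r[1, ] - pad, hi = r[2, ] + pad)
  })
  out <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- as.numeric(points[i, c("x", "y", "z")])
    rec <- NULL
    if (mode == "volume") {
      inside <- which(vapply(seq_along(el_list), function(k) {
        el_list[[k]]$dim == 3L && all(p >= bb[[k]]$lo) && all(p <= bb[[k]]$hi)
      }, TRUE))
      best <- NULL
      for (k in inside) {
        sol <- .invert_map(ctx$params[[k]], p)
        if (!is.null(sol) && sol$dist <= tol) {
          cand <- list(element = el_list[[k]]$id, xi = sol$xi, residual = sol$dist)
          if (is.null(best) || cand$residual < best$residual ||
              (cand$residual <= best$residual + 1e-12 && cand$element < best$element))
            best <- cand
        }
      }
      if (!is.null(best))
        rec <- data.frame(label = points$label[i], term = points$term[i],
          element = best$element, xi1 = best$xi[1], xi2 = best$xi[2], xi3 = best$xi[3],
          residual = best$residual, off_mesh = FALSE)
    }
    if (is.null(rec)) {
      pr <- project_point(mesh, field, p, params_cache = ctx)
      xi <- pr$mp$xi
      xi <- c(xi, rep(NA_real_, 3 - length(xi)))
      rec <- data.frame(label = points$label[i], term = points$term[i],
        element = pr$mp$element, xi1 = xi[1], xi2 = xi[2], xi3 = xi[3],
        residual = pr$distance, off_mesh = pr$distance > tol)
    }
    out[[i]] <- rec
  }
  do.call(rbind, out)
}

# Newton inversion of x(xi) = p inside one 3-D element; NULL if no
# converged interior solution.
.invert_map <- function(P, p, max_iter = 30L) {
  sd <- .proj_seeds(3L)
  pos <- P %*% sd$W
  k0 <- which.min(colSums((pos - p)^2))
  xi <- sd$xis[, k0]
  for (it in seq_len(max_iter)) {
    x <- as.vector(P %*% .tensor_weights_flat(xi))
    r <- p - x
    if (sqrt(sum(r^2)) < 1e-12) break
    J <- .jacobian_at(P, xi)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    step <- pmin(pmax(step, -0.5), 0.5)  # damp large exterior steps
    xi <- pmin(pmax(xi + step, 0), 1)
    if (max(abs(step)) < 1e-13) break
  }
  x <- as.vector(P %*% .tensor_weights_flat(xi))
  dist <- sqrt(sum((x - p)^2))
  if (any(xi < -1e-9) || any(xi > 1 + 1e-9)) return(NULL)
  list(xi = pmin(pmax(xi, 0), 1), dist = dist)
}

#' Evaluate embedded material points in another scaffold configuration
#'
#' Each material point is evaluated in the target mesh's field; labels and
#' terms are preserved. The target must contain every referenced element id
#' (same topology); rows whose element is missing are returned with
#' `ok = FALSE`.
#'
#' @param embedded data frame from [embed_points()] (columns element,
#'   xi1..xi3, label, term).
#' @param mesh target `hermite_mesh`.
#' @param field target coordinate field (e.g. `"reference"` of the generic
#'   scaffold).
#' @return data frame with label, term, x, y, z, ok.
#' @export
transfer_points <- function(embedded, mesh, field = "reference") {
  out <- vector("list", nrow(embedded))
  for (i in seq_len(nrow(embedded))) {
    eid <- embedded$element[i]
    el <- mesh$elements[[as.character(eid)]]
    if (is.null(el)) {
      out[[i]] <- data.frame(label = embedded$label[i], term = embedded$term[i],
        x = NA_real_, y = NA_real_, z = NA_real_, ok = FALSE)
      next
    }
    xi <- as.numeric(embedded[i, c("xi1", "xi2", "xi3")])[seq_len(el$dim)]
    x <- eval_field(mesh, field, material_point(eid, xi))
    out[[i]] <- data.frame(label = embedded$label[i], term = embedded$term[i],
      x = x[1], y = x[2], z = x[3], ok = TRUE)
  }
  do.call(rbind, out)
}

#' Least-squares similarity transform between matched landmark sets
#'
#' Finds scale s > 0, rotation R (proper orthogonal) and translation t
#' minimizing \eqn{\sum_i \|s R a_i + t - b_i\|^2} (the Umeyama/Kabsch
#' solution). At least 3 non-collinear pairs are required.
#'
#' @param src,dst numeric n x 3 matrices of matched points (n >= 3).
#' @return object of class `similarity_transform`: list with `scale`,
#'   `rotation`, `translation`, `rms`.
#' @export
fiducial_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || !identical(dim(src), dim(dst)))
    stop("need >= 3 matched point pairs", call. = FALSE)
  ca <- colMeans(src); cb <- colMeans(dst)
  A <- sweep(src, 2, ca); Bm <- sweep(dst, 2, cb)
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-10 * max(sv_a[1], 1))
    stop("fiducial points are collinear/degenerate; the transform is not determined", call. = FALSE)
  H <- crossprod(Bm, A)  # sum b_c a_c^T
  sv <- svd(H)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, dsign))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D) * sv$d) / sum(A^2)
  t <- cb - s * as.vector(R %*% ca)
  resid <- sweep(s * src %*% t(R), 2, t, "+") - dst
  structure(list(scale = s, rotation = R, translation = t,
    rms = sqrt(mean(rowSums(resid^2)))), class = "similarity_transform")
}

#' Apply a similarity transform to points
#' @param transform a `similarity_transform`.
#' @param points numeric n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(transform$scale * points %*% t(transform$rotation), 2, transform$translation, "+")
}

# Apply s, R, t to a coordinate field in place: value slots affinely, all
# derivative slots by s*R (an affine map transforms every mixed partial
# linearly).
.transform_field <- function(mesh, field, transform) {
  f <- mesh$fields[[field]]
  sR <- transform$scale * transform$rotation
  for (key in names(f$params)) for (v in seq_along(f$params[[key]])) {
    m <- f$params[[key]][[v]]
    m[, 1] <- as.vector(sR %*% m[, 1]) + transform$translation
    m[, 2:8] <- sR %*% m[, 2:8]
    f$params[[key]][[v]] <- m
  }
  mesh$fields[[field]] <- f
  mesh
}

#' Place an organ scaffold into a body scaffold via fiducial landmarks
#'
#' Evaluates matched fiducial material points in both scaffolds, fits the
#' least-squares similarity transform between them, and applies it to the
#' organ's coordinate field (values affinely; derivative slots rotated and
#' scaled).
#'
#' @param organ,body `hermite_mesh` objects.
#' @param pairs list of `list(organ = material_point, body = material_point)`
#'   (>= 3 pairs).
#' @param organ_field,body_field coordinate fields to evaluate the fiducials
#'   in; `organ_field` is also the field transformed.
#' @return the organ mesh with the transformed field; the fitted transform
#'   is attached as attribute `"transform"`.
#' @export
place_organ <- function(organ, body, pairs, organ_field = "reference",
                        body_field = "reference") {
  if (length(pairs) < 3L) stop("need >= 3 fiducial pairs", call. = FALSE)
  src <- t(vapply(pairs, function(p) eval_field(organ, organ_field, p$organ), numeric(3)))
  dst <- t(vapply(pairs, function(p) eval_field(body, body_field, p$body), numeric(3)))
  tr <- fiducial_transform(src, dst)
  organ <- .transform_field(organ, organ_field, tr)
  attr(organ, "transform") <- tr
  organ
}
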
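# Fitting a scaffold coordinate field to segmented specimen data:
# iterated closest-point projection plus regularized linear least squares
# over the nodal parameters.
#
# The data term is the weighted sum of squared distances between each datum
# and its (frozen) projection onto the scaffold. Two quadratic penalties
# regularize the deformation relative to the reference configuration: a
# linearized strain penalty (first-derivative Frobenius misfit to the
# reference) and a Sobolev-type smoothness penalty (second derivatives of
# the displacement). Both depend only on derivatives, so fitting commutes
# with translations of the data.

#' Fitting configuration
#'
#' @param group_weights named list mapping anatomical terms to data-point
#'   weights (default weight 1).
#' @param lambda_strain strain penalty coefficient (>= 0).
#' @param beta_smooth smoothness penalty coefficient (>= 0).
#' @param outer_iterations number of project/solve rounds.
#' @param rms_tol stop when the RMS data distance changes less than this
#'   (mm) between rounds.
#' @param fixed_landmarks list of hard constraints, each
#'   `list(mp = material_point(...), point = c(x, y, z))`; imposed exactly.
#' @param free_slots character subset of
#'   `c("value","d1","d2","d12","d3","d13","d23","d123")` to optimize, or
#'   `NULL` for all slots.
#' @param reference_field field the penalties are measured against.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(group_weights = list(), lambda_strain = 0.01,
                       beta_smooth = 0.001, outer_iterations = 4L,
                       rms_tol = 1e-6, fixed_landmarks = list(),
                       free_slots = NULL, reference_field = "reference") {
  if (!is.finite(lambda_strain) || lambda_strain < 0) stop("lambda_strain must be finite and >= 0", call. = FALSE)
  if (!is.finite(beta_smooth) || beta_smooth < 0) stop("beta_smooth must be finite and >= 0", call. = FALSE)
  if (!is.null(free_slots) && !all(free_slots %in% .slot_names))
    stop("unknown slot names in free_slots", call. = FALSE)
  structure(list(group_weights = group_weights, lambda_strain = lambda_strain,
    beta_smooth = beta_smooth, outer_iterations = as.integer(outer_iterations),
    rms_tol = rms_tol, fixed_landmarks = fixed_landmarks,
    free_slots = free_slots, reference_field = reference_field),
    class = "fit_config")
}

# seed grids (3 per direction) and their weight matrices, one per dimension
.proj_seed_cache <- new.env(parent = emptyenv())
.proj_seeds <- function(d) {
  key <- as.character(d)
  if (is.null(.proj_seed_cache[[key]])) {
    pts <- c(1, 3, 5) / 6
    xis <- t(as.matrix(expand.grid(rep(list(pts), d))))
    dimnames(xis) <- NULL
    .proj_seed_cache[[key]] <- list(xis = xis, W = .tensor_weights_batch(xis))
  }
  .proj_seed_cache[[key]]
}

# Gauss-Newton minimization of |x(xi) - p|^2 within [0,1]^d, with a
# golden-section steepest-descent fallback when the normal matrix is
# degenerate. Returns list(xi, dist, point).
.newton_project <- function(P, d, xi0, p, max_iter = 30L, step_tol = 1e-12) {
  xi <- xi0
  fx <- function(xi) as.vector(P %*% .tensor_weights_flat(xi))
  x <- fx(xi)
  f <- sum((x - p)^2)
  fstep <- Inf
  for (it in seq_len(max_iter)) {
    J <- .jacobian_at(P, xi)
    r_vec <- x - p
    g <- as.vector(crossprod(J, r_vec))
    H <- crossprod(J)
    # full Newton: add the residual-curvature term (Gauss-Newton alone
    # converges only linearly for distant points on curved elements)
    for (i in seq_len(d)) for (j in i:d) {
      dv <- integer(d); dv[i] <- dv[i] + 1L; dv[j] <- dv[j] + 1L
      hij <- sum(r_vec * as.vector(P %*% .tensor_weights_flat(xi, dv)))
      H[i, j] <- H[i, j] + hij
      if (i != j) H[j, i] <- H[j, i] + hij
    }
    # active-set reduction: coordinates pinned at a bound with the gradient
    # pushing outward stay fixed; solve the reduced system in the rest
    act <- (xi <= 0 & g > 0) | (xi >= 1 & g < 0)
    reduced_step <- function(Hm) {
      if (all(act)) return(NULL)
      fr <- which(!act)
      s_f <- tryCatch(solve(Hm[fr, fr, drop = FALSE] + diag(1e-12, length(fr)),
        -g[fr]), error = function(e) NULL)
      if (is.null(s_f) || any(!is.finite(s_f))) return(NULL)
      s <- numeric(d); s[fr] <- s_f
      s
    }
    try_step <- function(step) {
      if (is.null(step)) return(FALSE)
      alpha <- 1
      for (bt in 1:6) {
        xin <- pmin(pmax(xi + alpha * step, 0), 1)
        xn <- fx(xin)
        fn <- sum((xn - p)^2)
        if (fn < f) {
          xi <<- xin; x <<- xn; f <<- fn
          fstep <<- sqrt(sum((alpha * step)^2))
          return(TRUE)
        }
        alpha <- alpha / 2
      }
      FALSE
    }
    step <- reduced_step(H)
    moved <- try_step(step)
    if (!moved) {
      # the full-Newton model can be indefinite far out; retry Gauss-Newton
      step <- reduced_step(crossprod(J))
      moved <- try_step(step)
    }
    if (!moved) {
      # converged (or the Gauss-Newton direction is exhausted): fall back to
      # a short golden-section search along projected steepest descent only
      # while the step is still meaningful
      if (!is.null(step) && all(is.finite(step)) && sqrt(sum(step^2)) < 1e-9) break
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      dir <- -g / gn
      gr <- (sqrt(5) - 1) / 2
      a <- 0; b <- 1
      for (gs in 1:15) {
        t1 <- b - gr * (b - a); t2 <- a + gr * (b - a)
        p1 <- pmin(pmax(xi + t1 * dir, 0), 1); p2 <- pmin(pmax(xi + t2 * dir, 0), 1)
        if (sum((fx(p1) - p)^2) < sum((fx(p2) - p)^2)) b <- t2 else a <- t1
      }
      xin <- pmin(pmax(xi + 0.5 * (a + b) * dir, 0), 1)
      xn <- fx(xin); fn <- sum((xn - p)^2)
      if (fn < f) { fstep <- sqrt(sum((xin - xi)^2)); xi <- xin; x <- xn; f <- fn } else break
    }
    if (fstep < step_tol) break
  }
  list(xi = xi, dist = sqrt(f), point = x)
}

#' Project a point onto the nearest element of a scaffold
#'
#' Seeds a 3-per-direction local-coordinate grid in every candidate
#' element, Newton-iterates from the most promising seeds with clamping to
#' \eqn{[0,1]^d}, and returns the globally nearest material point. Distance
#' ties (< 1e-12) are broken by lowest element id, then lexicographically
#' smallest \eqn{\xi}.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field name.
#' @param p numeric 3-vector, mm.
#' @param elements optional integer vector restricting the candidate
#'   elements (e.g. an annotation group's).
#' @param params_cache optional precomputed element parameter list (from
#'   repeated calls); leave `NULL` normally.
#' @return a `projection`: list with `mp` ([material_point()]), `distance`
#'   (mm), `point` (the projected coordinates) and `weight`.
#' @export
project_point <- function(mesh, field, p, elements = NULL, params_cache = NULL) {
  ctx <- if (inherits(params_cache, "projection_context")) params_cache
         else .projection_context(mesh, field, elements)
  .project_point_ctx(ctx, as.numeric(p))
}

# Precompute everything projection needs for repeated queries against one
# field: gathered element parameters, seed-grid positions, and a per-element
# seed-resolution margin (no true minimum can undercut the best seed
# distance by more than the farthest-from-a-seed distance, bounded by
# 0.35 x element diameter).
.projection_context <- function(mesh, field, elements = NULL) {
  if (!length(mesh$elements)) stop("mesh has no elements", call. = FALSE)
  cand <- if (is.null(elements)) mesh$elements else mesh$elements[as.character(elements)]
  if (!length(cand) || any(vapply(cand, is.null, TRUE))) stop("unknown candidate elements", call. = FALSE)
  params <- .field_params_all(mesh, field, cand)
  n <- length(cand)
  seedpos <- vector("list", n); margin <- numeric(n)
  for (i in seq_len(n)) {
    sd <- .proj_seeds(cand[[i]]$dim)
    pos <- params[[i]] %*% sd$W
    seedpos[[i]] <- pos
    rng <- apply(pos, 1, range)
    margin[i] <- 0.35 * sqrt(sum((rng[2, ] - rng[1, ])^2)) + 1e-12
  }
  dims <- vapply(cand, `[[`, 0L, "dim")
  uniform <- length(unique(dims)) == 1L
  allpos <- if (uniform) do.call(cbind, seedpos) else NULL
  structure(list(els = unname(cand), params = unname(params), seedpos = seedpos,
    margin = margin, uniform_dim = if (uniform) dims[1] else NA_integer_,
    allpos = allpos), class = "projection_context")
}

.project_point_ctx <- function(ctx, p) {
  n <- length(ctx$els)
  seed_best <- numeric(n); seed_xi <- vector("list", n)
  if (!is.na(ctx$uniform_dim)) {
    sd <- .proj_seeds(ctx$uniform_dim)
    m <- ncol(sd$W)
    d2all <- colSums((ctx$allpos - p)^2)
    for (i in seq_len(n)) {
      d2 <- d2all[((i - 1L) * m + 1L):(i * m)]
      k <- order(d2)[1:2]
      seed_best[i] <- d2[k[1]]
      seed_xi[[i]] <- sd$xis[, k, drop = FALSE]
    }
  } else {
    for (i in seq_len(n)) {
      d2 <- colSums((ctx$seedpos[[i]] - p)^2)
      k <- order(d2)[1:2]
      seed_best[i] <- d2[k[1]]
      seed_xi[[i]] <- .proj_seeds(ctx$els[[i]]$dim)$xis[, k, drop = FALSE]
    }
  }
  ord <- order(seed_best)
  # phase 1: short Newton runs on every plausible element
  quick <- rep(Inf, n)
  best_q <- Inf
  for (i in ord) {
    if (sqrt(seed_best[i]) > best_q + ctx$margin[i]) next
    r <- .newton_project(ctx$params[[i]], ctx$els[[i]]$dim, seed_xi[[i]][, 1], p,
      max_iter = 6L)
    quick[i] <- r$dist
    if (r$dist < best_q) best_q <- r$dist
  }
  # phase 2: polish the near-winners, sweeping seeds (nearest first) until
  # three consecutive starts fail to improve the element's best
  polish <- which(quick <= best_q + 0.1 * ctx$margin + 1e-9)
  best_d <- Inf
  results <- list()
  for (i in polish) {
    el <- ctx$els[[i]]
    sd <- .proj_seeds(el$dim)
    d2 <- colSums((ctx$seedpos[[i]] - p)^2)
    ordseed <- order(d2)
    r <- NULL; stale <- 0L
    for (k in ordseed) {
      rk <- .newton_project(ctx$params[[i]], el$dim, sd$xis[, k], p)
      if (is.null(r) || rk$dist < r$dist - 1e-12) { r <- rk; stale <- 0L }
      else stale <- stale + 1L
      if (stale >= 3L) break
    }
    results[[length(results) + 1L]] <- list(el = el$id, r = r)
    if (r$dist < best_d) best_d <- r$dist
  }
  # tie-break: lowest element id, then lexicographically smallest xi
  cands <- Filter(function(z) z$r$dist <= best_d + 1e-12, results)
  ids <- vapply(cands, `[[`, 0L, "el")
  o <- order(ids)
  cands <- cands[o]
  pick <- cands[[1]]
  if (length(cands) > 1L) {
    for (z in cands[-1]) {
      if (z$el != pick$el) break
      cmp <- sign(z$r$xi - pick$r$xi)
      first <- cmp[cmp != 0]
      if (length(first) && first[1] < 0) pick <- z
    }
  }
  structure(list(mp = material_point(pick$el, pick$r$xi), distance = pick$r$dist,
    point = pick$r$point, weight = 1, data_index = NA_integer_),
    class = "projection")
}

#' Project every point of a contour dataset onto a scaffold
#'
#' Points whose anatomical term matches an annotation group (exact match,
#' then case-insensitive) are projected only onto that group's elements;
#' points with unmatched terms are projected against the whole mesh and the
#' terms are reported in the `unmatched_terms` attribute.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field name.
#' @param data a `contour_dataset` (see [read_segmentation_xml()]).
#' @param config a [fit_config()] (supplies per-group weights).
#' @return list of `projection` objects (one per data point, in dataset
#'   point order), with attribute `unmatched_terms`.
#' @export
project_dataset <- function(mesh, field, data, config = fit_config()) {
  pts <- dataset_points(data)
  if (!nrow(pts)) stop("empty dataset: no contour or marker points", call. = FALSE)
  terms <- annotation_terms(mesh)
  ctx_all <- .projection_context(mesh, field)
  ctx_cache <- list()
  unmatched <- character(0)
  out <- vector("list", nrow(pts))
  for (term in unique(pts$term)) {
    idx <- which(pts$term == term)
    hit <- which(terms == term)
    if (!length(hit)) hit <- which(tolower(terms) == tolower(term))
    ctx <- ctx_all
    if (length(hit) && length(mesh$annotations[[hit[1]]]$elements)) {
      if (is.null(ctx_cache[[term]]))
        ctx_cache[[term]] <- .projection_context(mesh, field,
          mesh$annotations[[hit[1]]]$elements)
      ctx <- ctx_cache[[term]]
    } else if (nzchar(term)) {
      unmatched <- c(unmatched, term)
    }
    w <- config$group_weights[[term]] %||% 1
    for (i in idx) {
      pr <- .project_point_ctx(ctx, as.numeric(pts[i, c("x", "y", "z")]))
      pr$weight <- w
      pr$data_index <- i
      pr$target <- as.numeric(pts[i, c("x", "y", "z")])
      pr$term <- term
      out[[i]] <- pr
    }
  }
  if (length(unmatched))
    message("terms without a matching annotation group (projected on whole mesh): ",
      paste(unique(unmatched), collapse = ", "))
  attr(out, "unmatched_terms") <- unique(unmatched)
  out
}

# ---- linear solve ---------------------------------------------------------

# Degree-of-freedom table for one field: per node, per stored version, one
# dof per parameter slot up to the node's maximal element dimension.
.dof_table <- function(mesh, field) {
  f <- mesh$fields[[field]]
  node_ns <- integer(0)
  for (el in mesh$elements) {
    ns <- 2L^el$dim
    for (nd in el$nodes) {
      key <- as.character(nd)
      node_ns[key] <- max(node_ns[key] %||% 0L, ns, na.rm = TRUE)
    }
  }
  base <- new.env(parent = emptyenv())
  n <- 0L
  rows <- list()
  for (key in names(f$params)) {
    ns <- node_ns[[key]]
    if (is.null(ns) || is.na(ns)) next  # node unused by any element
    for (v in seq_along(f$params[[key]])) {
      base[[paste0(key, "|", v)]] <- n
      rows[[length(rows) + 1L]] <- data.frame(node = as.integer(key), version = v,
        slot = seq_len(ns), index = n + seq_len(ns))
      n <- n + ns
    }
  }
  list(base = base, n = n, table = do.call(rbind, rows), node_ns = node_ns)
}

# dof indices of an element's parameter columns (flat corner-major layout)
.element_dofs <- function(dt, el) {
  ns <- 2L^el$dim
  out <- integer(length(el$nodes) * ns)
  for (j in seq_along(el$nodes)) {
    b <- dt$base[[paste0(el$nodes[j], "|", el$versions[j])]]
    if (is.null(b)) stop(sprintf("field has no version %d at node %d", el$versions[j], el$nodes[j]), call. = FALSE)
    out[((j - 1L) * ns + 1L):(j * ns)] <- b + seq_len(ns)
  }
  out
}

# field parameter vector over the dof table (components x ndof matrix)
.field_theta <- function(mesh, field, dt) {
  f <- mesh$fields[[field]]
  th <- matrix(0, f$components, dt$n)
  for (key in names(f$params)) {
    ns <- dt$node_ns[[key]]
    if (is.null(ns) || is.na(ns)) next
    for (v in seq_along(f$params[[key]])) {
      b <- dt$base[[paste0(key, "|", v)]]
      th[, b + seq_len(ns)] <- f$params[[key]][[v]][, seq_len(ns)]
    }
  }
  th
}

.write_theta <- function(mesh, field, dt, th) {
  f <- mesh$fields[[field]]
  for (key in names(f$params)) {
    ns <- dt$node_ns[[key]]
    if (is.null(ns) || is.na(ns)) next
    for (v in seq_along(f$params[[key]])) {
      b <- dt$base[[paste0(key, "|", v)]]
      m <- f$params[[key]][[v]]
      m[, seq_len(ns)] <- th[, b + seq_len(ns)]
      f$params[[key]][[v]] <- m
    }
  }
  mesh$fields[[field]] <- f
  mesh
}

# Dense per-element penalty blocks (identical for all elements of one
# dimension): 3-point Gauss quadrature per direction.
.penalty_blocks <- function(d) {
  g <- .gauss3()
  xis <- if (d == 3L) t(g$xi3) else t(g$xi2)
  wq <- if (d == 3L) g$w3 else g$w2
  nsq <- 2L^d * 2L^d
  S <- matrix(0, nsq, nsq); B <- matrix(0, nsq, nsq)
  for (i in seq_len(d)) {
    dv <- integer(d); dv[i] <- 1L
    G <- .tensor_weights_batch(xis, dv)
    S <- S + G %*% (wq * t(G))
  }
  specs <- list()
  for (i in seq_len(d)) { dv <- integer(d); dv[i] <- 2L; specs[[length(specs) + 1L]] <- list(dv = dv, m = 1) }
  if (d >= 2L) for (i in 1:(d - 1L)) for (j in (i + 1L):d) {
    dv <- integer(d); dv[i] <- 1L; dv[j] <- 1L
    specs[[length(specs) + 1L]] <- list(dv = dv, m = 2)  # mixed terms counted twice
  }
  for (sp in specs) {
    G <- .tensor_weights_batch(xis, sp$dv)
    B <- B + sp$m * (G %*% (wq * t(G)))
  }
  list(S = S, B = B)
}

#' Linear least-squares update of nodal parameters at frozen projections
#'
#' Minimizes the weighted squared data distances plus the strain and
#' smoothness penalties over all free nodal parameters, one sparse
#' normal-equations system per coordinate component (the system matrix is
#' shared). Hard landmark constraints are enforced exactly via an augmented
#' (KKT) system.
#'
#' @param mesh a `hermite_mesh`.
#' @param field field whose parameters are updated.
#' @param projections list of `projection`s carrying `target` points (from
#'   [project_dataset()]).
#' @param config a [fit_config()].
#' @return list with `mesh` (updated), `objective` (data + penalty terms at
#'   the solution, frozen projections) and `data_rms`.
#' @export
solve_linear_fit <- function(mesh, field, projections, config = fit_config()) {
  dt <- .dof_table(mesh, field)
  f <- mesh$fields[[field]]
  ncomp <- f$components
  npts <- length(projections)
  if (!npts) stop("no projections", call. = FALSE)
  ai <- vector("list", npts); aj <- vector("list", npts); ax <- vector("list", npts)
  wts <- numeric(npts); targets <- matrix(0, npts, ncomp)
  for (i in seq_len(npts)) {
    pr <- projections[[i]]
    el <- mesh$elements[[as.character(pr$mp$element)]]
    dofs <- .element_dofs(dt, el)
    w <- .tensor_weights_flat(pr$mp$xi)
    ai[[i]] <- rep(i, length(dofs)); aj[[i]] <- dofs; ax[[i]] <- w
    wts[i] <- pr$weight
    if (is.null(pr$target)) stop("projections must carry target points", call. = FALSE)
    targets[i, ] <- pr$target
  }
  A <- Matrix::sparseMatrix(i = unlist(ai), j = unlist(aj), x = unlist(ax),
    dims = c(npts, dt$n))
  blocks <- list()
  si <- list(); sj <- list(); sx <- list(); bx <- list()
  for (el in mesh$elements) {
    d <- el$dim
    key <- as.character(d)
    if (is.null(blocks[[key]])) blocks[[key]] <- .penalty_blocks(d)
    dofs <- .element_dofs(dt, el)
    nn <- length(dofs)
    si[[length(si) + 1L]] <- rep(dofs, times = nn)
    sj[[length(sj) + 1L]] <- rep(dofs, each = nn)
    sx[[length(sx) + 1L]] <- as.vector(blocks[[key]]$S)
    bx[[length(bx) + 1L]] <- as.vector(blocks[[key]]$B)
  }
  S <- Matrix::sparseMatrix(i = unlist(si), j = unlist(sj), x = unlist(sx), dims = c(dt$n, dt$n))
  B <- Matrix::sparseMatrix(i = unlist(si), j = unlist(sj), x = unlist(bx), dims = c(dt$n, dt$n))
  lam <- config$lambda_strain; bet <- config$beta_smooth
  M <- Matrix::crossprod(A * sqrt(wts), A * sqrt(wts)) + lam * S + bet * B
  th_ref <- .field_theta(mesh, config$reference_field, dt)
  th0 <- .field_theta(mesh, field, dt)
  Pen <- lam * S + bet * B
  rhs <- as.matrix(Matrix::crossprod(A, wts * targets) + Pen %*% t(th_ref))
  # free/frozen slot partition
  free <- rep(TRUE, dt$n)
  if (!is.null(config$free_slots)) {
    keep <- match(config$free_slots, .slot_names)
    free <- dt$table$slot[order(dt$table$index)] %in% keep
  }
  ncon <- length(config$fixed_landmarks)
  Ci <- list(); Cj <- list(); Cx <- list(); q <- matrix(0, ncon, ncomp)
  if (ncon) for (k in seq_len(ncon)) {
    lm <- config$fixed_landmarks[[k]]
    el <- mesh$elements[[as.character(lm$mp$element)]]
    dofs <- .element_dofs(dt, el)
    Ci[[k]] <- rep(k, length(dofs)); Cj[[k]] <- dofs
    Cx[[k]] <- .tensor_weights_flat(lm$mp$xi)
    q[k, ] <- lm$point
  }
  fi <- which(free); zi <- which(!free)
  Mff <- M[fi, fi, drop = FALSE]
  rhs_f <- rhs[fi, , drop = FALSE]
  if (length(zi)) rhs_f <- rhs_f - as.matrix(M[fi, zi, drop = FALSE] %*% t(th0[, zi, drop = FALSE]))
  # sparse solve with one step of iterative refinement (the normal matrix
  # can be ill-conditioned when the penalties are light)
  refine_solve <- function(K, rhs) {
    x <- Matrix::solve(K, rhs)
    x + Matrix::solve(K, rhs - K %*% x)
  }
  sol <- tryCatch({
    if (ncon) {
      C <- Matrix::sparseMatrix(i = unlist(Ci), j = unlist(Cj), x = unlist(Cx), dims = c(ncon, dt$n))
      Cf <- C[, fi, drop = FALSE]
      qf <- q
      if (length(zi)) qf <- q - as.matrix(C[, zi, drop = FALSE] %*% t(th0[, zi, drop = FALSE]))
      K <- rbind(cbind(Mff, Matrix::t(Cf)),
                 cbind(Cf, Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(ncon, ncon))))
      full <- refine_solve(K, rbind(rhs_f, qf))
      full[seq_along(fi), , drop = FALSE]
    } else {
      refine_solve(Mff, rhs_f)
    }
  }, error = function(e)
    stop("linear fit system is singular (insufficient data); set lambda_strain/beta_smooth > 0 [",
      conditionMessage(e), "]", call. = FALSE))
  th <- th0
  th[, fi] <- t(as.matrix(sol))
  if (any(!is.finite(th))) stop("non-finite nodal parameters in linear fit", call. = FALSE)
  mesh <- .write_theta(mesh, field, dt, th)
  # objective at the solution, projections frozen
  resid <- as.matrix(A %*% t(th)) - targets
  data_term <- sum(wts * rowSums(resid^2))
  dth <- th - th_ref
  pen <- 0
  for (c_ in seq_len(ncomp)) {
    v <- dth[c_, ]
    pen <- pen + lam * sum(v * as.vector(S %*% v)) + bet * sum(v * as.vector(B %*% v))
  }
  list(mesh = mesh, objective = data_term + pen,
    data_rms = sqrt(mean(rowSums(resid^2))))
}

#' Fit a scaffold to a contour dataset
#'
#' Outer loop of the fitting method: project all data points onto the
#' current geometry, solve the regularized linear least-squares problem at
#' frozen projections, and repeat. The result is stored as field `"fitted"`;
#' the reference field is untouched.
#'
#' @param mesh a `hermite_mesh` with a reference coordinate field.
#' @param data a `contour_dataset`.
#' @param config a [fit_config()].
#' @return list with `mesh` (carrying the `fitted` field) and `diagnostics`
#'   (data frame of per-iteration RMS and objective, plus `converged` flag
#'   and per-group RMS attributes).
#' @export
fit_scaffold <- function(mesh, data, config = fit_config()) {
  src <- config$reference_field
  if (is.null(mesh$fields[[src]])) stop(sprintf("no field '%s' to fit from", src), call. = FALSE)
  mesh <- copy_field(mesh, src, "fitted")
  rows <- list()
  prev_rms <- Inf
  converged <- FALSE
  projections <- NULL
  for (it in seq_len(config$outer_iterations)) {
    projections <- project_dataset(mesh, "fitted", data, config)
    rms <- sqrt(mean(vapply(projections, `[[`, 0, "distance")^2))
    s <- solve_linear_fit(mesh, "fitted", projections, config)
    mesh <- s$mesh
    rows[[it]] <- data.frame(iteration = it, rms = rms, objective = s$objective,
      post_rms = s$data_rms)
    if (abs(prev_rms - rms) < config$rms_tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  diag <- do.call(rbind, rows)
  per_group <- tapply(vapply(projections, `[[`, 0, "distance"),
    vapply(projections, function(p) p$term %||% "", ""),
    function(d) sqrt(mean(d^2)))
  attr(diag, "converged") <- converged
  attr(diag, "per_group_rms") <- per_group
  list(mesh = mesh, diagnostics = diag)
}

#' Fit a scaffold to material-registered contour data
#'
#' In the segmentation workflow this package models, contour data are often
#' registered to material coordinates on the static scaffold before any
#' deformable fitting (fiducial and concordant-point registration in the
#' segmentation software). When every contour point carries its material
#' address, the closest-point search is unnecessary: the correspondences
#' are known and one regularized linear solve fits the scaffold.
#'
#' @param mesh a `hermite_mesh` with a reference coordinate field.
#' @param data a `contour_dataset` whose contours carry an `mps` matrix
#'   (element, xi1..xi3 per point), e.g. from [sample_contours()].
#' @param config a [fit_config()].
#' @return list with `mesh` (carrying the `fitted` field) and `diagnostics`
#'   (single-row data frame: RMS before and after the solve).
#' @export
fit_scaffold_registered <- function(mesh, data, config = fit_config()) {
  stopifnot(inherits(data, "contour_dataset"))
  src <- config$reference_field
  mesh <- copy_field(mesh, src, "fitted")
  prs <- list()
  for (ct in data$contours) {
    if (is.null(ct$mps)) stop("contour '", ct$name, "' carries no material registration", call. = FALSE)
    w <- config$group_weights[[ct$name]] %||% 1
    for (q in seq_len(nrow(ct$points))) {
      mp <- material_point(ct$mps[q, 1], ct$mps[q, 2:4])
      prs[[length(prs) + 1L]] <- structure(list(mp = mp,
        distance = NA_real_, point = NULL, weight = w,
        data_index = length(prs) + 1L, target = ct$points[q, ],
        term = ct$name), class = "projection")
    }
  }
  if (!length(prs)) stop("empty dataset: no registered contour points", call. = FALSE)
  pre <- sqrt(mean(vapply(prs, function(pr)
    sum((eval_field(mesh, "fitted", pr$mp) - pr$target)^2), 0)))
  s <- solve_linear_fit(mesh, "fitted", prs, config)
  diag <- data.frame(iteration = 1L, rms = pre, objective = s$objective,
    post_rms = s$data_rms)
  attr(diag, "converged") <- TRUE
  list(mesh = s$mesh, diagnostics = diag)
}

#' Copy a field under a new name
#' @param mesh a `hermite_mesh`.
#' @param from,to field names.
#' @return the modified mesh.
#' @export
copy_field <- function(mesh, from, to) {
  f <- mesh$fields[[from]]
  if (is.null(f)) stop(sprintf("unknown field '%s'", from), call. = FALSE)
  mesh$fields[[to]] <- f
  mesh
}
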
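# Algorithmic generation of annotated organ/body scaffolds.
#
# All generators produce tricubic Hermite meshes whose nodal derivatives are
# shared between neighbouring elements, so generated scaffolds are C1 by
# construction. Two construction routes are used: a swept tube (cross
# section carried along a centerline on rotation-minimizing frames) and a
# generic "block from analytic map" used for chamber patches and vessel
# stubs.

#' Cross-section specification for tubular scaffolds
#'
#' Describes the (possibly non-circular) wall cross section of a tube
#' scaffold: a base radius plus optional taenia-coli-like longitudinal
#' thickenings and haustra-like axial bulging.
#'
#' @param base_radius mid-wall radius, mm.
#' @param wall_thickness wall thickness, mm.
#' @param n_around number of elements around the tube (>= 4).
#' @param taeniae data frame with columns `angle` (deg), `width` (deg) and
#'   `thickness` (mm bump height); angular windows must not overlap.
#' @param haustra_amplitude radial bulge amplitude, mm.
#' @param haustra_wavelength bulge waves per axial segment.
#' @return an object of class `cross_section_spec`.
#' @export
cross_section_spec <- function(base_radius, wall_thickness, n_around = 8L,
                               taeniae = NULL, haustra_amplitude = 0,
                               haustra_wavelength = 1) {
  if (base_radius <= 0 || wall_thickness <= 0) stop("radii must be positive", call. = FALSE)
  if (n_around < 4L) stop("need at least 4 elements around", call. = FALSE)
  if (is.null(taeniae)) taeniae <- data.frame(angle = numeric(0), width = numeric(0), thickness = numeric(0))
  if (nrow(taeniae) > 1L) {
    a <- taeniae$angle %% 360; w <- taeniae$width
    o <- order(a)
    a <- a[o]; w <- w[o]
    hi <- a + w / 2
    lo <- c(a[-1], a[1] + 360) - c(w[-1], w[1]) / 2
    if (any(hi > lo)) stop("taenia angular windows overlap", call. = FALSE)
  }
  structure(list(base_radius = base_radius, wall_thickness = wall_thickness,
    n_around = as.integer(n_around), taeniae = taeniae,
    haustra_amplitude = haustra_amplitude,
    haustra_wavelength = haustra_wavelength), class = "cross_section_spec")
}

# mid-wall radius at angle theta (rad, vector) and continuous axial segment
# coordinate seg. Taeniae are raised-cosine-squared bumps (C1); haustra a
# sinusoidal outward bulge between the taeniae.
.section_radius <- function(spec, theta, seg) {
  r <- rep(spec$base_radius, length(theta))
  envelope <- rep(1, length(theta))
  if (nrow(spec$taeniae)) for (i in seq_len(nrow(spec$taeniae))) {
    phi <- spec$taeniae$angle[i] * pi / 180
    w <- spec$taeniae$width[i] * pi / 180
    d <- atan2(sin(theta - phi), cos(theta - phi))  # wrapped difference
    win <- ifelse(abs(d) < w / 2, cos(pi * d / w)^2, 0)
    r <- r + spec$taeniae$thickness[i] * win
    envelope <- envelope * (1 - win)
  }
  if (spec$haustra_amplitude > 0) {
    bulge <- 0.5 * (1 + sin(2 * pi * spec$haustra_wavelength * seg - pi / 2))
    r <- r + spec$haustra_amplitude * bulge * envelope
  }
  r
}

#' Centerline of a tubular scaffold
#'
#' An ordered 3-D polyline (optionally with axial twist angles) through
#' which a natural cubic spline is passed; arc length is computed on
#' construction.
#'
#' @param points numeric matrix, n x 3, n >= 2, no repeated consecutive
#'   points (mm).
#' @param twist optional numeric vector of axial twist angles (deg), one per
#'   point.
#' @return an object of class `centerline`.
#' @export
centerline <- function(points, twist = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L) stop("centerline needs >= 2 points in 3-D", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("repeated consecutive centerline points", call. = FALSE)
  if (!is.null(twist) && length(twist) != nrow(points)) stop("one twist angle per point", call. = FALSE)
  s <- c(0, cumsum(seg))
  structure(list(points = points, s = s, twist = twist), class = "centerline")
}

# Resample a centerline at n+1 stations equally spaced in arc length.
# Returns centers, unit tangents, and twist per station.
.centerline_stations <- function(cl, n, fracs = NULL) {
  fx <- stats::splinefun(cl$s, cl$points[, 1], method = "natural")
  fy <- stats::splinefun(cl$s, cl$points[, 2], method = "natural")
  fz <- stats::splinefun(cl$s, cl$points[, 3], method = "natural")
  # reparameterize by true (spline) arc length
  sf <- seq(0, max(cl$s), length.out = 50 * length(cl$s))
  pf <- cbind(fx(sf), fy(sf), fz(sf))
  arc <- c(0, cumsum(sqrt(rowSums(diff(pf)^2))))
  target <- if (is.null(fracs)) seq(0, max(arc), length.out = n + 1) else fracs * max(arc)
  sk <- stats::approx(arc, sf, xout = target)$y
  C <- cbind(fx(sk), fy(sk), fz(sk))
  T <- cbind(fx(sk, deriv = 1), fy(sk, deriv = 1), fz(sk, deriv = 1))
  T <- T / sqrt(rowSums(T^2))
  tw <- if (is.null(cl$twist)) rep(0, n + 1) else
    stats::approx(cl$s, cl$twist, xout = pmin(sk, max(cl$s)))$y * pi / 180
  list(C = C, T = T, twist = tw, ds = max(arc) / n, arc = max(arc))
}

# Rotation-minimizing frames by the double-reflection method.
.rmf_frames <- function(C, T, twist) {
  n <- nrow(C)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  up <- diag(3)[which.min(abs(T[1, ])), ]
  v <- up - sum(up * T[1, ]) * T[1, ]
  e1[1, ] <- v / sqrt(sum(v^2))
  e2[1, ] <- .cross3(T[1, ], e1[1, ])
  for (k in 2:n) {
    v1 <- C[k, ] - C[k - 1, ]
    c1 <- sum(v1 * v1)
    rL <- e1[k - 1, ] - (2 / c1) * sum(v1 * e1[k - 1, ]) * v1
    tL <- T[k - 1, ] - (2 / c1) * sum(v1 * T[k - 1, ]) * v1
    v2 <- T[k, ] - tL
    c2 <- sum(v2 * v2)
    e1[k, ] <- if (c2 > 1e-14) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
    e1[k, ] <- e1[k, ] - sum(e1[k, ] * T[k, ]) * T[k, ]
    e1[k, ] <- e1[k, ] / sqrt(sum(e1[k, ]^2))
    e2[k, ] <- .cross3(T[k, ], e1[k, ])
  }
  for (k in seq_len(n)) if (twist[k] != 0) {
    ca <- cos(twist[k]); sa <- sin(twist[k])
    a <- ca * e1[k, ] + sa * e2[k, ]
    b <- -sa * e1[k, ] + ca * e2[k, ]
    e1[k, ] <- a; e2[k, ] <- b
  }
  list(e1 = e1, e2 = e2)
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

# Core swept-tube builder. radii_fun(theta_vec, seg) must return a matrix
# (length(theta) x n_boundaries) of strictly increasing radial boundary
# positions; n_boundaries - 1 element layers are built. Radial interpolation
# across boundaries uses a monotone (Hyman) spline so the radial derivative
# is single-valued at shared layer boundaries.
.sweep_tube <- function(radii_fun, cl, n_segments, n_around, block_name = "tube",
                        max_radius = NULL, station_fracs = NULL) {
  st <- .centerline_stations(cl, n_segments, station_fracs)
  # self-intersection guard: centerline curvature radius must exceed the
  # tube radius everywhere
  if (!is.null(max_radius) && n_segments >= 2) {
    for (k in 2:n_segments) {
      a <- st$C[k - 1, ]; b <- st$C[k, ]; cc <- st$C[k + 1, ]
      ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((cc - b)^2)); ac <- sqrt(sum((cc - a)^2))
      area2 <- sqrt(max(0, (ab + bc + ac) * (-ab + bc + ac) * (ab - bc + ac) * (ab + bc - ac))) / 4
      if (area2 > 1e-12) {
        rcurv <- ab * bc * ac / (4 * area2)
        if (rcurv < max_radius)
          stop(sprintf("centerline curvature radius %.3g mm at arc position %.3g mm is smaller than the tube radius %.3g mm",
            rcurv, (k - 1) * st$ds, max_radius), call. = FALSE)
      }
    }
  }
  fr <- .rmf_frames(st$C, st$T, st$twist)
  nb <- ncol(radii_fun(0, 0))
  nl <- nb - 1L
  nsta <- n_segments + 1L
  nid <- function(j, k, l) ((j - 1L) %% n_around) + n_around * ((k - 1L) + nsta * (l - 1L)) + 1L
  h <- 1e-5
  theta_of <- function(j) 2 * pi * (j - 1) / n_around
  # per-station per-node quantities; axial derivatives by station differencing
  val <- array(0, c(3, n_around, nsta, nb))
  d1 <- array(0, c(3, n_around, nsta, nb))
  d3 <- array(0, c(3, n_around, nsta, nb))
  d13 <- array(0, c(3, n_around, nsta, nb))
  for (k in seq_len(nsta)) {
    seg <- k - 1
    e1 <- fr$e1[k, ]; e2 <- fr$e2[k, ]; Ck <- st$C[k, ]
    # radial spline and its theta-sensitivity at each around node
    eval_m <- function(theta, rfrac, deriv_r = 0L) {
      bnd <- radii_fun(theta, seg)[1, ]
      wfrac <- seq(0, 1, length.out = nb)
      sp <- if (nb > 2L) stats::splinefun(wfrac, bnd, method = "hyman")
            else function(x, deriv = 0) if (deriv == 0) bnd[1] + x * (bnd[2] - bnd[1]) else bnd[2] - bnd[1]
      rho <- sp(rfrac, deriv = deriv_r)
      u <- cos(theta) * e1 + sin(theta) * e2
      up <- -sin(theta) * e1 + cos(theta) * e2
      if (deriv_r == 0L) list(m = Ck + rho * u, rho = rho, u = u, up = up)
      else list(m = rho * u, rho = rho, u = u, up = up)  # radial-deriv direction
    }
    for (j in seq_len(n_around)) {
      th <- theta_of(j)
      for (l in seq_len(nb)) {
        rf <- (l - 1) / nl
        a0 <- eval_m(th, rf, 0L)
        val[, j, k, l] <- a0$m
        # d/dtheta and cross d/dtheta d/drfrac by central differences
        mp <- eval_m(th + h, rf, 0L)$m; mm <- eval_m(th - h, rf, 0L)$m
        d1[, j, k, l] <- (mp - mm) / (2 * h) * (2 * pi / n_around)
        rp <- eval_m(th, rf, 1L)$m; # d m / d rfrac
        d3[, j, k, l] <- rp / nl
        rpp <- eval_m(th + h, rf, 1L)$m; rpm <- eval_m(th - h, rf, 1L)$m
        d13[, j, k, l] <- (rpp - rpm) / (2 * h) * (2 * pi / n_around) / nl
      }
    }
  }
  axdiff <- function(arr) {
    out <- arr
    for (k in seq_len(nsta)) {
      if (k == 1L) out[, , k, ] <- arr[, , 2, ] - arr[, , 1, ]
      else if (k == nsta) out[, , k, ] <- arr[, , nsta, ] - arr[, , nsta - 1, ]
      else out[, , k, ] <- (arr[, , k + 1, ] - arr[, , k - 1, ]) / 2
    }
    out
  }
  d2 <- axdiff(val); d12 <- axdiff(d1); d23 <- axdiff(d3); d123 <- axdiff(d13)
  mesh <- hermite_mesh()
  for (l in seq_len(nb)) for (k in seq_len(nsta)) for (j in seq_len(n_around)) {
    params <- cbind(val[, j, k, l], d1[, j, k, l], d2[, j, k, l], d12[, j, k, l],
                    d3[, j, k, l], d13[, j, k, l], d23[, j, k, l], d123[, j, k, l])
    mesh <- set_node_params(mesh, "reference", nid(j, k, l), params)
  }
  eid <- function(j, k, l) (j - 1L) + n_around * ((k - 1L) + n_segments * (l - 1L)) + 1L
  elems <- array(0L, c(n_around, n_segments, nl))
  for (l in seq_len(nl)) for (k in seq_len(n_segments)) for (j in seq_len(n_around)) {
    nodes <- c(nid(j, k, l), nid(j + 1L, k, l), nid(j, k + 1L, l), nid(j + 1L, k + 1L, l),
               nid(j, k, l + 1L), nid(j + 1L, k, l + 1L), nid(j, k + 1L, l + 1L), nid(j + 1L, k + 1L, l + 1L))
    mesh <- add_element(mesh, eid(j, k, l), 3L, nodes)
    elems[j, k, l] <- eid(j, k, l)
  }
  inner_nodes <- as.integer(outer(seq_len(n_around), seq_len(nsta), function(j, k) nid(j, k, 1L)))
  outer_nodes <- as.integer(outer(seq_len(n_around), seq_len(nsta), function(j, k) nid(j, k, nb)))
  start_nodes <- as.integer(outer(seq_len(n_around), seq_len(nb), function(j, l) nid(j, 1L, l)))
  end_nodes <- as.integer(outer(seq_len(n_around), seq_len(nb), function(j, l) nid(j, nsta, l)))
  mesh <- add_annotation(mesh, "inner surface", "", elements = as.integer(elems[, , 1]), nodes = inner_nodes)
  mesh <- add_annotation(mesh, "outer surface", "", elements = as.integer(elems[, , nl]), nodes = outer_nodes)
  mesh <- add_annotation(mesh, "start", "", nodes = start_nodes, kind = "landmark")
  mesh <- add_annotation(mesh, "end", "", nodes = end_nodes, kind = "landmark")
  mesh$metadata$blocks <- list()
  mesh$metadata$blocks[[block_name]] <- list(
    elems = elems, wrap_u = TRUE, n_around = n_around,
    n_segments = n_segments, n_layers = nl, stations = st$C, arc = st$arc)
  mesh
}

#' Build a tube scaffold by sweeping a cross section along a centerline
#'
#' The cross section is carried along the centerline on rotation-minimizing
#' (parallel-transported) frames and attached segment by segment, producing
#' a tricubic Hermite mesh of `n_segments` x `n_around` x 1 (through-wall)
#' elements with annotation groups `inner surface`, `outer surface`,
#' `start`, `end`.
#'
#' @param cross_section a [cross_section_spec()].
#' @param cl a [centerline()].
#' @param n_segments number of axial elements (>= 1).
#' @return a `hermite_mesh` with a `reference` coordinate field.
#' @export
build_tube <- function(cross_section, cl, n_segments) {
  stopifnot(inherits(cross_section, "cross_section_spec"), inherits(cl, "centerline"))
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  w <- cross_section$wall_thickness
  radii_fun <- function(theta, seg) {
    r <- .section_radius(cross_section, theta, seg)
    cbind(r - w / 2, r + w / 2)
  }
  max_r <- cross_section$base_radius + w / 2 + cross_section$haustra_amplitude +
    (if (nrow(cross_section$taeniae)) max(cross_section$taeniae$thickness) else 0)
  .sweep_tube(radii_fun, cl, as.integer(n_segments), cross_section$n_around,
    max_radius = max_r)
}

# ---- generic block from an analytic map -----------------------------------

# Build an nu x nv x nw block of tricubic elements from a smooth map
# f(u, v, w) -> 3-vector over [0,1]^3 (the map must tolerate arguments a
# step h outside the cube). All nodal derivatives come from central finite
# differences of the map, so shared nodes get identical parameters and the
# block is C1. wrap_u joins u = 1 back onto u = 0 (the map must be
# 1-periodic in u).
.block_from_map <- function(f, nu, nv, nw, wrap_u = FALSE, h = 1e-4,
                            block_name = "block") {
  nun <- if (wrap_u) nu else nu + 1L
  nid <- function(i, j, k) {
    ii <- if (wrap_u) ((i - 1L) %% nu) + 1L else i
    (ii - 1L) + nun * ((j - 1L) + (nv + 1L) * (k - 1L)) + 1L
  }
  mesh <- hermite_mesh()
  scl <- c(1 / nu, 1 / nv, 1 / nw)
  for (k in seq_len(nw + 1L)) for (j in seq_len(nv + 1L)) for (i in seq_len(nun)) {
    u <- (i - 1) / nu; v <- (j - 1) / nv; w <- (k - 1) / nw
    # central FD stencils for value, first, second-cross, third-cross derivs
    g <- function(du, dv, dw) f(u + du * h, v + dv * h, w + dw * h)
    v000 <- g(0, 0, 0)
    D <- list()
    D$d1 <- (g(1, 0, 0) - g(-1, 0, 0)) / (2 * h)
    D$d2 <- (g(0, 1, 0) - g(0, -1, 0)) / (2 * h)
    D$d3 <- (g(0, 0, 1) - g(0, 0, -1)) / (2 * h)
    D$d12 <- (g(1, 1, 0) - g(1, -1, 0) - g(-1, 1, 0) + g(-1, -1, 0)) / (4 * h^2)
    D$d13 <- (g(1, 0, 1) - g(1, 0, -1) - g(-1, 0, 1) + g(-1, 0, -1)) / (4 * h^2)
    D$d23 <- (g(0, 1, 1) - g(0, 1, -1) - g(0, -1, 1) + g(0, -1, -1)) / (4 * h^2)
    D$d123 <- (g(1, 1, 1) - g(1, 1, -1) - g(1, -1, 1) + g(1, -1, -1) -
               g(-1, 1, 1) + g(-1, 1, -1) + g(-1, -1, 1) - g(-1, -1, -1)) / (8 * h^3)
    params <- cbind(v000,
      D$d1 * scl[1], D$d2 * scl[2], D$d12 * scl[1] * scl[2],
      D$d3 * scl[3], D$d13 * scl[1] * scl[3], D$d23 * scl[2] * scl[3],
      D$d123 * scl[1] * scl[2] * scl[3])
    mesh <- set_node_params(mesh, "reference", nid(i, j, k), params)
  }
  elems <- array(0L, c(nu, nv, nw))
  eid <- 0L
  for (k in seq_len(nw)) for (j in seq_len(nv)) for (i in seq_len(nu)) {
    eid <- eid + 1L
    nodes <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i, j + 1L, k), nid(i + 1L, j + 1L, k),
               nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i, j + 1L, k + 1L), nid(i + 1L, j + 1L, k + 1L))
    mesh <- add_element(mesh, eid, 3L, nodes)
    elems[i, j, k] <- eid
  }
  mesh$metadata$blocks <- list()
  mesh$metadata$blocks[[block_name]] <- list(elems = elems, wrap_u = wrap_u,
    n_around = nu, n_segments = nv, n_layers = nw)
  mesh
}

# Merge meshes with disjoint node/element id spaces (ids are offset).
.merge_meshes <- function(meshes) {
  out <- hermite_mesh()
  node_off <- 0L; elem_off <- 0L
  for (m in meshes) {
    for (el in m$elements)
      out <- add_element(out, el$id + elem_off, el$dim, el$nodes + node_off, el$versions)
    for (fname in names(m$fields)) {
      f <- m$fields[[fname]]
      for (key in names(f$params)) for (v in seq_along(f$params[[key]]))
        out <- set_node_params(out, fname, as.integer(key) + node_off, f$params[[key]][[v]], v)
    }
    for (g in m$annotations)
      out <- add_annotation(out, g$term, g$ontology_id, g$elements + elem_off,
        g$nodes + node_off, g$kind)
    for (bn in names(m$metadata$blocks %||% list())) {
      b <- m$metadata$blocks[[bn]]
      b$elems <- b$elems + elem_off
      out$metadata$blocks[[bn]] <- b
    }
    node_off <- node_off + (if (length(m$node_ids)) max(m$node_ids) else 0L)
    elem_off <- elem_off + (if (length(m$elements)) max(vapply(m$elements, `[[`, 0L, "id")) else 0L)
  }
  out
}

# ---- species presets ------------------------------------------------------

.preset_db <- function() {
  arch <- function(width, height) rbind(
    c(-width / 2, 0, 0), c(-width / 2, 0, height * 0.4), c(-width / 2, 0, height * 0.8),
    c(-width / 3, 0, height), c(0, 0, height * 1.05), c(width / 3, 0, height),
    c(width / 2, 0, height * 0.8), c(width / 2, 0, height * 0.4), c(width / 2, 0, 0))
  helix <- function(r, pitch, turns, n) {
    t <- seq(0, 2 * pi * turns, length.out = n)
    cbind(r * cos(t), r * sin(t), pitch * t / (2 * pi))
  }
  gentle <- rbind(c(0, 0, 0), c(4, 0, 20), c(0, 4, 40), c(0, 0, 60))
  list(
    "human-colon" = list(kind = "colon", species = "human",
      section = cross_section_spec(22, 3, n_around = 8L,
        taeniae = data.frame(angle = c(0, 120, 240), width = 40, thickness = 1.5),
        haustra_amplitude = 2, haustra_wavelength = 0.5),
      centerline = centerline(arch(180, 200)), n_segments = 8L, n_taeniae = 3L),
    "pig-colon" = list(kind = "colon", species = "pig",
      section = cross_section_spec(15, 2.5, n_around = 8L,
        taeniae = data.frame(angle = c(0, 180), width = 40, thickness = 1.2),
        haustra_amplitude = 1.5, haustra_wavelength = 0.5),
      centerline = centerline(helix(60, 35, 2, 9)), n_segments = 8L, n_taeniae = 2L),
    "mouse-colon" = list(kind = "colon", species = "mouse",
      section = cross_section_spec(1.5, 0.4, n_around = 8L),
      centerline = centerline(gentle), n_segments = 6L, n_taeniae = 0L),
    "human-atria" = list(kind = "atria", species = "human", n_pulmonary_veins = 4L,
      has_ivc = TRUE, has_svc = TRUE, chamber_radius = 28, shell_thickness = 3),
    "pig-atria" = list(kind = "atria", species = "pig", n_pulmonary_veins = 2L,
      has_ivc = TRUE, has_svc = TRUE, chamber_radius = 22, shell_thickness = 2.5),
    "rat-atria" = list(kind = "atria", species = "rat", n_pulmonary_veins = 3L,
      has_ivc = TRUE, has_svc = TRUE, chamber_radius = 4, shell_thickness = 0.6),
    "rat-body" = list(kind = "body", species = "rat", length = 220, core_radius = 18,
      n_axial_segments = 6L, n_around = 8L, diaphragm_position = 0.35)
  )
}

#' List the built-in species presets
#' @return character vector of preset names.
#' @export
species_presets <- function() names(.preset_db())

#' Generate a scaffold from a species preset
#'
#' Dispatches to [make_colon()], [make_atria()] or [make_body()] with the
#' preset's parameter bundle. Presets encode the species-dependent topology:
#' 3/2/0 taeniae coli for the human/pig/mouse colon and 4/2/3 pulmonary
#' veins for the human/pig/rat atria.
#'
#' @param preset preset name (see [species_presets()]).
#' @param ... named parameter overrides merged over the preset bundle.
#' @return a `hermite_mesh`.
#' @export
make_scaffold <- function(preset, ...) {
  db <- .preset_db()
  p <- db[[preset]]
  if (is.null(p)) stop(sprintf("unknown preset '%s'; see species_presets()", preset), call. = FALSE)
  ov <- list(...)
  for (k in names(ov)) p[[k]] <- ov[[k]]
  switch(p$kind,
    colon = .make_colon_impl(p),
    atria = .make_atria_impl(p),
    body = make_body(length = p$length, core_radius = p$core_radius,
      n_axial_segments = p$n_axial_segments, n_around = p$n_around,
      diaphragm_position = p$diaphragm_position))
}

#' Colon scaffold with species-specific taeniae coli
#'
#' A swept-tube colon scaffold. Taenia coli annotation groups (`"taenia coli
#' 1"` ... `"taenia coli k"`) mark the element sectors under each
#' longitudinal band; the mouse preset has a smooth circular section and no
#' taenia groups.
#'
#' @param preset one of `"human-colon"`, `"pig-colon"`, `"mouse-colon"`.
#' @param ... parameter overrides (see [make_scaffold()]).
#' @return a `hermite_mesh`.
#' @export
make_colon <- function(preset, ...) {
  p <- .preset_db()[[preset]]
  if (is.null(p) || p$kind != "colon") stop(sprintf("'%s' is not a colon preset", preset), call. = FALSE)
  ov <- list(...); for (k in names(ov)) p[[k]] <- ov[[k]]
  .make_colon_impl(p)
}

.make_colon_impl <- function(p) {
  mesh <- build_tube(p$section, p$centerline, p$n_segments)
  names(mesh$metadata$blocks) <- "colon"
  blk <- mesh$metadata$blocks$colon
  all_elems <- as.integer(blk$elems)
  mesh <- add_annotation(mesh, "colon", "UBERON:0001155", elements = all_elems)
  tae <- p$section$taeniae
  n_around <- p$section$n_around
  if (nrow(tae)) for (i in seq_len(nrow(tae))) {
    lo <- (tae$angle[i] - tae$width[i] / 2) %% 360
    hi <- (tae$angle[i] + tae$width[i] / 2) %% 360
    sect <- 360 / n_around
    js <- which(vapply(seq_len(n_around), function(j) {
      a0 <- (j - 1) * sect; a1 <- j * sect
      if (lo <= hi) (a0 < hi && a1 > lo) else (a0 < hi || a1 > lo)
    }, TRUE))
    mesh <- add_annotation(mesh, paste("taenia coli", i), "UBERON:0012419",
      elements = as.integer(blk$elems[js, , ]))
  }
  mesh$metadata$preset <- paste0(p$species, "-colon")
  mesh
}

#' Atrial scaffold with species-specific vein topology
#'
#' Chambers are mapped spherical-shell patches; the atrial auricles, the
#' pulmonary veins and the venae cavae are short tube stubs attached over
#' the chamber roofs. Every structure gets its own annotation group; the rat
#' preset exposes exactly the nine groups left/right atrium, left/right
#' atrial auricle, left/middle/right pulmonary vein, and the inferior and
#' superior vena cava.
#'
#' @param preset one of `"human-atria"`, `"pig-atria"`, `"rat-atria"`, or
#'   `NULL` to use the explicit parameters.
#' @param n_pulmonary_veins number of pulmonary vein inlets (1..6).
#' @param has_ivc,has_svc include the inferior / superior vena cava stubs.
#' @param chamber_radius atrial chamber radius, mm.
#' @param shell_thickness wall (endocardial to epicardial) thickness, mm.
#' @return a `hermite_mesh`.
#' @export
make_atria <- function(preset = NULL, n_pulmonary_veins = 3L, has_ivc = TRUE,
                       has_svc = TRUE, chamber_radius = 4, shell_thickness = 0.6) {
  if (!is.null(preset)) {
    p <- .preset_db()[[preset]]
    if (is.null(p) || p$kind != "atria") stop(sprintf("'%s' is not an atria preset", preset), call. = FALSE)
    return(.make_atria_impl(p))
  }
  .make_atria_impl(list(species = NA_character_, n_pulmonary_veins = as.integer(n_pulmonary_veins),
    has_ivc = has_ivc, has_svc = has_svc, chamber_radius = chamber_radius,
    shell_thickness = shell_thickness))
}

.make_atria_impl <- function(p) {
  npv <- as.integer(p$n_pulmonary_veins)
  if (npv < 1L || npv > 6L) stop("n_pulmonary_veins must be in 1..6", call. = FALSE)
  r <- p$chamber_radius; t <- p$shell_thickness
  deg <- pi / 180
  sphere_patch <- function(center, th0, th1, ph0, ph1, name) {
    f <- function(u, v, w) {
      th <- (th0 + u * (th1 - th0)) * deg
      ph <- (ph0 + v * (ph1 - ph0)) * deg
      center + (r + (w - 0.5) * t) * c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
    }
    .block_from_map(f, 2L, 2L, 1L, block_name = name)
  }
  stub <- function(base, dir, radius, len, wall, name) {
    dir <- dir / sqrt(sum(dir^2))
    up <- diag(3)[which.min(abs(dir)), ]
    n1 <- up - sum(up * dir) * dir; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- .cross3(dir, n1)
    f <- function(u, v, w) {
      th <- 2 * pi * u
      base + v * len * dir + (radius + (w - 0.5) * wall) * (cos(th) * n1 + sin(th) * n2)
    }
    .block_from_map(f, 4L, 1L, 1L, wrap_u = TRUE, block_name = name)
  }
  cL <- c(-0.9 * r, 0, 0); cR <- c(0.9 * r, 0, 0)
  sph <- function(center, th, ph, rad = r) center + rad * c(cos(ph * deg) * cos(th * deg),
    cos(ph * deg) * sin(th * deg), sin(ph * deg))
  rdir <- function(th, ph) c(cos(ph * deg) * cos(th * deg), cos(ph * deg) * sin(th * deg), sin(ph * deg))
  stub_r <- 0.20 * r; stub_len <- 0.6 * r; stub_wall <- 0.5 * t
  comps <- list(); groups <- list()
  add_comp <- function(mesh, term, curie) {
    comps[[length(comps) + 1L]] <<- mesh
    groups[[length(groups) + 1L]] <<- list(term = term, ontology_id = curie)
  }
  add_comp(sphere_patch(cL, 100, 260, -50, 50, "LA"), "left atrium", "UBERON:0002079")
  add_comp(sphere_patch(cR, -80, 80, -50, 50, "RA"), "right atrium", "UBERON:0002078")
  add_comp(stub(sph(cL, 180, -10), rdir(180, -10), 1.4 * stub_r, stub_len, stub_wall, "LAA"),
    "left atrial auricle", "UBERON:0006630")
  add_comp(stub(sph(cR, 0, -10), rdir(0, -10), 1.4 * stub_r, stub_len, stub_wall, "RAA"),
    "right atrial auricle", "UBERON:0006631")
  pv_names <- switch(as.character(npv),
    "2" = c("left pulmonary vein", "right pulmonary vein"),
    "3" = c("left pulmonary vein", "middle pulmonary vein", "right pulmonary vein"),
    "4" = c("left superior pulmonary vein", "left inferior pulmonary vein",
            "right superior pulmonary vein", "right inferior pulmonary vein"),
    paste("pulmonary vein", seq_len(npv)))
  pv_th <- seq(130, 230, length.out = npv)
  for (i in seq_len(npv))
    add_comp(stub(sph(cL, pv_th[i], 58), rdir(pv_th[i], 58), stub_r, stub_len, stub_wall,
      paste0("PV", i)), pv_names[i], "UBERON:0002016")
  if (isTRUE(p$has_ivc))
    add_comp(stub(sph(cR, 20, -58), rdir(20, -58), 1.3 * stub_r, stub_len, stub_wall, "IVC"),
      "inferior vena cava", "UBERON:0001072")
  if (isTRUE(p$has_svc))
    add_comp(stub(sph(cR, 20, 58), rdir(20, 58), 1.2 * stub_r, stub_len, stub_wall, "SVC"),
      "superior vena cava", "UBERON:0001585")
  mesh <- .merge_meshes(comps)
  # one annotation group per component, covering all its elements
  off <- 0L
  for (i in seq_along(comps)) {
    n_el <- length(comps[[i]]$elements)
    ids <- as.integer(seq_len(n_el) + off)
    mesh <- add_annotation(mesh, groups[[i]]$term, groups[[i]]$ontology_id, elements = ids)
    off <- off + max(vapply(comps[[i]]$elements, `[[`, 0L, "id"))
  }
  validate_mesh(mesh)
  mesh$metadata$preset <- if (!is.na(p$species)) paste0(p$species, "-atria") else NULL
  mesh
}

#' Whole-body scaffold: visceral core plus outer layer
#'
#' A two-layer cylindrical scaffold: an inner annular core for the visceral
#' organs and an outer layer carrying the spinal cord and skin. The core is
#' divided by the diaphragm into thorax and abdomen; axial stations are laid
#' out so that one node ring falls exactly at the diaphragm level.
#'
#' @param length body axis length, mm (axial coordinate runs 0 = cranial to
#'   `length` = caudal).
#' @param core_radius radius of the core/outer-layer interface, mm.
#' @param n_axial_segments number of axial element segments (>= 2, so the
#'   diaphragm can separate thorax from abdomen).
#' @param n_around elements around the body axis.
#' @param diaphragm_position axial position of the diaphragm as a fraction
#'   of body length, strictly between 0 and 1.
#' @return a `hermite_mesh` with annotation groups `thorax`, `abdomen`,
#'   `diaphragm`, `spinal cord` and `skin`.
#' @export
make_body <- function(length = 220, core_radius = 18, n_axial_segments = 6L,
                      n_around = 8L, diaphragm_position = 0.35) {
  if (diaphragm_position <= 0 || diaphragm_position >= 1)
    stop("diaphragm_position must be strictly between 0 and 1", call. = FALSE)
  n_ax <- as.integer(n_axial_segments)
  if (n_ax < 2L) stop("need at least 2 axial segments to place the diaphragm", call. = FALSE)
  k_d <- min(max(1L, as.integer(round(diaphragm_position * n_ax))), n_ax - 1L)
  z_d <- diaphragm_position * length
  z <- c(seq(0, z_d, length.out = k_d + 1L), seq(z_d, length, length.out = n_ax - k_d + 1L)[-1])
  cl <- centerline(cbind(0, 0, z))
  lumen <- 0.25 * core_radius; outer_r <- 1.4 * core_radius
  radii_fun <- function(theta, seg) cbind(rep(lumen, base::length(theta)), core_radius, outer_r)
  mesh <- .sweep_tube(radii_fun, cl, n_ax, as.integer(n_around), block_name = "body",
    station_fracs = z / length)
  blk <- mesh$metadata$blocks$body
  core <- blk$elems[, , 1]; layer <- blk$elems[, , 2]
  thorax <- as.integer(core[, seq_len(k_d)])
  abdomen <- as.integer(core[, (k_d + 1L):n_ax])
  mesh <- add_annotation(mesh, "thorax", "UBERON:0000915", elements = thorax)
  mesh <- add_annotation(mesh, "abdomen", "UBERON:0000916", elements = abdomen)
  # diaphragm: landmark node ring (all radial boundaries of the core) at the
  # diaphragm station
  nsta <- n_ax + 1L
  nid <- function(j, k, l) ((j - 1L) %% n_around) + n_around * ((k - 1L) + nsta * (l - 1L)) + 1L
  dia_nodes <- as.integer(c(vapply(seq_len(n_around), function(j) nid(j, k_d + 1L, 1L), 0),
                            vapply(seq_len(n_around), function(j) nid(j, k_d + 1L, 2L), 0)))
  mesh <- add_annotation(mesh, "diaphragm", "UBERON:0001103", nodes = dia_nodes, kind = "landmark")
  # spinal cord: dorsal node path along the outer layer interface
  j_dorsal <- as.integer(round(n_around / 2)) + 1L
  sc_nodes <- as.integer(vapply(seq_len(nsta), function(k) nid(j_dorsal, k, 3L), 0))
  mesh <- add_annotation(mesh, "spinal cord", "UBERON:0002240", nodes = sc_nodes, kind = "landmark")
  mesh <- add_annotation(mesh, "skin", "UBERON:0002097", elements = as.integer(layer),
    nodes = as.integer(outer(seq_len(n_around), seq_len(nsta), function(j, k) nid(j, k, 3L))))
  mesh$metadata$preset <- "body"
  mesh$metadata$diaphragm_z <- z_d
  mesh
}
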
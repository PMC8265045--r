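# The scaffold mesh container.
#
# A mesh holds integer-id nodes, cubic Hermite elements (1/2/3-D), one or
# more named coordinate/scalar fields, and ontology-annotated groups of
# elements and nodes. Nodal parameters live under the field, per node, as a
# list of "derivative versions": each version is a components x 8 matrix
# whose columns follow the canonical slot order (value, d1, d2, d12, d3,
# d13, d23, d123). Versions beyond the first let elements meeting at apices
# or branch points select alternative derivative sets.

#' Create an empty scaffold mesh
#'
#' @param units coordinate units label (informational; the package works in
#'   mm throughout).
#' @return an object of class `hermite_mesh`.
#' @export
hermite_mesh <- function(units = "mm") {
  structure(list(
    node_ids = integer(0),
    elements = list(),
    fields = list(),
    annotations = list(),
    metadata = list(units = units)
  ), class = "hermite_mesh")
}

#' @export
print.hermite_mesh <- function(x, ...) {
  dims <- vapply(x$elements, `[[`, 0L, "dim")
  cat(sprintf("<hermite_mesh: %d nodes, %d elements%s, fields: %s, %d annotation groups>\n",
    length(x$node_ids), length(x$elements),
    if (length(dims)) sprintf(" (dim %s)", paste(sort(unique(dims)), collapse = ",")) else "",
    if (length(x$fields)) paste(names(x$fields), collapse = ", ") else "<none>",
    length(x$annotations)))
  invisible(x)
}

#' Add a cubic Hermite element
#'
#' Local nodes are listed lowest-\eqn{\xi} corner first with \eqn{\xi_1}
#' varying fastest (so a 3-D element lists corners 000, 100, 010, 110, 001,
#' 101, 011, 111 in \eqn{(\xi_1 \xi_2 \xi_3)} bit order).
#'
#' @param mesh a `hermite_mesh`.
#' @param id integer element id, unique within the mesh.
#' @param dim element dimension (1, 2 or 3).
#' @param nodes integer vector of 2^dim node ids.
#' @param versions per-local-node derivative-version selector (default all 1).
#' @return the modified mesh.
#' @export
add_element <- function(mesh, id, dim, nodes, versions = rep(1L, length(nodes))) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  if (!dim %in% 1:3) stop("element dimension must be 1, 2 or 3", call. = FALSE)
  if (length(nodes) != 2^dim)
    stop(sprintf("a %d-D element needs %d corner nodes, got %d", dim, 2^dim, length(nodes)), call. = FALSE)
  if (length(versions) != length(nodes)) stop("one version selector per local node", call. = FALSE)
  key <- as.character(id)
  if (!is.null(mesh$elements[[key]])) stop(sprintf("element id %s already present", key), call. = FALSE)
  mesh$elements[[key]] <- list(id = as.integer(id), dim = as.integer(dim),
    nodes = as.integer(nodes), versions = as.integer(versions))
  mesh$node_ids <- union(mesh$node_ids, as.integer(nodes))
  mesh
}

#' Set nodal parameters of a field at one node
#'
#' @param mesh a `hermite_mesh`.
#' @param field field name (created on first use).
#' @param node integer node id.
#' @param params numeric matrix, components x slots. Fewer than 8 slot
#'   columns are zero-padded on the right.
#' @param version derivative-version index (>= 1).
#' @return the modified mesh.
#' @export
set_node_params <- function(mesh, field, node, params, version = 1L) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  if (is.null(dim(params))) params <- matrix(params, nrow = length(params))
  nc <- nrow(params)
  if (ncol(params) > 8L) stop("at most 8 parameter slots per node", call. = FALSE)
  full <- matrix(0, nc, 8L)
  full[, seq_len(ncol(params))] <- params
  f <- mesh$fields[[field]]
  if (is.null(f)) f <- list(components = nc, params = list())
  if (f$components != nc)
    stop(sprintf("field '%s' has %d components, params have %d rows", field, f$components, nc), call. = FALSE)
  key <- as.character(as.integer(node))
  vers <- f$params[[key]]
  if (is.null(vers)) vers <- list()
  if (version > length(vers) + 1L)
    stop("derivative versions must be added consecutively", call. = FALSE)
  vers[[version]] <- full
  f$params[[key]] <- vers
  mesh$fields[[field]] <- f
  mesh$node_ids <- union(mesh$node_ids, as.integer(node))
  mesh
}

#' Get nodal parameters of a field at one node
#' @inheritParams set_node_params
#' @return components x 8 numeric matrix.
#' @export
get_node_params <- function(mesh, field, node, version = 1L) {
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("unknown field '%s'", field), call. = FALSE)
  vers <- f$params[[as.character(as.integer(node))]]
  if (is.null(vers) || version > length(vers))
    stop(sprintf("field '%s' has no version %d at node %d", field, version, node), call. = FALSE)
  vers[[version]]
}

#' Names of the fields stored on a mesh
#' @param mesh a `hermite_mesh`.
#' @return character vector.
#' @export
mesh_fields <- function(mesh) names(mesh$fields)

#' Material point
#'
#' The species-independent address of a tissue particle: an element id plus
#' local coordinates \eqn{\xi \in [0,1]^d}. The same material point refers to
#' the same particle in every configuration (field) of the scaffold.
#'
#' @param element integer element id.
#' @param xi numeric local coordinates, each in [0,1].
#' @return an object of class `material_point`.
#' @export
material_point <- function(element, xi) {
  xi <- as.numeric(xi)
  if (any(!is.finite(xi)) || any(xi < -1e-9) || any(xi > 1 + 1e-9))
    stop("material coordinates must lie in [0,1]", call. = FALSE)
  structure(list(element = as.integer(element), xi = pmin(pmax(xi, 0), 1)),
    class = "material_point")
}

#' @export
print.material_point <- function(x, ...) {
  cat(sprintf("<material_point: element %d, xi = (%s)>\n", x$element,
    paste(formatC(x$xi, digits = 4, format = "fg"), collapse = ", ")))
  invisible(x)
}

#' Add an annotation group
#'
#' Annotation groups attach standard anatomical terms (with ontology CURIEs,
#' e.g. `"UBERON:0000948"`) to subsets of elements and/or nodes, either as a
#' `region` or as a `landmark`.
#'
#' @param mesh a `hermite_mesh`.
#' @param term anatomical name (non-empty string).
#' @param ontology_id CURIE of the form `PREFIX:identifier`, or `""` (a
#'   warning is recorded in the group).
#' @param elements,nodes integer id vectors (either may be empty).
#' @param kind `"region"` or `"landmark"`.
#' @return the modified mesh.
#' @export
add_annotation <- function(mesh, term, ontology_id = "", elements = integer(0),
                           nodes = integer(0), kind = c("region", "landmark")) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  kind <- match.arg(kind)
  if (!nzchar(term)) stop("annotation term must be non-empty", call. = FALSE)
  warn <- character(0)
  if (!nzchar(ontology_id)) {
    warn <- sprintf("no ontology id recorded for term '%s'", term)
  } else if (!grepl("^[A-Za-z][A-Za-z0-9_.]*:\\S+$", ontology_id)) {
    stop(sprintf("ontology id '%s' is not a PREFIX:identifier CURIE", ontology_id), call. = FALSE)
  }
  bad_e <- setdiff(as.integer(elements), vapply(mesh$elements, `[[`, 0L, "id"))
  if (length(bad_e)) stop(sprintf("annotation '%s' references unknown elements: %s",
    term, paste(bad_e, collapse = ", ")), call. = FALSE)
  bad_n <- setdiff(as.integer(nodes), mesh$node_ids)
  if (length(bad_n)) stop(sprintf("annotation '%s' references unknown nodes: %s",
    term, paste(bad_n, collapse = ", ")), call. = FALSE)
  mesh$annotations[[length(mesh$annotations) + 1L]] <- list(
    term = term, ontology_id = ontology_id,
    elements = sort(as.integer(elements)), nodes = sort(as.integer(nodes)),
    kind = kind, warnings = warn)
  mesh
}

#' Terms of all annotation groups
#' @param mesh a `hermite_mesh`.
#' @return character vector of terms (one per group, in insertion order).
#' @export
annotation_terms <- function(mesh) vapply(mesh$annotations, `[[`, "", "term")

#' Look up an annotation group by term
#' @param mesh a `hermite_mesh`.
#' @param term exact anatomical term.
#' @return the group (list with term, ontology_id, elements, nodes, kind) or
#'   `NULL` if absent.
#' @export
get_annotation <- function(mesh, term) {
  hit <- which(annotation_terms(mesh) == term)
  if (!length(hit)) return(NULL)
  mesh$annotations[[hit[1L]]]
}

#' Axis-aligned bounding box of a coordinate field
#'
#' Computed over nodal value parameters of all versions.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field name.
#' @return a 2 x components matrix with rows `min` and `max`.
#' @export
mesh_bbox <- function(mesh, field = "reference") {
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("unknown field '%s'", field), call. = FALSE)
  vals <- do.call(cbind, lapply(f$params, function(vers)
    do.call(cbind, lapply(vers, function(m) m[, 1L, drop = FALSE]))))
  out <- rbind(min = apply(vals, 1, min), max = apply(vals, 1, max))
  colnames(out) <- paste0("x", seq_len(ncol(out)))
  out
}

# diagonal length of the bounding box
.bbox_diag <- function(mesh, field = "reference") {
  bb <- mesh_bbox(mesh, field)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

#' Validate a scaffold mesh
#'
#' Checks structural invariants: element corner counts, existence of all
#' referenced nodes/versions on every field defined over an element, and
#' (for 3-D elements, optionally) positivity of the reference-field Jacobian
#' determinant at all Gauss quadrature points.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field checked for Jacobian positivity, or `NULL`
#'   to skip the geometric check.
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_mesh <- function(mesh, field = "reference") {
  stopifnot(inherits(mesh, "hermite_mesh"))
  for (el in mesh$elements) {
    if (length(el$nodes) != 2^el$dim)
      stop(sprintf("element %d: expected %d corner nodes", el$id, 2^el$dim), call. = FALSE)
    for (fname in names(mesh$fields)) {
      f <- mesh$fields[[fname]]
      for (j in seq_along(el$nodes)) {
        vers <- f$params[[as.character(el$nodes[j])]]
        if (is.null(vers))
          stop(sprintf("field '%s' undefined at node %d (element %d)", fname, el$nodes[j], el$id), call. = FALSE)
        if (el$versions[j] > length(vers))
          stop(sprintf("element %d selects version %d of node %d on field '%s'; only %d exist",
            el$id, el$versions[j], el$nodes[j], fname, length(vers)), call. = FALSE)
      }
    }
  }
  if (!is.null(field) && !is.null(mesh$fields[[field]])) {
    g <- .gauss3()
    for (el in mesh$elements) {
      if (el$dim != 3L) next
      P <- .element_params(mesh, field, el)
      for (q in seq_len(nrow(g$xi3))) {
        J <- .jacobian_at(P, g$xi3[q, ])
        if (det(J) <= 0)
          stop(sprintf("element %d: non-positive Jacobian (det %.3g) at quadrature point", el$id, det(J)), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# 3-point Gauss-Legendre rule on [0,1], plus tensor grids
.gauss3 <- function() {
  a <- sqrt(3 / 5) / 2
  pts <- c(0.5 - a, 0.5, 0.5 + a)
  wts <- c(5, 8, 5) / 18
  xi3 <- as.matrix(expand.grid(pts, pts, pts))
  w3 <- apply(as.matrix(expand.grid(wts, wts, wts)), 1, prod)
  xi2 <- as.matrix(expand.grid(pts, pts))
  w2 <- apply(as.matrix(expand.grid(wts, wts)), 1, prod)
  dimnames(xi3) <- dimnames(xi2) <- NULL
  list(pts = pts, wts = wts, xi3 = xi3, w3 = w3, xi2 = xi2, w2 = w2)
}
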
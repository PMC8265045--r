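# Readers and writers: annotated segmentation XML, the native mesh format,
# VTK export, and embedded-point CSV tables.
#
# The segmentation dialect is a declared subset of the neuromorphology-style
# XML used by common segmentation tools: a root element with a `units`
# attribute ("um" by default, as in microscopy; "mm" accepted), `contour`
# elements with `name`/`ontologyId` attributes and `point` children
# (x, y, z, d attributes), and `marker` elements likewise. Coordinates are
# normalized to mm on load.

#' Contour dataset
#'
#' Annotated contour polylines and marker points from a segmentation file
#' (physical coordinates in mm, anatomical terms, ontology CURIEs).
#'
#' @param contours list of `list(name, ontology_id, closed, points)` with
#'   `points` an n x 3 matrix (n >= 2).
#' @param markers list of `list(label, term, ontology_id, point)`.
#' @param metadata list (source file, units, ...).
#' @return an object of class `contour_dataset`.
#' @export
contour_dataset <- function(contours = list(), markers = list(), metadata = list()) {
  for (ct in contours) {
    if (is.null(ct$points) || nrow(ct$points) < 2L)
      stop(sprintf("contour '%s' has fewer than 2 points", ct$name %||% "?"), call. = FALSE)
  }
  if (!length(contours) && !length(markers)) stop("empty dataset: no contours and no markers", call. = FALSE)
  structure(list(contours = contours, markers = markers, metadata = metadata),
    class = "contour_dataset")
}

#' @export
print.contour_dataset <- function(x, ...) {
  np <- sum(vapply(x$contours, function(ct) nrow(ct$points), 0L))
  cat(sprintf("<contour_dataset: %d contours (%d points), %d markers>\n",
    length(x$contours), np, length(x$markers)))
  invisible(x)
}

#' Flatten a contour dataset to a point table
#' @param data a `contour_dataset`.
#' @return data frame with x, y, z, term, kind, source index.
#' @export
dataset_points <- function(data) {
  stopifnot(inherits(data, "contour_dataset"))
  out <- list()
  for (i in seq_along(data$contours)) {
    ct <- data$contours[[i]]
    out[[length(out) + 1L]] <- data.frame(x = ct$points[, 1], y = ct$points[, 2],
      z = ct$points[, 3], term = ct$name, kind = "contour", source = i)
  }
  for (i in seq_along(data$markers)) {
    mk <- data$markers[[i]]
    out[[length(out) + 1L]] <- data.frame(x = mk$point[1], y = mk$point[2],
      z = mk$point[3], term = mk$term %||% "", kind = "marker", source = i)
  }
  if (!length(out)) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
    term = character(0), kind = character(0), source = integer(0)))
  do.call(rbind, out)
}

#' Read a segmentation XML file
#'
#' Parses the documented segmentation dialect: named, ontology-annotated
#' contours and markers. Unknown child elements are skipped with a warning;
#' a missing ontology id yields an empty id and a warning; coordinates in
#' µm (the default) are converted to mm.
#'
#' @param path file path.
#' @return a `contour_dataset`.
#' @export
read_segmentation_xml <- function(path) {
  doc <- xml2::read_xml(path)  # malformed XML raises an error with location
  units <- xml2::xml_attr(doc, "units")
  if (is.na(units)) units <- "um"
  scale <- switch(units, um = 1e-3, mm = 1,
    stop(sprintf("unknown units '%s' (expected um or mm)", units), call. = FALSE))
  contours <- list(); markers <- list(); skipped <- 0L
  read_points <- function(node) {
    pts <- xml2::xml_find_all(node, "./point")
    m <- matrix(0, length(pts), 3)
    if (length(pts)) {
      m[, 1] <- as.numeric(xml2::xml_attr(pts, "x"))
      m[, 2] <- as.numeric(xml2::xml_attr(pts, "y"))
      m[, 3] <- as.numeric(xml2::xml_attr(pts, "z"))
    }
    m * scale
  }
  get_curie <- function(node, what) {
    oid <- xml2::xml_attr(node, "ontologyId")
    if (is.na(oid) || !nzchar(oid)) {
      warning(sprintf("%s '%s' has no ontology id", what,
        xml2::xml_attr(node, "name")), call. = FALSE)
      oid <- ""
    }
    oid
  }
  for (child in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(child)
    if (tag == "contour") {
      pts <- read_points(child)
      if (nrow(pts) < 2L) {
        warning(sprintf("skipping contour '%s': fewer than 2 points",
          xml2::xml_attr(child, "name")), call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      closed <- identical(tolower(xml2::xml_attr(child, "closed")), "true")
      contours[[length(contours) + 1L]] <- list(
        name = xml2::xml_attr(child, "name") %|NA|% "",
        ontology_id = get_curie(child, "contour"), closed = closed, points = pts)
    } else if (tag == "marker") {
      pts <- read_points(child)
      if (!nrow(pts)) { warning("skipping marker without a point", call. = FALSE); skipped <- skipped + 1L; next }
      markers[[length(markers) + 1L]] <- list(
        label = xml2::xml_attr(child, "name") %|NA|% "",
        term = xml2::xml_attr(child, "term") %|NA|% (xml2::xml_attr(child, "name") %|NA|% ""),
        ontology_id = get_curie(child, "marker"), point = pts[1, ])
    } else {
      warning(sprintf("ignoring unknown element <%s>", tag), call. = FALSE)
      skipped <- skipped + 1L
    }
  }
  contour_dataset(contours, markers,
    metadata = list(source = path, units = units, skipped = skipped))
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

#' Write a contour dataset as segmentation XML
#' @param data a `contour_dataset`.
#' @param path output path.
#' @param units `"mm"` or `"um"`.
#' @return invisibly `path`.
#' @export
write_segmentation_xml <- function(data, path, units = "mm") {
  stopifnot(inherits(data, "contour_dataset"))
  scale <- switch(units, mm = 1, um = 1e3, stop("units must be mm or um", call. = FALSE))
  doc <- xml2::xml_new_root("segmentation", units = units)
  for (ct in data$contours) {
    nd <- xml2::xml_add_child(doc, "contour", name = ct$name,
      ontologyId = ct$ontology_id %||% "", closed = tolower(as.character(isTRUE(ct$closed))))
    for (r in seq_len(nrow(ct$points)))
      xml2::xml_add_child(nd, "point",
        x = format(ct$points[r, 1] * scale, digits = 17),
        y = format(ct$points[r, 2] * scale, digits = 17),
        z = format(ct$points[r, 3] * scale, digits = 17), d = "1")
  }
  for (mk in data$markers) {
    nd <- xml2::xml_add_child(doc, "marker", name = mk$label,
      term = mk$term %||% "", ontologyId = mk$ontology_id %||% "")
    xml2::xml_add_child(nd, "point",
      x = format(mk$point[1] * scale, digits = 17),
      y = format(mk$point[2] * scale, digits = 17),
      z = format(mk$point[3] * scale, digits = 17), d = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- native mesh format ---------------------------------------------------

.MESH_FORMAT <- "anatscaffold-mesh"
.MESH_VERSION <- 1L

# canonical JSON emitter: fixed key order as supplied, %.17g numbers (exact
# double round trip), no whitespace variation -> identical meshes serialize
# byte-identically.
.json_emit <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) {
      inner <- vapply(seq_along(x), function(i)
        paste0(.json_str(names(x)[i]), ":", .json_emit(x[[i]])), "")
      return(paste0("{", paste(inner, collapse = ","), "}"))
    }
    return(paste0("[", paste(vapply(x, .json_emit, ""), collapse = ","), "]"))
  }
  if (is.character(x)) {
    if (length(x) == 1L) return(.json_str(x))
    return(paste0("[", paste(vapply(x, .json_str, ""), collapse = ","), "]"))
  }
  if (is.logical(x)) {
    s <- ifelse(x, "true", "false")
    if (length(x) == 1L) return(s)
    return(paste0("[", paste(s, collapse = ","), "]"))
  }
  if (is.numeric(x)) {
    s <- vapply(x, function(v) {
      if (is.na(v)) "null"
      else if (is.integer(x) || (is.finite(v) && v == round(v) && abs(v) < 2^31)) sprintf("%d", as.integer(v))
      else sprintf("%.17g", v)
    }, "")
    if (length(x) == 1L) return(s)
    return(paste0("[", paste(s, collapse = ","), "]"))
  }
  stop("cannot serialize object of class ", paste(class(x), collapse = "/"), call. = FALSE)
}

.json_str <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  s <- gsub("\n", "\\\\n", s)
  paste0('"', s, '"')
}

.content_checksum <- function(txt) {
  b <- utf8ToInt(txt)
  as.integer(sum(b * rep_len(c(1, 3, 5, 7, 11, 13, 17, 19), length(b))) %% 2147483647)
}

#' Write a mesh in the native format
#'
#' A versioned, text-based (JSON) format with canonical key ordering:
#' identical meshes serialize byte-identically, and numeric values round
#' trip exactly.
#'
#' @param mesh a `hermite_mesh`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  elems <- mesh$elements[order(vapply(mesh$elements, `[[`, 0L, "id"))]
  body <- list(
    format = .MESH_FORMAT,
    version = .MESH_VERSION,
    units = mesh$metadata$units %||% "mm",
    nodes = sort(mesh$node_ids),
    elements = lapply(unname(elems), function(el)
      list(id = el$id, dim = el$dim, nodes = el$nodes, versions = el$versions)),
    fields = {
      fl <- list()
      for (fn in sort(names(mesh$fields))) {
        f <- mesh$fields[[fn]]
        keys <- names(f$params)[order(as.integer(names(f$params)))]
        pl <- list()
        for (k in keys) pl[[k]] <- lapply(f$params[[k]], function(m)
          lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ])))
        fl[[fn]] <- list(components = f$components, params = pl)
      }
      fl
    },
    annotations = lapply(mesh$annotations, function(g)
      list(term = g$term, ontology_id = g$ontology_id, elements = g$elements,
        nodes = g$nodes, kind = g$kind)),
    metadata = .serialize_metadata(mesh$metadata)
  )
  txt <- .json_emit(body)
  out <- paste0('{"checksum":', .content_checksum(txt), ',"mesh":', txt, "}")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

.serialize_metadata <- function(md) {
  out <- list()
  for (k in setdiff(names(md), "blocks")) {
    v <- md[[k]]
    if (is.character(v) || is.numeric(v) || is.logical(v)) out[[k]] <- v
  }
  if (!is.null(md$blocks)) {
    out$blocks <- lapply(md$blocks, function(b) {
      bl <- list(dims = dim(b$elems), elems = as.integer(b$elems),
        wrap_u = isTRUE(b$wrap_u), n_around = b$n_around,
        n_segments = b$n_segments, n_layers = b$n_layers)
      bl
    })
  }
  out
}

#' Read a mesh in the native format
#' @param path file path.
#' @return a `hermite_mesh`.
#' @export
read_mesh <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  top <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  j <- top$mesh
  if (!identical(j$format, .MESH_FORMAT))
    stop(sprintf("not a %s file", .MESH_FORMAT), call. = FALSE)
  if (!identical(as.integer(j$version), .MESH_VERSION))
    stop(sprintf("mesh format version %s is not supported (this build reads version %d)",
      j$version, .MESH_VERSION), call. = FALSE)
  inner <- .json_emit(.relist_mesh_body(j))
  if (!is.null(top$checksum) && .content_checksum(inner) != as.integer(top$checksum))
    warning("mesh file checksum mismatch: content may be corrupted", call. = FALSE)
  mesh <- hermite_mesh(units = j$units %||% "mm")
  for (el in j$elements)
    mesh <- add_element(mesh, el$id, el$dim, as.integer(unlist(el$nodes)),
      as.integer(unlist(el$versions)))
  for (fn in names(j$fields)) {
    f <- j$fields[[fn]]
    for (k in names(f$params)) {
      vers <- f$params[[k]]
      for (v in seq_along(vers)) {
        m <- do.call(rbind, lapply(vers[[v]], function(r) as.numeric(unlist(r))))
        mesh <- set_node_params(mesh, fn, as.integer(k), m, v)
      }
    }
  }
  for (g in j$annotations)
    mesh <- add_annotation(mesh, g$term, g$ontology_id %||% "",
      as.integer(unlist(g$elements)), as.integer(unlist(g$nodes)), g$kind)
  for (k in setdiff(names(j$metadata), c("units", "blocks")))
    mesh$metadata[[k]] <- {
      v <- j$metadata[[k]]
      if (is.list(v)) unlist(v) else v
    }
  if (!is.null(j$metadata$blocks)) {
    mesh$metadata$blocks <- lapply(j$metadata$blocks, function(b)
      list(elems = array(as.integer(unlist(b$elems)), as.integer(unlist(b$dims))),
        wrap_u = isTRUE(b$wrap_u), n_around = b$n_around,
        n_segments = b$n_segments, n_layers = b$n_layers))
  }
  mesh
}

# rebuild the canonical body from parsed JSON so the checksum can be
# recomputed independently of file whitespace
.relist_mesh_body <- function(j) {
  list(format = j$format, version = as.integer(j$version), units = j$units,
    nodes = as.integer(unlist(j$nodes)),
    elements = lapply(j$elements, function(el)
      list(id = as.integer(el$id), dim = as.integer(el$dim),
        nodes = as.integer(unlist(el$nodes)), versions = as.integer(unlist(el$versions)))),
    fields = {
      fl <- list()
      for (fn in names(j$fields)) {
        f <- j$fields[[fn]]
        pl <- list()
        for (k in names(f$params)) pl[[k]] <- lapply(f$params[[k]], function(vers)
          lapply(vers, function(r) as.numeric(unlist(r))))
        fl[[fn]] <- list(components = as.integer(f$components), params = pl)
      }
      fl
    },
    annotations = lapply(j$annotations, function(g)
      list(term = g$term, ontology_id = g$ontology_id, elements = as.integer(unlist(g$elements)),
        nodes = as.integer(unlist(g$nodes)), kind = g$kind)),
    metadata = {
      md <- j$metadata
      for (k in names(md)) if (k != "blocks") {
        v <- md[[k]]
        md[[k]] <- if (is.list(v)) unlist(v) else v
      }
      if (!is.null(md$blocks)) md$blocks <- lapply(md$blocks, function(b)
        list(dims = as.integer(unlist(b$dims)), elems = as.integer(unlist(b$elems)),
          wrap_u = isTRUE(b$wrap_u), n_around = as.integer(b$n_around),
          n_segments = as.integer(b$n_segments), n_layers = as.integer(b$n_layers)))
      md
    })
}

# ---- VTK export -----------------------------------------------------------

#' Export a mesh to a legacy VTK unstructured grid
#'
#' Each Hermite element is subdivided into `refine^d` linear cells
#' (hexahedra for 3-D elements, quads for 2-D) whose vertices are sampled
#' from the Hermite interpolation at \eqn{\xi} multiples of `1/refine`.
#' Annotation element groups are exported as 0/1 integer cell-data arrays.
#'
#' @param mesh a `hermite_mesh`.
#' @param field coordinate field to export.
#' @param path output `.vtk` path.
#' @param refine linear subdivisions per element direction (>= 1).
#' @return invisibly `path`.
#' @export
export_vtk <- function(mesh, field = "reference", path, refine = 1L) {
  refine <- as.integer(refine)
  if (refine < 1L) stop("refine must be >= 1", call. = FALSE)
  pts <- list(); cells <- list(); types <- integer(0); cell_elem <- integer(0)
  offset <- 0L
  for (el in mesh$elements) {
    d <- el$dim
    if (d < 2L) next
    P <- .element_params(mesh, field, el)
    n1 <- refine + 1L
    grid <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = n1)), d)))
    xis <- t(grid)
    W <- .tensor_weights_batch(xis)
    pos <- t(P %*% W)
    pts[[length(pts) + 1L]] <- pos
    gi <- function(i, j, k = 1L) (i - 1L) + n1 * ((j - 1L) + if (d == 3L) n1 * (k - 1L) else 0L) + offset
    idx <- as.matrix(expand.grid(lapply(seq_len(d), function(x) seq_len(refine))))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (d == 3L) {
        k <- idx[r, 3]
        corners <- c(gi(i, j, k), gi(i + 1L, j, k), gi(i + 1L, j + 1L, k), gi(i, j + 1L, k),
                     gi(i, j, k + 1L), gi(i + 1L, j, k + 1L), gi(i + 1L, j + 1L, k + 1L), gi(i, j + 1L, k + 1L))
        types <- c(types, 12L)
      } else {
        corners <- c(gi(i, j), gi(i + 1L, j), gi(i + 1L, j + 1L), gi(i, j + 1L))
        types <- c(types, 9L)
      }
      cells[[length(cells) + 1L]] <- corners
      cell_elem <- c(cell_elem, el$id)
    }
    offset <- offset + nrow(pos)
  }
  pts <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
    "anatomical scaffold export", "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(apply(pts, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
  total <- sum(vapply(cells, length, 0L)) + length(cells)
  writeLines(sprintf("CELLS %d %d", length(cells), total), con)
  writeLines(vapply(cells, function(cc) paste(c(length(cc), cc), collapse = " "), ""), con)
  writeLines(sprintf("CELL_TYPES %d", length(cells)), con)
  writeLines(as.character(types), con)
  groups <- Filter(function(g) length(g$elements) > 0, mesh$annotations)
  if (length(groups)) {
    writeLines(sprintf("CELL_DATA %d", length(cells)), con)
    for (g in groups) {
      nm <- gsub("[^A-Za-z0-9]+", "_", g$term)
      writeLines(c(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(as.character(as.integer(cell_elem %in% g$elements)), con)
    }
  }
  invisible(path)
}

# ---- embedded point tables ------------------------------------------------

#' Write / read embedded-point tables
#'
#' CSV with columns label, term, ontology_id, element, xi1..xi3, residual,
#' off_mesh.
#'
#' @param embedded data frame from [embed_points()].
#' @param path file path.
#' @return invisibly `path` (writer); the data frame (reader).
#' @export
write_cells_csv <- function(embedded, path) {
  df <- embedded
  if (is.null(df$ontology_id)) df$ontology_id <- ""
  cols <- c("label", "term", "ontology_id", "element", "xi1", "xi2", "xi3",
    "residual", "off_mesh")
  for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
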
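# Mesh refinement: split every element into a grid of child elements whose
# nodal parameters are sampled from the parent interpolation, so the
# geometry (any field) is unchanged at every former material location.
# Child nodes on shared parent faces are identified topologically (by the
# multilinear weights of the parent corner nodes at that location), so
# conforming parents yield conforming children; if two parents disagree on
# derivatives at a shared location (a C0-only mesh), the disagreeing
# parameters become additional derivative versions instead of being
# averaged away.

#' Refine a scaffold mesh
#'
#' @param mesh a `hermite_mesh`.
#' @param factors integer refinement factors per local direction (recycled
#'   or truncated to each element's dimension); each >= 1.
#' @return the refined `hermite_mesh` (all fields resampled, annotation
#'   groups propagated: element groups to the children of their members,
#'   node groups to the coincident child nodes).
#' @export
refine_mesh <- function(mesh, factors = c(2L, 2L, 2L)) {
  factors <- as.integer(factors)
  if (any(factors < 1L) || !length(factors) %in% 1:3)
    stop("refinement factors must be integers >= 1 (one per direction)", call. = FALSE)
  if (length(factors) < 3L) factors <- rep_len(factors, 3L)
  fields <- names(mesh$fields)
  out <- hermite_mesh(units = mesh$metadata$units)
  registry <- new.env(parent = emptyenv())   # key -> node id
  stored <- new.env(parent = emptyenv())     # id  -> list(field -> list of versions)
  next_node <- 0L; next_elem <- 0L
  parent_node_map <- integer(0)              # parent node id -> child node id
  elem_children <- list()                    # parent elem id chr -> child ids

  point_key <- function(el, t) {
    d <- length(t)
    bits <- .hermite_bits[[d]]
    wts <- rep(1, nrow(bits))
    for (i in seq_len(d)) wts <- wts * ifelse(bits[, i] == 1L, t[i], 1 - t[i])
    keep <- wts > 1e-13
    ids <- el$nodes[keep]; wts <- wts[keep]
    agg <- tapply(wts, ids, sum)
    ids <- as.integer(names(agg)); wts <- as.numeric(agg)
    o <- order(ids)
    paste(paste(ids[o], collapse = "_"), paste(sprintf("%.12f", wts[o]), collapse = "_"), sep = "|")
  }

  for (ekey in names(mesh$elements)) {
    el <- mesh$elements[[ekey]]
    d <- el$dim
    f <- factors[seq_len(d)]
    ns <- 2L^d
    Pf <- lapply(fields, function(fn) .element_params(mesh, fn, el))
    names(Pf) <- fields
    sbits <- .hermite_bits[[d]]
    # parameters of a child node at parent-local t, scaled to child xi units
    child_params <- function(t) {
      lapply(Pf, function(P) {
        m <- matrix(0, nrow(P), 8L)
        for (s in seq_len(ns)) {
          dv <- sbits[s, ]
          scl <- prod(ifelse(dv == 1L, 1 / f, 1))
          m[, s] <- (P %*% .tensor_weights_flat(t, dv)) * scl
        }
        m
      })
    }
    node_at <- function(t) {
      key <- point_key(el, t)
      pars <- child_params(t)
      id <- registry[[key]]
      if (is.null(id)) {
        next_node <<- next_node + 1L
        id <- next_node
        registry[[key]] <- id
        stored[[as.character(id)]] <- lapply(pars, function(m) list(m))
        return(c(id, 1L))
      }
      vers <- stored[[as.character(id)]]
      nv <- length(vers[[1]])
      for (v in seq_len(nv)) {
        same <- all(vapply(fields, function(fn) {
          a <- vers[[fn]][[v]]; b <- pars[[fn]]
          max(abs(a - b)) <= 1e-9 * (1 + max(abs(a)))
        }, TRUE))
        if (same) return(c(id, v))
      }
      for (fn in fields) vers[[fn]][[nv + 1L]] <- pars[[fn]]
      stored[[as.character(id)]] <- vers
      c(id, nv + 1L)
    }
    # child elements
    grid <- as.matrix(expand.grid(lapply(seq_len(d), function(i) 0:(f[i] - 1))))
    kids <- integer(0)
    for (r in seq_len(nrow(grid))) {
      base <- as.numeric(grid[r, ])
      nodes <- integer(ns); versions <- integer(ns)
      for (cb in seq_len(ns)) {
        t <- (base + sbits[cb, ]) / f
        nv <- node_at(t)
        nodes[cb] <- nv[1]; versions[cb] <- nv[2]
      }
      next_elem <- next_elem + 1L
      out <- add_element(out, next_elem, d, nodes, versions)
      kids <- c(kids, next_elem)
    }
    elem_children[[ekey]] <- kids
    # remember where the parent corners went (for node-group propagation)
    for (cb in seq_len(ns)) {
      t <- as.numeric(sbits[cb, ])
      key <- point_key(el, t)
      parent_node_map[as.character(el$nodes[cb])] <- registry[[key]]
    }
  }
  for (id_chr in ls(stored)) {
    vers <- stored[[id_chr]]
    for (fn in fields) for (v in seq_along(vers[[fn]]))
      out <- set_node_params(out, fn, as.integer(id_chr), vers[[fn]][[v]], v)
  }
  for (g in mesh$annotations) {
    ch_elems <- if (length(g$elements))
      as.integer(unlist(elem_children[as.character(g$elements)])) else integer(0)
    ch_nodes <- if (length(g$nodes))
      as.integer(parent_node_map[as.character(g$nodes)]) else integer(0)
    ch_nodes <- ch_nodes[!is.na(ch_nodes)]
    out <- add_annotation(out, g$term, g$ontology_id, ch_elems, ch_nodes, g$kind)
  }
  out$metadata <- mesh$metadata
  out$metadata$blocks <- NULL  # block grids do not survive refinement
  out$metadata$refined_by <- factors
  out
}
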
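#' Atom-group tracking across reactant pairs
#'
#' The conserved atom groups of a reactant pair are computed in the
#' adjacency-matrix formulation used by Ullmann-style sub-graph matching.
#' With `MA`, `MB` the substrate and product adjacency matrices and `M`
#' the 0/1 atom-mapping matrix, the candidate mapped-edge matrix is
#'
#'   `MC = M (M MB)'`
#'
#' read over Boolean semantics: `MC[u, v] = 1` iff the images of substrate
#' atoms `u` and `v` are adjacent in the product. A substrate bond `(u, v)`
#' is a *correct mapped edge* when additionally `MA[u, v] = 1` and both
#' endpoints are mapped; the connected components of these conserved bonds
#' are the atom groups transferred from substrate to product.
#'
#' @name atom-tracking
NULL

#' Candidate mapped-edge matrix
#'
#' Computes `MC = M (M MB)'` over Boolean semantics (any entry >= 1 becomes
#' 1). `MC[u, v] = 1` iff substrate atoms `u` and `v` both map to atoms
#' that are adjacent in the product graph.
#'
#' @param MA substrate adjacency matrix (square, symmetric 0/1)
#' @param MB product adjacency matrix
#' @param M 0/1 mapping matrix, `M[x, y] = 1` iff substrate atom `x` maps
#'   to product atom `y`; rows must contain at most one 1
#' @return square 0/1 integer matrix with `MA`'s dimensions
#' @export
candidate_edge_matrix <- function(MA, MB, M) {
  if (nrow(MA) != ncol(MA) || nrow(MB) != ncol(MB)) {
    stop("adjacency matrices must be square", call. = FALSE)
  }
  if (nrow(M) != nrow(MA) || ncol(M) != nrow(MB)) {
    stop("mapping matrix dimensions do not conform: expected ",
         nrow(MA), " x ", nrow(MB), call. = FALSE)
  }
  mc <- M %*% t(M %*% MB)
  mc <- (mc >= 1) * 1L
  storage.mode(mc) <- "integer"
  mc
}

mapping_matrix <- function(mapping, n_sub, n_prod) {
  m <- matrix(0L, n_sub, n_prod)
  if (nrow(mapping) > 0L) m[mapping + 1L] <- 1L
  m
}

#' Conserved substrate bonds of a reactant pair
#'
#' Returns exactly the substrate bonds whose two endpoints are mapped and
#' whose image atoms form a bond of the product — the correct mapped
#' edges. The direction of traversal matters: pass the inverted mapping
#' (and swapped graphs) for a pair traversed product-to-substrate.
#'
#' @param substrate,product `molecular_graph` objects
#' @param mapping 2-column matrix of (substrate index, product index)
#' @return 2-column matrix of conserved substrate bonds, canonical order
#' @export
conserved_bonds <- function(substrate, product, mapping) {
  ba <- substrate$bonds
  if (nrow(ba) == 0L || nrow(mapping) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  MA <- adjacency_matrix(substrate)
  MB <- adjacency_matrix(product)
  M <- mapping_matrix(mapping, n_atoms(substrate), n_atoms(product))
  MC <- candidate_edge_matrix(MA, MB, M)
  keep <- MA[ba + 1L] == 1L & MC[ba + 1L] == 1L
  canonical_bonds(ba[keep, , drop = FALSE])
}

#' Conserved atom groups of a reactant pair
#'
#' Connected components of the conserved-bond sub-graph of the substrate,
#' each with at least one bond. Isolated mapped atoms with no conserved
#' incident bond do not form groups: the minimal atom group is one covalent
#' bond with its two atoms.
#'
#' @param net a [metabolic_network()]
#' @param pair a [reactant_pair()] whose compounds exist in `net`
#' @return list of [atom_group()] in the substrate, ordered by smallest
#'   atom index
#' @export
conserved_atom_groups <- function(net, pair) {
  s <- net$compounds[[pair$substrate]]
  p <- net$compounds[[pair$product]]
  if (is.null(s) || is.null(p)) {
    stop("reactant pair references unknown compound", call. = FALSE)
  }
  bond_components(pair$substrate, conserved_bonds(s, p, pair$mapping))
}

#' Propagate source atom groups along a reaction path
#'
#' Tracks which source bonds survive every step of a directed path, under
#' composed atom mappings with the bond-conservation test re-applied at
#' each step. A source bond survives step `i` iff its current image is a
#' conserved bond of that step's reactant pair; its image is then advanced
#' through the step's mapping.
#'
#' @param net a [metabolic_network()]
#' @param edges ordered list of directed edges (as produced by
#'   [directed_edges()]) chaining head-to-tail from the source compound
#' @param source source compound id (start of the chain); for a zero-length
#'   path the result is the source's own bond components
#' @return list with one entry per path position: `list(compound_id, bonds,
#'   groups)` where `bonds` is the matrix of images, in that compound, of
#'   the surviving source bonds and `groups` their connected components
#' @export
propagate_along_path <- function(net, edges, source) {
  src <- net$compounds[[source]]
  if (is.null(src)) stop("unknown source compound '", source, "'", call. = FALSE)
  cur_id <- source
  # images: per surviving source bond, its current endpoints (2-col matrix)
  images <- src$bonds
  out <- list(list(compound_id = cur_id, bonds = canonical_bonds(images),
                   groups = bond_components(cur_id, images)))
  for (e in edges) {
    if (!identical(e$from, cur_id)) {
      stop("broken chain: edge starts at '", e$from, "' but path is at '",
           cur_id, "'", call. = FALSE)
    }
    sub <- net$compounds[[e$from]]
    prod <- net$compounds[[e$to]]
    step_keys <- bond_keys(conserved_bonds(sub, prod, e$mapping))
    if (nrow(images) > 0L) {
      surv <- bond_keys(canonical_bonds(images)) %in% step_keys
      # canonical_bonds may reorder; keep images canonical throughout
      images <- canonical_bonds(images)[surv, , drop = FALSE]
    }
    if (nrow(images) > 0L) {
      map_to <- function(idx) e$mapping[match(idx, e$mapping[, 1L]), 2L]
      images <- cbind(map_to(images[, 1L]), map_to(images[, 2L]))
      images <- canonical_bonds(images)
    }
    cur_id <- e$to
    out[[length(out) + 1L]] <-
      list(compound_id = cur_id, bonds = images,
           groups = bond_components(cur_id, images))
  }
  out
}
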
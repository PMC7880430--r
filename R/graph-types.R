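#' Molecular graphs, atom groups and reactant pairs
#'
#' A compound is modelled as a labelled graph: atoms are nodes carrying a
#' chemical element symbol, covalent bonds are untyped undirected edges.
#' Atom indices are 0-based and contiguous, matching the network JSON
#' dialect. Hydrogens are not represented; atom-mapped reactant-pair data
#' of the kind emulated here is heavy-atom based.
#'
#' @name graph-types
NULL

#' Canonicalize a bond matrix
#'
#' Bonds are stored as a 2-column integer matrix of 0-based atom indices
#' with `u < v` per row, rows sorted lexicographically and duplicates
#' removed. A `NULL` or zero-row input yields a 0-row matrix.
#'
#' @param bonds matrix, list of pairs, or NULL
#' @return 2-column integer matrix
#' @keywords internal
canonical_bonds <- function(bonds) {
  if (is.null(bonds) || (is.list(bonds) && length(bonds) == 0L)) {
    return(matrix(integer(0), ncol = 2L))
  }
  if (is.list(bonds)) bonds <- do.call(rbind, lapply(bonds, as.integer))
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) == 0L) return(bonds)
  u <- pmin(bonds[, 1L], bonds[, 2L])
  v <- pmax(bonds[, 1L], bonds[, 2L])
  m <- unique(cbind(u, v))
  m <- m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

bond_keys <- function(bonds) {
  if (nrow(bonds) == 0L) return(character(0))
  paste(bonds[, 1L], bonds[, 2L], sep = "-")
}

bonds_from_keys <- function(keys) {
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2L))
  parts <- strsplit(keys, "-", fixed = TRUE)
  canonical_bonds(t(vapply(parts, function(p) as.integer(p), integer(2L))))
}

#' Create a molecular graph
#'
#' @param id compound identifier (non-empty string)
#' @param elements character vector of element symbols; atom `i` (0-based)
#'   is `elements[i + 1]`
#' @param bonds bonds as a 2-column matrix or list of index pairs (0-based)
#' @return object of class `molecular_graph` with fields `id`, `elements`,
#'   `bonds`
#' @export
#' @examples
#' g <- molecular_graph("C00022", c("C", "C", "C", "O", "O"),
#'                      list(c(0, 1), c(1, 2), c(1, 3), c(1, 4)))
#' n_bonds(g)
molecular_graph <- function(id, elements, bonds = NULL) {
  g <- structure(
    list(id = as.character(id),
         elements = as.character(elements),
         bonds = canonical_bonds(bonds)),
    class = "molecular_graph")
  validate_molecular_graph(g)
  g
}

validate_molecular_graph <- function(g) {
  if (length(g$id) != 1L || is.na(g$id) || !nzchar(g$id)) {
    stop("compound id must be a non-empty string", call. = FALSE)
  }
  n <- length(g$elements)
  if (any(is.na(g$elements)) || any(!nzchar(g$elements))) {
    stop("compound '", g$id, "': element symbols must be non-empty",
         call. = FALSE)
  }
  b <- g$bonds
  if (nrow(b) > 0L) {
    if (any(b < 0L) || any(b >= n)) {
      stop("compound '", g$id, "': bond references atom index outside 0..",
           n - 1L, call. = FALSE)
    }
    if (any(b[, 1L] == b[, 2L])) {
      stop("compound '", g$id, "': self-bond not allowed", call. = FALSE)
    }
  }
  invisible(g)
}

#' Number of atoms / bonds in a molecular graph
#' @param g a `molecular_graph`
#' @return integer count
#' @export
n_atoms <- function(g) length(g$elements)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' Adjacency matrix of a molecular graph
#'
#' @param g a `molecular_graph`
#' @return symmetric 0/1 matrix with zero diagonal, one row per atom
#' @export
adjacency_matrix <- function(g) {
  n <- n_atoms(g)
  m <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0L) {
    idx <- g$bonds + 1L
    m[idx] <- 1L
    m[idx[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  m
}

#' Create an atom group
#'
#' An atom group is a connected set of covalently bonded atoms within one
#' compound; the minimal atom group is a single bond with its two atoms.
#' Bond-less "groups" (isolated mapped atoms) are not representable.
#'
#' @param compound_id owning compound identifier
#' @param bonds non-empty bond set (2-column matrix or list of pairs)
#' @return object of class `atom_group` with fields `compound_id`, `bonds`,
#'   `atoms` (sorted union of bond endpoints)
#' @export
atom_group <- function(compound_id, bonds) {
  bonds <- canonical_bonds(bonds)
  if (nrow(bonds) == 0L) {
    stop("an atom group must contain at least one bond", call. = FALSE)
  }
  atoms <- sort(unique(as.integer(bonds)))
  grp <- structure(
    list(compound_id = as.character(compound_id), bonds = bonds,
         atoms = atoms),
    class = "atom_group")
  if (!bonds_connected(bonds)) {
    stop("atom group bonds must induce a single connected component",
         call. = FALSE)
  }
  grp
}

bonds_connected <- function(bonds) {
  if (nrow(bonds) <= 1L) return(TRUE)
  verts <- as.character(sort(unique(as.integer(bonds))))
  g <- igraph::graph_from_edgelist(
    cbind(as.character(bonds[, 1L]), as.character(bonds[, 2L])),
    directed = FALSE)
  igraph::components(g)$no == 1L
}

#' Split a bond set into its connected atom groups
#'
#' Connected components of the sub-graph induced by `bonds`, each returned
#' as an [atom_group()]. Deterministic order: by smallest atom index.
#'
#' @param compound_id owning compound id
#' @param bonds 2-column matrix of bonds (possibly empty)
#' @return list of `atom_group`
#' @export
bond_components <- function(compound_id, bonds) {
  bonds <- canonical_bonds(bonds)
  if (nrow(bonds) == 0L) return(list())
  g <- igraph::graph_from_edgelist(
    cbind(as.character(bonds[, 1L]), as.character(bonds[, 2L])),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_bond <- memb[as.character(bonds[, 1L])]
  groups <- lapply(split(seq_len(nrow(bonds)), comp_of_bond), function(rows) {
    atom_group(compound_id, bonds[rows, , drop = FALSE])
  })
  min_atom <- vapply(groups, function(gr) gr$atoms[1L], integer(1L))
  groups <- groups[order(min_atom, method = "radix")]
  names(groups) <- NULL
  groups
}

#' Create a reactant pair
#'
#' A reactant pair is a substrate/product compound pair within one reaction
#' that shares atoms, annotated with a partial injective atom-to-atom
#' mapping and, optionally, the reaction Gibbs free-energy change.
#'
#' @param reaction reaction identifier
#' @param substrate,product compound identifiers
#' @param mapping 2-column matrix or list of `(substrate_index,
#'   product_index)` pairs, 0-based
#' @param dG Gibbs free-energy change of the reaction, or `NA` when unknown
#' @param reversible may the pair be traversed product-to-substrate?
#'   Defaults to `TRUE`: reactions in reactant-pair databases are typically
#'   written without a committed direction.
#' @return object of class `reactant_pair`
#' @export
reactant_pair <- function(reaction, substrate, product, mapping,
                          dG = NA_real_, reversible = TRUE) {
  if (is.list(mapping)) mapping <- do.call(rbind, lapply(mapping, as.integer))
  if (is.null(mapping)) mapping <- matrix(integer(0), ncol = 2L)
  mapping <- matrix(as.integer(mapping), ncol = 2L)
  if (nrow(mapping) > 0L) {
    mapping <- mapping[order(mapping[, 1L], method = "radix"), , drop = FALSE]
  }
  structure(
    list(reaction = as.character(reaction),
         substrate = as.character(substrate),
         product = as.character(product),
         mapping = mapping,
         dG = as.numeric(dG),
         reversible = isTRUE(reversible)),
    class = "reactant_pair")
}

#' Invert a partial injective atom mapping
#'
#' @param mapping 2-column matrix of `(from, to)` pairs
#' @return 2-column matrix of `(to, from)` pairs, sorted by first column
#' @export
invert_mapping <- function(mapping) {
  inv <- mapping[, c(2L, 1L), drop = FALSE]
  if (nrow(inv) > 0L) inv <- inv[order(inv[, 1L], method = "radix"), , drop = FALSE]
  dimnames(inv) <- NULL
  inv
}

#' Compose two partial atom mappings
#'
#' `(x -> z)` is in the result iff `m1` maps `x -> y` and `m2` maps
#' `y -> z`. The composition of injective partial maps is injective.
#'
#' @param m1 mapping from compound A to compound B (2-column matrix)
#' @param m2 mapping from compound B to compound C
#' @return mapping from A to C, sorted by first column
#' @export
compose_mappings <- function(m1, m2) {
  if (nrow(m1) == 0L || nrow(m2) == 0L) return(matrix(integer(0), ncol = 2L))
  pos <- match(m1[, 2L], m2[, 1L])
  keep <- !is.na(pos)
  out <- cbind(m1[keep, 1L], m2[pos[keep], 2L])
  out <- matrix(as.integer(out), ncol = 2L)
  if (nrow(out) > 0L) out <- out[order(out[, 1L], method = "radix"), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$id, ": ", n_atoms(x), " atoms (",
      paste(x$elements, collapse = ""), "), ", n_bonds(x), " bonds\n",
      sep = "")
  invisible(x)
}

#' @export
print.reactant_pair <- function(x, ...) {
  cat("<reactant_pair> ", x$reaction, ": ", x$substrate,
      if (x$reversible) " <-> " else " --> ", x$product, ", ",
      nrow(x$mapping), " mapped atoms",
      if (!is.na(x$dG)) paste0(", dG = ", x$dG), "\n", sep = "")
  invisible(x)
}

#' @export
print.atom_group <- function(x, ...) {
  cat("<atom_group> in ", x$compound_id, ": ", length(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}
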
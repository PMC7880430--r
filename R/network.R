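#' Metabolic networks of reactant pairs
#'
#' A metabolic network is a set of compounds (molecular graphs) connected
#' by reactant pairs. The network JSON dialect carries explicit atom lists,
#' bond lists and atom-index mappings, so no structure perception is needed.
#'
#' @name network
NULL

#' Create and validate a metabolic network
#'
#' @param compounds list of [molecular_graph()] objects
#' @param reactant_pairs list of [reactant_pair()] objects
#' @return object of class `metabolic_network` with `compounds` (named list,
#'   keyed by compound id) and `reactant_pairs`
#' @export
metabolic_network <- function(compounds, reactant_pairs = list()) {
  ids <- vapply(compounds, function(g) g$id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(compounds) <- ids
  net <- structure(list(compounds = compounds,
                        reactant_pairs = reactant_pairs),
                   class = "metabolic_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  for (g in net$compounds) validate_molecular_graph(g)
  triples <- character(length(net$reactant_pairs))
  for (i in seq_along(net$reactant_pairs)) {
    rp <- net$reactant_pairs[[i]]
    label <- paste0("reactant pair '", rp$reaction, "' (", rp$substrate,
                    " -> ", rp$product, ")")
    s <- net$compounds[[rp$substrate]]
    p <- net$compounds[[rp$product]]
    if (is.null(s)) stop(label, ": unknown substrate compound", call. = FALSE)
    if (is.null(p)) stop(label, ": unknown product compound", call. = FALSE)
    m <- rp$mapping
    if (nrow(m) > 0L) {
      if (anyDuplicated(m[, 1L]) || anyDuplicated(m[, 2L])) {
        stop(label, ": atom mapping is not injective", call. = FALSE)
      }
      if (any(m[, 1L] < 0L) || any(m[, 1L] >= n_atoms(s)) ||
          any(m[, 2L] < 0L) || any(m[, 2L] >= n_atoms(p))) {
        stop(label, ": mapped atom index out of range", call. = FALSE)
      }
      bad <- s$elements[m[, 1L] + 1L] != p$elements[m[, 2L] + 1L]
      if (any(bad)) {
        j <- which(bad)[1L]
        stop(label, ": atom ", m[j, 1L], " (", s$elements[m[j, 1L] + 1L],
             ") mapped onto atom ", m[j, 2L], " (",
             p$elements[m[j, 2L] + 1L], ") with different element",
             call. = FALSE)
      }
    }
    triples[i] <- paste(rp$reaction, rp$substrate, rp$product, sep = "")
  }
  if (anyDuplicated(triples)) {
    stop("duplicate (reaction, substrate, product) triple", call. = FALSE)
  }
  invisible(net)
}

#' Read a metabolic network from its JSON dialect
#'
#' The dialect is a top-level object with `compounds`
#' (`[{"id", "atoms": [{"i", "element"}], "bonds": [[i,j], ...]}]`) and
#' `reactant_pairs` (`[{"reaction", "substrate", "product",
#' "mapping": [[s,p], ...], "dG": number|null, "reversible": bool}]`).
#'
#' @param path file path
#' @return a validated [metabolic_network()]
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(obj$compounds)) {
    stop("not a network file: missing 'compounds'", call. = FALSE)
  }
  compounds <- lapply(obj$compounds, function(cp) {
    idx <- vapply(cp$atoms, function(a) as.integer(a$i), integer(1L))
    if (length(idx) && !identical(sort(idx), seq_along(idx) - 1L)) {
      stop("compound '", cp$id, "': atom indices must be 0..n-1 with no gaps",
           call. = FALSE)
    }
    elements <- character(length(idx))
    for (a in cp$atoms) elements[as.integer(a$i) + 1L] <- as.character(a$element)
    molecular_graph(cp$id, elements, cp$bonds)
  })
  pairs <- lapply(obj$reactant_pairs, function(rp) {
    reactant_pair(rp$reaction, rp$substrate, rp$product, rp$mapping,
                  dG = if (is.null(rp$dG)) NA_real_ else as.numeric(rp$dG),
                  reversible = if (is.null(rp$reversible)) TRUE
                               else isTRUE(rp$reversible))
  })
  metabolic_network(compounds, pairs)
}

#' Write a metabolic network to its JSON dialect
#'
#' Serialization is deterministic: compounds sorted by id, reactant pairs by
#' (reaction, substrate, product), bonds and mappings in canonical order.
#' Two calls on equal networks produce byte-identical files.
#'
#' @param net a [metabolic_network()]
#' @param path destination file path
#' @return `invisible(path)`
#' @export
write_network <- function(net, path) {
  ids <- sort(names(net$compounds), method = "radix")
  compounds <- lapply(ids, function(id) {
    g <- net$compounds[[id]]
    list(id = id,
         atoms = lapply(seq_along(g$elements), function(i) {
           list(i = i - 1L, element = g$elements[i])
         }),
         bonds = bond_matrix_to_list(g$bonds))
  })
  rp_key <- vapply(net$reactant_pairs, function(rp) {
    paste(rp$reaction, rp$substrate, rp$product, sep = "")
  }, character(1L))
  pairs <- lapply(net$reactant_pairs[order(rp_key, method = "radix")],
                  function(rp) {
    list(reaction = rp$reaction, substrate = rp$substrate,
         product = rp$product,
         mapping = bond_matrix_to_list(rp$mapping),
         dG = if (is.na(rp$dG)) NULL else rp$dG,
         reversible = rp$reversible)
  })
  json <- jsonlite::toJSON(list(compounds = compounds,
                                reactant_pairs = pairs),
                           auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

bond_matrix_to_list <- function(m) {
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

#' Expand a network into directed traversal edges
#'
#' Every reactant pair yields one forward edge (substrate to product);
#' reversible pairs additionally yield a reverse edge carrying the inverted
#' atom mapping. Parallel edges between the same compound pair are kept
#' distinct, keyed by reaction id.
#'
#' @param net a [metabolic_network()]
#' @return list of edges, each `list(from, to, reaction, mapping, dG,
#'   forward)`
#' @export
directed_edges <- function(net) {
  edges <- vector("list", 0L)
  for (rp in net$reactant_pairs) {
    edges[[length(edges) + 1L]] <-
      list(from = rp$substrate, to = rp$product, reaction = rp$reaction,
           mapping = rp$mapping, dG = rp$dG, forward = TRUE)
    if (rp$reversible) {
      edges[[length(edges) + 1L]] <-
        list(from = rp$product, to = rp$substrate, reaction = rp$reaction,
             mapping = invert_mapping(rp$mapping), dG = rp$dG,
             forward = FALSE)
    }
  }
  edges
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$compounds), " compounds, ",
      length(x$reactant_pairs), " reactant pairs\n", sep = "")
  invisible(x)
}
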
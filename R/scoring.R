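#' Pathway scoring and ranking
#'
#' A linear pathway with reactions `r_1 .. r_lc` joining consecutive
#' compounds `(v_i, v_j)` is scored
#'
#'   `Score = alpha_s * sum sim(v_i, v_j)
#'            - alpha_sf * sum (3200 + fe(r_i)) / 10000
#'            + alpha_t * t / e`
#'
#' where `sim` is a compound similarity in `[0, 1]`, `fe(r_i)` the Gibbs
#' free-energy change of reaction `r_i`, `t` the number of minimal atom
#' groups (conserved bonds) transferred to the target and `e` the bond
#' count of the source compound. A branched pathway with `n_b` branched
#' compounds and member scores `Score(p_i)` is scored
#'
#'   `Score_Branch = alpha_p * n_b + (1 - alpha_p) * mean(Score(p_i))`.
#'
#' @name scoring
NULL

#' Scoring weights
#'
#' Defaults follow the method's standard settings: `alpha_s = 0.1`,
#' `alpha_sf = 0.2`, `alpha_t = 0.2`, `alpha_p = 0.8`.
#'
#' @param alpha_s weight of compound similarity
#' @param alpha_sf weight of the Gibbs free-energy penalty
#' @param alpha_t weight of the conserved atom-group fraction `t / e`
#' @param alpha_p weight of the branched-compound count
#' @return object of class `scoring_weights`
#' @export
scoring_weights <- function(alpha_s = 0.1, alpha_sf = 0.2, alpha_t = 0.2,
                            alpha_p = 0.8) {
  w <- c(alpha_s = alpha_s, alpha_sf = alpha_sf, alpha_t = alpha_t,
         alpha_p = alpha_p)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("all weights must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(w), class = "scoring_weights")
}

#' Normalized Gibbs free-energy term
#'
#' The affine normalization `(3200 + dG) / 10000` brings reaction
#' free-energy changes onto the scale of the similarity term; over the
#' range of tabulated values, `[-2233.7, 10194.7]`, it maps into
#' `[0.097, 1.339]`.
#'
#' @param delta_g Gibbs free-energy change(s) of a reaction
#' @return numeric of the same length
#' @export
#' @examples
#' gibbs_term(-2233.7)  # 0.09663
#' gibbs_term(10194.7)  # 1.33947
gibbs_term <- function(delta_g) {
  stopifnot(is.numeric(delta_g), all(is.finite(delta_g)))
  (3200 + delta_g) / 10000
}

#' Gibbs free-energy table
#'
#' Reaction free-energy changes, with a default for reactions that carry
#' no value. The default of 0 sits mid-scale after normalization (0.32).
#'
#' @param values named numeric vector, reaction id -> delta G
#' @param default value used when a reaction is absent
#' @return object of class `gibbs_table`
#' @export
gibbs_table <- function(values = numeric(0), default = 0) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            is.numeric(default), is.finite(default))
  structure(list(values = values, default = default), class = "gibbs_table")
}

#' Read a Gibbs table from a two-column TSV (reaction_id, delta_g)
#' @param path file path
#' @param default value for absent reactions
#' @return a [gibbs_table()]
#' @export
read_gibbs_table <- function(path, default = 0) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("reaction", "delta_g"),
                          stringsAsFactors = FALSE)
  gibbs_table(stats::setNames(as.numeric(df$delta_g), df$reaction), default)
}

# delta G for one pathway edge: the edge's own value, else the table's
edge_delta_g <- function(tbl, e) {
  if (!is.null(e$dG) && !is.na(e$dG)) return(e$dG)
  v <- tbl$values[e$reaction]
  if (length(v) == 1L && !is.na(v)) unname(v) else tbl$default
}

#' Similarity provider from an explicit table
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `sim` (values in
#'   `[0, 1]`); symmetry is implied, self-similarity is 1
#' @param default similarity for pairs absent from the table (default 0)
#' @return a function `(id_a, id_b) -> similarity`
#' @export
similarity_table <- function(pairs, default = 0) {
  stopifnot(all(c("id_a", "id_b", "sim") %in% names(pairs)))
  if (any(pairs$sim < 0 | pairs$sim > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "")
  tab <- stats::setNames(pairs$sim, key(pairs$id_a, pairs$id_b))
  function(id_a, id_b) {
    if (identical(id_a, id_b)) return(1)
    v <- tab[key(id_a, id_b)]
    if (length(v) == 1L && !is.na(v)) unname(v) else default
  }
}

#' Read a similarity table from a three-column TSV (id_a, id_b, sim)
#' @param path file path
#' @param default similarity for absent pairs
#' @return a function `(id_a, id_b) -> similarity`
#' @export
read_similarity_table <- function(path, default = 0) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id_a", "id_b", "sim"),
                          stringsAsFactors = FALSE)
  similarity_table(df, default)
}

#' Structural similarity provider over a network's compounds
#'
#' Tanimoto similarity on the maximum common edge sub-graph, computed by
#' [structural_similarity()] and cached per compound pair. Exact and
#' intended for fixture-scale compounds; supply a [similarity_table()] for
#' larger molecules.
#'
#' @param net a [metabolic_network()]
#' @return a function `(id_a, id_b) -> similarity`
#' @export
similarity_structural <- function(net) {
  cache <- new.env(parent = emptyenv())
  function(id_a, id_b) {
    key <- paste(min(id_a, id_b), max(id_a, id_b), sep = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    a <- net$compounds[[id_a]]
    b <- net$compounds[[id_b]]
    if (is.null(a) || is.null(b)) {
      stop("similarity requested for unknown compound", call. = FALSE)
    }
    v <- structural_similarity(a, b)
    cache[[key]] <- v
    v
  }
}

#' Maximum-common-edge-subgraph Tanimoto similarity
#'
#' `|mcs| / (|bonds_a| + |bonds_b| - |mcs|)` where `|mcs|` is the bond
#' count of the maximum common edge sub-graph under element-compatible
#' atom correspondence. Exhaustive (exact) via maximum clique on the
#' bond-assignment compatibility graph; symmetric, bounded in `[0, 1]`,
#' and 1 on isomorphic graphs. Bond-less graphs score 0 against any bonded
#' graph; two bond-less graphs score 1 iff their element multisets are
#' identical.
#'
#' @param a,b `molecular_graph` objects
#' @return similarity in `[0, 1]`
#' @export
structural_similarity <- function(a, b) {
  na <- n_bonds(a); nb <- n_bonds(b)
  if (na == 0L && nb == 0L) {
    return(as.numeric(identical(sort(a$elements), sort(b$elements))))
  }
  if (na == 0L || nb == 0L) return(0)
  # identical labelled graphs: MCS is the whole graph
  if (identical(a$elements, b$elements) && identical(a$bonds, b$bonds)) {
    return(1)
  }
  mcs <- mcs_bond_count(a, b)
  mcs / (na + nb - mcs)
}

# Maximum common edge subgraph size via maximum clique over oriented
# bond-to-bond assignments with consistent injective atom correspondence.
mcs_bond_count <- function(a, b) {
  ea <- a$elements; eb <- b$elements
  ba <- a$bonds; bb <- b$bonds
  nodes <- list()
  for (i in seq_len(nrow(ba))) {
    u <- ba[i, 1L]; v <- ba[i, 2L]
    for (j in seq_len(nrow(bb))) {
      x <- bb[j, 1L]; y <- bb[j, 2L]
      if (ea[u + 1L] == eb[x + 1L] && ea[v + 1L] == eb[y + 1L]) {
        nodes[[length(nodes) + 1L]] <- c(i, j, u, v, x, y)
      }
      if (ea[u + 1L] == eb[y + 1L] && ea[v + 1L] == eb[x + 1L]) {
        nodes[[length(nodes) + 1L]] <- c(i, j, u, v, y, x)
      }
    }
  }
  if (length(nodes) == 0L) return(0L)
  nm <- do.call(rbind, nodes)  # columns: bond_a, bond_b, u, v, img_u, img_v
  nn <- nrow(nm)
  if (nn == 1L) return(1L)
  compat <- matrix(FALSE, nn, nn)
  for (p in seq_len(nn - 1L)) {
    for (q in seq(p + 1L, nn)) {
      if (nm[p, 1L] == nm[q, 1L] || nm[p, 2L] == nm[q, 2L]) next
      from <- c(nm[p, 3L], nm[p, 4L], nm[q, 3L], nm[q, 4L])
      to <- c(nm[p, 5L], nm[p, 6L], nm[q, 5L], nm[q, 6L])
      mp <- unique(cbind(from, to))
      if (anyDuplicated(mp[, 1L]) || anyDuplicated(mp[, 2L])) next
      compat[p, q] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(compat, mode = "upper")
  igraph::clique_num(g)
}

#' Score a linear pathway
#'
#' @param lp a [linear_pathway()] with propagated conserved groups
#' @param weights a [scoring_weights()]
#' @param sim similarity provider: a function `(id_a, id_b) -> [0, 1]`
#' @param gibbs a [gibbs_table()]; an edge's own `dG` takes precedence
#' @param e source bond count; defaults to the bonds of the pathway's own
#'   source compound record (must be >= 1)
#' @return numeric score
#' @export
score_linear <- function(lp, weights = scoring_weights(), sim, gibbs = gibbs_table(),
                         e = NULL) {
  if (is.null(e)) e <- nrow(lp$conserved[[1L]]$bonds)
  if (e == 0L) stop("source compound must contain at least one bond",
                    call. = FALSE)
  lc <- length(lp$edges)
  sim_sum <- 0
  g_sum <- 0
  for (i in seq_len(lc)) {
    sim_sum <- sim_sum + sim(lp$compounds[i], lp$compounds[i + 1L])
    g_sum <- g_sum + gibbs_term(edge_delta_g(gibbs, lp$edges[[i]]))
  }
  t_count <- count_minimal_groups(lp)
  weights$alpha_s * sim_sum - weights$alpha_sf * g_sum +
    weights$alpha_t * (t_count / e)
}

#' Score a branched pathway
#'
#' @param bp a [branched_pathway()]
#' @param weights a [scoring_weights()]
#' @param member_scores numeric vector of member linear-pathway scores,
#'   one per member, in member order
#' @return `alpha_p * n_b + (1 - alpha_p) * mean(member_scores)` where
#'   `n_b` is the number of branched compounds
#' @export
score_branched <- function(bp, weights = scoring_weights(), member_scores) {
  stopifnot(length(member_scores) == length(bp$members))
  n_b <- length(bp$branched_compounds)
  weights$alpha_p * n_b + (1 - weights$alpha_p) * mean(member_scores)
}

#' Rank scored branched pathways
#'
#' Descending score; ties broken by fewer total reactions, then canonical
#' serialization, so the order is stable under input permutation.
#'
#' @param pathways list of scored [branched_pathway()]
#' @return the list, reordered
#' @export
rank_pathways <- function(pathways) {
  if (length(pathways) == 0L) return(pathways)
  scores <- vapply(pathways, function(bp) bp$score, numeric(1L))
  if (any(is.na(scores))) {
    stop("all pathways must be scored before ranking", call. = FALSE)
  }
  n_rxn <- vapply(pathways, bp_n_reactions, integer(1L))
  keys <- vapply(pathways, bp_key, character(1L))
  pathways[order(-scores, n_rxn, keys, method = "radix")]
}
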
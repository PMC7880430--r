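# Fixture builders and independent brute-force oracles used across tests.
# All randomness is driven by the caller's set.seed().

# random labelled molecular graph; connectivity not enforced
random_graph <- function(id, n_atoms = 5L, p_bond = 0.4,
                         alphabet = c("C", "C", "N", "O")) {
  elements <- sample(alphabet, n_atoms, replace = TRUE)
  pairs <- which(upper.tri(matrix(0, n_atoms, n_atoms)), arr.ind = TRUE) - 1L
  keep <- stats::runif(nrow(pairs)) < p_bond
  molecular_graph(id, elements, pairs[keep, , drop = FALSE])
}

# random reactant pair between two random graphs: an injective partial map
# over element-compatible atoms
random_pair_fixture <- function(n_sub = 5L, n_prod = 5L, p_bond = 0.4,
                                p_map = 0.7) {
  sub <- random_graph("sub", n_sub, p_bond)
  prod <- random_graph("prod", n_prod, p_bond)
  perm <- sample.int(n_prod) - 1L
  mapping <- matrix(integer(0), ncol = 2L)
  used <- integer(0)
  for (x in seq_len(n_sub) - 1L) {
    if (stats::runif(1) > p_map) next
    for (y in perm) {
      if (y %in% used) next
      if (sub$elements[x + 1L] == prod$elements[y + 1L]) {
        mapping <- rbind(mapping, c(x, y))
        used <- c(used, y)
        break
      }
    }
  }
  pair <- reactant_pair("Rx", "sub", "prod", mapping)
  list(sub = sub, prod = prod, pair = pair,
       net = metabolic_network(list(sub, prod), list(pair)))
}

# oracle: substrate bonds with both endpoints mapped onto a product bond
brute_conserved_bonds <- function(sub, prod, mapping) {
  prod_keys <- apply(prod$bonds, 1L, function(b) paste(sort(b), collapse = "-"))
  if (nrow(sub$bonds) == 0L) return(matrix(integer(0), ncol = 2L))
  keep <- logical(nrow(sub$bonds))
  for (i in seq_len(nrow(sub$bonds))) {
    u <- sub$bonds[i, 1L]; v <- sub$bonds[i, 2L]
    iu <- mapping[match(u, mapping[, 1L]), 2L]
    iv <- mapping[match(v, mapping[, 1L]), 2L]
    if (is.na(iu) || is.na(iv)) next
    keep[i] <- paste(sort(c(iu, iv)), collapse = "-") %in% prod_keys
  }
  sub$bonds[keep, , drop = FALSE]
}

# oracle: exhaustive DFS enumeration of all simple paths, sorted by
# (length, canonical key), truncated to k
oracle_k_shortest <- function(net, source, target, k, max_len = 12L) {
  edges <- directed_edges(net)
  res <- list()
  recur <- function(compounds, eds) {
    last <- compounds[length(compounds)]
    if (identical(last, target)) {
      res[[length(res) + 1L]] <<- list(compounds = compounds, edges = eds)
      return(invisible())
    }
    if (length(eds) >= max_len) return(invisible())
    for (e in edges) {
      if (identical(e$from, last) && !(e$to %in% compounds)) {
        recur(c(compounds, e$to), c(eds, list(e)))
      }
    }
  }
  recur(source, list())
  keys <- vapply(res, function(p) agtpath:::path_key(p$compounds, p$edges),
                 character(1L))
  lens <- vapply(res, function(p) length(p$edges), integer(1L))
  res <- res[order(lens, keys, method = "radix")]
  res[seq_len(min(k, length(res)))]
}

path_signature <- function(p) agtpath:::path_key(p$compounds, p$edges)

# oracle: maximum common edge subgraph size by exhaustive backtracking over
# oriented bond assignments (independent of the clique formulation)
brute_mcs_bonds <- function(a, b) {
  ba <- a$bonds; bb <- b$bonds
  best <- 0L
  recur <- function(i, used_b, amap) {
    # amap: named vector, names = a atoms (as char), values = b atoms
    remaining <- nrow(ba) - i + 1L
    size <- length(used_b)
    if (size + remaining <= best) return(invisible())
    if (i > nrow(ba)) {
      best <<- max(best, size)
      return(invisible())
    }
    u <- ba[i, 1L]; v <- ba[i, 2L]
    for (j in seq_len(nrow(bb))) {
      if (j %in% used_b) next
      for (or in 1:2) {
        x <- bb[j, if (or == 1L) 1L else 2L]
        y <- bb[j, if (or == 1L) 2L else 1L]
        if (a$elements[u + 1L] != b$elements[x + 1L]) next
        if (a$elements[v + 1L] != b$elements[y + 1L]) next
        m2 <- amap
        ku <- as.character(u); kv <- as.character(v)
        if (!is.null(m2[[ku]]) && m2[[ku]] != x) next
        if (!is.null(m2[[kv]]) && m2[[kv]] != y) next
        if (is.null(m2[[ku]]) && x %in% unlist(m2)) next
        if (is.null(m2[[kv]]) && y %in% unlist(m2)) next
        if (is.null(m2[[ku]]) && is.null(m2[[kv]]) && x == y) next
        m2[[ku]] <- x; m2[[kv]] <- y
        recur(i + 1L, c(used_b, j), m2)
      }
    }
    recur(i + 1L, used_b, amap)  # leave bond i unmapped
    invisible()
  }
  recur(1L, integer(0), list())
  best
}

# a chain network of identity reactant pairs over copies of one graph
identity_chain_network <- function(g, n_steps, reversible = FALSE) {
  ids <- paste0("K", seq_len(n_steps + 1L))
  compounds <- lapply(ids, function(id) molecular_graph(id, g$elements, g$bonds))
  all_atoms <- seq_along(g$elements) - 1L
  pairs <- lapply(seq_len(n_steps), function(i) {
    reactant_pair(paste0("RK", i), ids[i], ids[i + 1L],
                  cbind(all_atoms, all_atoms), reversible = reversible)
  })
  list(net = metabolic_network(compounds, pairs), ids = ids)
}

# plain-list linear pathway (result-file shape) for the evaluation metrics
chain_pathway <- function(compounds, reactions = NULL) {
  if (is.null(reactions)) {
    reactions <- paste0("r_", head(compounds, -1L), "_", compounds[-1L])
  }
  list(compounds = compounds, reactions = reactions)
}

# random branched pathway in plain-list form: chains over a shared label
# pool, all sharing one source and one target so the graph is connected
random_plain_pathway <- function(pool_c = LETTERS[1:8],
                                 pool_r = paste0("R", 1:10),
                                 n_members = 2L) {
  ends <- sample(pool_c, 2L)
  members <- lapply(seq_len(n_members), function(i) {
    len <- sample(1:3, 1L)
    mid <- sample(setdiff(pool_c, ends), len)
    rxs <- sample(pool_r, len + 1L)
    chain_pathway(c(ends[1L], mid, ends[2L]), rxs)
  })
  list(linear_pathways = members)
}
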
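#' Linear atom-group-conserving pathway search
#'
#' The search enumerates the top-k shortest simple paths from source to
#' target over the directed reactant-pair edges, then keeps the paths whose
#' target compound retains atom groups traceable, through composed atom
#' mappings, to the source compound.
#'
#' @name linear-search
NULL

#' Search parameters
#'
#' @param k number of candidate linear pathways to enumerate (default 2000)
#' @param min_groups minimum number of minimal atom groups (conserved
#'   bonds) that must reach the target (default 2)
#' @param max_path_len cap on reactions per path (default 12); bounds the
#'   enumeration on dense networks
#' @return object of class `search_params`
#' @export
search_params <- function(k = 2000L, min_groups = 2L, max_path_len = 12L) {
  k <- as.integer(k); min_groups <- as.integer(min_groups)
  max_path_len <- as.integer(max_path_len)
  stopifnot(k >= 1L, min_groups >= 1L, max_path_len >= 1L)
  structure(list(k = k, min_groups = min_groups,
                 max_path_len = max_path_len),
            class = "search_params")
}

path_key <- function(compounds, edges) {
  steps <- vapply(edges, function(e) {
    paste0(e$reaction, if (e$forward) "+" else "-")
  }, character(1L))
  n <- length(compounds)
  inter <- character(2L * n - 1L)
  inter[seq(1L, 2L * n - 1L, by = 2L)] <- compounds
  if (n > 1L) inter[seq(2L, 2L * n - 2L, by = 2L)] <- steps
  paste(inter, collapse = "")
}

#' Top-k shortest simple paths between two compounds
#'
#' Best-first enumeration of loop-free (compound-simple) paths over
#' [directed_edges()], in order of increasing reaction count; ties of equal
#' length are broken lexicographically on the interleaved
#' (compound, reaction) sequence. Parallel reactions between the same
#' compound pair yield distinct paths.
#'
#' @param net a [metabolic_network()]
#' @param source,target compound ids, `source != target`
#' @param params a [search_params()]
#' @return list of up to `k` paths, each `list(compounds, edges)`; empty
#'   list when no path exists
#' @export
k_shortest_paths <- function(net, source, target, params = search_params()) {
  if (is.null(net$compounds[[source]])) {
    stop("unknown compound id '", source, "'", call. = FALSE)
  }
  if (is.null(net$compounds[[target]])) {
    stop("unknown compound id '", target, "'", call. = FALSE)
  }
  if (identical(source, target)) {
    stop("source and target must differ", call. = FALSE)
  }
  edges <- directed_edges(net)
  from <- vapply(edges, function(e) e$from, character(1L))
  adj <- split(seq_along(edges), from)

  # frontier of partial simple paths, ordered by (length, canonical key)
  items <- list(list(compounds = source, edges = list()))
  lens <- 0L
  keys <- source
  found <- list()
  while (length(items) > 0L && length(found) < params$k) {
    i <- order(lens, keys, method = "radix")[1L]
    cur <- items[[i]]
    cur_len <- lens[i]
    items <- items[-i]; lens <- lens[-i]; keys <- keys[-i]
    last <- cur$compounds[length(cur$compounds)]
    if (identical(last, target)) {
      found[[length(found) + 1L]] <- cur
      next
    }
    if (cur_len >= params$max_path_len) next
    for (j in adj[[last]]) {
      e <- edges[[j]]
      if (e$to %in% cur$compounds) next
      nxt <- list(compounds = c(cur$compounds, e$to),
                  edges = c(cur$edges, list(e)))
      items[[length(items) + 1L]] <- nxt
      lens <- c(lens, cur_len + 1L)
      keys <- c(keys, path_key(nxt$compounds, nxt$edges))
    }
  }
  found
}

#' Find linear atom-group-conserving pathways
#'
#' Runs [k_shortest_paths()] and keeps the paths along which at least
#' `min_groups` minimal atom groups (conserved bonds) from the source
#' survive into the target, with the full per-compound conserved groups
#' attached. Order is inherited from the shortest-path enumeration.
#'
#' @inheritParams k_shortest_paths
#' @return list of [linear_pathway()]
#' @export
find_linear_conserving <- function(net, source, target,
                                   params = search_params()) {
  paths <- k_shortest_paths(net, source, target, params)
  conserving_from_paths(net, paths, source, params$min_groups)
}

# conservation filter over already-enumerated paths
conserving_from_paths <- function(net, paths, source, min_groups) {
  out <- list()
  for (p in paths) {
    conserved <- propagate_along_path(net, p$edges, source)
    t_count <- nrow(conserved[[length(conserved)]]$bonds)
    if (t_count >= min_groups) {
      out[[length(out) + 1L]] <-
        linear_pathway(p$compounds, p$edges, conserved)
    }
  }
  out
}
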
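#' Comparing computed and known pathways
#'
#' Pathways are compared as directed bipartite graphs of labelled compound
#' and reaction nodes, with edges substrate-compound -> reaction and
#' reaction -> product-compound. Seven metrics are computed: the ratio of
#' the edges of the largest common connected sub-graph to the known
#' pathway's edges (R_ELCCS), and sensitivity, positive predictive value
#' and accuracy over compounds (Sn, PPV, AC) and over reactions (R_Sn,
#' R_PPV, R_AC). A node counts as a true positive only if it is present in
#' both pathways and its precedence relative to every other shared node of
#' its kind (directed reachability) agrees between the two pathways.
#'
#' @name evaluation
NULL

#' Build the bipartite pathway graph
#'
#' Accepts a [branched_pathway()], a [linear_pathway()], or a plain list
#' of the result-file shape (`$linear_pathways` or `$compounds` +
#' `$reactions`). Reaction node labels are made distinct from compound
#' labels internally.
#'
#' @param x pathway object
#' @return object of class `pathway_graph`: `list(edges, compounds,
#'   reactions, graph)` where `graph` is a directed `igraph`
#' @export
pathway_graph <- function(x) {
  chains <- list()
  if (inherits(x, "branched_pathway")) {
    chains <- lapply(x$members, function(m) {
      list(compounds = m$compounds, reactions = pathway_reactions(m),
           forward = vapply(m$edges, function(e) e$forward, logical(1L)))
    })
  } else if (inherits(x, "linear_pathway")) {
    chains <- list(list(compounds = x$compounds,
                        reactions = pathway_reactions(x),
                        forward = vapply(x$edges, function(e) e$forward,
                                         logical(1L))))
  } else if (is.list(x) && !is.null(x$linear_pathways)) {
    chains <- lapply(x$linear_pathways, function(m) {
      list(compounds = as.character(unlist(m$compounds)),
           reactions = as.character(unlist(m$reactions)),
           forward = rep(TRUE, length(unlist(m$reactions))))
    })
  } else if (is.list(x) && !is.null(x$compounds) && !is.null(x$reactions)) {
    chains <- list(list(compounds = as.character(unlist(x$compounds)),
                        reactions = as.character(unlist(x$reactions)),
                        forward = rep(TRUE, length(unlist(x$reactions)))))
  } else {
    stop("cannot interpret object as a pathway", call. = FALSE)
  }
  from <- character(0); to <- character(0)
  compounds <- character(0); reactions <- character(0)
  for (ch in chains) {
    stopifnot(length(ch$compounds) == length(ch$reactions) + 1L)
    compounds <- c(compounds, ch$compounds)
    reactions <- c(reactions, ch$reactions)
    for (i in seq_along(ch$reactions)) {
      rlab <- paste0("r", ch$reactions[i])
      from <- c(from, paste0("c", ch$compounds[i]), rlab)
      to <- c(to, rlab, paste0("c", ch$compounds[i + 1L]))
    }
  }
  el <- unique(cbind(from, to))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  structure(list(edges = el,
                 compounds = sort(unique(compounds), method = "radix"),
                 reactions = sort(unique(reactions), method = "radix"),
                 graph = g),
            class = "pathway_graph")
}

as_pathway_graph <- function(x) {
  if (inherits(x, "pathway_graph")) x else pathway_graph(x)
}

#' Edge ratio of the largest common connected sub-graph
#'
#' The label-matched edge intersection of the two pathway graphs is
#' formed; its largest connected component (connectivity judged on the
#' undirected skeleton) is the largest common connected sub-graph, and the
#' metric is its edge count divided by the known pathway's edge count.
#'
#' @param computed,known pathway objects or [pathway_graph()]s
#' @return value in `[0, 1]`
#' @export
r_elccs <- function(computed, known) {
  pc <- as_pathway_graph(computed)
  pk <- as_pathway_graph(known)
  n_known <- nrow(pk$edges)
  if (n_known == 0L) stop("known pathway has no edges", call. = FALSE)
  keyc <- paste(pc$edges[, 1L], pc$edges[, 2L], sep = "")
  keyk <- paste(pk$edges[, 1L], pk$edges[, 2L], sep = "")
  inter <- pk$edges[keyk %in% keyc, , drop = FALSE]
  if (nrow(inter) == 0L) return(0)
  g <- igraph::graph_from_edgelist(inter, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_edges <- table(memb[inter[, 1L]])
  max(comp_edges) / n_known
}

# pairwise precedence consistency of shared labels under directed
# reachability; returns tp count and the set of consistent labels
order_consistent <- function(gc, gk, shared_labels) {
  if (length(shared_labels) == 0L) {
    return(character(0))
  }
  reach <- function(g, labels) {
    d <- igraph::distances(g, v = labels, to = labels, mode = "out")
    is.finite(d) & d > 0
  }
  rc <- reach(gc, shared_labels)
  rk <- reach(gk, shared_labels)
  ok <- vapply(seq_along(shared_labels), function(i) {
    all(rc[i, ] == rk[i, ]) && all(rc[, i] == rk[, i])
  }, logical(1L))
  shared_labels[ok]
}

node_metrics <- function(computed, known, kind = c("compound", "reaction")) {
  kind <- match.arg(kind)
  pc <- as_pathway_graph(computed)
  pk <- as_pathway_graph(known)
  prefix <- if (kind == "compound") "c" else "r"
  set_c <- if (kind == "compound") pc$compounds else pc$reactions
  set_k <- if (kind == "compound") pk$compounds else pk$reactions
  shared <- intersect(set_c, set_k)
  shared_labels <- if (length(shared) > 0L) paste0(prefix, shared)
                   else character(0)
  consistent <- order_consistent(pc$graph, pk$graph, shared_labels)
  tp <- length(consistent)
  inconsistent <- length(shared) - tp
  fn <- length(setdiff(set_k, set_c)) + inconsistent
  fp <- length(setdiff(set_c, set_k)) + inconsistent
  sn <- if (tp + fn > 0L) tp / (tp + fn) else 0
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else 0
  list(sn = sn, ppv = ppv, ac = (sn + ppv) / 2, tp = tp, fp = fp, fn = fn)
}

#' Compound-level comparison metrics
#'
#' @inheritParams r_elccs
#' @return list with `sn`, `ppv`, `ac`, `tp`, `fp`, `fn`
#' @export
compound_metrics <- function(computed, known) {
  node_metrics(computed, known, "compound")
}

#' Reaction-level comparison metrics
#'
#' @inheritParams r_elccs
#' @return list with `r_sn`, `r_ppv`, `r_ac`, `r_tp`, `r_fp`, `r_fn`
#' @export
reaction_metrics <- function(computed, known) {
  m <- node_metrics(computed, known, "reaction")
  list(r_sn = m$sn, r_ppv = m$ppv, r_ac = m$ac,
       r_tp = m$tp, r_fp = m$fp, r_fn = m$fn)
}

#' All seven comparison metrics for a computed/known pathway pair
#'
#' @inheritParams r_elccs
#' @return object of class `comparison_result` with fields `r_elccs`,
#'   `sn`, `ppv`, `ac`, `r_sn`, `r_ppv`, `r_ac` and the underlying counts
#' @export
compare_pathways <- function(computed, known) {
  pc <- as_pathway_graph(computed)
  pk <- as_pathway_graph(known)
  cm <- compound_metrics(pc, pk)
  rm <- reaction_metrics(pc, pk)
  structure(c(list(r_elccs = r_elccs(pc, pk)), cm, rm),
            class = "comparison_result")
}

#' Average comparison metrics over a result set
#'
#' @param results non-empty list of `comparison_result`
#' @return `comparison_result` with each field replaced by its arithmetic
#'   mean over the set
#' @export
mean_over_set <- function(results) {
  if (length(results) == 0L) stop("empty result list", call. = FALSE)
  fields <- names(results[[1L]])
  out <- lapply(fields, function(f) {
    mean(vapply(results, function(r) as.numeric(r[[f]]), numeric(1L)))
  })
  names(out) <- fields
  structure(out, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  cat(sprintf("  R_ELCCS %.4f | Sn %.4f PPV %.4f AC %.4f | R_Sn %.4f R_PPV %.4f R_AC %.4f\n",
              x$r_elccs, x$sn, x$ppv, x$ac, x$r_sn, x$r_ppv, x$r_ac))
  invisible(x)
}
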
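#' End-to-end branched pathway search
#'
#' The full method runs in three steps: (1) enumerate candidate linear
#' pathways and keep the atom-group-conserving ones, (2) merge them at
#' branched compounds under the rule in force, (3) score and rank the
#' branched pathways. With `rule = "auto"` the non-overlapping rule is
#' tried first and the overlapping rule only when it returns nothing.
#'
#' @param net a [metabolic_network()] or a path to a network JSON file
#' @param source,target compound ids
#' @param params a [search_params()] (defaults: k = 2000, min_groups = 2,
#'   max_path_len = 12)
#' @param rule `"auto"`, `"overlap"` or `"nonoverlap"`
#' @param weights a [scoring_weights()] (defaults 0.1 / 0.2 / 0.2 / 0.8)
#' @param sim similarity provider function; default is the structural
#'   (maximum-common-edge-subgraph Tanimoto) provider over `net`
#' @param gibbs a [gibbs_table()]; per-edge `dG` values take precedence
#' @param top_n number of ranked branched pathways to return (default 5)
#' @param max_combo_size,max_results see [merge_config()]
#' @param verbose emit per-stage counts to stderr
#' @return object of class `pathway_search_result`: `list(pathways,
#'   rule_used, stats)` where `pathways` is the ranked, truncated list of
#'   scored [branched_pathway()] and `stats` records the pathway counts at
#'   each stage
#' @export
run_search <- function(net, source, target,
                       params = search_params(),
                       rule = c("auto", "overlap", "nonoverlap"),
                       weights = scoring_weights(),
                       sim = NULL,
                       gibbs = gibbs_table(),
                       top_n = 5L,
                       max_combo_size = 3L,
                       max_results = 10000L,
                       verbose = FALSE) {
  rule <- match.arg(rule)
  if (is.character(net)) net <- read_network(net)
  if (is.null(sim)) sim <- similarity_structural(net)
  top_n <- as.integer(top_n)
  stopifnot(top_n >= 1L)
  say <- function(...) if (verbose) message("[agtpath] ", ...)

  candidates <- k_shortest_paths(net, source, target, params)
  say("candidate linear pathways: ", length(candidates))
  conserving <- conserving_from_paths(net, candidates, source,
                                      params$min_groups)
  say("atom-group-conserving pathways: ", length(conserving))

  n_branch_cands <- length(candidate_branch_compounds(conserving))
  say("candidate branched compounds: ", n_branch_cands)

  merge_with <- function(r) {
    merge_pathways(conserving,
                   merge_config(rule = r, max_combo_size = max_combo_size,
                                max_results = max_results))
  }
  if (rule == "overlap") {
    merged <- merge_with("overlapping")
    rule_used <- "overlapping"
  } else if (rule == "nonoverlap") {
    merged <- merge_with("non_overlapping")
    rule_used <- "non_overlapping"
  } else {
    merged <- merge_with("non_overlapping")
    rule_used <- "non_overlapping"
    if (length(merged) == 0L) {
      say("non-overlapping rule returned nothing; falling back to ",
          "overlapping rule")
      merged <- merge_with("overlapping")
      rule_used <- "overlapping"
    }
  }
  say("merged branched pathways (", rule_used, " rule): ", length(merged))

  scored <- lapply(merged, function(bp) {
    member_scores <- vapply(bp$members, function(m) {
      score_linear(m, weights, sim, gibbs)
    }, numeric(1L))
    for (i in seq_along(bp$members)) bp$members[[i]]$score <- member_scores[i]
    bp$score <- score_branched(bp, weights, member_scores)
    bp
  })
  ranked <- rank_pathways(scored)
  out <- ranked[seq_len(min(top_n, length(ranked)))]
  say("returned: ", length(out), " of ", length(ranked))
  structure(list(pathways = out,
                 rule_used = rule_used,
                 stats = list(candidate_linear = length(candidates),
                              conserving_linear = length(conserving),
                              candidate_branch_compounds = n_branch_cands,
                              merged = length(merged),
                              returned = length(out))),
            class = "pathway_search_result")
}

#' @export
print.pathway_search_result <- function(x, ...) {
  cat("<pathway_search_result> ", x$stats$returned, " branched pathways (",
      x$rule_used, " rule; ", x$stats$conserving_linear,
      " conserving linear pathways from ", x$stats$candidate_linear,
      " candidates)\n", sep = "")
  for (i in seq_along(x$pathways)) {
    bp <- x$pathways[[i]]
    cat(sprintf("%3d. score %.4f | %d members at {%s}\n", i, bp$score,
                length(bp$members),
                paste(bp$branched_compounds, collapse = ", ")))
  }
  invisible(x)
}
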
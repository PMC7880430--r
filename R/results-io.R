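#' Reading and writing pathway result files
#'
#' Results are serialized as a JSON object with a `query` record (the
#' search parameters) and a `branched_pathways` array. Serialization is
#' canonical — member pathways in sorted order, keys in fixed order — so
#' two calls on equal inputs produce byte-identical files and a written
#' file re-reads to an equal object.
#'
#' @name results-io
NULL

lp_to_record <- function(lp) {
  list(compounds = as.list(lp$compounds),
       reactions = as.list(pathway_reactions(lp)),
       conserved_bonds_at_target = count_minimal_groups(lp),
       score = if (is.na(lp$score)) NULL else lp$score)
}

bp_to_record <- function(bp) {
  list(score = if (is.na(bp$score)) NULL else bp$score,
       rule = bp$rule,
       branched_compounds = as.list(bp$branched_compounds),
       linear_pathways = lapply(bp$members, lp_to_record))
}

#' Write branched pathways to a result JSON file
#'
#' @param pathways list of [branched_pathway()]
#' @param path destination file
#' @param query named list recording the query (source, target,
#'   parameters); stored verbatim
#' @return `invisible(path)`
#' @export
write_results <- function(pathways, path, query = list()) {
  obj <- list(query = query,
              branched_pathways = lapply(pathways, bp_to_record))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a pathway result JSON file
#'
#' Returns the plain-list form of the file: `list(query,
#' branched_pathways)`, each branched pathway a list with `score`, `rule`,
#' `branched_compounds` and `linear_pathways` (each with `compounds`,
#' `reactions`, `conserved_bonds_at_target`, `score`). This form is
#' accepted directly by [pathway_graph()] and the comparison metrics.
#'
#' @param path file path
#' @return list with `query` and `branched_pathways`
#' @export
read_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(obj$branched_pathways)) {
    stop("not a pathway result file: missing 'branched_pathways'",
         call. = FALSE)
  }
  obj
}

#' Render a branched pathway as Graphviz DOT
#'
#' Compound nodes are ellipses, reaction nodes boxes; branched compounds
#' are highlighted.
#'
#' @param bp a [branched_pathway()]
#' @return character vector of DOT lines
#' @export
pathway_to_dot <- function(bp) {
  pg <- pathway_graph(bp)
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c("digraph branched_pathway {", "  rankdir=LR;")
  for (cpd in pg$compounds) {
    style <- if (cpd %in% bp$branched_compounds) {
      "shape=ellipse, style=filled, fillcolor=lightblue"
    } else "shape=ellipse"
    lines <- c(lines, paste0("  ", q(paste0("c", cpd)), " [", style,
                             ", label=", q(cpd), "];"))
  }
  for (rxn in pg$reactions) {
    lines <- c(lines, paste0("  ", q(paste0("r", rxn)),
                             " [shape=box, label=", q(rxn), "];"))
  }
  for (i in seq_len(nrow(pg$edges))) {
    lines <- c(lines, paste0("  ", q(pg$edges[i, 1L]), " -> ",
                             q(pg$edges[i, 2L]), ";"))
  }
  c(lines, "}")
}
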
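#' Linear and branched pathway objects
#'
#' A linear pathway is an alternating compound/reaction chain from source
#' to target, annotated with the conserved atom groups transferred from the
#' source into every compound. A branched pathway is a set of linear
#' pathways sharing source and target, joined at one or more branched
#' compounds.
#'
#' @name pathways
NULL

#' Construct a linear pathway
#'
#' @param compounds ordered compound ids (length = #reactions + 1),
#'   pairwise distinct
#' @param edges ordered list of directed edges (see [directed_edges()]);
#'   `edges[[i]]` connects `compounds[i]` to `compounds[i + 1]`
#' @param conserved per-compound propagation records from
#'   [propagate_along_path()]
#' @param score optional numeric score
#' @return object of class `linear_pathway`
#' @export
linear_pathway <- function(compounds, edges, conserved, score = NA_real_) {
  stopifnot(length(compounds) == length(edges) + 1L,
            length(conserved) == length(compounds))
  if (anyDuplicated(compounds)) {
    stop("linear pathway compounds must be pairwise distinct", call. = FALSE)
  }
  for (i in seq_along(edges)) {
    if (!identical(edges[[i]]$from, compounds[i]) ||
        !identical(edges[[i]]$to, compounds[i + 1L])) {
      stop("edge ", i, " does not connect compounds ", i, " and ", i + 1L,
           call. = FALSE)
    }
  }
  structure(list(compounds = compounds, edges = edges,
                 conserved = conserved, score = score),
            class = "linear_pathway")
}

#' Reaction ids of a linear pathway, in order
#' @param lp a `linear_pathway`
#' @return character vector
#' @export
pathway_reactions <- function(lp) {
  vapply(lp$edges, function(e) e$reaction, character(1L))
}

#' Conserved bonds of a linear pathway at a given compound
#'
#' @param lp a `linear_pathway` with propagated conserved groups
#' @param compound_id compound id; defaults to the target (last compound)
#' @return 2-column matrix of conserved bonds in that compound (empty if
#'   the compound is not on the pathway)
#' @export
conserved_bonds_at <- function(lp, compound_id = NULL) {
  if (is.null(compound_id)) compound_id <- lp$compounds[length(lp$compounds)]
  i <- match(compound_id, lp$compounds)
  if (is.na(i)) return(matrix(integer(0), ncol = 2L))
  lp$conserved[[i]]$bonds
}

#' Number of minimal atom groups transferred to the target
#'
#' A minimal atom group is one conserved covalent bond with its two atoms,
#' so the count `t` is the total number of conserved bonds at the target
#' compound. `t / e`, with `e` the source bond count, lies in `[0, 1]`.
#'
#' @param lp a `linear_pathway` with propagated conserved groups
#' @return integer `t`
#' @export
count_minimal_groups <- function(lp) {
  nrow(conserved_bonds_at(lp))
}

#' Canonical serialization key of a linear pathway
#'
#' Interleaved compound/reaction sequence with a traversal-direction
#' marker, joined on a control character; used for deterministic ordering
#' and duplicate detection.
#'
#' @param lp a `linear_pathway`
#' @return single string
#' @keywords internal
lp_key <- function(lp) {
  steps <- vapply(lp$edges, function(e) {
    paste0(e$reaction, if (e$forward) "+" else "-")
  }, character(1L))
  n <- length(lp$compounds)
  inter <- character(2L * n - 1L)
  inter[seq(1L, 2L * n - 1L, by = 2L)] <- lp$compounds
  if (n > 1L) inter[seq(2L, 2L * n - 2L, by = 2L)] <- steps
  paste(inter, collapse = "")
}

#' Construct a branched pathway
#'
#' @param members list of `linear_pathway` (>= 2), sharing source and
#'   target
#' @param branched_compounds compound ids at which members are joined;
#'   each must appear in >= 2 members and be neither source nor target
#' @param rule `"overlapping"` or `"non_overlapping"` — the merging rule
#'   that produced this pathway
#' @param score optional numeric score
#' @return object of class `branched_pathway`
#' @export
branched_pathway <- function(members, branched_compounds, rule,
                             score = NA_real_) {
  if (length(members) < 2L) {
    stop("a branched pathway needs at least two member pathways",
         call. = FALSE)
  }
  rule <- match.arg(rule, c("overlapping", "non_overlapping"))
  src <- members[[1L]]$compounds[1L]
  tgt <- members[[1L]]$compounds[length(members[[1L]]$compounds)]
  for (m in members) {
    if (!identical(m$compounds[1L], src) ||
        !identical(m$compounds[length(m$compounds)], tgt)) {
      stop("member pathways must share source and target", call. = FALSE)
    }
  }
  branched_compounds <- sort(unique(as.character(branched_compounds)),
                             method = "radix")
  if (length(branched_compounds) == 0L) {
    stop("a branched pathway needs at least one branched compound",
         call. = FALSE)
  }
  for (bc in branched_compounds) {
    n_in <- sum(vapply(members, function(m) bc %in% m$compounds, logical(1L)))
    if (bc %in% c(src, tgt) || n_in < 2L) {
      stop("'", bc, "' is not a valid branched compound (must be an ",
           "interior compound of at least two members)", call. = FALSE)
    }
  }
  # canonical member order for stable serialization
  keys <- vapply(members, lp_key, character(1L))
  members <- members[order(keys, method = "radix")]
  structure(list(members = members,
                 branched_compounds = branched_compounds,
                 rule = rule, score = score),
            class = "branched_pathway")
}

bp_key <- function(bp) {
  paste(sort(vapply(bp$members, lp_key, character(1L)), method = "radix"),
        collapse = "")
}

#' Total number of reactions across member pathways
#' @param bp a `branched_pathway`
#' @return integer
#' @keywords internal
bp_n_reactions <- function(bp) {
  sum(vapply(bp$members, function(m) length(m$edges), integer(1L)))
}

#' @export
print.linear_pathway <- function(x, ...) {
  cat("<linear_pathway> ", paste(x$compounds, collapse = " -> "), "\n",
      "  reactions: ", paste(pathway_reactions(x), collapse = ", "), "\n",
      "  conserved bonds at target: ", count_minimal_groups(x),
      if (!is.na(x$score)) paste0("\n  score: ", format(x$score)), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.branched_pathway <- function(x, ...) {
  cat("<branched_pathway> ", length(x$members), " linear pathways joined at {",
      paste(x$branched_compounds, collapse = ", "), "} [", x$rule, " rule]",
      if (!is.na(x$score)) paste0(", score ", format(x$score)), "\n",
      sep = "")
  for (m in x$members) {
    cat("  ", paste(m$compounds, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}
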
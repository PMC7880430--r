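#' Merging linear pathways into branched pathways
#'
#' Candidate branched compounds are the compounds contained in at least
#' two linear pathways, excluding source and target. At each candidate the
#' member pathways are classified by the bond structure of their conserved
#' atom groups there: pathways whose groups share bonds with the running
#' overlap are *overlapping* members, the rest are *non-overlapping*
#' members. Branched pathways are then produced by merging the members of
#' combinations of qualifying compounds under the rule in force.
#'
#' Overlap is defined at bond granularity: two conserved-group sets overlap
#' iff they share at least one bond of the branched compound. The
#' classification follows the published pseudocode literally, seeding the
#' running overlap from consecutive pathways in search-rank order; the
#' input order of `P` is therefore part of the contract.
#'
#' @name branch-merge
NULL

#' Merge configuration
#'
#' @param rule `"overlapping"` or `"non_overlapping"`
#' @param max_combo_size cap on the size of branched-compound combinations
#'   (default 3); bounds the combinatorial enumeration
#' @param max_results cap on emitted branched pathways (default 10000)
#' @return object of class `merge_config`
#' @export
merge_config <- function(rule = c("overlapping", "non_overlapping"),
                         max_combo_size = 3L, max_results = 10000L) {
  rule <- match.arg(rule)
  max_combo_size <- as.integer(max_combo_size)
  max_results <- as.integer(max_results)
  stopifnot(max_combo_size >= 1L, max_results >= 1L)
  structure(list(rule = rule, max_combo_size = max_combo_size,
                 max_results = max_results),
            class = "merge_config")
}

#' Candidate branched compounds of a pathway set
#'
#' @param P list of [linear_pathway()] sharing source and target
#' @return sorted character vector of compounds occurring in at least two
#'   pathways, excluding the shared source and target
#' @export
candidate_branch_compounds <- function(P) {
  if (length(P) == 0L) return(character(0))
  src <- P[[1L]]$compounds[1L]
  tgt <- P[[1L]]$compounds[length(P[[1L]]$compounds)]
  occ <- table(unlist(lapply(P, function(lp) unique(lp$compounds))))
  out <- names(occ)[occ >= 2L]
  sort(setdiff(out, c(src, tgt)), method = "radix")
}

# union of a pathway's conserved group bond keys at compound bn
lp_bonds_at <- function(lp, bn) bond_keys(conserved_bonds_at(lp, bn))

#' Classify pathways at a candidate branched compound
#'
#' Runs the overlap classification at `bn` over the pathways of `P` that
#' carry at least one conserved bond there, in the given order. A running
#' overlap set is seeded from the first consecutive pair of pathways and
#' intersected with each overlapping member's bond set; members sharing no
#' bond with the running overlap are classified as non-overlapping.
#'
#' @param P ordered list of [linear_pathway()]
#' @param bn a compound id from [candidate_branch_compounds()]
#' @return object of class `branch_classification`: fields `compound_id`,
#'   `overlap_members` (indices into `P`), `overlap_bonds` (shared bond
#'   keys), `nonoverlap_members`, `nonoverlap_bonds` (per-member bond-key
#'   sets), and logical flags `overlapping`, `non_overlapping`
#' @export
classify_overlap <- function(P, bn) {
  has_bn <- which(vapply(P, function(lp) length(lp_bonds_at(lp, bn)) > 0L,
                         logical(1L)))
  if (length(has_bn) < 2L) {
    stop("'", bn, "' is not a candidate branched compound of P",
         call. = FALSE)
  }
  sets <- lapply(has_bn, function(i) lp_bonds_at(P[[i]], bn))
  n <- length(has_bn)
  overlap_atom <- character(0)
  non_atom <- list()
  p_over <- integer(0)
  p_non <- integer(0)
  for (i in seq_len(n)) {
    iagt <- sets[[i]]
    if (length(overlap_atom) == 0L && i < n) {
      overlap_atom <- intersect(sets[[i]], sets[[i + 1L]])
    }
    if (length(intersect(iagt, overlap_atom)) == 0L) {
      non_atom[[length(non_atom) + 1L]] <- iagt
      p_non <- c(p_non, has_bn[i])
    } else {
      overlap_atom <- intersect(iagt, overlap_atom)
      p_over <- c(p_over, has_bn[i])
    }
  }
  structure(list(
    compound_id = bn,
    overlap_members = p_over,
    overlap_bonds = sort(overlap_atom, method = "radix"),
    nonoverlap_members = p_non,
    nonoverlap_bonds = non_atom,
    overlapping = length(overlap_atom) > 0L && length(p_over) > 1L,
    non_overlapping = length(non_atom) > 0L && length(p_non) > 1L),
    class = "branch_classification")
}

#' Merge linear pathways into branched pathways
#'
#' Classifies every candidate branched compound, keeps those qualifying
#' under `config$rule`, and enumerates non-empty combinations of them (size
#' at most `max_combo_size`, in deterministic order: increasing size, then
#' lexicographic). Each combination is merged by taking the union of the
#' per-compound member pathways; duplicates under canonical member-set
#' equality are dropped and at most `max_results` pathways are returned.
#'
#' @param P ordered list of [linear_pathway()] (search-rank order)
#' @param config a [merge_config()]
#' @return list of [branched_pathway()]; empty when no compound qualifies
#' @export
merge_pathways <- function(P, config = merge_config()) {
  if (length(P) == 0L) return(list())
  cands <- candidate_branch_compounds(P)
  members_of <- list()
  for (bn in cands) {
    n_with <- sum(vapply(P, function(lp) length(lp_bonds_at(lp, bn)) > 0L,
                         logical(1L)))
    if (n_with < 2L) next
    cls <- classify_overlap(P, bn)
    if (config$rule == "overlapping" && cls$overlapping) {
      members_of[[bn]] <- cls$overlap_members
    } else if (config$rule == "non_overlapping" && cls$non_overlapping) {
      members_of[[bn]] <- cls$nonoverlap_members
    }
  }
  if (length(members_of) == 0L) return(list())
  compounds <- sort(names(members_of), method = "radix")
  out <- list()
  seen <- character(0)
  for (size in seq_len(min(config$max_combo_size, length(compounds)))) {
    combos <- utils::combn(compounds, size, simplify = FALSE)
    for (combo in combos) {
      idx <- sort(unique(unlist(members_of[combo])))
      if (length(idx) < 2L) next
      bp <- branched_pathway(P[idx], combo, rule = config$rule)
      key <- bp_key(bp)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- bp
      if (length(out) >= config$max_results) return(out)
    }
  }
  out
}
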
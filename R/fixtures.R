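#' Synthetic atom-mapped networks with planted branched pathways
#'
#' The generator builds toy reactant-pair networks in which a known
#' branched pathway is planted: several linear routes from a source to a
#' target compound, each conserving a connected atom group of the source,
#' joined at a designated branched compound where the conserved groups
#' either share bonds (overlapping mode) or are pairwise bond-disjoint
#' (non-overlapping mode). Decoy reactions that map only non-adjacent
#' atoms onward (so no bonded pair survives) are added as negative
#' controls, directly probing the minimal-atom-group (one conserved bond)
#' filter.
#'
#' All compounds along the planted routes are structural copies of the
#' source graph and mappings are identity maps restricted to the conserved
#' piece, which makes the planted conserved groups exactly controllable:
#' the piece carried by each route is a contiguous run of atoms on the
#' source's chain backbone, so runs with shared atoms share chain bonds
#' and atom-disjoint runs are bond-disjoint.
#'
#' @name fixtures
NULL

#' Specification of a synthetic fixture
#'
#' @param n_planted_linear number of planted conserving routes (>= 2;
#'   >= 3 for `"mixed"`)
#' @param overlap_mode `"overlapping"`, `"non_overlapping"` or `"mixed"`
#'   (an overlapping pair plus bond-disjoint extra routes)
#' @param atoms_per_compound integer range (length 2) for the backbone
#'   compound size; the draw is raised if needed so every route can carry
#'   a distinct conserved piece
#' @param bond_density probability of each extra non-chain bond in the
#'   backbone graph
#' @param n_decoy_reactions number of decoy reactant pairs
#' @param n_filler_compounds extra background compounds chained by
#'   non-conserving reactions
#' @param conserved_fraction target fraction of source bonds carried by
#'   each planted route, in `(0, 1]`; every route always carries at least
#'   2 bonds
#' @param seed RNG seed; a single stream governs all randomness
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_planted_linear = 2L,
                         overlap_mode = c("overlapping", "non_overlapping",
                                          "mixed"),
                         atoms_per_compound = c(8L, 12L),
                         bond_density = 0.1,
                         n_decoy_reactions = 4L,
                         n_filler_compounds = 3L,
                         conserved_fraction = 0.4,
                         seed = 1L) {
  overlap_mode <- match.arg(overlap_mode)
  n_planted_linear <- as.integer(n_planted_linear)
  if (n_planted_linear < 2L) {
    stop("need at least two planted routes", call. = FALSE)
  }
  if (overlap_mode == "mixed" && n_planted_linear < 3L) {
    stop("mixed mode needs at least three planted routes", call. = FALSE)
  }
  if (conserved_fraction <= 0 || conserved_fraction > 1) {
    stop("conserved_fraction must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(atoms_per_compound) == 2L,
            n_decoy_reactions >= 0L, n_filler_compounds >= 0L)
  structure(list(n_planted_linear = n_planted_linear,
                 overlap_mode = overlap_mode,
                 atoms_per_compound = as.integer(atoms_per_compound),
                 bond_density = bond_density,
                 n_decoy_reactions = as.integer(n_decoy_reactions),
                 n_filler_compounds = as.integer(n_filler_compounds),
                 conserved_fraction = conserved_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# chain backbone 0-1-...-(n-1) plus random extra bonds between
# non-consecutive atoms; elements over the heavy-atom alphabet
chain_backbone <- function(n, density) {
  elements <- sample(c("C", "C", "C", "N", "O", "P", "S"), n, replace = TRUE)
  bonds <- cbind(0:(n - 2L), 1:(n - 1L))
  if (n > 2L) {
    extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    extra <- extra[extra[, 2L] - extra[, 1L] >= 2L, , drop = FALSE] - 1L
    add <- stats::runif(nrow(extra)) < density
    bonds <- rbind(bonds, extra[add, , drop = FALSE])
  }
  list(elements = elements, bonds = canonical_bonds(bonds))
}

# planted steps are written directed, as in the figure-style
# constructions they emulate; decoy and filler pairs stay reversible
identity_pair <- function(reaction, from, to, atoms, dG) {
  reactant_pair(reaction, from, to, cbind(atoms, atoms), dG = dG,
                reversible = FALSE)
}

# contiguous atom runs on the chain defining each route's conserved piece
plan_runs <- function(n, n_routes, mode, fraction) {
  target_len <- max(3L, min(n, round(fraction * (n - 1L)) + 1L))
  if (mode == "overlapping") {
    c0 <- sample.int(n - 2L, 1L) - 1L  # core atoms c0..c0+2 (2 chain bonds)
    lapply(seq_len(n_routes), function(i) {
      extend <- max(0L, target_len - 3L)
      left <- sample.int(extend + 1L, 1L) - 1L
      lo <- max(0L, c0 - left)
      # every run fully contains the core atoms c0..c0+2, so any two runs
      # share the two core chain bonds
      hi <- min(n - 1L, max(c0 + 2L, lo + target_len - 1L))
      lo:hi
    })
  } else if (mode == "non_overlapping") {
    seg <- n %/% n_routes
    len <- max(3L, min(seg, target_len))
    lapply(seq_len(n_routes), function(i) {
      base <- (i - 1L) * seg
      slack <- seg - len
      off <- if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
      (base + off):(base + off + len - 1L)
    })
  } else {  # mixed: overlapping pair on the left half, disjoint runs right
    n_dis <- n_routes - 2L
    half <- max(4L, n - 3L * n_dis)
    over <- plan_runs(half, 2L, "overlapping", fraction)
    dis <- lapply(plan_runs(n - half, n_dis, "non_overlapping", fraction),
                  function(r) r + half)
    c(over, dis)
  }
}

#' Generate a synthetic network with a planted branched pathway
#'
#' Deterministic under `spec$seed` (the caller's RNG state is restored on
#' exit). Returns the network, the intended branched pathway as ground
#' truth, and the parameters a search should use to recover it.
#'
#' @param spec a [fixture_spec()]
#' @return list with `network` ([metabolic_network()]), `ground_truth`
#'   ([branched_pathway()]), `source`, `target`, `branched_compound`, and
#'   `params` (list with `min_groups`, `rule`)
#' @export
generate_network <- function(spec) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  n_routes <- spec$n_planted_linear
  mode <- spec$overlap_mode
  lo <- spec$atoms_per_compound[1L]
  hi <- spec$atoms_per_compound[2L]
  n_min <- switch(mode,
                  overlapping = max(lo, 5L),
                  non_overlapping = max(lo, 3L * n_routes),
                  mixed = max(lo, 4L + 3L * (n_routes - 2L)))
  n <- sample(seq.int(n_min, max(n_min, hi)), 1L)
  bk <- chain_backbone(n, spec$bond_density)
  runs <- plan_runs(n, n_routes, mode, spec$conserved_fraction)

  copy_of <- function(id) molecular_graph(id, bk$elements, bk$bonds)
  compounds <- list(copy_of("S"), copy_of("T"), copy_of("B"))
  pairs <- list()
  routes <- vector("list", n_routes)
  for (i in seq_len(n_routes)) {
    atoms <- runs[[i]]
    a_id <- sprintf("A%02d", i)
    z_id <- sprintf("Z%02d", i)
    compounds <- c(compounds, list(copy_of(a_id), copy_of(z_id)))
    dGs <- round(stats::rnorm(4L, 0, 25), 1L)
    rids <- sprintf("R%02d_%d", i, 1:4)
    pairs <- c(pairs, list(
      identity_pair(rids[1L], "S", a_id, atoms, dGs[1L]),
      identity_pair(rids[2L], a_id, "B", atoms, dGs[2L]),
      identity_pair(rids[3L], "B", z_id, atoms, dGs[3L]),
      identity_pair(rids[4L], z_id, "T", atoms, dGs[4L])))
    routes[[i]] <- list(compounds = c("S", a_id, "B", z_id, "T"),
                        reactions = rids)
  }

  # an independent (pairwise non-adjacent) atom set for decoy mappings
  adj <- adjacency_matrix(compounds[[1L]])
  indep <- integer(0)
  for (a in sample.int(n) - 1L) {
    if (all(adj[a + 1L, indep + 1L] == 0L)) indep <- c(indep, a)
    if (length(indep) >= 3L) break
  }

  # decoys: short S -> D -> T chains whose first step maps only the
  # independent set, so no bonded atom pair survives it
  d_count <- 0L
  j <- 0L
  while (d_count < spec$n_decoy_reactions) {
    j <- j + 1L
    d_id <- sprintf("D%02d", j)
    compounds <- c(compounds, list(copy_of(d_id)))
    pairs <- c(pairs, list(
      reactant_pair(sprintf("RD%02d_1", j), "S", d_id,
                    cbind(indep, indep),
                    dG = round(stats::rnorm(1, 0, 25), 1),
                    reversible = TRUE)))
    d_count <- d_count + 1L
    if (d_count < spec$n_decoy_reactions) {
      pairs <- c(pairs, list(
        identity_pair(sprintf("RD%02d_2", j), d_id, "T",
                      seq_len(n) - 1L, round(stats::rnorm(1, 0, 25), 1))))
      d_count <- d_count + 1L
    }
  }

  # filler compounds chained off the source by non-conserving reactions
  prev <- "S"
  for (f in seq_len(spec$n_filler_compounds)) {
    f_id <- sprintf("F%02d", f)
    compounds <- c(compounds, list(copy_of(f_id)))
    pairs <- c(pairs, list(
      reactant_pair(sprintf("RF%02d", f), prev, f_id,
                    cbind(indep[1L], indep[1L]),
                    dG = round(stats::rnorm(1, 0, 25), 1),
                    reversible = TRUE)))
    prev <- f_id
  }

  net <- metabolic_network(compounds, pairs)

  eds <- directed_edges(net)
  edge_for <- function(rid, from) {
    for (ed in eds) {
      if (identical(ed$reaction, rid) && identical(ed$from, from)) return(ed)
    }
    stop("internal: planted edge not found")
  }
  gt_rule <- if (mode == "non_overlapping") "non_overlapping" else "overlapping"
  gt_idx <- if (mode == "mixed") 1:2 else seq_len(n_routes)
  members <- lapply(routes[gt_idx], function(rt) {
    el <- lapply(seq_along(rt$reactions), function(s) {
      edge_for(rt$reactions[s], rt$compounds[s])
    })
    linear_pathway(rt$compounds, el, propagate_along_path(net, el, "S"))
  })
  gt <- branched_pathway(members, "B", rule = gt_rule)
  list(network = net, ground_truth = gt, source = "S", target = "T",
       branched_compound = "B",
       params = list(min_groups = 2L, rule = gt_rule))
}

#' Minimal hand-coded branched-merge fixtures
#'
#' Two fixed networks realizing the two merging-rule configurations on an
#' 8-atom chain compound whose bonds `e1..e7` join atoms `(0,1)..(6,7)`:
#'
#' * `"overlapping"`: two routes through branched compound `bn1`
#'   conserving bonds `{e4, e5, e6}` and `{e5, e6, e7}`, overlapping in
#'   `{e5, e6}`;
#' * `"non_overlapping"`: two routes through `bn2` conserving the
#'   bond-disjoint sets `{e3, e4}` and `{e1}` (the latter a single minimal
#'   atom group).
#'
#' @param mode `"overlapping"` or `"non_overlapping"`
#' @return list with `network`, `expected` ([branched_pathway()]),
#'   `source`, `target`, `branched_compound`, `params`
#' @export
fig_branch_fixture <- function(mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  elements <- rep("C", 8L)
  bonds <- cbind(0:6, 1:7)
  bn <- if (mode == "overlapping") "bn1" else "bn2"
  if (mode == "overlapping") {
    atoms1 <- 3:6  # bonds e4, e5, e6
    atoms2 <- 4:7  # bonds e5, e6, e7
  } else {
    atoms1 <- 2:4  # bonds e3, e4
    atoms2 <- 0:1  # bond e1
  }
  mk <- function(id) molecular_graph(id, elements, bonds)
  compounds <- lapply(c("src", "c1", "c2", bn, "d1", "d2", "tgt"), mk)
  route <- function(i, atoms) {
    list(compounds = c("src", paste0("c", i), bn, paste0("d", i), "tgt"),
         reactions = sprintf("P%d_%d", i, 1:4),
         atoms = atoms)
  }
  routes <- list(route(1L, atoms1), route(2L, atoms2))
  pairs <- list()
  for (rt in routes) {
    for (s in 1:4) {
      pairs <- c(pairs, list(identity_pair(rt$reactions[s],
                                           rt$compounds[s],
                                           rt$compounds[s + 1L],
                                           rt$atoms, dG = -10)))
    }
  }
  net <- metabolic_network(compounds, pairs)
  eds <- directed_edges(net)
  edge_for <- function(rid, from) {
    for (ed in eds) {
      if (identical(ed$reaction, rid) && identical(ed$from, from)) return(ed)
    }
  }
  members <- lapply(routes, function(rt) {
    el <- lapply(1:4, function(s) edge_for(rt$reactions[s], rt$compounds[s]))
    linear_pathway(rt$compounds, el, propagate_along_path(net, el, "src"))
  })
  expected <- branched_pathway(members, bn, rule = mode)
  list(network = net, expected = expected, source = "src", target = "tgt",
       branched_compound = bn,
       params = list(min_groups = 1L, rule = mode))
}
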
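# Build a hand-specified linear pathway over copies of one backbone graph:
# each route maps an atom run identically along the whole chain, so its
# conserved bonds at every compound are the run's induced bonds.
planted_route <- function(backbone, route_compounds, atoms, tag) {
  mk <- function(id) molecular_graph(id, backbone$elements, backbone$bonds)
  pairs <- lapply(seq_len(length(route_compounds) - 1L), function(i) {
    reactant_pair(sprintf("%s_%d", tag, i), route_compounds[i],
                  route_compounds[i + 1L], cbind(atoms, atoms),
                  reversible = FALSE)
  })
  list(compounds = lapply(unique(route_compounds), mk), pairs = pairs,
       ids = route_compounds)
}

# assemble several routes into a network and return the linear pathways
planted_pathway_set <- function(backbone, routes) {
  all_compounds <- list()
  all_pairs <- list()
  for (r in routes) {
    for (cmp in r$compounds) {
      if (!cmp$id %in% vapply(all_compounds, function(x) x$id,
                              character(1L))) {
        all_compounds <- c(all_compounds, list(cmp))
      }
    }
    all_pairs <- c(all_pairs, r$pairs)
  }
  net <- metabolic_network(all_compounds, all_pairs)
  eds <- directed_edges(net)
  lps <- lapply(routes, function(r) {
    el <- lapply(r$pairs, function(p) {
      for (e in eds) {
        if (identical(e$reaction, p$reaction) &&
            identical(e$from, p$substrate)) return(e)
      }
    })
    linear_pathway(r$ids, el, propagate_along_path(net, el, r$ids[1L]))
  })
  list(net = net, lps = lps)
}

chain8 <- molecular_graph("bk", rep("C", 8), cbind(0:6, 1:7))

test_that("candidate branched compounds are shared interior compounds", {
  r1 <- planted_route(chain8, c("s", "a", "t"), 0:3, "P1")
  r2 <- planted_route(chain8, c("s", "b", "t"), 0:3, "P2")
  ps <- planted_pathway_set(chain8, list(r1, r2))
  expect_length(candidate_branch_compounds(ps$lps), 0L)

  r3 <- planted_route(chain8, c("s", "a", "m", "t"), 0:3, "P3")
  r4 <- planted_route(chain8, c("s", "b", "m", "t"), 0:3, "P4")
  ps2 <- planted_pathway_set(chain8, list(r3, r4))
  expect_equal(candidate_branch_compounds(ps2$lps), "m")
})

test_that("candidate selection equals brute-force occurrence counting", {
  set.seed(606)
  pool <- paste0("x", 1:6)
  for (rep in 1:10) {
    routes <- lapply(1:5, function(i) {
      mid <- sample(pool, sample(1:3, 1L))
      planted_route(chain8, c("s", mid, "t"), 0:3, paste0("Q", rep, "_", i))
    })
    ps <- planted_pathway_set(chain8, routes)
    got <- candidate_branch_compounds(ps$lps)
    occ <- table(unlist(lapply(ps$lps, function(lp) unique(lp$compounds))))
    want <- sort(setdiff(names(occ)[occ >= 2L], c("s", "t")))
    expect_equal(got, want)
  }
})

test_that("overlap classification separates shared-bond and disjoint groups", {
  # identical conserved groups at the branch: overlapping, full shared set
  r1 <- planted_route(chain8, c("s", "a", "m", "c", "t"), 0:3, "P1")
  r2 <- planted_route(chain8, c("s", "b", "m", "d", "t"), 0:3, "P2")
  ps <- planted_pathway_set(chain8, list(r1, r2))
  cls <- classify_overlap(ps$lps, "m")
  expect_true(cls$overlapping)
  expect_false(cls$non_overlapping)
  expect_equal(cls$overlap_members, c(1L, 2L))
  expect_setequal(cls$overlap_bonds, c("0-1", "1-2", "2-3"))

  # bond-disjoint groups: non-overlapping only
  r3 <- planted_route(chain8, c("s", "a", "m", "c", "t"), 0:2, "P3")
  r4 <- planted_route(chain8, c("s", "b", "m", "d", "t"), 4:6, "P4")
  ps2 <- planted_pathway_set(chain8, list(r3, r4))
  cls2 <- classify_overlap(ps2$lps, "m")
  expect_false(cls2$overlapping)
  expect_true(cls2$non_overlapping)
  expect_equal(cls2$nonoverlap_members, c(1L, 2L))

  expect_error(classify_overlap(ps2$lps, "zz"), "not a candidate")
})

test_that("three-way classification follows the running-overlap trace", {
  # routes 1 and 2 share bonds 4-5 and 5-6; route 3 is bond-disjoint
  r1 <- planted_route(chain8, c("s", "a", "m", "c", "t"), 3:6, "P1")
  r2 <- planted_route(chain8, c("s", "b", "m", "d", "t"), 4:7, "P2")
  r3 <- planted_route(chain8, c("s", "e", "m", "f", "t"), 0:2, "P3")
  ps <- planted_pathway_set(chain8, list(r1, r2, r3))
  cls <- classify_overlap(ps$lps, "m")
  expect_true(cls$overlapping)
  expect_equal(cls$overlap_members, c(1L, 2L))
  expect_setequal(cls$overlap_bonds, c("4-5", "5-6"))
  # the lone disjoint pathway cannot qualify the compound as non-overlapping
  expect_false(cls$non_overlapping)
  expect_equal(cls$nonoverlap_members, 3L)
})

test_that("merging requires a shared interior compound", {
  r1 <- planted_route(chain8, c("s", "a", "t"), 0:3, "P1")
  r2 <- planted_route(chain8, c("s", "b", "t"), 0:3, "P2")
  ps <- planted_pathway_set(chain8, list(r1, r2))
  expect_length(merge_pathways(ps$lps, merge_config("overlapping")), 0L)
  expect_length(merge_pathways(ps$lps, merge_config("non_overlapping")), 0L)
})

test_that("the overlapping rule merges routes sharing bonds at the branch", {
  fx <- fig_branch_fixture("overlapping")
  got <- merge_pathways(fx$expected$members, merge_config("overlapping"))
  expect_length(got, 1L)
  expect_equal(got[[1L]]$branched_compounds, "bn1")
  expect_length(got[[1L]]$members, 2L)
  # no merge under the non-overlapping rule
  expect_length(merge_pathways(fx$expected$members,
                               merge_config("non_overlapping")), 0L)
})

test_that("the non-overlapping rule merges bond-disjoint routes", {
  fx <- fig_branch_fixture("non_overlapping")
  got <- merge_pathways(fx$expected$members, merge_config("non_overlapping"))
  expect_length(got, 1L)
  expect_equal(got[[1L]]$branched_compounds, "bn2")
  expect_length(got[[1L]]$members, 2L)
  expect_length(merge_pathways(fx$expected$members,
                               merge_config("overlapping")), 0L)
})

test_that("combination enumeration matches the subset oracle", {
  # four routes, two branch compounds (m1 overlapping-qualifying via
  # routes 1,2; m2 via routes 3,4)
  r1 <- planted_route(chain8, c("s", "a", "m1", "c", "t"), 0:3, "P1")
  r2 <- planted_route(chain8, c("s", "b", "m1", "d", "t"), 0:3, "P2")
  r3 <- planted_route(chain8, c("s", "e", "m2", "f", "t"), 4:7, "P3")
  r4 <- planted_route(chain8, c("s", "g", "m2", "h", "t"), 4:7, "P4")
  ps <- planted_pathway_set(chain8, list(r1, r2, r3, r4))
  got <- merge_pathways(ps$lps, merge_config("overlapping",
                                             max_combo_size = 2L))
  # oracle: subsets {m1}, {m2}, {m1, m2} with unioned members
  keys <- sort(vapply(got, agtpath:::bp_key, character(1L)))
  mk_bp <- function(idx, bns) {
    branched_pathway(ps$lps[idx], bns, rule = "overlapping")
  }
  want <- sort(vapply(list(mk_bp(1:2, "m1"), mk_bp(3:4, "m2"),
                           mk_bp(1:4, c("m1", "m2"))),
                      agtpath:::bp_key, character(1L)))
  expect_equal(keys, want)
})

test_that("rule soundness holds for every emitted branched compound", {
  set.seed(707)
  fxs <- c(lapply(1:4, function(s) {
    generate_network(fixture_spec(overlap_mode = "overlapping",
                                  n_planted_linear = 3L, seed = s))
  }), lapply(5:8, function(s) {
    generate_network(fixture_spec(overlap_mode = "non_overlapping",
                                  n_planted_linear = 3L, seed = s))
  }))
  for (fx in fxs) {
    lps <- find_linear_conserving(fx$network, "S", "T",
                                  search_params(k = 200, min_groups = 2))
    for (rule in c("overlapping", "non_overlapping")) {
      bps <- merge_pathways(lps, merge_config(rule))
      for (bp in bps) {
        expect_gte(length(bp$members), 2L)
        expect_gte(length(bp$branched_compounds), 1L)
        for (bn in bp$branched_compounds) {
          sets <- lapply(bp$members, function(m) {
            agtpath:::bond_keys(conserved_bonds_at(m, bn))
          })
          sets <- sets[vapply(sets, length, integer(1L)) > 0L]
          if (rule == "non_overlapping") {
            # pairwise bond-disjoint at the branch compound
            for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
              expect_length(intersect(sets[[i]], sets[[j]]), 0L)
            }
          } else {
            # a common non-empty intersection across overlap members
            common <- Reduce(intersect, sets)
            expect_gt(length(common), 0L)
          }
        }
      }
      # duplicate-free under canonical-form equality
      keys <- vapply(bps, agtpath:::bp_key, character(1L))
      expect_false(anyDuplicated(keys) > 0L)
    }
  }
})

test_that("decoy pathways that avoid branch compounds do not change merges", {
  r1 <- planted_route(chain8, c("s", "a", "m", "c", "t"), 0:3, "P1")
  r2 <- planted_route(chain8, c("s", "b", "m", "d", "t"), 0:3, "P2")
  r5 <- planted_route(chain8, c("s", "q", "t"), 4:6, "P5")
  ps_with <- planted_pathway_set(chain8, list(r1, r2, r5))
  ps_perm <- planted_pathway_set(chain8, list(r5, r1, r2))
  key_set <- function(ps) {
    sort(vapply(merge_pathways(ps$lps, merge_config("overlapping")),
                agtpath:::bp_key, character(1L)))
  }
  expect_equal(key_set(ps_with), key_set(ps_perm))
})
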
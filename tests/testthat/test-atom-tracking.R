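test_that("candidate edge matrix marks pairs with adjacent images", {
  # no mappings, no candidates
  MA <- matrix(0L, 3, 3); MA[1, 2] <- MA[2, 1] <- 1L
  MB <- MA
  expect_true(all(candidate_edge_matrix(MA, MB, matrix(0L, 3, 3)) == 0L))
  # single shared edge under the identity mapping
  MA2 <- matrix(0L, 2, 2); MA2[1, 2] <- MA2[2, 1] <- 1L
  MC <- candidate_edge_matrix(MA2, MA2, diag(2))
  expect_equal(MC, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(candidate_edge_matrix(MA, MB, matrix(0L, 2, 3)),
               "conform")
})

test_that("candidate edge matrix equals the adjacent-image brute force", {
  set.seed(101)
  for (rep in 1:30) {
    fx <- random_pair_fixture(n_sub = 5L, n_prod = 5L)
    MA <- adjacency_matrix(fx$sub)
    MB <- adjacency_matrix(fx$prod)
    m <- fx$pair$mapping
    M <- matrix(0L, 5, 5)
    if (nrow(m) > 0L) M[m + 1L] <- 1L
    MC <- candidate_edge_matrix(MA, MB, M)
    img <- function(x) {
      i <- match(x, m[, 1L])
      if (is.na(i)) NA_integer_ else m[i, 2L]
    }
    for (u in 0:4) for (v in 0:4) {
      iu <- img(u); iv <- img(v)
      want <- !is.na(iu) && !is.na(iv) && MB[iu + 1L, iv + 1L] == 1L
      expect_equal(MC[u + 1L, v + 1L], as.integer(want))
    }
  }
})

test_that("conserved bonds are the correctly mapped substrate bonds", {
  # identity pair: every substrate bond is conserved
  g <- molecular_graph("g", c("C", "C", "O", "N"),
                       list(c(0, 1), c(1, 2), c(1, 3)))
  all_atoms <- 0:3
  expect_equal(conserved_bonds(g, g, cbind(all_atoms, all_atoms)), g$bonds)
  # mapping only one endpoint of every bond conserves nothing
  expect_equal(nrow(conserved_bonds(g, g, cbind(c(0L, 2L, 3L), c(0L, 2L, 3L)))),
               0L)
})

test_that("conserved bonds match brute-force enumeration on random pairs", {
  set.seed(202)
  for (rep in 1:150) {
    fx <- random_pair_fixture(n_sub = sample(2:6, 1L),
                              n_prod = sample(2:6, 1L))
    expect_equal(conserved_bonds(fx$sub, fx$prod, fx$pair$mapping),
                 brute_conserved_bonds(fx$sub, fx$prod, fx$pair$mapping))
  }
})

test_that("conserved atom groups are the components of the conserved bonds", {
  # identity pair on a connected compound: one group spanning all bonds
  g <- molecular_graph("g", rep("C", 6), list(c(0, 1), c(1, 2), c(2, 3),
                                              c(3, 4), c(4, 5)))
  net <- metabolic_network(
    list(g, molecular_graph("h", g$elements, g$bonds)),
    list(reactant_pair("R", "g", "h", cbind(0:5, 0:5))))
  grps <- conserved_atom_groups(net, net$reactant_pairs[[1L]])
  expect_length(grps, 1L)
  expect_equal(grps[[1L]]$atoms, 0:5)
  expect_equal(nrow(grps[[1L]]$bonds), 5L)

  # mapping that keeps two separate edges: two one-bond groups
  net2 <- metabolic_network(
    list(g, molecular_graph("h", g$elements, g$bonds)),
    list(reactant_pair("R", "g", "h", cbind(c(0L, 1L, 3L, 4L),
                                            c(0L, 1L, 3L, 4L)))))
  grps2 <- conserved_atom_groups(net2, net2$reactant_pairs[[1L]])
  expect_length(grps2, 2L)
  expect_equal(vapply(grps2, function(x) nrow(x$bonds), integer(1L)),
               c(1L, 1L))
  # deterministic order: by smallest atom index
  expect_equal(vapply(grps2, function(x) x$atoms[1L], integer(1L)),
               c(0L, 3L))
})

test_that("a six-atom fragment mapped intact forms a single atom group", {
  # pyruvate-like fragment embedded in a larger substrate; the fragment is
  # mapped intact, the rest of the substrate is not mapped
  sub <- molecular_graph("sub", c(rep("C", 3), "O", "O", "O", "C", "N"),
                         list(c(0, 1), c(1, 2), c(1, 3), c(0, 4), c(0, 5),
                              c(6, 7)))
  prod <- molecular_graph("prod", c(rep("C", 3), "O", "O", "O", "S"),
                          list(c(0, 1), c(1, 2), c(1, 3), c(0, 4), c(0, 5),
                               c(5, 6)))
  net <- metabolic_network(
    list(sub, prod),
    list(reactant_pair("R", "sub", "prod", cbind(0:5, 0:5))))
  grps <- conserved_atom_groups(net, net$reactant_pairs[[1L]])
  expect_length(grps, 1L)
  expect_length(grps[[1L]]$atoms, 6L)
  expect_equal(nrow(grps[[1L]]$bonds), 5L)
})

test_that("mapping composition behaves algebraically", {
  m1 <- cbind(c(0L, 1L, 2L), c(2L, 0L, 1L))
  id <- cbind(0:2, 0:2)
  expect_equal(compose_mappings(m1, id), m1)
  expect_equal(compose_mappings(id, m1), m1)
  # disjoint maps compose to the empty map
  expect_equal(nrow(compose_mappings(cbind(0L, 2L), cbind(1L, 5L))), 0L)
  # associativity on random chains
  set.seed(303)
  for (rep in 1:25) {
    rand_map <- function() {
      k <- sample(0:5, 1L)
      if (k == 0L) return(matrix(integer(0), ncol = 2L))
      cbind(sample(0:7, k), sample(0:7, k))
    }
    a <- rand_map(); b <- rand_map(); c <- rand_map()
    expect_equal(compose_mappings(compose_mappings(a, b), c),
                 compose_mappings(a, compose_mappings(b, c)))
  }
})

test_that("propagation along a path tracks surviving source bonds", {
  g <- molecular_graph("g", rep("C", 5),
                       list(c(0, 1), c(1, 2), c(2, 3), c(3, 4)))
  # zero-length path: the whole source as its components
  chain <- identity_chain_network(g, 3L)
  prop0 <- propagate_along_path(chain$net, list(), "K1")
  expect_length(prop0, 1L)
  expect_equal(prop0[[1L]]$bonds, g$bonds)
  expect_length(prop0[[1L]]$groups, 1L)

  # identity chain: conserved set constant along the path
  eds <- directed_edges(chain$net)
  prop <- propagate_along_path(chain$net, eds, "K1")
  expect_length(prop, 4L)
  for (entry in prop) expect_equal(entry$bonds, g$bonds)
})

test_that("a bond dropped at step two strictly decreases conservation there", {
  g <- molecular_graph("g", rep("C", 4), list(c(0, 1), c(1, 2), c(2, 3)))
  mk <- function(id) molecular_graph(id, g$elements, g$bonds)
  # step 1 identity; step 2 drops atom 3 (loses bond 2-3); step 3 identity
  pairs <- list(
    reactant_pair("R1", "a", "b", cbind(0:3, 0:3), reversible = FALSE),
    reactant_pair("R2", "b", "c", cbind(0:2, 0:2), reversible = FALSE),
    reactant_pair("R3", "c", "d", cbind(0:3, 0:3), reversible = FALSE))
  net <- metabolic_network(list(mk("a"), mk("b"), mk("c"), mk("d")), pairs)
  eds <- directed_edges(net)
  prop <- propagate_along_path(net, eds, "a")
  counts <- vapply(prop, function(e) nrow(e$bonds), integer(1L))
  expect_equal(counts, c(3L, 3L, 2L, 2L))
  # stepwise brute-force recomputation agrees at every position
  surviving <- g$bonds
  for (i in seq_along(eds)) {
    sub <- net$compounds[[eds[[i]]$from]]
    prod <- net$compounds[[eds[[i]]$to]]
    step <- brute_conserved_bonds(sub, prod, eds[[i]]$mapping)
    step_keys <- apply(step, 1L, paste, collapse = "-")
    keep <- apply(surviving, 1L, paste, collapse = "-") %in% step_keys
    surviving <- surviving[keep, , drop = FALSE]
    m <- eds[[i]]$mapping
    if (nrow(surviving) > 0L) {
      surviving <- cbind(m[match(surviving[, 1L], m[, 1L]), 2L],
                         m[match(surviving[, 2L], m[, 1L]), 2L])
      surviving <- agtpath:::canonical_bonds(surviving)
    }
    expect_equal(prop[[i + 1L]]$bonds, surviving)
  }
})

test_that("conserved bond counts never increase along random paths", {
  set.seed(404)
  for (rep in 1:20) {
    g <- random_graph("g", 6L, 0.5)
    mk <- function(id) molecular_graph(id, g$elements, g$bonds)
    ids <- paste0("n", 1:4)
    pairs <- lapply(1:3, function(i) {
      kept <- sort(sample(0:5, sample(3:6, 1L)))
      reactant_pair(paste0("R", i), ids[i], ids[i + 1L], cbind(kept, kept),
                    reversible = FALSE)
    })
    net <- metabolic_network(lapply(ids, mk), pairs)
    prop <- propagate_along_path(net, directed_edges(net), "n1")
    counts <- vapply(prop, function(e) nrow(e$bonds), integer(1L))
    expect_true(all(diff(counts) <= 0L))
    # every emitted group is connected and lies inside its compound
    for (entry in prop) {
      for (grp in entry$groups) {
        cmp_bonds <- apply(net$compounds[[entry$compound_id]]$bonds, 1L,
                           paste, collapse = "-")
        expect_true(all(apply(grp$bonds, 1L, paste, collapse = "-")
                        %in% cmp_bonds))
        expect_gte(nrow(grp$bonds), 1L)
      }
    }
  }
})
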
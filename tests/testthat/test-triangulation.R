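test_that("greedy family takes every separator when all are parallel", {
  D1 <- legal_minimal_separators(fx$F1)
  Q1 <- greedy_parallel_family(D1)
  expect_length(Q1, 5L)            # = 2n - 3 at n = 4
  expect_length(greedy_parallel_family(legal_minimal_separators(fx$F2)), 3L)
  D3 <- legal_minimal_separators(fx$F3)
  Q3 <- greedy_parallel_family(D3)
  expect_length(Q3, 1L)
  expect_length(Q3$members[[1]]$vertices, 0L)
})

test_that("saturation adds exactly the missing in-separator pairs", {
  D1 <- legal_minimal_separators(fx$F1)
  H1 <- saturate(D1$G, greedy_parallel_family(D1))
  expect_equal(nrow(H1$fill_edges), 1L)
  expect_setequal(D1$G$label[H1$fill_edges[1, ]], c("c1_s0", "c2_s0"))
  # the unique fill edge coincides with the F-edge of the augmented graph
  G2 <- augmented_pig(fx$F1)
  expect_true(G2$kind[H1$fill_edges[1, 1], H1$fill_edges[1, 2]] == "F")
  expect_true(is_chordal_graph(H1))
  D2 <- legal_minimal_separators(fx$F2)
  expect_equal(nrow(saturate(D2$G, greedy_parallel_family(D2))$fill_edges), 0L)
  D3 <- legal_minimal_separators(fx$F3)
  expect_equal(nrow(saturate(D3$G, greedy_parallel_family(D3))$fill_edges), 0L)
})

test_that("MCS clique tree handles the textbook cases", {
  path <- matrix(FALSE, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- TRUE
  ct <- mcs_clique_tree(path)
  expect_length(ct$cliques, 2L)
  expect_setequal(lapply(ct$cliques, sort), list(c(1L, 2L), c(2L, 3L)))
  expect_equal(ct$separators[[1]], 2L)
  triangle <- matrix(TRUE, 3, 3); diag(triangle) <- FALSE
  ct2 <- mcs_clique_tree(triangle)
  expect_length(ct2$cliques, 1L)
  expect_equal(nrow(ct2$edges), 0L)
  square <- matrix(FALSE, 4, 4)
  square[cbind(c(1, 2, 3, 4), c(2, 3, 4, 1))] <- TRUE
  square <- square | t(square)
  expect_error(mcs_clique_tree(square), class = "pp_not_chordal_error")
  expect_false(is_chordal_graph(square))
  expect_true(is_chordal_graph(triangle))
})

test_that("the F1 clique tree is the hand-derived 6-clique tree", {
  D <- legal_minimal_separators(fx$F1)
  G <- D$G
  H <- saturate(G, greedy_parallel_family(D))
  ct <- mcs_clique_tree(H)
  expect_length(ct$cliques, 6L)
  keys <- sep_keys(ct$cliques, G)
  # the four taxon-row cliques plus the two Steiner species
  expect_setequal(keys, c(
    "c0_s0|c1_s0|c2_s1", "c0_s1|c1_s0|c2_s2", "c0_s1|c1_s1|c2_s0",
    "c0_s0|c1_s2|c2_s0", "c0_s0|c1_s0|c2_s0", "c0_s1|c1_s0|c2_s0"))
  # the five edge intersections are exactly the separator set
  expect_equal(nrow(ct$edges), 5L)
  expect_setequal(sep_keys(ct$separators, G), sep_keys(D$separators, G))
  expect_false(any(ct$artificial))
})

test_that("clique trees satisfy the subtree and separator properties", {
  for (inst in random_instances(56:70)) {
    M <- inst$matrix
    D <- legal_minimal_separators(M)
    H <- saturate(D$G, greedy_parallel_family(D))
    ct <- mcs_clique_tree(H)
    expect_lte(nrow(ct$edges), 2L * M$n - 3L)
    # every vertex's cliques form a connected subtree
    for (v in seq_len(D$G$n_vertices)) {
      nodes <- which(vapply(ct$cliques, function(K) v %in% K, logical(1)))
      expect_true(perfectphylo:::nodes_connected(nodes, ct$edges))
    }
    # every non-artificial edge intersection is a minimal separator of H
    oracle <- sep_keys(brute_minimal_separators(H, method = "neighborhood"),
                       D$G)
    real <- !ct$artificial
    expect_true(all(sep_keys(ct$separators[real], D$G) %in% oracle))
    # cliques really are maximal cliques
    for (K in ct$cliques) {
      expect_true(all(H$adj[K, K] | diag(length(K))))
      outside <- setdiff(seq_len(D$G$n_vertices), K)
      expect_false(any(vapply(outside, function(u) all(H$adj[u, K]),
                              logical(1))))
    }
  }
})

test_that("assembled fixture phylogenies match the derived trees", {
  t1 <- construct_phylogeny(fx$F1)
  expect_equal(t1$n_nodes, 6L)
  sp <- apply(t1$species, 1, paste, collapse = ",")
  expect_true(all(c("0,0,0", "1,0,0") %in% sp))   # the two Steiner species
  expect_false(anyNA(t1$species))
  expect_true(verify_phylogeny(fx$F1, t1))
  # t1 and t2 hang off the two Steiner nodes u=(0,0,0), v=(1,0,0)
  u <- which(sp == "0,0,0"); v <- which(sp == "1,0,0")
  ek <- apply(t1$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_true(paste(sort(c(u, v)), collapse = "-") %in% ek)

  t2 <- construct_phylogeny(fx$F2)
  expect_equal(t2$n_nodes, 4L)
  expect_true(all(seq_len(4) %in% t2$node_of_taxon))  # all nodes taxon-labeled
  deg <- tabulate(c(t2$edges), nbins = 4)
  expect_equal(sort(deg), c(1L, 1L, 2L, 2L))          # a path
  expect_true(verify_phylogeny(fx$F2, t2))

  t3 <- construct_phylogeny(fx$F3)
  expect_equal(t3$n_nodes, 3L)
  expect_equal(sum(t3$artificial), 2L)                # forest joined artificially
  expect_true(verify_phylogeny(fx$F3, t3))
})

test_that("construct rejects incompatible fixtures with the right witness", {
  r4 <- construct_phylogeny(fx$F4)
  expect_s3_class(r4, "incompatibility_report")
  expect_equal(r4$step, 1L)
  expect_equal(r4$witness$characters, c(0L, 1L))
  r5 <- construct_phylogeny(fx$F5)
  expect_equal(r5$step, 3L)
  expect_length(r5$witness$vertices, 2L)
})

test_that("verify_phylogeny catches broken trees", {
  # star with all-ancestral center: state c0_s1 sits on two non-adjacent leaves
  star <- structure(list(
    n_nodes = 5L,
    species = rbind(c(0L, 0L, 0L), fx$F1$states),
    node_names = paste0("N", 0:4),
    edges = cbind(1L, 2:5), artificial = rep(FALSE, 4),
    node_of_taxon = 2:5, taxa = fx$F1$taxa,
    characters = fx$F1$characters), class = "perfect_phylogeny")
  ok <- verify_phylogeny(fx$F1, star)
  expect_false(ok)
  expect_match(paste(attr(ok, "violations"), collapse = " "), "not convex")
  # single-taxon matrix on its single-node tree
  M1 <- suppressWarnings(character_matrix(rbind(t1 = c(0, 1))))
  tr1 <- construct_phylogeny(M1)
  expect_equal(tr1$n_nodes, 1L)
  expect_true(verify_phylogeny(M1, tr1))
})

test_that("saturation succeeds for any greedy order and is minimal", {
  for (name in c("F1", "F2", "F3")) {
    M <- fx[[name]]
    D <- legal_minimal_separators(M)
    fills <- list()
    for (seed in 1:20) {
      Q <- greedy_parallel_family(D, seed = seed)
      H <- saturate(D$G, Q)
      expect_true(is_chordal_graph(H))
      adj <- H$adj; storage.mode(adj) <- "integer"
      fill <- H$fill_edges; storage.mode(fill) <- "integer"
      expect_true(perfectphylo:::cpp_is_minimal_fill(adj, fill))
      fills[[seed]] <- nrow(H$fill_edges)
    }
  }
})

test_that("newick output round-trips through ape and the label table", {
  tr <- construct_phylogeny(fx$F1)
  nwk <- tempfile(fileext = ".nwk"); lab <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(nwk, lab)))
  write_phylogeny(tr, nwk, lab)
  expect_match(readLines(nwk), "^\\(.*\\)N\\d+;$")
  phy <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(phy) + phy$Nnode, tr$n_nodes)
  back <- read_phylogeny(nwk, lab, fx$F1)
  expect_true(verify_phylogeny(fx$F1, back))
  expect_equal(sort(apply(back$species, 1, paste, collapse = ",")),
               sort(apply(tr$species, 1, paste, collapse = ",")))
  # as_phylo agrees with what ape parsed
  phy2 <- as_phylo(tr)
  expect_s3_class(phy2, "phylo")
  expect_equal(sort(phy2$tip.label), sort(phy$tip.label))
  # a two-node tree still writes valid newick without ape
  M2 <- character_matrix(cbind(c1 = c(0, 1)), taxa = c("t1", "t2"))
  tr2 <- construct_phylogeny(M2)
  expect_equal(unname(write_phylogeny(tr2)[1]),
               paste0(perfectphylo:::newick_string(tr2), ";"))
})

test_that("species entries for characters absent from a clique stay missing", {
  # two characters private to disjoint taxa: Steiner-free but disconnected
  M <- character_matrix(rbind(t1 = c(0, 0), t2 = c(1, 0), t3 = c(2, 1)))
  tr <- construct_phylogeny(M)
  expect_true(verify_phylogeny(M, tr))
})
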
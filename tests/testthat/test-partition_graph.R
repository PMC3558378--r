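test_that("taxon rows induce cliques and F3 is three disjoint edges", {
  G <- partition_intersection_graph(fx$F3)
  expect_equal(G$n_vertices, 6L)
  expect_equal(sum(G$adj) / 2, 3)
  expect_equal(max(perfectphylo:::graph_components(G$adj)), 3L)
  # a taxon row is a clique of size m
  G1 <- partition_intersection_graph(fx$F1)
  for (ids in G1$taxa_cliques)
    expect_true(all(G1$adj[ids, ids] | diag(3) == 1))
})

test_that("M* adjacency follows the shared-taxon rule", {
  M <- mstar_matrix(7)
  G <- partition_intersection_graph(M)
  v <- function(name, state)
    pig_vertex_id(G, match(name, M$characters) - 1L, state)
  # cell 1 of c3.5 and cell 1 of c4.6 share taxon t5
  expect_true(G$adj[v("c3.5", 1L), v("c4.6", 1L)])
  # cell 0 of c3.5 and cell 1 of c4.6 share no taxon
  expect_false(G$adj[v("c3.5", 0L), v("c4.6", 1L)])
})

test_that("induced subgraph equals the pig of the column submatrix", {
  G <- partition_intersection_graph(fx$F1)
  sub <- induced_character_subgraph(G, c(0L, 1L))
  direct <- partition_intersection_graph(
    character_matrix(fx$F1$states[, 1:2]))
  expect_equal(sub$adj, direct$adj)
  expect_equal(sub$char, direct$char)
  # one character: edgeless
  expect_equal(sum(induced_character_subgraph(G, 1L)$adj), 0)
  # F4 on both characters is the four-gamete 4-cycle
  G4 <- partition_intersection_graph(fx$F4)
  cyc <- chordless_cycles(G4)
  expect_length(cyc, 1L)
  expect_length(cyc[[1]], 4L)
})

test_that("cyclic_character_pairs flags exactly the cyclic pairs", {
  expect_equal(cyclic_character_pairs(fx$F4), rbind(c(0L, 1L)))
  expect_equal(nrow(cyclic_character_pairs(fx$F5)), 0L)
  expect_equal(nrow(cyclic_character_pairs(fx$F1)), 0L)
})

test_that("chordless cycle enumeration matches the hand-derived cycles", {
  G1 <- partition_intersection_graph(fx$F1)
  cyc <- chordless_cycles(G1)
  expect_length(cyc, 1L)
  expect_setequal(G1$label[cyc[[1]]], c("c0_s0", "c1_s0", "c0_s1", "c2_s0"))
  # colors: character 0 twice, characters 1 and 2 once
  expect_equal(sort(table(G1$char[cyc[[1]]])), sort(c(`0` = 2, `1` = 1, `2` = 1)),
               ignore_attr = TRUE)
  G5 <- partition_intersection_graph(fx$F5)
  keys <- vapply(chordless_cycles(G5), function(cy)
    paste(sort(G5$label[cy]), collapse = "|"), character(1))
  expect_true(paste(sort(c("c0_s0", "c1_s0", "c0_s1", "c2_s0", "c1_s1")),
                    collapse = "|") %in% keys)
  # chordal graphs have none: two disjoint taxon triangles
  Gtri <- partition_intersection_graph(
    character_matrix(rbind(c(0, 0, 0), c(1, 1, 1))))
  expect_length(chordless_cycles(Gtri), 0L)
})

test_that("augmented graph adds exactly the forced chords", {
  G <- augmented_pig(fx$F1)
  fedges <- which(G$kind == "F" & upper.tri(G$kind), arr.ind = TRUE)
  expect_equal(nrow(fedges), 1L)
  expect_setequal(G$label[fedges[1, ]], c("c1_s0", "c2_s0"))
  expect_equal(sum(augmented_pig(fx$F2)$kind == "F"), 0L)
  expect_equal(sum(augmented_pig(fx$F3)$kind == "F"), 0L)
  expect_error(augmented_pig(fx$F4), class = "pp_obstruction_error")
})

test_that("graphs of compatible matrices satisfy the chordless-cycle structure", {
  # on the augmented graph: no chordless cycle may use an F-edge, and
  # all-E chordless cycles have length four with four distinct colors
  for (inst in random_instances(1:20)) {
    M <- inst$matrix
    G <- partition_intersection_graph(M)
    expect_false(any(G$adj & outer(G$char, G$char, "==")))
    expect_equal(G$n_vertices, sum(G$arities))
    expect_lte(G$n_vertices, 3L * M$m)
    G2 <- augmented_pig(M)
    for (cy in chordless_cycles(G2)) {
      kinds <- G2$kind[cbind(cy, cy[c(2:length(cy), 1)])]
      expect_false(any(kinds == "F"))
      expect_length(cy, 4L)
      expect_length(unique(G2$char[cy]), 4L)
    }
  }
})

test_that("M* edges are exactly the cell intersections (exhaustive, n <= 8)", {
  for (n in 4:8) {
    M <- mstar_matrix(n)
    G <- partition_intersection_graph(M)
    ij <- t(combn(n - 1L, 2))
    cells <- function(r) {
      i <- ij[r, 1]; j <- ij[r, 2]
      list(seq_len(i), seq(i + 1L, j), seq(j + 1L, n))
    }
    mismatches <- 0L
    for (r1 in seq_len(nrow(ij) - 1L)) {
      for (r2 in seq(r1 + 1L, nrow(ij))) {
        c1 <- cells(r1); c2 <- cells(r2)
        for (k1 in 1:3) for (k2 in 1:3) {
          expected <- length(intersect(c1[[k1]], c2[[k2]])) > 0
          u <- pig_vertex_id(G, r1 - 1L, k1 - 1L)
          v <- pig_vertex_id(G, r2 - 1L, k2 - 1L)
          if (G$adj[u, v] != expected) mismatches <- mismatches + 1L
        }
      }
    }
    expect_equal(mismatches, 0L, info = paste("n =", n))
  }
})

test_that("graph export writes a readable edge list", {
  G <- partition_intersection_graph(fx$F3)
  f <- tempfile()
  on.exit(unlink(f))
  export_graph(G, f, format = "tsv")
  df <- read.delim(f)
  expect_equal(nrow(df), 3L)
  expect_true(all(df$kind == "E"))
  export_graph(G, f, format = "dot")
  expect_match(readLines(f)[1], "graph pig")
})
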
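test_that("proper clusters of the fixtures have the derived splitting vectors", {
  G1 <- partition_intersection_graph(fx$F1)
  pc1 <- proper_clusters(fx$F1)
  expect_length(pc1, 5L)
  expect_setequal(
    sep_keys(lapply(pc1, `[[`, "splitting_vector"), G1),
    c("c1_s0|c2_s0", "c0_s1|c2_s0", "c0_s0|c2_s0", "c0_s0|c1_s0",
      "c0_s1|c1_s0"))
  G2 <- partition_intersection_graph(fx$F2)
  pc2 <- proper_clusters(fx$F2)
  expect_setequal(
    sep_keys(lapply(pc2, `[[`, "splitting_vector"), G2),
    c("c1_s0|c2_s0", "c0_s1|c2_s0", "c0_s1|c1_s1"))
  # F3: every split shares nothing, so splitting vectors are empty
  pc3 <- proper_clusters(fx$F3)
  expect_true(any(lengths(lapply(pc3, `[[`, "splitting_vector")) == 0L))
  # every cluster names a witness character sharing no state
  for (p in c(pc1, pc2, pc3)) expect_false(is.na(p$witness_character))
})

test_that("s_partition groups taxa by off-separator shared states", {
  G1 <- partition_intersection_graph(fx$F1)
  expect_equal(s_partition(fx$F1, vid(G1, c("c1_s0", "c2_s0"))),
               c(1L, 2L, 2L, 1L))
  expect_equal(s_partition(fx$F3, integer(0)), c(1L, 2L, 3L))
  G2 <- partition_intersection_graph(fx$F2)
  expect_equal(s_partition(fx$F2, vid(G2, c("c0_s1", "c2_s0"))),
               c(1L, 1L, 2L, 2L))
  expect_error(s_partition(fx$F1, vid(G1, c("c0_s0", "c0_s1"))),
               class = "pp_parameter_error")
})

test_that("separator_from_cluster certifies full components", {
  G1 <- partition_intersection_graph(fx$F1)
  pc <- proper_clusters(fx$F1)
  key <- sep_keys(lapply(pc, `[[`, "splitting_vector"), G1)
  s <- separator_from_cluster(fx$F1, pc[[which(key == "c0_s1|c2_s0")]])
  expect_s3_class(s, "pp_separator")
  singleton <- Filter(function(co) length(co$vertices) == 1L, s$components)
  expect_length(singleton, 1L)
  expect_equal(G1$label[singleton[[1]]$vertices], "c1_s1")
  expect_true(singleton[[1]]$full)
  expect_equal(singleton[[1]]$taxa, 3L)
  other <- Filter(function(co) length(co$vertices) > 1L, s$components)
  expect_true(other[[1]]$full)
  expect_equal(other[[1]]$taxa, c(1L, 2L, 4L))
  # F3 with the empty vector: three components, all full
  s3 <- perfectphylo:::build_separator(fx$F3, integer(0))
  expect_length(s3$components, 3L)
  expect_true(all(vapply(s3$components, `[[`, logical(1), "full")))
})

test_that("legal minimal separators match the brute oracle on fixtures", {
  for (name in c("F1", "F2", "F3", "F5")) {
    M <- fx[[name]]
    D <- legal_minimal_separators(M)
    G <- D$G
    brute <- Filter(
      function(s) !anyDuplicated(G$char[s]) && length(s) < M$m,
      brute_minimal_separators(G, method = "subset"))
    expect_setequal(sep_keys(D$separators, G), sep_keys(brute, G))
  }
  expect_equal(sep_keys(legal_minimal_separators(fx$F1)$separators,
                        partition_intersection_graph(fx$F1)),
               c("c0_s0|c1_s0", "c0_s0|c2_s0", "c0_s1|c1_s0", "c0_s1|c2_s0",
                 "c1_s0|c2_s0"))
  expect_length(legal_minimal_separators(fx$F2)$separators, 3L)
  # F3: exactly the empty separator
  D3 <- legal_minimal_separators(fx$F3)
  expect_length(D3$separators, 1L)
  expect_length(D3$separators[[1]]$vertices, 0L)
})

test_that("legal minimal separators equal the brute set on exhaustive n=4, m<=3 instances", {
  cols <- perfectphylo:::four_taxa_columns()
  expect_length(cols, 13L)
  count <- 0L
  for (id in seq_len(2L^13 - 1L)) {
    idx <- which(bitwAnd(id, 2L^(0:12)) > 0L)
    if (length(idx) > 3L) next
    count <- count + 1L
    M <- character_matrix(do.call(cbind, cols[idx]))
    D <- legal_minimal_separators(M)
    G <- D$G
    brute <- Filter(
      function(s) !anyDuplicated(G$char[s]) && length(s) < M$m,
      brute_minimal_separators(G, method = "subset"))
    expect_setequal(sep_keys(D$separators, G), sep_keys(brute, G))
  }
  expect_equal(count, choose(13, 1) + choose(13, 2) + choose(13, 3))
})

test_that("unseparated monochromatic pairs decide compatibility", {
  D1 <- legal_minimal_separators(fx$F1)
  expect_equal(nrow(unseparated_monochromatic_pairs(fx$F1, D1)), 0L)
  D3 <- legal_minimal_separators(fx$F3)
  expect_equal(nrow(unseparated_monochromatic_pairs(fx$F3, D3)), 0L)
  D5 <- legal_minimal_separators(fx$F5)
  un <- unseparated_monochromatic_pairs(fx$F5, D5)
  expect_gt(nrow(un), 0L)
  # witnesses are genuine monochromatic pairs
  expect_true(all(D5$G$char[un[, 1]] == D5$G$char[un[, 2]]))
})

test_that("are_parallel agrees with the brute component-containment test", {
  for (name in c("F1", "F2", "F3")) {
    D <- legal_minimal_separators(fx[[name]])
    k <- length(D$separators)
    par <- crossing_relation(D)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      expect_equal(par[i, j],
                   brute_is_parallel(D$G, D$separators[[i]]$vertices,
                                     D$separators[[j]]$vertices),
                   info = paste(name, i, j))
    }
    expect_true(all(diag(par)))
    expect_equal(par, t(par))
  }
  for (inst in random_instances(21:35)) {
    D <- legal_minimal_separators(inst$matrix)
    par <- crossing_relation(D)
    k <- length(D$separators)
    brute <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      brute_is_parallel(D$G, D$separators[[i]]$vertices,
                        D$separators[[j]]$vertices)))
    expect_equal(unname(par), unname(brute), info = paste("seed", inst))
  }
})

test_that("F1 separators are all pairwise parallel, as its path phylogeny requires", {
  D <- legal_minimal_separators(fx$F1)
  expect_true(all(crossing_relation(D)))
  expect_true(all(crossing_relation(legal_minimal_separators(fx$F2))))
})

test_that("separator-set size and member-size bounds hold on generated data", {
  for (inst in random_instances(36:55)) {
    M <- inst$matrix
    D <- legal_minimal_separators(M)
    expect_lte(length(D$separators), 3L * M$m)
    for (s in D$separators) {
      expect_lt(length(s$vertices), M$m)
      expect_false(anyDuplicated(D$G$char[s$vertices]) > 0)
      expect_gte(sum(vapply(s$components, `[[`, logical(1), "full")), 2L)
    }
  }
})
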
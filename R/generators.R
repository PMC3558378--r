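# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# random unrooted binary tree topology on n labeled leaves, built by
# attaching each new leaf to a uniformly chosen edge (uniform over
# labeled topologies); leaves are nodes 1..n, internals n+1..2n-2
random_tree_edges <- function(n) {
  stopifnot(n >= 2)
  edges <- matrix(c(1L, 2L), 1, 2)
  next_internal <- n + 1L
  for (leaf in seq_len(n)[-(1:2)]) {
    r <- sample(nrow(edges), 1)
    a <- edges[r, 1]; b <- edges[r, 2]
    w <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges[-r, , drop = FALSE],
                   c(a, w), c(w, b), c(w, leaf))
  }
  edges
}

edge_components <- function(n_nodes, edges, drop_rows) {
  keep <- edges[setdiff(seq_len(nrow(edges)), drop_rows), , drop = FALSE]
  comp <- seq_len(n_nodes)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(keep))) {
      a <- comp[keep[r, 1]]; b <- comp[keep[r, 2]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Random matrix with a known perfect phylogeny
#'
#' Draws a random fully resolved tree on `n` leaf taxa, then derives
#' each character from it the only way a character can be compatible: a
#' two-state character cuts one edge, a three-state character cuts two
#' (each resulting subtree is one state).  Three-state characters are
#' redrawn until each of the three subtrees contains a leaf, so the
#' realized arity among taxa really is three.  The generating tree is
#' returned as a fully labeled `perfect_phylogeny`, so
#' [verify_phylogeny()] holds by construction.
#'
#' @param n number of taxa (>= 2).
#' @param m number of characters.
#' @param three_state_fraction fraction of characters cut from two
#'   edges (default 0.5; the rest are binary).
#' @param seed integer seed.
#' @return list with `matrix` (a [character_matrix()]) and `phylogeny`
#'   (the generating tree, internal Steiner nodes unlabeled).
#' @export
random_pp_matrix <- function(n, m, three_state_fraction = 0.5, seed = 1L) {
  stopifnot(n >= 2, m >= 1)
  n3 <- round(three_state_fraction * m)
  n_edges <- if (n == 2) 1L else 2L * n - 3L
  if (n3 > 0 && n_edges < 2L)
    pp_parameter_error("a three-state character needs a tree with at least 2 edges")
  with_seed(seed, {
    edges <- random_tree_edges(n)
    n_nodes <- max(edges)
    arity <- c(rep(3L, n3), rep(2L, m - n3))[sample.int(m)]
    node_states <- matrix(NA_integer_, n_nodes, m)
    for (j in seq_len(m)) {
      repeat {
        cut <- sample(nrow(edges), arity[j] - 1L)
        comp <- edge_components(n_nodes, edges, cut)
        leaf_comp <- comp[seq_len(n)]
        if (length(unique(leaf_comp)) == arity[j]) break
      }
      # canonical states: numbered by first appearance among the taxa
      node_states[, j] <- match(comp, unique(leaf_comp)) - 1L
    }
    M <- character_matrix(node_states[seq_len(n), , drop = FALSE],
                          taxa = paste0("t", seq_len(n)))
    tree <- structure(
      list(n_nodes = n_nodes, species = node_states,
           node_names = paste0("N", seq_len(n_nodes) - 1L),
           edges = edges, artificial = rep(FALSE, nrow(edges)),
           node_of_taxon = seq_len(n), taxa = M$taxa,
           characters = M$characters),
      class = "perfect_phylogeny")
    list(matrix = M, phylogeny = tree)
  })
}

#' Caterpillar-interval family with a quadratic-size graph
#'
#' For `n` taxa on a caterpillar tree, one three-state character per
#' pair `1 <= i < j < n`: taxa `1..i` take state 0, `i+1..j` state 1,
#' `j+1..n` state 2 (cells 0, 1, 2).  The matrix has
#' `choose(n - 1, 2)` characters and a perfect phylogeny, yet its
#' partition intersection graph has at least `choose(n, 4)` edges —
#' the worst case that rules out algorithms whose cost is linear in
#' the explicit graph.
#'
#' @param n number of taxa (>= 4).
#' @return a [character_matrix()] with characters named `c<i>.<j>`.
#' @export
mstar_matrix <- function(n) {
  if (n < 4) pp_parameter_error("mstar_matrix needs n >= 4")
  ij <- t(combn(n - 1L, 2))
  st <- vapply(seq_len(nrow(ij)), function(r) {
    i <- ij[r, 1]; j <- ij[r, 2]
    c(rep(0L, i), rep(1L, j - i), rep(2L, n - j))
  }, integer(n))
  colnames(st) <- sprintf("c%d.%d", ij[, 1], ij[, 2])
  character_matrix(st, taxa = paste0("t", seq_len(n)))
}

#' Certified-incompatible matrices
#'
#' `pair_cycle` embeds a two-character four-gamete cycle (all four
#' state combinations realized), rejected at step 1 of the pipeline.
#' `long_cycle` embeds a five-taxon pattern whose character pairs are
#' all acyclic but whose graph has a chordless 5-cycle, rejected at
#' step 3; extra taxa are padded by duplicating the last row, which
#' never removes an obstruction.
#'
#' @param n number of taxa (>= 4 for `pair_cycle`, >= 5 for
#'   `long_cycle`).
#' @param mode `"pair_cycle"` or `"long_cycle"`.
#' @param seed integer seed (used to fill rows beyond the embedded
#'   obstruction in `pair_cycle`).
#' @return a [character_matrix()].
#' @export
make_incompatible <- function(n, mode = c("pair_cycle", "long_cycle"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "pair_cycle") {
    if (n < 4) pp_parameter_error("pair_cycle needs n >= 4")
    with_seed(seed, {
      a <- c(0L, 0L, 1L, 1L, sample(0:1, n - 4L, replace = TRUE))
      b <- c(0L, 1L, 1L, 0L, sample(0:1, n - 4L, replace = TRUE))
      character_matrix(cbind(a, b), taxa = paste0("t", seq_len(n)))
    })
  } else {
    if (n < 5) pp_parameter_error("long_cycle needs n >= 5")
    base <- rbind(c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 2L, 0L),
                  c(2L, 1L, 0L), c(0L, 1L, 1L))
    st <- base[c(seq_len(5), rep(5L, n - 5L)), , drop = FALSE]
    character_matrix(st, taxa = paste0("t", seq_len(n)))
  }
}
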
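# maximal cliques of the parallel relation (Bron-Kerbosch, no pivoting:
# separator sets are tiny)
all_maximal_parallel_families <- function(par) {
  k <- nrow(par)
  if (k == 0L) return(list(integer(0)))
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- setdiff(which(par[v, ]), v)
      bk(c(R, v), intersect(setdiff(P, v), nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  out
}

#' Enumerate every proper minimal triangulation
#'
#' Each maximal pairwise parallel family of legal minimal separators
#' saturates to a distinct proper minimal triangulation (and every
#' proper minimal triangulation arises this way), so enumerating the
#' maximal cliques of the parallel relation enumerates the
#' triangulations.  Intended for small instances: the number of
#' maximal families can grow exponentially.
#'
#' @param M a compatible [character_matrix()].
#' @return list with one entry per triangulation: `index` (separator
#'   positions in [legal_minimal_separators()] order), `fill`
#'   (two-column matrix of fill edges), `n_separators` (the number of
#'   minimal separators of the triangulated graph, equal to the family
#'   size).  Empty list when `M` is incompatible.
#' @export
all_proper_minimal_triangulations <- function(M) {
  if (nrow(cyclic_character_pairs(M)) > 0L) return(list())
  D <- legal_minimal_separators(M)
  if (nrow(unseparated_monochromatic_pairs(M, D)) > 0L) return(list())
  par <- crossing_relation(D)
  lapply(all_maximal_parallel_families(par), function(fam) {
    H <- saturate(D$G, D$separators[fam])
    list(index = fam, fill = H$fill_edges, n_separators = length(fam))
  })
}

# the 13 non-constant columns on 4 taxa: every partition of {1..4} into
# 2 or 3 cells, states canonical by first appearance
four_taxa_columns <- function() {
  cols <- list()
  for (a in 0:2) for (b in 0:2) for (c in 0:2) {
    col <- c(0L, a, b, c)
    k <- length(unique(col))
    if (k < 2L || k > 3L) next
    if (!all(sort(unique(col)) == seq_len(k) - 1L)) next
    if (!identical(col, match(col, unique(col)) - 1L)) next  # canonical
    cols[[length(cols) + 1L]] <- col
  }
  cols
}

# Exhaustive audit of the four-taxon family: every nonempty subset of the
# 13 distinct non-constant columns, run through the main pipeline and the
# brute-force oracles.  Returns one row per subset.  Columns:
#   m            number of characters
#   compatible   verdict of the separator pipeline (construct)
#   oracle_ok    verdict agrees with the brute decision oracle
#   n_tri        number of proper minimal triangulations (maximal parallel
#                families); NA when incompatible
#   max_nsep     largest minimal-separator count over those triangulations
#   tri_ok       triangulation fill sets and separator counts agree with the
#                branching oracle
#   seps_ok      legal minimal separators from proper clusters equal the
#                brute legal minimal separators with |S| < m
#   gprime_ok    minimal separators of the F-edge-augmented graph equal the
#                legal minimal separators of the base graph (compatible only)
n4_family_stats <- function(check_oracle = TRUE, check_tri = TRUE,
                            check_seps = TRUE, check_gprime = TRUE) {
  cols <- four_taxa_columns()
  nsub <- 2L^length(cols) - 1L
  res <- vector("list", nsub)
  for (id in seq_len(nsub)) {
    idx <- which(bitwAnd(id, 2L^(seq_along(cols) - 1L)) > 0L)
    M <- character_matrix(do.call(cbind, cols[idx]))
    G <- partition_intersection_graph(M)
    tri <- all_proper_minimal_triangulations(M)
    compatible <- is_compatible(construct_phylogeny(M))
    if (compatible != (length(tri) > 0L))
      pp_internal_error("construct and triangulation enumeration disagree")
    oracle_ok <- if (check_oracle) brute_pp_decide(M) == compatible else NA
    tri_ok <- NA
    if (check_tri && compatible) {
      bt <- brute_proper_minimal_triangulations(M)
      key <- function(f) paste(t(f), collapse = ",")
      tri_ok <- setequal(vapply(tri, function(x) key(x$fill), character(1)),
                         vapply(bt, function(x) key(x$fill), character(1))) &&
        setequal(
          paste(vapply(tri, function(x) key(x$fill), character(1)),
                vapply(tri, `[[`, integer(1), "n_separators")),
          paste(vapply(bt, function(x) key(x$fill), character(1)),
                vapply(bt, function(x) length(x$separators), integer(1))))
    } else if (check_tri && !compatible && check_oracle) {
      tri_ok <- length(brute_proper_minimal_triangulations(M)) == 0L
    }
    seps_ok <- NA
    if (check_seps) {
      D <- legal_minimal_separators(M)
      mine <- vapply(D$separators, function(s)
        paste(s$vertices, collapse = ","), character(1))
      legal <- Filter(function(s) !anyDuplicated(G$char[s]) && length(s) < M$m,
                      brute_minimal_separators(G, method = "neighborhood"))
      seps_ok <- setequal(mine, vapply(legal, paste, character(1), collapse = ","))
    }
    gprime_ok <- NA
    if (check_gprime && compatible) {
      G2 <- augmented_pig(M)
      legal_all <- Filter(function(s) !anyDuplicated(G$char[s]),
                          brute_minimal_separators(G, method = "neighborhood"))
      g2seps <- brute_minimal_separators(G2, method = "neighborhood")
      gprime_ok <- setequal(
        vapply(legal_all, paste, character(1), collapse = ","),
        vapply(g2seps, paste, character(1), collapse = ","))
    }
    res[[id]] <- data.frame(
      id = id, m = M$m, compatible = compatible, oracle_ok = oracle_ok,
      n_tri = if (compatible) length(tri) else NA_integer_,
      max_nsep = if (compatible)
        max(vapply(tri, `[[`, integer(1), "n_separators")) else NA_integer_,
      tri_ok = tri_ok, seps_ok = seps_ok, gprime_ok = gprime_ok)
  }
  do.call(rbind, res)
}

# matrix for a family subset id (bitmask over the 13 columns)
n4_family_matrix <- function(id) {
  cols <- four_taxa_columns()
  idx <- which(bitwAnd(id, 2L^(seq_along(cols) - 1L)) > 0L)
  character_matrix(do.call(cbind, cols[idx]))
}
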
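#' Brute-force minimal separator enumeration
#'
#' Reference implementation used by the tests: a set S is kept exactly
#' when the graph minus S has two or more full components.  The
#' default `"subset"` method scans every vertex subset and is exact by
#' definition but limited to 20 vertices; `"neighborhood"` grows the
#' set from component neighborhoods of closed vertex neighborhoods
#' (re-certifying every candidate with the same full-component test)
#' and handles larger graphs.  Both return the empty separator when
#' the graph is disconnected.
#'
#' @param G a `colored_graph` or logical adjacency matrix.
#' @param method `"subset"` or `"neighborhood"`.
#' @return list of sorted integer vertex sets, in canonical order.
#' @export
brute_minimal_separators <- function(G, method = c("subset", "neighborhood")) {
  method <- match.arg(method)
  adj <- oracle_adj(G)
  if (method == "subset") {
    if (nrow(adj) > 20L)
      pp_size_limit_error("subset scan limited to 20 vertices; use method = 'neighborhood'")
    out <- cpp_min_seps_subsets(adj)
  } else {
    out <- cpp_min_seps_close(adj)
  }
  out <- lapply(out, as.integer)
  out[order(vapply(out, function(s)
    paste(sprintf("%04d", c(length(s), s)), collapse = ""), character(1)))]
}

oracle_adj <- function(G) {
  adj <- if (is.matrix(G)) G else G$adj
  storage.mode(adj) <- "integer"
  adj
}

#' Brute-force parallelism test
#'
#' Direct check of the definition: S is parallel to S2 when S lies
#' inside a single component of the graph minus S2, plus S2 itself.
#'
#' @param G a `colored_graph` or adjacency matrix.
#' @param S,S2 integer vertex sets (minimal separators of `G`).
#' @return logical.
#' @export
brute_is_parallel <- function(G, S, S2) {
  adj <- if (is.matrix(G)) G else G$adj
  if (length(setdiff(S, S2)) == 0L) return(TRUE)
  comp <- graph_components(adj, removed = S2)
  for (k in seq_len(max(comp, na.rm = TRUE))) {
    C <- which(!is.na(comp) & comp == k)
    if (all(S %in% c(C, S2))) return(TRUE)
  }
  FALSE
}

#' Chordality by simplicial elimination (oracle)
#'
#' Independent of the Maximum Cardinality Search test used on the main
#' path: repeatedly deletes simplicial vertices and succeeds when the
#' graph empties.
#'
#' @param G a `colored_graph` or adjacency matrix.
#' @return logical.
#' @export
brute_is_chordal <- function(G) {
  cpp_is_chordal_elim(oracle_adj(G))
}

pig_colors <- function(G) as.integer(G$char)

# candidate fill edges: non-adjacent different-color vertex pairs
legal_fill_candidates <- function(G) {
  N <- G$n_vertices
  out <- matrix(integer(0), 0, 2)
  if (N < 2) return(out)
  for (u in seq_len(N - 1L))
    for (v in seq((u + 1L), N))
      if (!G$adj[u, v] && G$char[u] != G$char[v]) out <- rbind(out, c(u, v))
  out
}

#' Brute-force perfect phylogeny decision
#'
#' True exactly when some set of legal (different-color, non-edge)
#' vertex pairs added to the partition intersection graph yields a
#' chordal graph.  With at most `max_subset_candidates` candidate
#' pairs every subset is tried; beyond that, the decision branches on
#' legal chords of chordless cycles (equivalent, still exhaustive, and
#' feasible on the exhaustive small-matrix families used in testing).
#'
#' @param M a [character_matrix()].
#' @param max_subset_candidates subset-scan threshold (default 12).
#' @return logical.
#' @export
brute_pp_decide <- function(M, max_subset_candidates = 12L) {
  G <- partition_intersection_graph(M)
  cand <- legal_fill_candidates(G)
  if (nrow(cand) <= max_subset_candidates) {
    adj <- oracle_adj(G)
    for (mask in 0:(2^nrow(cand) - 1L)) {
      a <- adj
      picked <- which(bitwAnd(mask, 2^(seq_len(nrow(cand)) - 1L)) > 0L)
      for (r in picked) {
        a[cand[r, 1], cand[r, 2]] <- a[cand[r, 2], cand[r, 1]] <- 1L
      }
      if (cpp_is_chordal_elim(a)) return(TRUE)
    }
    return(FALSE)
  }
  res <- tryCatch(
    cpp_proper_fills(oracle_adj(G), pig_colors(G), TRUE, 2e6),
    error = function(e) pp_size_limit_error(conditionMessage(e)))
  length(res) > 0L
}

#' Brute-force enumeration of proper minimal triangulations
#'
#' Enumerates, by branching over the legal chords of chordless cycles,
#' every inclusion-minimal legal fill set that makes the partition
#' intersection graph chordal; each surviving fill set is certified
#' minimal by single-edge removal.  For each triangulation H the
#' minimal separators of H are also returned (enumerated by the
#' neighborhood oracle).
#'
#' @param M a [character_matrix()].
#' @return list with one entry per proper minimal triangulation:
#'   `fill` (two-column vertex-id matrix) and `separators` (list of
#'   vertex sets).  Empty when no proper triangulation exists.
#' @export
brute_proper_minimal_triangulations <- function(M) {
  G <- partition_intersection_graph(M)
  adj <- oracle_adj(G)
  res <- tryCatch(
    cpp_proper_fills(adj, pig_colors(G), FALSE, 2e6),
    error = function(e) pp_size_limit_error(conditionMessage(e)))
  out <- list()
  seen <- character(0)
  for (fill in res) {
    a <- adj
    for (r in seq_len(nrow(fill)))
      a[fill[r, 1], fill[r, 2]] <- a[fill[r, 2], fill[r, 1]] <- 1L
    if (!cpp_is_minimal_fill(a, fill)) next
    key <- paste(t(fill), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(
      fill = fill,
      separators = brute_minimal_separators(a == 1L, method = "neighborhood"))
  }
  out
}
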
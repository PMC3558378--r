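#' Proper clusters of a character matrix
#'
#' A proper cluster is a bipartition of the taxa such that every
#' character shares at most one state across the two sides and at least
#' one character (the witness) shares none.  The states shared across
#' the bipartition form its splitting vector.  Candidates are generated
#' per character from the bipartitions of its state set (one for a
#' binary character, three for a three-state one), so at most `3m`
#' candidates are examined and no subset search over taxa ever happens.
#'
#' @param M a [character_matrix()].
#' @return list of clusters, each with `side_a`, `side_b` (taxon
#'   indices), `splitting_vector` (vertex ids in the partition
#'   intersection graph), `witness_character` (0-based), and the
#'   generating `from_character` / `split_states`.
#' @export
proper_clusters <- function(M, G = NULL) {
  if (is.null(G)) G <- partition_intersection_graph(M)
  out <- list()
  seen <- character(0)
  for (j in seq_len(M$m)) {
    k <- G$arities[j]
    splits <- if (k == 1L) list() else if (k == 2L) list(0L) else list(0L, 1L, 2L)
    for (A in splits) {
      side_a <- which(M$states[, j] %in% A)
      side_b <- setdiff(seq_len(M$n), side_a)
      key <- paste(sort(if (1L %in% side_a) side_a else side_b), collapse = ",")
      if (key %in% seen) next
      sv <- integer(0)
      ok <- TRUE
      witness <- NA_integer_
      for (c2 in seq_len(M$m)) {
        shared <- intersect(unique(M$states[side_a, c2]),
                            unique(M$states[side_b, c2]))
        if (length(shared) > 1L) { ok <- FALSE; break }
        if (length(shared) == 0L && is.na(witness)) witness <- c2 - 1L
        if (length(shared) == 1L)
          sv <- c(sv, pig_vertex_id(G, c2 - 1L, shared))
      }
      if (!ok) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(
        side_a = side_a, side_b = side_b,
        splitting_vector = sort(sv), witness_character = witness,
        from_character = j - 1L, split_states = A)
    }
  }
  out
}

#' S-partition of the taxa induced by a legal vertex set
#'
#' Groups the taxa by the transitive closure of the relation "t and t'
#' share a character state that is not in `x`", computed by union-find
#' in one pass over the columns.  For a legal minimal separator S this
#' partition is exactly the grouping of taxa by the connected component
#' of the separator-deleted graph holding their states.
#'
#' @param M a [character_matrix()].
#' @param x integer vertex ids (at most one state per character).
#' @return integer vector of class ids (1-based, numbered by first
#'   taxon appearance), one per taxon.
#' @export
s_partition <- function(M, x, G = NULL) {
  if (is.null(G)) G <- partition_intersection_graph(M)
  if (anyDuplicated(G$char[x]))
    pp_parameter_error("x is illegal: two states of one character")
  parent <- seq_len(M$n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_len(M$m)) {
    for (s in seq_len(G$arities[j]) - 1L) {
      if (pig_vertex_id(G, j - 1L, s) %in% x) next
      taxa <- which(M$states[, j] == s)
      if (length(taxa) >= 2L) {
        r <- find(taxa[1])
        for (t2 in taxa[-1]) parent[find(t2)] <- r
      }
    }
  }
  roots <- vapply(seq_len(M$n), find, integer(1))
  match(roots, unique(roots))
}

#' Build a legal minimal separator from a proper cluster
#'
#' The candidate separator is the cluster's splitting vector.  Its
#' S-partition yields the components of the separator-deleted graph; a
#' component is full when every separator vertex appears in the rows of
#' its taxa.  The candidate is certified (and returned) only when at
#' least two components are full, which characterizes minimal
#' separators; otherwise `NULL`.
#'
#' @param M a [character_matrix()].
#' @param pc a cluster from [proper_clusters()].
#' @return a `pp_separator` or `NULL`.
#' @export
separator_from_cluster <- function(M, pc, G = NULL) {
  build_separator(M, pc$splitting_vector, cluster = pc, G = G)
}

build_separator <- function(M, S, cluster = NULL, G = NULL) {
  if (is.null(G)) G <- partition_intersection_graph(M)
  cls <- s_partition(M, S, G)
  comps <- lapply(seq_len(max(cls)), function(k) {
    taxa <- which(cls == k)
    ids <- unique(sort(unlist(G$taxa_cliques[taxa])))
    list(vertices = setdiff(ids, S), taxa = taxa,
         full = all(S %in% ids))
  })
  if (sum(vapply(comps, `[[`, logical(1), "full")) < 2L) return(NULL)
  structure(
    list(vertices = sort(as.integer(S)), labels = G$label[sort(as.integer(S))],
         components = comps, taxa_class = cls, n = M$n, m = M$m,
         cluster = cluster),
    class = "pp_separator")
}

#' @export
print.pp_separator <- function(x, ...) {
  cat(sprintf("pp_separator {%s}: %d components (%d full)\n",
              paste(x$labels, collapse = ", "), length(x$components),
              sum(vapply(x$components, `[[`, logical(1), "full"))))
  invisible(x)
}

#' Legal minimal separators of the partition intersection graph
#'
#' Generates, from the proper clusters of the matrix, every legal
#' minimal separator with fewer than `m` vertices, deduplicated by
#' vertex set and stored in canonical (sorted label) order.  The empty
#' separator appears exactly when the graph is disconnected.  Each
#' member is certified: legal coloring, fewer than `m` vertices, and at
#' least two full components.
#'
#' @param M a [character_matrix()].
#' @return a `pp_separator_set`: list with `separators`, the graph `G`,
#'   and the matrix `M`.
#' @export
legal_minimal_separators <- function(M) {
  G <- partition_intersection_graph(M)
  seps <- list()
  keys <- character(0)
  for (pc in proper_clusters(M, G)) {
    sep <- separator_from_cluster(M, pc, G)
    if (is.null(sep)) next
    key <- paste(sep$vertices, collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    seps[[length(seps) + 1L]] <- sep
  }
  ord <- order(vapply(seps, function(s)
    paste(sprintf("%04d", s$vertices), collapse = "|"), character(1)))
  seps <- seps[ord]
  for (s in seps) {
    if (length(s$vertices) >= M$m)
      pp_internal_error("separator with >= m vertices generated")
    if (anyDuplicated(G$char[s$vertices]))
      pp_internal_error("illegal separator generated")
  }
  if (length(seps) > 3L * M$m)
    pp_internal_error("more than 3m separators generated")
  structure(list(separators = seps, G = G, M = M), class = "pp_separator_set")
}

#' @export
print.pp_separator_set <- function(x, ...) {
  cat(sprintf("pp_separator_set: %d legal minimal separators\n",
              length(x$separators)))
  for (s in x$separators)
    cat(sprintf("  {%s}\n", paste(s$labels, collapse = ", ")))
  invisible(x)
}

#' @export
length.pp_separator_set <- function(x) length(x$separators)

#' Monochromatic pairs not separated by any legal minimal separator
#'
#' Step 3 of the pipeline: given step 1 passed, the matrix is
#' compatible exactly when every same-character vertex pair is
#' separated by some member of the legal minimal separator set.
#'
#' @param M a [character_matrix()].
#' @param D a `pp_separator_set` from [legal_minimal_separators()].
#' @return two-column matrix of unseparated vertex-id pairs (zero rows
#'   means every monochromatic pair is separated).
#' @export
unseparated_monochromatic_pairs <- function(M, D) {
  G <- D$G
  pairs <- monochromatic_pairs(G)
  if (nrow(pairs) == 0L) return(pairs)
  # vertex -> component id map per separator (NA on separator vertices)
  maps <- lapply(D$separators, function(s) {
    mp <- rep(NA_integer_, G$n_vertices)
    for (k in seq_along(s$components)) mp[s$components[[k]]$vertices] <- k
    mp
  })
  ok <- vapply(seq_len(nrow(pairs)), function(r) {
    u <- pairs[r, 1]; v <- pairs[r, 2]
    for (mp in maps)
      if (!is.na(mp[u]) && !is.na(mp[v]) && mp[u] != mp[v]) return(TRUE)
    FALSE
  }, logical(1))
  pairs[!ok, , drop = FALSE]
}

#' Are two legal minimal separators parallel?
#'
#' Tested through the taxa: S and S' are parallel exactly when some
#' full component C of the S-deleted graph has its taxa t(C) contained
#' in a single part of the S'-partition.  This agrees with the
#' graph-theoretic definition (S inside one component of G - S' plus
#' S') and costs O(n) given the stored partitions.
#'
#' @param S,S2 `pp_separator` objects from the same matrix.
#' @return logical.
#' @export
are_parallel <- function(S, S2) {
  for (comp in S$components) {
    if (!comp$full) next
    if (length(unique(S2$taxa_class[comp$taxa])) == 1L) return(TRUE)
  }
  FALSE
}

#' Pairwise parallel relation over a separator set
#'
#' @param D a `pp_separator_set`.
#' @return symmetric logical matrix; entry `[i, j]` is `TRUE` when
#'   separators i and j are parallel.
#' @export
crossing_relation <- function(D) {
  k <- length(D$separators)
  par <- matrix(TRUE, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        par[i, j] <- par[j, i] <- are_parallel(D$separators[[i]],
                                               D$separators[[j]])
      }
    }
  }
  par
}
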
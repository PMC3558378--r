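#' Partition intersection graph of a character matrix
#'
#' Vertices are the realized character states, colored by character
#' (label `c<char>_s<state>`, 0-based); an E-edge joins two states that
#' co-occur in some taxon, so every taxon row induces an m-clique.  No
#' edge ever joins two states of the same character.
#'
#' @param M a [character_matrix()].
#' @return an object of class `colored_graph`: fields `n_vertices`,
#'   `char`, `state` (0-based per vertex), `label`, `adj` (logical
#'   adjacency matrix), `kind` (edge kind: `"E"`, `"F"` or `"fill"`),
#'   `m`, `arities`, `offsets`, and `taxa_cliques` (vertex ids of each
#'   taxon's clique).
#' @export
partition_intersection_graph <- function(M) {
  stopifnot(inherits(M, "character_matrix"))
  arities <- unname(apply(M$states, 2, max) + 1L)
  offsets <- c(0L, cumsum(arities))
  N <- offsets[M$m + 1L]
  char <- rep(seq_len(M$m) - 1L, arities)
  state <- unlist(lapply(arities, function(k) seq_len(k) - 1L))
  adj <- matrix(FALSE, N, N)
  kind <- matrix("", N, N)
  taxa_cliques <- vector("list", M$n)
  for (t in seq_len(M$n)) {
    ids <- offsets[seq_len(M$m)] + M$states[t, ] + 1L
    taxa_cliques[[t]] <- ids
    adj[ids, ids] <- TRUE
  }
  diag(adj) <- FALSE
  kind[adj] <- "E"
  g <- structure(
    list(n_vertices = N, char = char, state = state,
         label = sprintf("c%d_s%d", char, state),
         adj = adj, kind = kind, m = M$m,
         arities = arities, offsets = offsets,
         taxa_cliques = taxa_cliques),
    class = "colored_graph")
  assert_properly_colored(g)
  g
}

assert_properly_colored <- function(G) {
  bad <- G$adj & outer(G$char, G$char, "==")
  if (any(bad))
    pp_internal_error("colored graph has a same-color edge")
  invisible(TRUE)
}

#' Vertex ids for (character, state) pairs
#' @param G a `colored_graph`.
#' @param char,state 0-based character and state indices (vectorized).
#' @return integer vertex ids.
#' @export
pig_vertex_id <- function(G, char, state) G$offsets[char + 1L] + state + 1L

#' @export
print.colored_graph <- function(x, ...) {
  cat(sprintf("colored_graph: %d vertices (%d characters), %d edges (%d E, %d F, %d fill)\n",
              x$n_vertices, x$m, sum(x$adj) / 2,
              sum(x$kind == "E") / 2, sum(x$kind == "F") / 2,
              sum(x$kind == "fill") / 2))
  invisible(x)
}

#' Subgraph induced by a subset of characters
#'
#' Equals the partition intersection graph of the corresponding column
#' submatrix.
#'
#' @param G a `colored_graph` built by [partition_intersection_graph()].
#' @param characters 0-based character indices.
#' @return a `colored_graph` on the restricted vertex set (characters
#'   renumbered consecutively, original indices in `$orig_char`).
#' @export
induced_character_subgraph <- function(G, characters) {
  characters <- sort(unique(as.integer(characters)))
  stopifnot(all(characters >= 0L & characters < G$m))
  keep <- which(G$char %in% characters)
  newchar <- match(G$char[keep], characters) - 1L
  arities <- G$arities[characters + 1L]
  structure(
    list(n_vertices = length(keep), char = newchar, state = G$state[keep],
         label = sprintf("c%d_s%d", newchar, G$state[keep]),
         adj = G$adj[keep, keep, drop = FALSE],
         kind = G$kind[keep, keep, drop = FALSE],
         m = length(characters), arities = arities,
         offsets = c(0L, cumsum(arities)),
         taxa_cliques = lapply(G$taxa_cliques, function(ids)
           match(intersect(ids, keep), keep)),
         orig_char = characters),
    class = "colored_graph")
}

# connected components; returns integer component id per vertex, NA on
# removed vertices
graph_components <- function(adj, removed = integer(0)) {
  N <- nrow(adj)
  comp <- rep(NA_integer_, N)
  alive <- setdiff(seq_len(N), removed)
  k <- 0L
  for (v in alive) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    frontier <- v
    comp[v] <- k
    while (length(frontier)) {
      nb <- which(matrixStats_any(adj[frontier, , drop = FALSE]))
      nb <- nb[is.na(comp[nb]) & !(nb %in% removed)]
      comp[nb] <- k
      frontier <- nb
    }
  }
  comp
}

matrixStats_any <- function(m) colSums(m) > 0

#' Screen all character pairs for cycles
#'
#' Step 1 of the pipeline: a pair of characters is compatible only if
#' their two-color partition intersection graph is acyclic (a forest,
#' tested component-wise as |edges| >= |vertices|).  A cycle here is a
#' local obstruction and the whole matrix is incompatible.
#'
#' @param M a [character_matrix()].
#' @return a two-column matrix of violating 0-based character pairs
#'   (zero rows when step 1 passes).
#' @export
cyclic_character_pairs <- function(M) {
  G <- partition_intersection_graph(M)
  bad <- matrix(integer(0), 0, 2)
  if (M$m < 2L) return(bad)
  for (i in seq_len(M$m - 1L)) {
    for (j in seq((i + 1L), M$m)) {
      ids <- which(G$char %in% c(i - 1L, j - 1L))
      sub <- G$adj[ids, ids, drop = FALSE]
      comp <- graph_components(sub)
      for (k in seq_len(max(comp))) {
        vs <- comp == k
        if (sum(sub[vs, vs]) / 2 >= sum(vs)) {  # edges >= vertices: cycle
          bad <- rbind(bad, c(i - 1L, j - 1L))
          break
        }
      }
    }
  }
  bad
}

#' Enumerate chordless cycles of length >= 4
#'
#' Chordless 4-cycles are found from non-adjacent vertex pairs and their
#' common neighbors; longer cycles (diagnostics only) by depth-first
#' search over induced paths.  Every reported cycle is chord-free.
#'
#' @param G a `colored_graph`.
#' @param max_len optional bound on the cycle length.
#' @return list of integer vertex-id cycles (each in cyclic order).
#' @export
chordless_cycles <- function(G, max_len = NULL) {
  adj <- G$adj
  N <- G$n_vertices
  if (is.null(max_len)) max_len <- N
  out <- list()
  seen <- character(0)
  if (max_len >= 4 && N >= 4) {
    for (u in seq_len(N - 1L)) {
      for (v in seq((u + 1L), N)) {
        if (adj[u, v]) next
        cn <- which(adj[u, ] & adj[v, ])
        if (length(cn) < 2) next
        for (a in seq_len(length(cn) - 1L)) {
          for (b in seq((a + 1L), length(cn))) {
            x <- cn[a]; x2 <- cn[b]
            if (adj[x, x2]) next
            key <- paste(sort(c(u, x, v, x2)), collapse = "-")
            if (!(key %in% seen)) {
              seen <- c(seen, key)
              out[[length(out) + 1L]] <- c(u, x, v, x2)
            }
          }
        }
      }
    }
  }
  if (max_len >= 5) out <- c(out, long_chordless_cycles(adj, max_len))
  out
}

# DFS over induced paths: p1 is the smallest cycle vertex, p2 < last to
# kill reflections; a closing neighbor of p1 ends a cycle, any chord
# prunes the branch.
long_chordless_cycles <- function(adj, max_len) {
  N <- nrow(adj)
  out <- list()
  extend <- function(path) {
    last <- path[length(path)]
    for (v in which(adj[last, ])) {
      if (v <= path[1] || v %in% path) next
      mid <- path[-c(1, length(path))]
      if (length(mid) && any(adj[v, mid])) next
      closes <- adj[v, path[1]]
      if (closes && length(path) + 1L >= 5L && path[2] < v)
        out[[length(out) + 1L]] <<- c(path, v)
      if (!closes && length(path) + 1L < max_len) extend(c(path, v))
    }
  }
  for (s in seq_len(N)) {
    for (v2 in which(adj[s, ])) if (v2 > s) extend(c(s, v2))
  }
  out
}

#' Augmented graph with forced chords (F-edges)
#'
#' Every chordless 4-cycle of the partition intersection graph on
#' exactly three colors has a monochromatic diagonal that can never be
#' an edge; the other diagonal is therefore forced into any proper
#' triangulation.  Adding all such forced chords (F-edges) yields the
#' augmented graph.  This graph is not on the main construction path:
#' it exists to test the structural theory (its minimal separators are
#' exactly the legal minimal separators of the base graph for
#' compatible input).
#'
#' @param M a [character_matrix()]; character pairs must be acyclic
#'   (step 1), otherwise a two-color 4-cycle with no legal chord raises
#'   an obstruction error.
#' @return a `colored_graph` with F-edges tagged `kind = "F"`.
#' @export
augmented_pig <- function(M) {
  G <- partition_intersection_graph(M)
  for (cyc in chordless_cycles(G, max_len = 4)) {
    cols <- G$char[cyc]
    if (length(unique(cols)) == 2L)
      pp_obstruction_error("two-color chordless 4-cycle: character pair is incompatible")
    if (length(unique(cols)) == 3L) {
      dup <- cols[duplicated(cols)]
      chord <- cyc[cols != dup]  # the two singleton-color vertices
      G$adj[chord[1], chord[2]] <- G$adj[chord[2], chord[1]] <- TRUE
      G$kind[chord[1], chord[2]] <- G$kind[chord[2], chord[1]] <- "F"
    }
  }
  assert_properly_colored(G)
  G
}

#' Export a colored graph for debugging
#'
#' @param G a `colored_graph`.
#' @param file path or connection.
#' @param format `"tsv"` (edge list with kind column) or `"dot"`.
#' @return `file`, invisibly.
#' @export
export_graph <- function(G, file, format = c("tsv", "dot")) {
  format <- match.arg(format)
  idx <- which(G$adj & upper.tri(G$adj), arr.ind = TRUE)
  from <- G$label[idx[, 1]]; to <- G$label[idx[, 2]]
  kind <- G$kind[idx]
  if (format == "tsv") {
    write.table(data.frame(from = from, to = to, kind = kind),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("graph pig {",
               sprintf("  \"%s\" [color=%d];", G$label, G$char),
               sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];", from, to, kind),
               "}")
    writeLines(lines, file)
  }
  invisible(file)
}

# all monochromatic vertex pairs, as a 2-column id matrix
monochromatic_pairs <- function(G) {
  out <- matrix(integer(0), 0, 2)
  for (ch in unique(G$char)) {
    ids <- which(G$char == ch)
    if (length(ids) >= 2) out <- rbind(out, t(combn(ids, 2)))
  }
  out
}
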
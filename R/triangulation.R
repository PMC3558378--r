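#' Greedy maximal pairwise parallel family of separators
#'
#' Scans the separator set in a given order and keeps every separator
#' parallel to all previously kept ones; the result is maximal by
#' construction.  Any maximal family induces a correct proper minimal
#' triangulation for compatible input, so the order affects only which
#' phylogeny is returned, never whether one is found.  The family can
#' never exceed `2n - 3` members once steps 1 and 3 have passed; a
#' larger family signals an implementation bug.
#'
#' @param D a `pp_separator_set` from [legal_minimal_separators()].
#' @param order optional permutation of `seq_along(D$separators)`.
#' @param seed optional integer; when given (and `order` is not), the
#'   canonical order is shuffled reproducibly.
#' @return a `pp_parallel_family`: list with `members` (separator
#'   objects), `index` (positions in `D`), and `D`.
#' @export
greedy_parallel_family <- function(D, order = NULL, seed = NULL) {
  k <- length(D$separators)
  if (is.null(order)) {
    order <- seq_len(k)
    if (!is.null(seed) && k > 0L) order <- with_seed(seed, sample(k))
  }
  stopifnot(setequal(order, seq_len(k)))
  par <- crossing_relation(D)
  chosen <- integer(0)
  for (i in order) {
    if (all(par[i, chosen])) chosen <- c(chosen, i)
  }
  n <- D$M$n
  if (length(chosen) > 2L * n - 3L && n >= 2L)
    pp_internal_error(sprintf(
      "parallel family has %d > 2n-3 = %d members", length(chosen), 2L * n - 3L))
  structure(list(members = D$separators[chosen], index = sort(chosen), D = D),
            class = "pp_parallel_family")
}

#' @export
length.pp_parallel_family <- function(x) length(x$members)

#' Saturate a family of separators into a triangulated graph
#'
#' Adds, inside every separator of the family, each absent vertex pair
#' as a fill edge.  Fill edges are always between different characters
#' because the separators are legal.  For a maximal parallel family on
#' compatible input the result is a proper minimal triangulation; the
#' routine verifies chordality and raises an internal error otherwise.
#'
#' @param G a `colored_graph` (the base partition intersection graph).
#' @param Q a `pp_parallel_family` (or list of `pp_separator`).
#' @param check verify chordality of the result (default `TRUE`).
#' @return a `colored_graph` with the fill pairs tagged
#'   `kind = "fill"` and listed in `$fill_edges` (two-column matrix).
#' @export
saturate <- function(G, Q, check = TRUE) {
  members <- if (inherits(Q, "pp_parallel_family")) Q$members else Q
  fills <- matrix(integer(0), 0, 2)
  for (s in members) {
    vs <- s$vertices
    if (length(vs) < 2L) next
    prs <- t(combn(vs, 2))
    for (r in seq_len(nrow(prs))) {
      u <- prs[r, 1]; v <- prs[r, 2]
      if (!G$adj[u, v]) {
        if (G$char[u] == G$char[v])
          pp_internal_error("monochromatic fill edge attempted")
        G$adj[u, v] <- G$adj[v, u] <- TRUE
        G$kind[u, v] <- G$kind[v, u] <- "fill"
        fills <- rbind(fills, c(u, v))
      }
    }
  }
  G$fill_edges <- fills
  assert_properly_colored(G)
  if (check && !is_chordal_graph(G))
    pp_internal_error("saturated graph is not chordal")
  G
}

#' Chordality test by Maximum Cardinality Search
#'
#' @param G a `colored_graph` or logical adjacency matrix.
#' @return logical.
#' @export
is_chordal_graph <- function(G) {
  adj <- if (is.matrix(G)) G else G$adj
  !is.null(tryCatch(mcs_sweep(adj), pp_not_chordal_error = function(e) NULL))
}

# One MCS sweep: returns the visit order, each vertex's already-visited
# neighborhood (madj), and the Blair-Peyton clique boundaries.  Raises
# pp_not_chordal_error when the Tarjan-Yannakakis test fails.
mcs_sweep <- function(adj) {
  N <- nrow(adj)
  visited <- logical(N)
  weight <- integer(N)
  order <- integer(N)
  pos <- integer(N)              # visit position of each vertex
  madj <- vector("list", N)
  new_clique <- logical(N)       # does this vertex open a new clique?
  prev_card <- -1L
  for (i in seq_len(N)) {
    cand <- which(!visited)
    v <- cand[which.max(weight[cand])]  # ties: lowest vertex id
    mv <- which(adj[v, ] & visited)
    order[i] <- v; pos[v] <- i
    madj[[v]] <- mv
    new_clique[v] <- length(mv) <= prev_card || i == 1L
    if (length(mv) > 0L) {
      u <- mv[which.max(pos[mv])]      # most recently visited member
      rest <- setdiff(mv, u)
      if (!all(rest %in% c(madj[[u]], u)))
        pp_not_chordal_error("MCS exposed a missing chord")
    }
    prev_card <- length(mv)
    visited[v] <- TRUE
    weight[adj[v, ]] <- weight[adj[v, ]] + 1L
  }
  list(order = order, pos = pos, madj = madj, new_clique = new_clique)
}

#' Clique tree of a chordal graph by Maximum Cardinality Search
#'
#' Blair-Peyton construction: vertices are visited in MCS order (ties
#' broken by lowest vertex id, so output is deterministic); a new
#' maximal clique opens whenever the visited-neighbor count fails to
#' grow, and attaches to the clique of the most recently visited member
#' of its boundary, whose intersection is a minimal separator of the
#' graph.  On a disconnected graph the forest components are joined by
#' edges between their lexicographically smallest cliques, flagged
#' artificial.
#'
#' @param H a chordal `colored_graph` (e.g. from [saturate()]).
#' @return a `clique_tree`: `cliques` (list of vertex-id sets),
#'   `edges` (two-column matrix of clique indices), `separators` (list
#'   of vertex-id intersections per edge), `artificial` (logical per
#'   edge), `clique_of_vertex`.
#' @export
mcs_clique_tree <- function(H) {
  adj <- if (is.matrix(H)) H else H$adj
  N <- nrow(adj)
  sweep <- tryCatch(mcs_sweep(adj),
                    pp_not_chordal_error = function(e)
                      pp_not_chordal_error("graph is not chordal"))
  cliques <- list()
  edges <- matrix(integer(0), 0, 2)
  seps <- list()
  artificial <- logical(0)
  clique_idx <- integer(N)
  current <- 0L
  for (v in sweep$order) {
    mv <- sweep$madj[[v]]
    if (sweep$new_clique[v]) {
      cliques[[current <- length(cliques) + 1L]] <- sort(c(mv, v))
      if (length(mv) > 0L) {
        u <- mv[which.max(sweep$pos[mv])]
        p <- clique_idx[u]
        edges <- rbind(edges, c(p, current))
        seps[[length(seps) + 1L]] <- sort(mv)
        artificial <- c(artificial, FALSE)
      }
    } else {
      cliques[[current]] <- sort(c(cliques[[current]], v))
    }
    clique_idx[v] <- current
  }
  # join forest components (disconnected input) by artificial edges
  k <- length(cliques)
  comp <- tree_components(k, edges)
  if (max(comp) > 1L) {
    keyfun <- function(i) paste(sprintf("%05d", cliques[[i]]), collapse = "")
    reps <- vapply(split(seq_len(k), comp), function(ix)
      ix[order(vapply(ix, keyfun, character(1)))[1]], integer(1))
    for (r in reps[-1]) {
      edges <- rbind(edges, c(reps[1], r))
      seps[[length(seps) + 1L]] <- intersect(cliques[[reps[1]]], cliques[[r]])
      artificial <- c(artificial, TRUE)
    }
  }
  structure(list(cliques = cliques, edges = edges, separators = seps,
                 artificial = artificial, clique_of_vertex = clique_idx,
                 graph = if (is.matrix(H)) NULL else H),
            class = "clique_tree")
}

tree_components <- function(k, edges) {
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges[r, 1]]; b <- comp[edges[r, 2]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' @export
print.clique_tree <- function(x, ...) {
  cat(sprintf("clique_tree: %d maximal cliques, %d edges (%d artificial)\n",
              length(x$cliques), nrow(x$edges), sum(x$artificial)))
  invisible(x)
}
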
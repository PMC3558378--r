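#' Read a phylogeny out of a clique tree
#'
#' Each maximal clique of a proper triangulation contains at most one
#' state per character and therefore spells a species: the state carried
#' for each character present in the clique, missing (`NA`, printed
#' `*`) for the others.  Missing entries are never imputed.  Every
#' taxon's row clique is a maximal clique of the triangulation, so each
#' taxon maps to exactly one node; duplicate rows share a node.  Every
#' leaf of the tree carries at least one taxon.
#'
#' @param M a [character_matrix()].
#' @param ct a `clique_tree` from [mcs_clique_tree()] run on a proper
#'   triangulation of the partition intersection graph of `M`.
#' @return a `perfect_phylogeny`: `n_nodes`, `species` (nodes x m
#'   integer matrix, `NA` = missing), `node_names` (`N0..Nk`), `edges`,
#'   `artificial` (per edge), `node_of_taxon`, `taxa`, `characters`.
#' @export
assemble_phylogeny <- function(M, ct) {
  G <- ct$graph
  if (is.null(G)) pp_parameter_error("clique tree lacks its colored graph")
  k <- length(ct$cliques)
  species <- matrix(NA_integer_, k, M$m, dimnames = list(NULL, M$characters))
  for (i in seq_len(k)) {
    vs <- ct$cliques[[i]]
    species[i, G$char[vs] + 1L] <- G$state[vs]
  }
  keys <- vapply(ct$cliques, function(v) paste(v, collapse = ","), character(1))
  node_of_taxon <- vapply(seq_len(M$n), function(t) {
    key <- paste(sort(G$taxa_cliques[[t]]), collapse = ",")
    match(key, keys)
  }, integer(1))
  if (anyNA(node_of_taxon))
    pp_internal_error("a taxon's clique is not a node of the clique tree")
  deg <- tabulate(c(ct$edges), nbins = k)
  leaves <- if (k == 1L) 1L else which(deg <= 1L)
  if (!all(leaves %in% node_of_taxon))
    pp_internal_error("a leaf of the clique tree carries no taxon")
  structure(
    list(n_nodes = k, species = species,
         node_names = paste0("N", seq_len(k) - 1L),
         edges = ct$edges, artificial = ct$artificial,
         node_of_taxon = node_of_taxon, taxa = M$taxa,
         characters = M$characters),
    class = "perfect_phylogeny")
}

#' @export
print.perfect_phylogeny <- function(x, ...) {
  cat(sprintf("perfect_phylogeny: %d nodes, %d taxa, %d characters\n",
              x$n_nodes, length(x$taxa), ncol(x$species)))
  for (i in seq_len(x$n_nodes)) {
    taxa <- x$taxa[x$node_of_taxon == i]
    cat(sprintf("  %s (%s)%s\n", x$node_names[i], species_string(x$species[i, ]),
                if (length(taxa)) paste0(" <- ", paste(taxa, collapse = ",")) else ""))
  }
  invisible(x)
}

species_string <- function(sp) {
  paste(ifelse(is.na(sp), "*", sp), collapse = ",")
}

#' Verify the perfect-phylogeny conditions
#'
#' Independent of how the tree was produced, checks that (1) each taxon
#' labels exactly one node and its row agrees with that node's species
#' wherever the species is not missing, (2) every leaf is labeled by at
#' least one taxon, and (3) for every character state the nodes whose
#' species carry it induce a connected subtree.
#'
#' @param M a [character_matrix()].
#' @param tree a `perfect_phylogeny`.
#' @return `TRUE`/`FALSE`, with the failed checks in
#'   `attr(, "violations")`.
#' @export
verify_phylogeny <- function(M, tree) {
  v <- character(0)
  k <- tree$n_nodes
  if (ncol(tree$species) != M$m)
    v <- c(v, "species length differs from the number of characters")
  nt <- tree$node_of_taxon
  if (length(nt) != M$n || anyNA(nt) || any(nt < 1L | nt > k)) {
    v <- c(v, "taxon-to-node mapping is not a total map")
  } else if (ncol(tree$species) == M$m) {
    for (t in seq_len(M$n)) {
      sp <- tree$species[nt[t], ]
      if (!all(is.na(sp) | sp == M$states[t, ]))
        v <- c(v, sprintf("taxon %s disagrees with its node species", M$taxa[t]))
    }
  }
  deg <- tabulate(c(tree$edges), nbins = k)
  leaves <- if (k == 1L) 1L else which(deg <= 1L)
  if (!all(leaves %in% nt))
    v <- c(v, "an unlabeled leaf")
  if (nrow(tree$edges) != k - 1L ||
      (k > 1L && max(tree_components(k, tree$edges)) != 1L))
    v <- c(v, "edges do not form a tree")
  # convexity: each (character, state) occupies a connected subtree
  if (ncol(tree$species) == M$m) {
    for (j in seq_len(M$m)) {
      for (s in unique(M$states[, j])) {
        nodes <- which(!is.na(tree$species[, j]) & tree$species[, j] == s)
        if (length(nodes) > 1L && !nodes_connected(nodes, tree$edges))
          v <- c(v, sprintf("state %d of character %s is not convex",
                            s, M$characters[j]))
      }
    }
  }
  structure(length(v) == 0L, violations = v)
}

nodes_connected <- function(nodes, edges) {
  inset <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  sub <- edges[inset, , drop = FALSE]
  comp <- nodes[1]
  repeat {
    grow <- unique(c(sub[sub[, 1] %in% comp, 2], sub[sub[, 2] %in% comp, 1]))
    grow <- setdiff(grow, comp)
    if (!length(grow)) break
    comp <- c(comp, grow)
  }
  length(comp) == length(nodes)
}

#' Write a phylogeny as Newick plus a node-label table
#'
#' Plain Newick (no branch lengths), nodes named `N0..Nk`; the species
#' strings, taxon lists and artificial-edge flags go to a sidecar TSV
#' (columns `node`, `species`, `taxa`, `artificial_parent_edge`).
#'
#' @param tree a `perfect_phylogeny`.
#' @param file Newick output path or connection.
#' @param labels_file optional sidecar TSV path.
#' @return the Newick string, invisibly.
#' @export
write_phylogeny <- function(tree, file = NULL, labels_file = NULL) {
  nwk <- paste0(newick_string(tree), ";")
  if (!is.null(file)) writeLines(nwk, file)
  if (!is.null(labels_file)) {
    parent <- tree_parents(tree)
    art <- rep(NA, tree$n_nodes)
    for (r in seq_len(nrow(tree$edges))) {
      child <- if (parent[tree$edges[r, 2]] == tree$edges[r, 1])
        tree$edges[r, 2] else tree$edges[r, 1]
      art[child] <- tree$artificial[r]
    }
    df <- data.frame(
      node = tree$node_names,
      species = apply(tree$species, 1, species_string),
      taxa = vapply(seq_len(tree$n_nodes), function(i)
        paste(tree$taxa[tree$node_of_taxon == i], collapse = ","), character(1)),
      artificial_parent_edge = art)
    write.table(df, labels_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(nwk)
}

tree_parents <- function(tree) {
  k <- tree$n_nodes
  parent <- rep(NA_integer_, k)
  parent[1] <- 0L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (r in seq_len(nrow(tree$edges))) {
        a <- tree$edges[r, 1]; b <- tree$edges[r, 2]
        if (a == v && is.na(parent[b])) { parent[b] <- v; nxt <- c(nxt, b) }
        if (b == v && is.na(parent[a])) { parent[a] <- v; nxt <- c(nxt, a) }
      }
    }
    frontier <- nxt
  }
  parent
}

newick_string <- function(tree) {
  if (tree$n_nodes == 1L) return(tree$node_names[1])
  parent <- tree_parents(tree)
  children <- lapply(seq_len(tree$n_nodes), function(v) which(parent == v))
  emit <- function(v) {
    ch <- children[[v]]
    if (!length(ch)) return(tree$node_names[v])
    paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")",
           tree$node_names[v])
  }
  emit(1L)
}

#' Convert to an ape `phylo` object
#'
#' The clique tree is taken as rooted at its first node; node labels are
#' preserved.  Degree-two internal nodes are kept (ape tolerates
#' singleton nodes; use [ape::collapse.singles()] to drop them).
#'
#' @param tree a `perfect_phylogeny` with at least 3 nodes.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  if (tree$n_nodes < 3L)
    pp_parameter_error("as_phylo needs at least 3 nodes; use write_phylogeny")
  parent <- tree_parents(tree)
  deg <- tabulate(c(tree$edges), nbins = tree$n_nodes)
  is_tip <- deg == 1L & seq_len(tree$n_nodes) != 1L
  idx <- integer(tree$n_nodes)
  idx[is_tip] <- seq_len(sum(is_tip))
  idx[!is_tip] <- sum(is_tip) + seq_len(sum(!is_tip))
  edge <- cbind(idx[parent[-1]], idx[-1])
  phy <- structure(list(
    edge = edge, Nnode = sum(!is_tip),
    tip.label = tree$node_names[is_tip][order(idx[is_tip])],
    node.label = tree$node_names[!is_tip][order(idx[!is_tip])]),
    class = "phylo", order = "cladewise")
  phy
}

#' Read a phylogeny written by [write_phylogeny()]
#'
#' @param file Newick path.
#' @param labels_file the sidecar TSV.
#' @param M the [character_matrix()] the tree claims to display (used
#'   to order taxa).
#' @return a `perfect_phylogeny`.
#' @export
read_phylogeny <- function(file, labels_file, M) {
  txt <- paste(readLines(file), collapse = "")
  lab <- read.delim(labels_file, sep = "\t", colClasses = "character")
  k <- nrow(lab)
  if (k == 1L) {
    nodes <- sub(";$", "", trimws(txt))
    edges <- matrix(integer(0), 0, 2)
  } else {
    phy <- ape::read.tree(text = txt)
    names_all <- c(phy$tip.label, phy$node.label)
    edges <- cbind(match(names_all[phy$edge[, 1]], lab$node),
                   match(names_all[phy$edge[, 2]], lab$node))
    if (anyNA(edges)) pp_format_error("newick node names do not match the label table")
  }
  species <- t(vapply(strsplit(lab$species, ","), function(p) {
    p[p == "*"] <- NA
    as.integer(p)
  }, integer(ncol(M$states))))
  node_of_taxon <- rep(NA_integer_, M$n)
  for (i in seq_len(k)) {
    tx <- strsplit(lab$taxa[i], ",")[[1]]
    node_of_taxon[match(tx, M$taxa)] <- i
  }
  art <- rep(FALSE, max(nrow(edges), 0L))
  if ("artificial_parent_edge" %in% names(lab) && nrow(edges)) {
    flagged <- which(lab$artificial_parent_edge == "TRUE")
    art <- apply(edges, 1, function(e) any(e %in% flagged) &&
                   any(lab$artificial_parent_edge[e] == "TRUE"))
  }
  structure(
    list(n_nodes = k, species = species, node_names = lab$node,
         edges = edges, artificial = art,
         node_of_taxon = node_of_taxon, taxa = M$taxa,
         characters = M$characters),
    class = "perfect_phylogeny")
}
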
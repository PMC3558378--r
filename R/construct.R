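#' Decide and construct a perfect phylogeny
#'
#' Runs the seven-step separator pipeline: (1) reject if any character
#' pair's two-color graph has a cycle; (2) generate the legal minimal
#' separators with fewer than m vertices from proper clusters; (3)
#' reject if some monochromatic vertex pair is separated by none of
#' them; (4) compute the pairwise parallel relation; (5) greedily pick
#' a maximal pairwise parallel family; (6) saturate the family into a
#' proper minimal triangulation; (7) read a Maximum Cardinality Search
#' clique tree of the triangulation out as the phylogeny.
#'
#' Incompatible data is a result, not an error: the function then
#' returns an `incompatibility_report` carrying the rejecting step (1
#' or 3) and a witness (a cyclic character pair, or an unseparated
#' monochromatic state pair).
#'
#' @param M a [character_matrix()].
#' @param seed optional integer; shuffles the greedy order in step 5
#'   (any maximal family is correct, so this varies the tree returned,
#'   not the verdict).
#' @return a verified `perfect_phylogeny`, or an
#'   `incompatibility_report`.
#' @examples
#' fx <- pp_fixtures()
#' construct_phylogeny(fx$F1)
#' construct_phylogeny(fx$F4)
#' @export
construct_phylogeny <- function(M, seed = NULL) {
  stopifnot(inherits(M, "character_matrix"))
  bad <- cyclic_character_pairs(M)
  if (nrow(bad) > 0L)
    return(incompatibility_report(
      step = 1L, witness = list(characters = unname(bad[1, ])),
      message = sprintf("characters %d and %d induce a cycle",
                        bad[1, 1], bad[1, 2])))
  D <- legal_minimal_separators(M)
  un <- unseparated_monochromatic_pairs(M, D)
  if (nrow(un) > 0L)
    return(incompatibility_report(
      step = 3L,
      witness = list(vertices = D$G$label[un[1, ]]),
      message = sprintf("monochromatic pair {%s, %s} is separated by no legal minimal separator",
                        D$G$label[un[1, 1]], D$G$label[un[1, 2]])))
  Q <- greedy_parallel_family(D, seed = seed)
  H <- saturate(D$G, Q)
  ct <- mcs_clique_tree(H)
  tree <- assemble_phylogeny(M, ct)
  ok <- verify_phylogeny(M, tree)
  if (!ok)
    pp_internal_error(paste("constructed tree failed verification:",
                            paste(attr(ok, "violations"), collapse = "; ")))
  tree
}

incompatibility_report <- function(step, witness, message) {
  structure(list(compatible = FALSE, step = step, witness = witness,
                 message = message),
            class = "incompatibility_report")
}

#' @export
print.incompatibility_report <- function(x, ...) {
  cat(sprintf("incompatible (step %d): %s\n", x$step, x$message))
  invisible(x)
}

#' Is this object a phylogeny (as opposed to an incompatibility report)?
#' @param x result of [construct_phylogeny()].
#' @return logical.
#' @export
is_compatible <- function(x) inherits(x, "perfect_phylogeny")

report_json <- function(x) {
  jsonlite::toJSON(list(compatible = FALSE, step = x$step,
                        witness = x$witness, message = x$message),
                   auto_unbox = TRUE)
}
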
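fx <- pp_fixtures()

# vertex ids from "c<char>_s<state>" labels
vid <- function(G, labels) match(labels, G$label)

# separator vertex sets as sorted label strings, for set comparison
sep_keys <- function(seps, G) {
  vapply(seps, function(s) {
    v <- if (inherits(s, "pp_separator")) s$vertices else s
    paste(sort(G$label[v]), collapse = "|")
  }, character(1))
}

# Erdos-Renyi adjacency matrix for oracle cross-checks
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
  adj | t(adj)
}

# small random instances shared by the property tests
random_instances <- function(seeds, nmax = 8, mmax = 8) {
  lapply(seeds, function(s) {
    n <- 3 + (s %% (nmax - 2))
    m <- 2 + (s %% (mmax - 1))
    random_pp_matrix(n, m, three_state_fraction = 0.5, seed = s)
  })
}
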
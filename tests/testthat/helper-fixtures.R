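# Shared fixtures, built in code at load time.

# Small hand-specified trees.
tree_cherry <- ape::read.tree(text = "(A:1,B:1);")
tree_balanced <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree_star3 <- ape::read.tree(text = "(A:1,B:1,C:1);")
tree_nonultra <- ape::read.tree(text = "(A:1,(B:1,C:2):1);")

# A reusable simulated study (complete data, no masking) for fit tests.
study50 <- simulate_path_model(
  sim_config(n_species = 50, missing_asr_fraction = 0, seed = 2024)
)

# Brute-force phylogenetic covariance: for each pair of tips, sum the
# branch lengths of the shared portion of their root-to-tip paths.
# Independent of ape::vcv (walks the edge table directly).
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- V[j, i] <- sum(tree$edge.length[shared])
    }
  }
  V
}

# A trait vector on a tree's tips, named.
tip_trait <- function(tree, values) stats::setNames(values, tree$tip.label)
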
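# Brute-force branch-enumeration oracles for phylogenetic diversity
# measures. Deliberately independent of the package's postorder
# accumulation: each branch's descendant leaves are found by naive
# recursive descent over the edge list, then every branch is classified
# one at a time.

oracle_branch_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_branch_leaves, tree = tree))
}

oracle_faith_pd <- function(features, tree) {
  total <- 0
  for (i in seq_len(nrow(tree$edge))) {
    leaves <- oracle_branch_leaves(tree, tree$edge[i, 2])
    if (any(leaves %in% features)) total <- total + tree$edge.length[i]
  }
  total
}

oracle_unweighted_unifrac <- function(a, b, tree) {
  uniq <- 0; both <- 0
  for (i in seq_len(nrow(tree$edge))) {
    leaves <- oracle_branch_leaves(tree, tree$edge[i, 2])
    in_a <- any(leaves %in% a); in_b <- any(leaves %in% b)
    len <- tree$edge.length[i]
    if (in_a || in_b) both <- both + len
    if (xor(in_a, in_b)) uniq <- uniq + len
  }
  if (both == 0) 0 else uniq / both
}

oracle_weighted_unifrac <- function(a, b, tree, normalized = FALSE) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(tree$edge))) {
    leaves <- oracle_branch_leaves(tree, tree$edge[i, 2])
    fa <- sum(a[leaves], na.rm = TRUE) / sum(a)
    fb <- sum(b[leaves], na.rm = TRUE) / sum(b)
    len <- tree$edge.length[i]
    num <- num + len * abs(fa - fb)
    den <- den + len * (fa + fb)
  }
  if (!normalized) num else if (den == 0) 0 else num / den
}

# random test instances
random_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, tip.label = sprintf("t%02d", seq_len(n_leaves)))
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 2), 3)
  tr
}

random_community <- function(tree) {
  k <- sample(seq_along(tree$tip.label), 1)
  sample(tree$tip.label, k)
}

random_counts <- function(tree) {
  x <- stats::rpois(length(tree$tip.label), 3)
  if (sum(x) == 0) x[sample(length(x), 1)] <- 1L
  stats::setNames(x, tree$tip.label)
}
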
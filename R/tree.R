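#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' phylogenetic diversity code relies on: a rooted tree, unique leaf labels,
#' and non-negative branch lengths. Edges without a stated branch length are
#' read as length 0. Internal node labels are ignored.
#'
#' @param path path to a newick file, or a newick string via `text`.
#' @param text optional newick string (used instead of `path`).
#' @return an [ape::phylo] tree.
#' @export
read_phylogeny <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) stop("unparseable newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick input")
  validate_phylogeny(tree)
}

#' Validate phylogeny invariants
#'
#' @param tree an [ape::phylo] tree.
#' @return the tree (branch lengths filled with 0 where absent), invisibly
#'   usable downstream.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop(sprintf("duplicate leaf label '%s'", dup[1L]))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree")
  if (!is.null(tree$root.edge)) {
    if (is.na(tree$root.edge)) tree$root.edge <- 0
    if (tree$root.edge < 0) stop("negative root edge")
  }
  # the unique basal node is the root; a basal polytomy (e.g. a star tree)
  # is a valid rooted topology for path-union diversity measures
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root) != 1L)
    stop("tree must have exactly one root")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Align a feature table with a phylogeny
#'
#' Restricts the table to features present as tree leaves and prunes the
#' tree to leaves present in the table. Pruning collapses unary internal
#' nodes, accumulating their branch lengths, so the root-to-leaf path length
#' of every retained leaf is preserved. Features in the table but absent
#' from the tree (e.g. sOTUs that failed phylogenetic placement) are dropped
#' and counted, never silently imputed.
#'
#' @param table a [feature_table()].
#' @param tree an [ape::phylo] tree whose leaf labels are feature ids.
#' @return list with elements `table`, `tree`, `dropped_features` (ids
#'   removed from the table) and `dropped_leaves` (ids pruned from the tree).
#' @export
align_table_tree <- function(table, tree) {
  tree <- validate_phylogeny(tree)
  shared <- intersect(colnames(table), tree$tip.label)
  if (!length(shared))
    stop("no features shared between table and tree leaves")
  dropped_features <- setdiff(colnames(table), shared)
  dropped_leaves <- setdiff(tree$tip.label, shared)
  out_table <- table
  if (length(dropped_features)) {
    out_table <- unclass(table)[, shared, drop = FALSE]
    class(out_table) <- class(table)
  }
  out_tree <- tree
  if (length(dropped_leaves)) {
    pruned <- ape::keep.tip(tree, shared)
    # basal edges collapsed away by the pruning are accumulated into the
    # stem (root.edge), so every retained leaf keeps its original
    # root-to-leaf path length
    d0 <- ape::node.depth.edgelength(tree)[match(shared, tree$tip.label)]
    d1 <- ape::node.depth.edgelength(pruned)[match(shared, pruned$tip.label)]
    stem <- unique(round(d0 - d1, 10))
    if (length(stem) != 1L)
      stop("pruning changed relative leaf depths")   # cannot happen
    old_stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
    if (stem > 0 || old_stem > 0) pruned$root.edge <- old_stem + stem
    out_tree <- validate_phylogeny(pruned)
  }
  list(table = out_table, tree = out_tree,
       dropped_features = dropped_features, dropped_leaves = dropped_leaves)
}
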
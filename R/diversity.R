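# stem (root.edge) length: a branch above the root through which every
# leaf descends; produced by align_table_tree() when basal edges are
# collapsed, so pruned trees keep their original root-to-leaf depths
.stem <- function(tree) if (is.null(tree$root.edge)) 0 else tree$root.edge

# Per-node totals of a tip-indexed quantity, by postorder accumulation.
# x is a vector (or matrix with one column per sample) over tree$tip.label;
# returns totals over all nodes (tips first, then internal nodes, ape order).
.node_totals <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.matrix(x)) {
    tot <- matrix(0, nnode, ncol(x))
    tot[seq_len(ntip), ] <- x
    for (i in seq_len(nrow(po$edge))) {
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      tot[p, ] <- tot[p, ] + tot[ch, ]
    }
  } else {
    tot <- numeric(nnode)
    tot[seq_len(ntip)] <- x
    for (i in seq_len(nrow(po$edge))) {
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      tot[p] <- tot[p] + tot[ch]
    }
  }
  tot
}

.tip_vector <- function(tree, features) {
  bad <- setdiff(features, tree$tip.label)
  if (length(bad))
    stop(sprintf("feature '%s' not found among tree leaves", bad[1L]))
  as.numeric(tree$tip.label %in% features)
}

.tip_counts <- function(tree, counts) {
  if (is.null(names(counts)))
    stop("count vector must be named by feature id")
  bad <- setdiff(names(counts)[counts > 0], tree$tip.label)
  if (length(bad))
    stop(sprintf("feature '%s' not found among tree leaves", bad[1L]))
  x <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  keep <- intersect(names(counts), tree$tip.label)
  x[keep] <- counts[keep]
  x
}

#' Shannon diversity of a count vector
#'
#' Shannon entropy H = -sum p_i log(p_i) over positive-count features, with
#' p_i the relative abundance. The default base is 2 (bits), the dominant
#' convention in amplicon pipelines; `base` is exposed for nats or dits.
#'
#' @param counts non-negative numeric vector of read counts.
#' @param base logarithm base (default 2).
#' @return Shannon diversity (>= 0).
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector: Shannon diversity undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Observed richness of a count vector
#'
#' @param counts non-negative numeric vector of read counts.
#' @return integer number of features with at least one read.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  sum(counts > 0)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths over the union of root-to-leaf paths of the present
#' features. The convention is root-inclusive: the branches connecting the
#' present subtree to the tree root are counted.
#'
#' @param features character vector of present feature ids (tree leaves).
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @return total branch length (>= 0) spanned by the present features.
#' @export
faith_pd <- function(features, tree) {
  if (!length(features)) stop("empty feature set")
  tree <- validate_phylogeny(tree)
  tot <- .node_totals(tree, .tip_vector(tree, unique(features)))
  sum(tree$edge.length[tot[tree$edge[, 2L]] > 0]) + .stem(tree)
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of total branch length (over the union of the two communities'
#' root-to-leaf paths) that is unique to exactly one community. A branch
#' belongs to a community when any leaf descending through it is present.
#'
#' @param a,b character vectors of present feature ids.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @return distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(a, b, tree) {
  if (!length(a) || !length(b)) stop("empty community")
  tree <- validate_phylogeny(tree)
  ta <- .node_totals(tree, .tip_vector(tree, unique(a)))
  tb <- .node_totals(tree, .tip_vector(tree, unique(b)))
  child <- tree$edge[, 2L]
  in_a <- ta[child] > 0
  in_b <- tb[child] > 0
  len <- tree$edge.length
  denom <- sum(len[in_a | in_b]) + .stem(tree)   # stem is shared by both
  if (denom == 0) return(0)
  sum(len[xor(in_a, in_b)]) / denom
}

#' Weighted UniFrac distance between two communities
#'
#' Raw form: sum over branches of branch length times |A - B|, where A and B
#' are the fractions of each community's reads descending through the
#' branch. The normalized form divides by the same sum with (A + B) in place
#' of |A - B|, bounding the distance to \[0, 1\]. The raw form is the
#' default; normalization is a flag so either convention can be reproduced
#' exactly.
#'
#' @param a,b named non-negative count vectors (names are feature ids).
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param normalized divide by the abundance-weighted total branch length.
#' @return non-negative distance (in \[0, 1\] when `normalized`).
#' @export
weighted_unifrac <- function(a, b, tree, normalized = FALSE) {
  if (sum(a) <= 0 || sum(b) <= 0) stop("zero-total count vector")
  tree <- validate_phylogeny(tree)
  fa <- .node_totals(tree, .tip_counts(tree, a) / sum(a))
  fb <- .node_totals(tree, .tip_counts(tree, b) / sum(b))
  child <- tree$edge[, 2L]
  len <- tree$edge.length
  raw <- sum(len * abs(fa[child] - fb[child]))   # stem carries |1 - 1| = 0
  if (!normalized) return(raw)
  denom <- sum(len * (fa[child] + fb[child])) + 2 * .stem(tree)
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise phylogenetic beta-diversity matrix
#'
#' Computes all pairwise UniFrac distances for the samples of a feature
#' table aligned to a tree. The per-branch descendant abundances are
#' computed once per sample, so large tables cost one tree traversal per
#' sample plus the pairwise combination step.
#'
#' @param table a [feature_table()] whose features exactly match the tree
#'   leaves (use [align_table_tree()] first).
#' @param tree rooted [ape::phylo] tree.
#' @param metric `"unweighted_unifrac"` or `"weighted_unifrac"`.
#' @param normalized for weighted UniFrac, use the normalized form.
#' @return symmetric `dist`-free base matrix with zero diagonal, dimnames
#'   the sample ids.
#' @export
beta_distance_matrix <- function(table, tree,
                                 metric = c("unweighted_unifrac",
                                            "weighted_unifrac"),
                                 normalized = FALSE) {
  metric <- match.arg(metric)
  tree <- validate_phylogeny(tree)
  if (!setequal(colnames(table), tree$tip.label))
    stop("table features and tree leaves differ; run align_table_tree() first")
  m <- unclass(table)[, tree$tip.label, drop = FALSE]
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop(sprintf("sample '%s' has zero total count",
                 rownames(m)[which(totals <= 0)[1L]]))
  n <- nrow(m)
  child <- tree$edge[, 2L]
  len <- tree$edge.length
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "unweighted_unifrac") {
    pres <- .node_totals(tree, t(m > 0))[child, , drop = FALSE] > 0
    # branch-length inner products: and[i,j] = sum len over branches in both
    storage.mode(pres) <- "double"
    and <- crossprod(pres * sqrt(len))
    tot <- diag(and)
    or <- outer(tot, tot, "+") - and + .stem(tree)
    uniq <- or - and - .stem(tree)
    d <- ifelse(or > 0, uniq / or, 0)
    diag(d) <- 0
    dimnames(d) <- list(rownames(m), rownames(m))
  } else {
    frac <- .node_totals(tree, t(m / totals))[child, , drop = FALSE]
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      diffs <- abs(frac[, js, drop = FALSE] - frac[, i])
      raw <- colSums(diffs * len)
      if (normalized) {
        den <- colSums((frac[, js, drop = FALSE] + frac[, i]) * len) +
          2 * .stem(tree)
        raw <- ifelse(den > 0, raw / den, 0)
      }
      d[i, js] <- raw
      d[js, i] <- raw
    }
  }
  d
}

#' Validate a distance matrix
#'
#' @param d square numeric matrix.
#' @return `d`, invisibly, if symmetric with zero diagonal and non-negative
#'   entries.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")
  if (any(d < -1e-12)) stop("negative distances")
  invisible(d)
}

#' Long-format alpha-diversity table
#'
#' @param table a [feature_table()].
#' @param tree rooted [ape::phylo] tree (required for `faith_pd`).
#' @param metrics subset of `c("richness", "shannon", "faith_pd")`.
#' @return data.frame with columns `sample_id`, `metric`, `value`.
#' @export
alpha_diversity <- function(table, tree = NULL,
                            metrics = c("richness", "shannon", "faith_pd")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if ("faith_pd" %in% metrics && is.null(tree))
    stop("faith_pd requires a tree")
  m <- unclass(table)
  out <- list()
  for (metric in metrics) {
    vals <- switch(metric,
      richness = apply(m, 1L, richness),
      shannon = apply(m, 1L, shannon),
      faith_pd = {
        tree <- validate_phylogeny(tree)
        pres <- t(m[, tree$tip.label, drop = FALSE] > 0)
        storage.mode(pres) <- "double"
        tot <- .node_totals(tree, pres)[tree$edge[, 2L], , drop = FALSE] > 0
        as.numeric(crossprod(tot, tree$edge.length)) + .stem(tree)
      })
    out[[metric]] <- data.frame(sample_id = rownames(m), metric = metric,
                                value = as.numeric(vals),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a square distance matrix as TSV
#'
#' Square layout with a header row and identifier column, interoperable
#' with common ecology tools.
#'
#' @param d symmetric matrix with sample-id dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  d <- as.matrix(raw)
  validate_distance_matrix(d)
  d
}
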
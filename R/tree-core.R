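# Rooted-tree plumbing: reading, writing, pruning, node ages, subsampling.
# Trees are ape "phylo" objects; tree samples are "multiPhylo" lists over a
# shared taxon set (the container used for Bayesian posterior samples).

#' Read phylogenies from Newick or NEXUS files
#'
#' Reads one or more rooted trees, resolving NEXUS translate tables to tip
#' labels and normalising labels (spaces to underscores, quotes stripped) so
#' they match trait tables from other sources. All trees in the file are
#' returned, in file order, as a `multiPhylo`.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (sniff the `#NEXUS` header), `"newick"`, `"nexus"`.
#' @return a `multiPhylo` object (length >= 1).
#' @export
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("(A:1,B:1);", f)
#' read_trees(f)
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("tree file not found: %s", path)
  if (format == "auto") {
    head1 <- toupper(trimws(readLines(path, n = 5L, warn = FALSE)))
    format <- if (any(startsWith(head1, "#NEXUS"))) "nexus" else "newick"
  }
  trees <- tryCatch(
    switch(format,
           newick = ape::read.tree(path),
           nexus  = ape::read.nexus(path)),
    error = function(e)
      stop_validation("cannot parse %s as %s: %s", path, format,
                      conditionMessage(e)))
  if (is.null(trees)) stop_validation("no trees found in %s", path)
  trees <- as_tree_sample(trees)
  for (i in seq_along(trees)) {
    trees[[i]]$tip.label <- normalise_label(trees[[i]]$tip.label)
    check_phylo(trees[[i]])
  }
  attr(trees, "source") <- path
  trees
}

#' @rdname read_trees
#' @param trees a `phylo` or `multiPhylo`.
#' @param digits significant digits for branch lengths on output.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus"),
                        digits = 12) {
  format <- match.arg(format)
  trees <- as_tree_sample(trees)
  if (format == "newick") {
    ape::write.tree(trees, file = path, digits = digits)
  } else {
    ape::write.nexus(trees, file = path, translate = TRUE)
  }
  invisible(path)
}

#' Coerce to a tree sample
#'
#' Wraps a single `phylo` (or list of them) as a `multiPhylo`, checking that
#' every element is a valid tree.
#'
#' @param x a `phylo`, `multiPhylo`, or list of `phylo`.
#' @return a `multiPhylo`.
#' @export
as_tree_sample <- function(x) {
  if (inherits(x, "phylo")) x <- structure(list(x), class = "multiPhylo")
  if (!inherits(x, "multiPhylo")) {
    if (!is.list(x) || !length(x) || !all(vapply(x, inherits, TRUE, "phylo")))
      stop_validation("cannot interpret input as a set of trees")
    class(x) <- "multiPhylo"
  }
  if (!length(x)) stop_validation("empty tree sample")
  x
}

#' Prune a tree to a taxon subset
#'
#' Drops all tips not in `keep`, suppressing the resulting unbranched internal
#' nodes with branch lengths summed, so patristic distances among retained
#' tips are conserved exactly.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain (>= 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  check_phylo(tree)
  keep <- unique(normalise_label(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop_validation("labels not in tree: %s", paste(missing, collapse = ", "))
  if (length(keep) < 2)
    stop_validation("pruning must retain at least 2 tips (got %d)",
                    length(keep))
  ape::keep.tip(tree, keep)
}

#' Node ages of a dated tree
#'
#' Ages are measured in time units before the present: for every node,
#' age = (maximum root-to-tip path length) - (root-to-node path length), so
#' the tips of an ultrametric tree sit at age 0 and the root is deepest.
#' Non-ultrametric trees are flagged, not rejected, since posterior samples
#' may carry small rounding jitter.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tolerance relative tolerance: the tree is flagged non-ultrametric
#'   when any tip age exceeds `tolerance * depth`.
#' @return numeric vector of ages indexed by node number (tips first), with
#'   attributes `ultrametric` (logical) and `depth` (root age).
#' @export
node_ages <- function(tree, tolerance = 1e-6) {
  check_phylo(tree)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop_validation("node_ages requires complete branch lengths")
  depth_from_root <- ape::node.depth.edgelength(tree)
  depth <- max(depth_from_root)
  ages <- depth - depth_from_root
  tip_ages <- ages[seq_len(n_tips(tree))]
  ultra <- all(tip_ages <= tolerance * max(depth, .Machine$double.eps))
  names(ages) <- c(tree$tip.label,
                   as.character(root_node(tree) - 1L + seq_len(tree$Nnode)))
  structure(ages, ultrametric = ultra, depth = depth)
}

#' Subsample a tree set without replacement
#'
#' @param sample a `multiPhylo`.
#' @param n number of trees to draw (uniformly, without replacement).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG.
#' @return a `multiPhylo` of length `n`.
#' @export
subsample_trees <- function(sample, n, seed = NULL) {
  sample <- as_tree_sample(sample)
  if (n < 1 || n > length(sample))
    stop_validation("n must be in 1..%d (got %s)", length(sample), n)
  idx <- with_seed(seed, sample.int(length(sample), n))
  out <- sample[idx]
  class(out) <- "multiPhylo"
  out
}
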
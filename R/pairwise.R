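# Phylogenetically independent pairwise comparisons: pairs of species
# contrasting in a predictor trait (e.g. succulence) whose connecting paths
# share no tree edges, scored by a sign test on a dependent trait (e.g.
# medicinal use). Pair selection is a seeded greedy post-order pass; because
# pools passed up a branch are always monochromatic in the predictor and at
# most one tip may cross any edge, the resulting paths are edge-disjoint by
# construction (and verified structurally on every run).

# Edges (as "parent-child" keys) on the path between two tips via their MRCA.
.path_edges <- function(tree, a, b, parent_of) {
  anc <- function(t) {
    out <- t
    while (!is.na(parent_of[out[length(out)]]))
      out <- c(out, parent_of[out[length(out)]])
    out
  }
  pa <- anc(a); pb <- anc(b)
  mrca <- pa[match(TRUE, pa %in% pb)]
  up <- function(p) {
    i <- match(mrca, p)
    if (i < 2) character(0)
    else paste(p[2:i], p[1:(i - 1)], sep = "-")
  }
  c(up(pa), up(pb))
}

#' Select phylogenetically independent pairs contrasting in a predictor
#'
#' Greedy post-order pairing: each subtree passes up at most one unpaired
#' candidate tip (chosen uniformly at random among those available, all of
#' which share the same predictor state); at each internal node, candidates
#' from different child subtrees with contrasting predictor states are
#' matched uniformly at random. The paths connecting the resulting pairs are
#' edge-disjoint and each tip is used at most once; the set is maximal for
#' the greedy order and reproducible per seed.
#'
#' @param tree a rooted `phylo`.
#' @param predictor named 0/1 vector over the tips (non-constant).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return class `"pair_set"`: data frame with columns `tip1`, `tip0`
#'   (labels of the state-1 and state-0 tip), `node` (matching node), and
#'   attribute `paths` (list of edge-key vectors consumed by each pair).
#' @export
select_independent_pairs <- function(tree, predictor, seed = NULL) {
  check_phylo(tree)
  x <- align_trait(tree, predictor)
  if (all(x == x[[1]]))
    stop_validation("no contrasting pairs: predictor is constant")
  ntip <- n_tips(tree)
  with_seed(seed, {
    po <- ape::reorder.phylo(tree, "postorder")
    kids_of <- split(po$edge[, 2L], po$edge[, 1L])
    # candidate tip passed up through each node (0 = none), and its state
    cand <- integer(ntip + tree$Nnode)
    cand[seq_len(ntip)] <- seq_len(ntip)
    pairs <- list()
    for (v in unique(po$edge[, 1L])) {
      ch <- kids_of[[as.character(v)]]
      cs <- cand[ch]
      cs <- cs[cs > 0L]
      if (length(cs)) {
        zeros <- cs[x[cs] == 0L]
        ones <- cs[x[cs] == 1L]
        nm <- min(length(zeros), length(ones))
        if (nm > 0L) {
          z <- if (length(zeros) > 1L) sample(zeros, nm) else zeros
          o <- if (length(ones) > 1L) sample(ones, nm) else ones
          for (i in seq_len(nm))
            pairs[[length(pairs) + 1L]] <-
              data.frame(tip1 = o[i], tip0 = z[i], node = v)
          cs <- setdiff(cs, c(z[seq_len(nm)], o[seq_len(nm)]))
        }
        cand[v] <- if (!length(cs)) 0L
          else if (length(cs) == 1L) cs
          else sample(cs, 1L)     # only one tip may cross the edge above
      }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs)
      else data.frame(tip1 = integer(), tip0 = integer(), node = integer())
    parent_of <- rep(NA_integer_, ntip + tree$Nnode)
    parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
    paths <- lapply(seq_len(nrow(pairs)), function(i)
      .path_edges(tree, pairs$tip1[i], pairs$tip0[i], parent_of))
    if (length(paths) && anyDuplicated(unlist(paths)))
      stop("internal error: selected pair paths share an edge")  # hard assert
    out <- data.frame(tip1 = tree$tip.label[pairs$tip1],
                      tip0 = tree$tip.label[pairs$tip0],
                      node = pairs$node)
    structure(out, paths = paths, class = c("pair_set", "data.frame"))
  })
}

#' Sign test for correlated change over independent pairs
#'
#' Within each pair the predictor states differ by construction; a pair is
#' informative when the dependent states differ too. Under the null that the
#' dependent trait is distributed independently of the predictor, the
#' direction of each informative difference is a fair coin, so the one-tailed
#' p-value is the binomial tail `P(X >= k)` with `n` informative pairs and
#' `k` concordant ones (direction `+1`: the predictor-1 tip also shows
#' dependent state 1; direction `-1`: the reverse).
#'
#' @param pairs a `pair_set` from [select_independent_pairs].
#' @param dependent named 0/1 vector over the tips.
#' @param direction `+1` or `-1`, the hypothesised direction of association.
#' @param two_tailed double the one-tailed p (capped at 1).
#' @return class `"pairwise_result"`: list with `n_pairs`, `n_informative`,
#'   `n_concordant`, `p`, `direction`, `two_tailed`, and `undefined` (TRUE
#'   when no pair is informative; `p` is then `NA`, flagged, not an error).
#' @export
sign_test <- function(pairs, dependent, direction = 1, two_tailed = FALSE) {
  if (!inherits(pairs, "pair_set"))
    stop_validation("pairs must come from select_independent_pairs()")
  if (!nrow(pairs)) stop_validation("empty pair set")
  if (!direction %in% c(1, -1)) stop_validation("direction must be +1 or -1")
  if (is.data.frame(dependent))
    dependent <- stats::setNames(dependent[[2]], dependent[[1]])
  names(dependent) <- normalise_label(names(dependent))
  y1 <- dependent[pairs$tip1]
  y0 <- dependent[pairs$tip0]
  informative <- !is.na(y1) & !is.na(y0) & y1 != y0
  n <- sum(informative)
  conc <- if (direction == 1) sum(y1[informative] == 1)
          else sum(y0[informative] == 1)
  if (n == 0) {
    return(structure(list(n_pairs = nrow(pairs), n_informative = 0L,
                          n_concordant = 0L, p = NA_real_,
                          direction = direction, two_tailed = two_tailed,
                          undefined = TRUE),
                     class = "pairwise_result"))
  }
  p <- stats::pbinom(conc - 1, n, 0.5, lower.tail = FALSE)
  if (two_tailed) p <- min(1, 2 * p)
  structure(list(n_pairs = nrow(pairs), n_informative = as.integer(n),
                 n_concordant = as.integer(conc), p = p,
                 direction = direction, two_tailed = two_tailed,
                 undefined = FALSE),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise comparison test: %d pair(s), %d informative, %d concordant\n",
              x$n_pairs, x$n_informative, x$n_concordant))
  if (x$undefined) cat("  p undefined (no informative pairs)\n")
  else cat(sprintf("  %s p = %.*g (direction %+d)\n",
                   if (x$two_tailed) "two-tailed" else "one-tailed",
                   digits, x$p, x$direction))
  invisible(x)
}

#' Pairwise test over many random pair sets
#'
#' Pair selection is random, so the test is repeated over `n_sets`
#' independently seeded selections and summarised by the median p (the full
#' per-set distribution is retained). Sets with no informative pairs are
#' excluded from the median and counted.
#'
#' @inheritParams select_independent_pairs
#' @param dependent named 0/1 vector over the tips.
#' @param n_sets number of random pair sets (>= 1).
#' @param direction,two_tailed passed to [sign_test].
#' @return class `"pairwise_sets"`: list with `median_p`, `mean_p`,
#'   `p_values` (per set), `n_undefined`, `results` (per-set
#'   `pairwise_result`s).
#' @export
pairwise_over_sets <- function(tree, predictor, dependent, n_sets = 100,
                               seed = NULL, direction = 1,
                               two_tailed = FALSE) {
  if (n_sets < 1) stop_validation("n_sets must be >= 1")
  results <- lapply(seq_len(n_sets), function(i) {
    ps <- select_independent_pairs(tree, predictor,
                                   seed = derive_seed(seed, i))
    sign_test(ps, dependent, direction = direction, two_tailed = two_tailed)
  })
  p <- vapply(results, `[[`, 0, "p")
  structure(list(median_p = stats::median(p, na.rm = TRUE),
                 mean_p = mean(p, na.rm = TRUE),
                 p_values = p, n_sets = n_sets,
                 n_undefined = sum(is.na(p)), results = results),
            class = "pairwise_sets")
}

#' @export
print.pairwise_sets <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise test over %d pair set(s): median p = %.*g (mean %.*g, %d undefined)\n",
              x$n_sets, digits, x$median_p, digits, x$mean_p, x$n_undefined))
  invisible(x)
}

#' Pairwise test over a posterior tree sample
#'
#' Runs [pairwise_over_sets] on every tree (same seed per tree, so identical
#' trees give identical results) and reports the median of the per-tree
#' median p-values.
#'
#' @param sample a `multiPhylo`.
#' @inheritParams pairwise_over_sets
#' @return class `"pairwise_trees"`: list with `median_p` (median of
#'   medians), `per_tree_median_p`, `n_failed`, `results`.
#' @export
pairwise_over_trees <- function(sample, predictor, dependent, n_sets = 100,
                                seed = NULL, direction = 1,
                                two_tailed = FALSE) {
  sample <- as_tree_sample(sample)
  results <- lapply(seq_along(sample), function(i)
    tryCatch(pairwise_over_sets(sample[[i]], predictor, dependent,
                                n_sets = n_sets, seed = seed,
                                direction = direction,
                                two_tailed = two_tailed),
             error = function(e) e))
  ok <- vapply(results, inherits, TRUE, "pairwise_sets")
  med <- vapply(results[ok], `[[`, 0, "median_p")
  structure(list(median_p = stats::median(med, na.rm = TRUE),
                 per_tree_median_p = med,
                 n_trees = length(sample), n_failed = sum(!ok),
                 results = results),
            class = "pairwise_trees")
}

#' @export
print.pairwise_trees <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise test over %d tree(s) (%d failed): median of per-tree median p = %.*g\n",
              x$n_trees, x$n_failed, digits, x$median_p))
  invisible(x)
}
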
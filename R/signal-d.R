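# Phylogenetic signal in binary traits: the D statistic. The observed sum of
# nodal value changes is rescaled between two simulated expectations — random
# shuffling of the trait at its observed prevalence (no signal, D = 1) and a
# Brownian-threshold simulation at the same prevalence (Brownian clumping,
# D = 0) — so D is comparable across trees and prevalences.
#
# Nodal estimator: internal node values are the arithmetic mean of their
# children's values, computed tips-to-root; d_sum is the sum over non-root
# nodes of |value(node) - value(parent)|. Because the observed d and both
# null expectations use the same estimator, the calibration endpoints (1 for
# shuffled, 0 for Brownian-threshold traits) hold for any consistent
# estimator; absolute d values may differ from other implementations.

# Sum of nodal changes for one or many traits at once. `tipmat` is an
# n_tips x m 0/1 matrix; returns a length-m vector.
d_sum_matrix <- function(tree, tipmat) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- n_tips(tree)
  ntot <- ntip + tree$Nnode
  m <- ncol(tipmat)
  vals <- matrix(0, ntot, m)
  vals[seq_len(ntip), ] <- tipmat
  acc <- matrix(0, ntot, m)
  cnt <- integer(ntot)
  ne <- nrow(po$edge)
  for (i in seq_len(ne)) {          # postorder: children settled before use
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    if (ch > ntip) vals[ch, ] <- acc[ch, ] / cnt[ch]
    acc[p, ] <- acc[p, ] + vals[ch, ]
    cnt[p] <- cnt[p] + 1L
  }
  rt <- root_node(tree)
  vals[rt, ] <- acc[rt, ] / cnt[rt]
  d <- numeric(m)
  for (i in seq_len(ne)) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    d <- d + abs(vals[ch, ] - vals[p, ])
  }
  d
}

#' Sum of nodal value changes for a binary trait
#'
#' Internal node values are computed tips-to-root as the mean of child
#' values (tips carry their 0/1 state); the statistic is the sum over all
#' non-root nodes of the absolute difference from the parent value.
#' Polytomies are handled natively by the same recursion. This is the raw
#' quantity rescaled into the D statistic by [phylo_d].
#'
#' @param tree a rooted `phylo`.
#' @param trait named 0/1 vector (or 2-column data frame) over the tips; no
#'   missing values (prune first).
#' @return a single nonnegative number.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' d_sum(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1.0
d_sum <- function(tree, trait) {
  check_phylo(tree)
  x <- align_trait(tree, trait)
  d_sum_matrix(tree, matrix(x, ncol = 1L))
}

# Null d distributions for a fixed tree and prevalence, vectorised across
# replicates.
.null_d_random <- function(tree, k, n_sim) {
  n <- n_tips(tree)
  tipmat <- matrix(0L, n, n_sim)
  for (j in seq_len(n_sim)) tipmat[sample.int(n, k), j] <- 1L
  d_sum_matrix(tree, tipmat)
}

.null_d_brownian <- function(tree, k, n_sim) {
  x <- bm_tip_values(tree, n_sim)
  d_sum_matrix(tree, threshold_top_k(x, k))
}

#' Phylogenetic signal in a binary trait (D statistic)
#'
#' Computes `D = (d_obs - mean(d_brownian)) / (mean(d_random) -
#' mean(d_brownian))`, where the null means are Monte Carlo expectations of
#' the nodal-change sum under `n_sim` prevalence-preserving random shuffles
#' and `n_sim` Brownian-threshold simulations on the same tree. D is
#' reported unclamped: values below 0 (more clumped than Brownian) or above
#' 1 (overdispersed) are admissible. Simulation p-values use a pseudocount,
#' `(1 + b) / (1 + n_sim)`, so they are never exactly zero:
#' `p_vs_random` counts null shuffles at least as clumped as the observed
#' trait (`d_rand <= d_obs`), `p_vs_brownian` counts Brownian nulls at least
#' as dispersed (`d_brown >= d_obs`).
#'
#' @inheritParams d_sum
#' @param n_sim number of null simulations per scenario (>= 100).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param missing_action how to treat tips with missing states:
#'   `"prune"` drops them from the tree, `"as_zero"` scores them 0.
#' @return object of class `"phylo_d"`: list with `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_vs_random`, `p_vs_brownian`, `n_sim`,
#'   `seed`, `prevalence`, `n_tips`, and the two null vectors
#'   (`null_d_random`, `null_d_brownian`).
#' @export
phylo_d <- function(tree, trait, n_sim = 1000, seed = NULL,
                    missing_action = c("prune", "as_zero")) {
  check_phylo(tree)
  missing_action <- match.arg(missing_action)
  if (n_sim < 100) stop_validation("n_sim must be >= 100 (got %s)", n_sim)
  x <- align_trait(tree, trait, allow_missing = TRUE)
  if (anyNA(x)) {
    if (missing_action == "prune") {
      keep <- names(x)[!is.na(x)]
      if (length(keep) < 2)
        stop_validation("fewer than 2 tips with non-missing states")
      tree <- prune_to_taxa(tree, keep)
      x <- x[tree$tip.label]
    } else {
      x[is.na(x)] <- 0L
    }
  }
  n <- n_tips(tree)
  k <- sum(x == 1L)
  if (k == 0L || k == n)
    stop_validation("signal undefined at prevalence 0 or n (constant trait)")
  with_seed(seed, {
    d_obs <- d_sum_matrix(tree, matrix(x, ncol = 1L))
    d_rand <- .null_d_random(tree, k, n_sim)
    d_brown <- .null_d_brownian(tree, k, n_sim)
    mr <- mean(d_rand); mb <- mean(d_brown)
    if (abs(mr - mb) < 1e-9 * max(mr, 1e-300))
      stop_validation(paste0(
        "degenerate D denominator (null means %.6g and %.6g nearly equal); ",
        "a larger tree is needed"), mr, mb)
    structure(list(
      d_obs = unname(d_obs), mean_d_random = mr, mean_d_brownian = mb,
      D = unname((d_obs - mb) / (mr - mb)),
      p_vs_random = (1 + sum(d_rand <= d_obs)) / (1 + n_sim),
      p_vs_brownian = (1 + sum(d_brown >= d_obs)) / (1 + n_sim),
      n_sim = n_sim, seed = seed, prevalence = k, n_tips = n,
      null_d_random = d_rand, null_d_brownian = d_brown),
      class = "phylo_d")
  })
}

#' @export
print.phylo_d <- function(x, digits = 4, ...) {
  cat(sprintf("Phylogenetic signal (D) for a binary trait (%d of %d tips in state 1)\n",
              x$prevalence, x$n_tips))
  cat(sprintf("  d_obs = %.*g; null means: random %.*g, Brownian %.*g (n_sim = %d)\n",
              digits, x$d_obs, digits, x$mean_d_random, digits,
              x$mean_d_brownian, x$n_sim))
  cat(sprintf("  D = %.*g; P(random null <= d_obs) = %.*g; P(Brownian null >= d_obs) = %.*g\n",
              digits, x$D, digits, x$p_vs_random, digits, x$p_vs_brownian))
  invisible(x)
}

#' D statistic over a posterior tree sample
#'
#' Runs [phylo_d] on every tree of a sample sharing the trait's taxon set and
#' summarises by the median D, median p-values, and 2.5/97.5 percentile
#' intervals — the standard way of propagating topological uncertainty from
#' a Bayesian posterior. Every tree receives the same seed, so a sample of
#' identical trees reproduces the single-tree result exactly. Trees failing
#' the D preconditions are recorded as failures and excluded from the
#' summaries.
#'
#' @param sample a `multiPhylo` over a shared taxon set.
#' @inheritParams phylo_d
#' @return class `"phylo_d_sample"`: list with `results` (per-tree
#'   `phylo_d` or condition objects), `D` (vector), `median_D`,
#'   `median_p_vs_random`, `median_p_vs_brownian`, `ci_D` (2.5/97.5
#'   percentiles), `n_failed`.
#' @export
phylo_d_over_sample <- function(sample, trait, n_sim = 1000, seed = NULL,
                                missing_action = c("prune", "as_zero")) {
  sample <- as_tree_sample(sample)
  missing_action <- match.arg(missing_action)
  results <- lapply(seq_along(sample), function(i) {
    tryCatch(phylo_d(sample[[i]], trait, n_sim = n_sim, seed = seed,
                     missing_action = missing_action),
             error = function(e) e)
  })
  ok <- vapply(results, inherits, TRUE, "phylo_d")
  Dv <- vapply(results[ok], `[[`, 0, "D")
  structure(list(
    results = results,
    D = Dv,
    median_D = stats::median(Dv),
    median_p_vs_random = stats::median(
      vapply(results[ok], `[[`, 0, "p_vs_random")),
    median_p_vs_brownian = stats::median(
      vapply(results[ok], `[[`, 0, "p_vs_brownian")),
    ci_D = if (length(Dv)) stats::quantile(Dv, c(0.025, 0.975)) else
      c(`2.5%` = NA_real_, `97.5%` = NA_real_),
    n_trees = length(sample), n_failed = sum(!ok)),
    class = "phylo_d_sample")
}

#' @export
print.phylo_d_sample <- function(x, digits = 4, ...) {
  cat(sprintf("D over %d trees (%d failed): median D = %.*g [%.*g, %.*g]\n",
              x$n_trees, x$n_failed, digits, x$median_D,
              digits, x$ci_D[[1]], digits, x$ci_D[[2]]))
  cat(sprintf("  median P vs random = %.*g; median P vs Brownian = %.*g\n",
              digits, x$median_p_vs_random, digits, x$median_p_vs_brownian))
  invisible(x)
}
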
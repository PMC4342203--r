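# Fitch parsimony for binary characters on rooted, possibly multifurcating
# trees. The bottom-up pass uses the standard multifurcation extension: a
# node's state set is the set of states contained in the largest number of
# child state sets, and the added cost is the number of children whose set
# excludes the chosen state (for bifurcations this reduces to classic
# Fitch). Transition polarity (gain 0->1 vs loss 1->0) depends on the
# reconstruction, so min/max gain and loss counts are reported over all
# most-parsimonious reconstructions via a second dynamic programme, with an
# accelerated-transformation resolution available as a concrete option.

#' Fitch parsimony ancestral states and transition counts
#'
#' @param tree a rooted `phylo` (polytomies allowed).
#' @param trait named 0/1 vector over the tips, no missing values.
#' @param resolution `"mpr"` reports only min/max over all
#'   most-parsimonious reconstructions; `"acctran"` additionally commits to
#'   one reconstruction in which ambiguous changes are placed as close to
#'   the root as possible.
#' @return class `"fitch_asr"`: list with `min_changes`, `node_sets`
#'   (per-node state sets as `"0"`, `"1"` or `"01"`), `gains_min`,
#'   `gains_max`, `losses_min`, `losses_max`, and (for
#'   `resolution = "acctran"`) `states`, `gains`, `losses` of the committed
#'   reconstruction.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch(tr, c(A = 1, B = 1, C = 0, D = 0))$min_changes  # 1
fitch <- function(tree, trait, resolution = c("mpr", "acctran")) {
  check_phylo(tree)
  resolution <- match.arg(resolution)
  x <- align_trait(tree, trait)
  ntip <- n_tips(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  kids_of <- split(po$edge[, 2L], po$edge[, 1L])   # parent -> children

  # bottom-up Sankoff for 2 states: m = min subtree cost; pen[v, s+1] =
  # cost(v, s) - m (0 for optimal states, possibly > 1, Inf for a tip's
  # other state); Gmin/Gmax = min/max gains (0->1 changes) below v among
  # subtree reconstructions attaining cost(v, s)
  INF <- .Machine$integer.max %/% 4L
  m <- numeric(ntot)
  pen <- matrix(0L, ntot, 2L)
  pen[cbind(seq_len(ntip), 2L - x)] <- INF   # tip: other state impossible
  Gmin <- matrix(0, ntot, 2L)
  Gmax <- matrix(0, ntot, 2L)
  # optimal child states t given parent state s: minimise pen(c,t) + [t != s]
  opt_states <- function(cc, s) {
    costs <- c(pen[cc, 1L] + (s != 0L), pen[cc, 2L] + (s != 1L))
    which(costs == min(costs)) - 1L
  }
  internal_post <- unique(po$edge[, 1L])           # postorder: children first
  for (v in internal_post) {
    ch <- kids_of[[as.character(v)]]
    q <- vapply(0:1, function(s)
      sum(vapply(ch, function(cc)
        min(pen[cc, s + 1L], pen[cc, 2L - s] + 1L), 0)), 0)
    m[v] <- sum(m[ch]) + min(q)
    pen[v, ] <- as.integer(q - min(q))
    for (s in 0:1) {
      gmin <- 0; gmax <- 0
      for (cc in ch) {
        t_opts <- opt_states(cc, s)
        gopt <- vapply(t_opts, function(t)
          (s == 0L && t == 1L) + Gmin[cc, t + 1L], 0)
        gopt_max <- vapply(t_opts, function(t)
          (s == 0L && t == 1L) + Gmax[cc, t + 1L], 0)
        gmin <- gmin + min(gopt)
        gmax <- gmax + max(gopt_max)
      }
      Gmin[v, s + 1L] <- gmin
      Gmax[v, s + 1L] <- gmax
    }
  }
  rt <- root_node(tree)
  min_changes <- m[rt]
  root_states <- which(pen[rt, ] == 0L) - 1L
  gains_min <- min(Gmin[rt, root_states + 1L])
  gains_max <- max(Gmax[rt, root_states + 1L])
  node_sets <- vapply(seq_len(ntot), function(v)
    paste(which(pen[v, ] == 0L) - 1L, collapse = ""), "")
  out <- list(min_changes = as.integer(round(min_changes)),
              node_sets = node_sets,
              gains_min = as.integer(round(gains_min)),
              gains_max = as.integer(round(gains_max)),
              losses_min = as.integer(round(min_changes - gains_max)),
              losses_max = as.integer(round(min_changes - gains_min)),
              resolution = resolution)
  if (resolution == "acctran") {
    states <- integer(ntot)
    states[seq_len(ntip)] <- x
    states[rt] <- sort(root_states)[1L]
    gains <- 0L; losses <- 0L
    for (v in rev(internal_post)) {            # preorder: root first
      s <- states[v]
      for (cc in kids_of[[as.character(v)]]) {
        t_opts <- opt_states(cc, s)
        # accelerated transformation: when both states are optimal, place
        # the change on this edge rather than deeper in the subtree
        t <- if (length(t_opts) > 1L) 1L - s else t_opts
        states[cc] <- t
        if (s == 0L && t == 1L) gains <- gains + 1L
        if (s == 1L && t == 0L) losses <- losses + 1L
      }
    }
    out$states <- states
    out$gains <- gains
    out$losses <- losses
  }
  structure(out, class = "fitch_asr")
}

#' @export
print.fitch_asr <- function(x, ...) {
  cat(sprintf("Fitch parsimony: %d change(s); gains %d..%d, losses %d..%d over MPRs\n",
              x$min_changes, x$gains_min, x$gains_max,
              x$losses_min, x$losses_max))
  if (!is.null(x$states))
    cat(sprintf("  acctran resolution: %d gain(s), %d loss(es)\n",
                x$gains, x$losses))
  invisible(x)
}

#' Distribution of parsimony transition counts over a tree sample
#'
#' Applies [fitch] to every tree and tabulates the chosen transition count,
#' giving the fraction of trees supporting each count — the form in which
#' posterior support for, say, "six losses" is assessed.
#'
#' @param sample a `multiPhylo` over a shared taxon set.
#' @param trait named 0/1 vector.
#' @param count which per-tree count to tabulate: minimum losses, maximum
#'   losses, minimum gains, maximum gains, or the total change minimum.
#' @return class `"transition_distribution"`: list with `counts` (per-tree
#'   vector), `histogram` (data frame `count`, `n_trees`, `fraction`),
#'   `n_failed`.
#' @export
count_transitions_over_sample <- function(sample, trait,
                                          count = c("losses_min", "losses_max",
                                                    "gains_min", "gains_max",
                                                    "min_changes")) {
  sample <- as_tree_sample(sample)
  count <- match.arg(count)
  res <- lapply(seq_along(sample), function(i)
    tryCatch(fitch(sample[[i]], trait), error = function(e) e))
  ok <- vapply(res, inherits, TRUE, "fitch_asr")
  counts <- vapply(res[ok], `[[`, 0L, count)
  tab <- table(counts)
  structure(list(
    counts = counts,
    histogram = data.frame(count = as.integer(names(tab)),
                           n_trees = as.integer(tab),
                           fraction = as.integer(tab) / sum(ok)),
    statistic = count,
    n_trees = length(sample), n_failed = sum(!ok)),
    class = "transition_distribution")
}

#' @export
print.transition_distribution <- function(x, ...) {
  cat(sprintf("Parsimony %s over %d trees (%d failed):\n", x$statistic,
              x$n_trees, x$n_failed))
  print(x$histogram, row.names = FALSE)
  invisible(x)
}
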
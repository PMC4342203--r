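# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: parsimony by exhaustive enumeration of ancestral
# assignments, Fisher's exact test by explicit binomial-coefficient
# enumeration, Brownian tip values by direct multivariate-normal sampling
# from the analytic covariance matrix.

# Minimum parsimony changes (and gain range among minimal reconstructions)
# by brute force over all 2^Nnode internal assignments.
brute_fitch <- function(tree, trait) {
  nn <- tree$Nnode
  x <- trait[tree$tip.label]
  best <- Inf; gmin <- Inf; gmax <- -Inf
  for (code in 0:(2^nn - 1)) {
    st <- c(x, as.integer(intToBits(code))[seq_len(nn)])
    ch <- st[tree$edge[, 2]]
    pa <- st[tree$edge[, 1]]
    changes <- sum(ch != pa)
    gains <- sum(pa == 0 & ch == 1)
    if (changes < best) {
      best <- changes; gmin <- gains; gmax <- gains
    } else if (changes == best) {
      gmin <- min(gmin, gains); gmax <- max(gmax, gains)
    }
  }
  list(min_changes = best, gains_min = gmin, gains_max = gmax)
}

# Two-sided Fisher p by explicit enumeration of the hypergeometric support
# with log-binomial coefficients (minimum-likelihood rule).
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  pr <- exp(lchoose(m, support) + lchoose(n, k - support) -
              lchoose(m + n, k))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Tip values under Brownian motion sampled directly from the analytic
# covariance matrix (shared root-to-MRCA path lengths), independent of the
# package's tree-traversal simulation.
mvn_tip_values <- function(tree, nrep) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  Sigma <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mrca <- if (i == j) i else ape::getMRCA(tree, c(i, j))
    Sigma[i, j] <- depth[mrca]
  }
  L <- chol(Sigma)
  t(L) %*% matrix(stats::rnorm(n * nrep), n, nrep)
}

# Paths of tip pairs as edge keys, for edge-disjointness checks.
pair_path_edges <- function(tree, lab1, lab2) {
  i <- match(lab1, tree$tip.label)
  j <- match(lab2, tree$tip.label)
  parent_of <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  anc <- function(t) {
    out <- t
    while (!is.na(parent_of[out[length(out)]]))
      out <- c(out, parent_of[out[length(out)]])
    out
  }
  pa <- anc(i); pb <- anc(j)
  mrca <- pa[match(TRUE, pa %in% pb)]
  up <- function(p) {
    kk <- match(mrca, p)
    if (kk < 2) character(0)
    else paste(p[2:kk], p[1:(kk - 1)], sep = "-")
  }
  c(up(pa), up(pb))
}

# A fixed small ultrametric tree used in several tests.
balanced_tree <- function(n = 16) {
  stopifnot(log2(n) %% 1 == 0)
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
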
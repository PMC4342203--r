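# Synthetic-data generators. Every stage of the analysis can be exercised on
# simulated inputs with known ground truth: pure-birth trees, binary traits
# under shuffle / Brownian-threshold / Mk / correlated-pair models, forward
# range histories over a set of areas with a full event log, and toy gapped
# alignments for the indel coder. All generators take an explicit seed and
# are exactly reproducible.

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from two lineages at the root, each of the
#' current k lineages splits after an exponential waiting time with total
#' rate `k * birth_rate`; the clock stops one waiting time after the n-th
#' lineage appears, so all pendant branches are positive and the tree is
#' exactly ultrametric.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0), per unit time.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an ultrametric `phylo` with tips labelled `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n <- as.integer(n_tips)
  if (is.na(n) || n < 2) stop_validation("n_tips must be >= 2 (got %s)", n_tips)
  if (birth_rate <= 0) stop_validation("birth_rate must be > 0")
  with_seed(seed, {
    root <- n + 1L
    next_internal <- n + 2L
    edge <- matrix(0L, 2L * n - 2L, 2L)
    edge_len <- numeric(2L * n - 2L)
    ei <- 0L
    par <- c(root, root)       # parent node of each active lineage
    tstart <- c(0, 0)          # birth time of each active lineage
    t <- 0
    k <- 2L
    while (k < n) {
      t <- t + stats::rexp(1L, birth_rate * k)
      i <- sample.int(k, 1L)
      m <- next_internal
      next_internal <- next_internal + 1L
      ei <- ei + 1L
      edge[ei, ] <- c(par[i], m)
      edge_len[ei] <- t - tstart[i]
      par[i] <- m; tstart[i] <- t
      par <- c(par, m); tstart <- c(tstart, t)
      k <- k + 1L
    }
    t_end <- t + stats::rexp(1L, birth_rate * n)
    for (i in seq_len(n)) {
      ei <- ei + 1L
      edge[ei, ] <- c(par[i], i)
      edge_len[ei] <- t_end - tstart[i]
    }
    tree <- structure(list(edge = edge, edge.length = edge_len,
                           tip.label = paste0("t", seq_len(n)),
                           Nnode = n - 1L),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate a randomly shuffled binary trait
#'
#' Assigns state 1 to exactly `k` tips chosen uniformly at random, destroying
#' any phylogenetic structure: the null against which phylogenetic signal is
#' judged.
#'
#' @param tree a `phylo`.
#' @param k prevalence: number of tips in state 1, `0 < k < n_tips`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return named integer 0/1 vector over `tree$tip.label`.
#' @export
simulate_trait_random <- function(tree, k, seed = NULL) {
  check_phylo(tree)
  n <- n_tips(tree)
  if (k <= 0 || k >= n)
    stop_validation("prevalence k must satisfy 0 < k < %d (got %s)", n, k)
  with_seed(seed, {
    x <- integer(n)
    x[sample.int(n, k)] <- 1L
    stats::setNames(x, tree$tip.label)
  })
}

# Tip values of `nrep` independent unit-rate Brownian motions run from root
# value 0; per-branch increment variance equals the branch length. Returns an
# n_tips x nrep matrix. Vectorised across replicates for speed.
bm_tip_values <- function(tree, nrep = 1L) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntot <- n_tips(tree) + tree$Nnode
  x <- matrix(0, ntot, nrep)
  elen <- po$edge.length
  for (i in rev(seq_len(nrow(po$edge)))) {   # reverse postorder = root first
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    x[ch, ] <- if (elen[i] > 0)
      x[p, ] + stats::rnorm(nrep, 0, sqrt(elen[i]))
    else x[p, ]
  }
  x[seq_len(n_tips(tree)), , drop = FALSE]
}

# 0/1 matrix marking, per column, the k largest values; ties broken uniformly
# at random so the prevalence is always exactly k.
threshold_top_k <- function(xmat, k) {
  n <- nrow(xmat)
  out <- matrix(0L, n, ncol(xmat))
  for (j in seq_len(ncol(xmat))) {
    ord <- order(-xmat[, j], sample.int(n))
    out[ord[seq_len(k)], j] <- 1L
  }
  out
}

#' Simulate a binary trait under the Brownian threshold model
#'
#' A continuous liability evolves by Brownian motion from root value 0 with
#' per-branch variance equal to branch length; the `k` tips with the largest
#' liabilities receive state 1 (ties broken uniformly at random). This is the
#' strong-phylogenetic-dependence scenario of the D statistic: prevalence is
#' held exactly at `k` while closely related tips share correlated
#' liabilities. The Brownian rate is fixed at 1 because thresholding only
#' uses ranks.
#'
#' @inheritParams simulate_trait_random
#' @return named integer 0/1 vector over `tree$tip.label`.
#' @export
simulate_trait_brownian_threshold <- function(tree, k, seed = NULL) {
  check_phylo(tree)
  n <- n_tips(tree)
  if (k <= 0 || k >= n)
    stop_validation("prevalence k must satisfy 0 < k < %d (got %s)", n, k)
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop_validation("Brownian threshold needs positive branch lengths")
  with_seed(seed, {
    x <- bm_tip_values(tree, 1L)
    stats::setNames(drop(threshold_top_k(x, k)), tree$tip.label)
  })
}

# -- Mk (2-state continuous-time Markov) trait simulation ---------------------

# Simulate state evolution along one branch; returns final state and counts.
.mk_branch <- function(state, len, q01, q10) {
  n01 <- 0L; n10 <- 0L
  remaining <- len
  repeat {
    rate <- if (state == 0L) q01 else q10
    if (rate <= 0) break
    w <- stats::rexp(1L, rate)
    if (w >= remaining) break
    remaining <- remaining - w
    if (state == 0L) { state <- 1L; n01 <- n01 + 1L }
    else             { state <- 0L; n10 <- n10 + 1L }
  }
  list(state = state, n01 = n01, n10 = n10)
}

#' Simulate a binary trait under a 2-state Markov (Mk) model
#'
#' Continuous-time Markov chain with gain rate `q01` (0 to 1) and loss rate
#' `q10` (1 to 0) run from the root down every branch. The realised number of
#' changes per branch is retained, giving a ground truth against which
#' parsimony change counts can be compared (Fitch counts are lower bounds).
#'
#' @inheritParams simulate_trait_random
#' @param q01,q10 nonnegative per-unit-time transition rates.
#' @param root_state state at the root, 0 or 1.
#' @return an object of class `"mk_sim"`: list with `trait` (named 0/1
#'   vector), `node_states` (all-node states), `branch_changes` (data frame
#'   `parent`, `child`, `n01`, `n10`), `n_gains`, `n_losses`, and `constant`
#'   (flag set when both rates are zero).
#' @export
simulate_trait_mk <- function(tree, q01, q10, root_state = 0L, seed = NULL) {
  check_phylo(tree)
  if (q01 < 0 || q10 < 0) stop_validation("rates must be nonnegative")
  if (!root_state %in% c(0L, 1L)) stop_validation("root_state must be 0 or 1")
  with_seed(seed, {
    po <- ape::reorder.phylo(tree, "postorder")
    ntot <- n_tips(tree) + tree$Nnode
    states <- integer(ntot)
    states[root_node(tree)] <- as.integer(root_state)
    ne <- nrow(po$edge)
    n01 <- integer(ne); n10 <- integer(ne)
    for (i in rev(seq_len(ne))) {
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      res <- .mk_branch(states[p], po$edge.length[i], q01, q10)
      states[ch] <- res$state
      n01[i] <- res$n01; n10[i] <- res$n10
    }
    structure(list(
      trait = stats::setNames(states[seq_len(n_tips(tree))], tree$tip.label),
      node_states = states,
      branch_changes = data.frame(parent = po$edge[, 1L],
                                  child = po$edge[, 2L],
                                  n01 = n01, n10 = n10),
      n_gains = sum(n01), n_losses = sum(n10),
      constant = (q01 == 0 && q10 == 0)),
      class = "mk_sim")
  })
}

# -- Correlated pair of binary traits -----------------------------------------

#' Transition rates for the dependent two-trait model
#'
#' The joint chain over states (A,B) in \{00,01,10,11\} permits one change at
#' a time; the eight rates let each trait's gain/loss rate depend on the
#' current state of the other trait. `correlated_rates_independent()` builds
#' the null where the traits evolve independently;
#' `correlated_rates_strong()` is a strong-dependence preset in which the
#' dependent trait B tracks the predictor A closely (B is gained almost only
#' while A = 1 and lost almost only while A = 0), used for power studies.
#'
#' @param a01,a10 gain/loss rates of trait A (independent model).
#' @param b01,b10 gain/loss rates of trait B (independent model).
#' @return named numeric vector of length 8 with names
#'   `a01_b0, a10_b0, a01_b1, a10_b1, b01_a0, b10_a0, b01_a1, b10_a1`
#'   (e.g. `a01_b1` = rate of A 0→1 while B = 1).
#' @export
correlated_rates_independent <- function(a01 = 0.3, a10 = 0.3,
                                         b01 = 0.3, b10 = 0.3) {
  c(a01_b0 = a01, a10_b0 = a10, a01_b1 = a01, a10_b1 = a10,
    b01_a0 = b01, b10_a0 = b10, b01_a1 = b01, b10_a1 = b10)
}

#' @rdname correlated_rates_independent
#' @export
correlated_rates_strong <- function() {
  c(a01_b0 = 0.3, a10_b0 = 0.3, a01_b1 = 0.3, a10_b1 = 0.3,
    b01_a0 = 0.02, b10_a0 = 3, b01_a1 = 3, b10_a1 = 0.02)
}

#' Simulate two binary traits under a dependent 4-state model
#'
#' @inheritParams simulate_trait_random
#' @param rates named numeric vector of 8 nonnegative rates as produced by
#'   [correlated_rates_independent()].
#' @param root_state integer vector `c(a, b)` of root states.
#' @return class `"correlated_sim"`: list with `trait_a`, `trait_b` (named
#'   0/1 vectors), `node_states` (ntot x 2 matrix) and `history` (data frame
#'   of transitions: `child` branch, `trait` = "A"/"B", `from`, `to`,
#'   `other_state` = the other trait's state at the instant of change).
#' @export
simulate_correlated_traits <- function(tree, rates,
                                       root_state = c(0L, 0L), seed = NULL) {
  check_phylo(tree)
  needed <- c("a01_b0", "a10_b0", "a01_b1", "a10_b1",
              "b01_a0", "b10_a0", "b01_a1", "b10_a1")
  if (is.null(names(rates)) || !all(needed %in% names(rates)))
    stop_validation("rates must carry names %s", paste(needed, collapse = ", "))
  rates <- rates[needed]
  if (any(rates < 0)) stop_validation("rates must be nonnegative")
  with_seed(seed, {
    po <- ape::reorder.phylo(tree, "postorder")
    ntot <- n_tips(tree) + tree$Nnode
    st <- matrix(0L, ntot, 2L)
    st[root_node(tree), ] <- as.integer(root_state)
    hist <- list()
    for (i in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      a <- st[p, 1L]; b <- st[p, 2L]
      remaining <- po$edge.length[i]
      repeat {
        ra <- if (a == 0L) rates[[paste0("a01_b", b)]]
              else         rates[[paste0("a10_b", b)]]
        rb <- if (b == 0L) rates[[paste0("b01_a", a)]]
              else         rates[[paste0("b10_a", a)]]
        total <- ra + rb
        if (total <= 0) break
        w <- stats::rexp(1L, total)
        if (w >= remaining) break
        remaining <- remaining - w
        if (stats::runif(1L) < ra / total) {
          hist[[length(hist) + 1L]] <-
            data.frame(child = ch, trait = "A", from = a, to = 1L - a,
                       other_state = b)
          a <- 1L - a
        } else {
          hist[[length(hist) + 1L]] <-
            data.frame(child = ch, trait = "B", from = b, to = 1L - b,
                       other_state = a)
          b <- 1L - b
        }
      }
      st[ch, ] <- c(a, b)
    }
    history <- if (length(hist)) do.call(rbind, hist)
      else data.frame(child = integer(), trait = character(),
                      from = integer(), to = integer(),
                      other_state = integer())
    tipsq <- seq_len(n_tips(tree))
    structure(list(
      trait_a = stats::setNames(st[tipsq, 1L], tree$tip.label),
      trait_b = stats::setNames(st[tipsq, 2L], tree$tip.label),
      node_states = st, history = history),
      class = "correlated_sim")
  })
}

# -- Forward range evolution (dispersal-extinction-cladogenesis style) --------

.range_to_string <- function(r) paste(sort(r), collapse = "")

.string_to_range <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "")[[1]]
}

#' Simulate a geographic range history with a ground-truth event log
#'
#' Forward counterpart of dispersal-extinction-cladogenesis reconstructions.
#' Along each branch, the range gains each unoccupied area at rate `d` and
#' loses each occupied area at rate `e`, with each area changing at most
#' once per branch (an area gained along a branch is not lost again on the
#' same branch, and vice versa) so that the event history is exactly
#' identifiable from the node ranges it produces. Events are applied in time
#' order and loss proposals that would empty the range are rejected. At each
#' node, a single-area range is copied
#' to both children (within-area speciation); a wider range either splits
#' into two disjoint nonempty parts with probability `clado_prob_vicariance`
#' (vicariance) or is kept whole by one child while the other receives a
#' single area of it (peripheral isolation). Every anagenetic and
#' cladogenetic event is appended to the truth log with its time (age before
#' present).
#'
#' @param tree a dated (ultrametric) `phylo`.
#' @param areas character vector (>= 2) of single-letter area codes.
#' @param d,e nonnegative per-area dispersal and extinction rates.
#' @param clado_prob_vicariance probability in \[0,1\] that a widespread
#'   range splits by vicariance at a node.
#' @param root_range character vector of areas occupied at the root;
#'   `NULL` draws one area uniformly.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `ranges` (a [range_assignment] including branch-start
#'   inherited ranges) and `log` (an `event_log` data frame: `type`, `time`,
#'   `node`, `areas`).
#' @export
simulate_range_history <- function(tree, areas = LETTERS[1:8], d = 0.1,
                                   e = 0.03, clado_prob_vicariance = 0.5,
                                   root_range = NULL, seed = NULL) {
  check_phylo(tree)
  areas <- as.character(areas)
  if (length(areas) < 2) stop_validation("need at least 2 areas")
  if (any(nchar(areas) != 1) || anyDuplicated(areas))
    stop_validation("areas must be distinct single characters")
  if (d < 0 || e < 0) stop_validation("rates must be nonnegative")
  if (clado_prob_vicariance < 0 || clado_prob_vicariance > 1)
    stop_validation("clado_prob_vicariance must lie in [0,1]")
  ages <- node_ages(tree)
  with_seed(seed, {
    if (is.null(root_range)) root_range <- sample(areas, 1L)
    root_range <- unique(as.character(root_range))
    if (!length(root_range) || !all(root_range %in% areas))
      stop_validation("root_range must be a nonempty subset of areas")
    ntot <- n_tips(tree) + tree$Nnode
    node_range <- vector("list", ntot)
    inherited <- vector("list", ntot)
    node_range[[root_node(tree)]] <- root_range
    log <- list()
    add <- function(type, time, node, area_str) {
      log[[length(log) + 1L]] <<-
        data.frame(type = type, time = time, node = node, areas = area_str)
    }
    children_of <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
    # preorder over internal nodes: root first
    po <- ape::reorder.phylo(tree, "postorder")
    internal_order <- rev(unique(po$edge[, 1L]))
    for (v in internal_order) {
      R <- node_range[[v]]
      kids <- children_of(v)
      inh <- vector("list", length(kids))
      if (length(R) == 1L) {
        for (j in seq_along(kids)) inh[[j]] <- R
        add("within_area", ages[[v]], v, .range_to_string(R))
      } else if (stats::runif(1L) < clado_prob_vicariance) {
        # disjoint split: uniform nonempty proper subset to child 1
        repeat {
          pick <- as.logical(stats::rbinom(length(R), 1L, 0.5))
          if (any(pick) && !all(pick)) break
        }
        inh[[1L]] <- R[pick]
        inh[[2L]] <- R[!pick]
        if (length(kids) > 2L)       # polytomy: extra children take part 2
          for (j in 3:length(kids)) inh[[j]] <- R[!pick]
        add("vicariance", ages[[v]], v,
            paste(.range_to_string(inh[[1L]]), .range_to_string(inh[[2L]]),
                  sep = "|"))
      } else {
        iso <- sample.int(length(kids), 1L)   # which child is isolated
        one <- sample(R, 1L)
        for (j in seq_along(kids))
          inh[[j]] <- if (j == iso) one else R
        add("peripheral_isolation", ages[[v]], v,
            paste(.range_to_string(R), .range_to_string(one), sep = "|"))
      }
      # anagenetic evolution down each child branch: each area flips at most
      # once per branch (first event only), keeping the history identifiable
      # from the node ranges
      for (j in seq_along(kids)) {
        ch <- kids[j]
        inherited[[ch]] <- inh[[j]]
        R0 <- inh[[j]]
        t_hi <- ages[[v]]; t_lo <- ages[[ch]]
        L <- t_hi - t_lo
        ev_area <- character(0); ev_type <- character(0); ev_t <- numeric(0)
        trunc_time <- function(rate) {
          # first-event time on (0, L], conditional on occurrence
          u <- stats::runif(1L)
          -log(1 - u * (1 - exp(-rate * L))) / rate
        }
        if (L > 0 && d > 0) for (a in setdiff(areas, R0)) {
          if (stats::runif(1L) < 1 - exp(-d * L)) {
            ev_area <- c(ev_area, a); ev_type <- c(ev_type, "dispersal")
            ev_t <- c(ev_t, t_hi - trunc_time(d))
          }
        }
        if (L > 0 && e > 0) for (a in R0) {
          if (stats::runif(1L) < 1 - exp(-e * L)) {
            ev_area <- c(ev_area, a); ev_type <- c(ev_type, "extinction")
            ev_t <- c(ev_t, t_hi - trunc_time(e))
          }
        }
        R2 <- R0
        for (idx in order(-ev_t)) {        # apply in chronological order
          if (ev_type[idx] == "dispersal") {
            R2 <- c(R2, ev_area[idx])
            add("dispersal", ev_t[idx], ch, ev_area[idx])
          } else if (length(R2) > 1L) {    # never empty the range
            R2 <- setdiff(R2, ev_area[idx])
            add("extinction", ev_t[idx], ch, ev_area[idx])
          }
        }
        node_range[[ch]] <- R2
      }
    }
    ranges <- range_assignment(
      vapply(node_range, .range_to_string, ""), areas = areas,
      inherited = vapply(inherited, function(x)
        if (is.null(x)) NA_character_ else .range_to_string(x), ""),
      tip_labels = tree$tip.label)
    log <- do.call(rbind, log)
    log <- log[order(-log$time), , drop = FALSE]
    rownames(log) <- NULL
    list(ranges = ranges,
         log = structure(log, class = c("event_log", "data.frame"),
                         root_age = unname(attr(ages, "depth"))))
  })
}

# -- Toy alignments for indel coding ------------------------------------------

#' Generate a toy nucleotide alignment with known indels
#'
#' Random A/C/G/T matrix with `indel_events` gap runs placed at mutually
#' non-adjacent interior column spans, each applied to a random proper subset
#' of taxa. The placed spans are retained as ground truth for validating the
#' indel coder.
#'
#' @param n_seqs number of sequences (>= 2).
#' @param length alignment length in columns.
#' @param indel_events number of gap runs to insert.
#' @param max_len maximum span length (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return character matrix (taxa x columns, rownames = taxa) with attribute
#'   `truth`: data frame `start`, `end` of the inserted spans.
#' @export
generate_toy_alignment <- function(n_seqs, length, indel_events = 0,
                                   max_len = 4, seed = NULL) {
  if (n_seqs < 2) stop_validation("n_seqs must be >= 2")
  if (max_len >= length - 1)
    stop_validation("indel span length %d does not fit in alignment of %d",
                    max_len, length)
  with_seed(seed, {
    aln <- matrix(sample(c("A", "C", "G", "T"), n_seqs * length,
                         replace = TRUE),
                  n_seqs, length,
                  dimnames = list(paste0("s", seq_len(n_seqs)), NULL))
    truth <- data.frame(start = integer(), end = integer())
    occupied <- rep(FALSE, length)
    occupied[c(1L, length)] <- TRUE    # keep spans interior
    placed <- 0L
    tries <- 0L
    while (placed < indel_events) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop_validation("cannot place %d non-adjacent indel spans in %d columns",
                        indel_events, length)
      len <- sample.int(max_len, 1L)
      s <- sample.int(length - len - 1L, 1L) + 1L
      e <- s + len - 1L
      window <- max(1L, s - 1L):min(length, e + 1L)
      if (any(occupied[window])) next
      occupied[window] <- TRUE
      taxa <- sample.int(n_seqs, sample.int(n_seqs - 1L, 1L))
      aln[taxa, s:e] <- "-"
      truth <- rbind(truth, data.frame(start = s, end = e))
      placed <- placed + 1L
    }
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    attr(aln, "truth") <- truth
    aln
  })
}
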
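test_that("yule simulation honours its contract", {
  cherry <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(cherry$edge.length[1], cherry$edge.length[2])

  a <- ape::write.tree(simulate_yule_tree(40, 1, seed = 9))
  b <- ape::write.tree(simulate_yule_tree(40, 1, seed = 9))
  c_ <- ape::write.tree(simulate_yule_tree(40, 1, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c_))

  big <- simulate_yule_tree(128, 1, seed = 2)
  expect_equal(length(big$tip.label), 128)
  ages <- node_ages(big)
  expect_true(attr(ages, "ultrametric"))
  expect_true(all(big$edge.length > 0))

  expect_error(simulate_yule_tree(1, 1), ">= 2")
  expect_error(simulate_yule_tree(5, 0), "> 0")
})

test_that("random trait assignment matches the binomial law", {
  tr <- simulate_yule_tree(8, 1, seed = 1)
  k <- 3
  counts <- integer(8)
  nrep <- 10000
  set.seed(11)
  for (r in seq_len(nrep))
    counts <- counts + simulate_trait_random(tr, k)[tr$tip.label]
  p <- k / 8
  sigma <- sqrt(nrep * p * (1 - p))
  expect_true(all(abs(counts - nrep * p) < 3 * sigma))

  edge <- simulate_trait_random(tr, 7, seed = 2)
  expect_equal(sum(edge == 0), 1)
  expect_identical(simulate_trait_random(tr, 3, seed = 5),
                   simulate_trait_random(tr, 3, seed = 5))
  expect_error(simulate_trait_random(tr, 0), "prevalence")
  expect_error(simulate_trait_random(tr, 8), "prevalence")
})

test_that("brownian threshold trait keeps prevalence and tree covariance", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  nrep <- 4000
  both_ab <- both_ad <- 0
  set.seed(21)
  for (r in seq_len(nrep)) {
    x <- simulate_trait_brownian_threshold(tr, 2)
    expect_equal(sum(x), 2)
    both_ab <- both_ab + (x[["A"]] == 1 && x[["B"]] == 1)
    both_ad <- both_ad + (x[["A"]] == 1 && x[["D"]] == 1)
  }
  # oracle: same probabilities from direct MVN sampling of the analytic
  # covariance (shared-path) matrix
  set.seed(22)
  vals <- mvn_tip_values(tr, nrep)
  o_ab <- o_ad <- 0
  for (j in seq_len(nrep)) {
    top2 <- order(-vals[, j])[1:2]
    o_ab <- o_ab + all(c(1, 2) %in% top2)   # A,B are tips 1,2
    o_ad <- o_ad + all(c(1, 4) %in% top2)
  }
  expect_gt(both_ab, both_ad)               # cherries co-occur more often
  expect_gt(o_ab, o_ad)
  # tree-traversal and covariance-matrix routes agree within Monte Carlo error
  expect_lt(abs(both_ab - o_ab) / nrep, 4 * sqrt(0.25 / nrep) * 2)
  expect_lt(abs(both_ad - o_ad) / nrep, 4 * sqrt(0.25 / nrep) * 2)
})

test_that("brownian threshold on a star tree is indistinguishable from random", {
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, 8)
  nrep <- 4000
  counts <- integer(8)
  set.seed(31)
  for (r in seq_len(nrep))
    counts <- counts + simulate_trait_brownian_threshold(star, 2)
  # every tip equally likely to be in the top 2
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("mk simulation returns a true change count bounded below by Fitch", {
  tr <- simulate_yule_tree(6, 1, seed = 4)
  s0 <- simulate_trait_mk(tr, 0, 0, root_state = 1, seed = 1)
  expect_true(all(s0$trait == 1))
  expect_equal(s0$n_gains + s0$n_losses, 0)
  expect_true(s0$constant)

  s1 <- simulate_trait_mk(tr, 0.5, 0, root_state = 0, seed = 2)
  expect_equal(s1$n_losses, 0)

  set.seed(41)
  for (r in 1:50) {
    s <- simulate_trait_mk(tr, 0.8, 0.8)
    if (length(unique(s$trait)) < 2) next
    expect_gte(s$n_gains + s$n_losses, fitch(tr, s$trait)$min_changes)
  }
  expect_error(simulate_trait_mk(tr, -1, 0), "nonnegative")
})

test_that("correlated-trait simulation respects its rate structure", {
  tr <- simulate_yule_tree(40, 1, seed = 6)
  z <- simulate_correlated_traits(tr, correlated_rates_independent(0, 0, 0, 0),
                                  seed = 1)
  expect_true(all(z$trait_a == 0) && all(z$trait_b == 0))
  expect_equal(nrow(z$history), 0)

  # B permitted to change only while A = 1: every B transition in the true
  # history must have other_state = 1, and B stays 0 wherever A never reached 1
  rates <- c(a01_b0 = 0.4, a10_b0 = 0.2, a01_b1 = 0.4, a10_b1 = 0.2,
             b01_a0 = 0, b10_a0 = 0, b01_a1 = 2, b10_a1 = 2)
  set.seed(51)
  for (r in 1:20) {
    s <- simulate_correlated_traits(tr, rates)
    bh <- s$history[s$history$trait == "B", ]
    if (nrow(bh)) expect_true(all(bh$other_state == 1))
  }
  expect_error(simulate_correlated_traits(tr, rates * -1), "nonnegative")
})

test_that("range histories keep ranges nonempty with times inside branches", {
  tr <- simulate_yule_tree(30, 1, seed = 7)
  ages <- node_ages(tr)

  frozen <- simulate_range_history(tr, d = 0, e = 0, seed = 1,
                                   root_range = c("A", "B"))
  expect_true(all(frozen$log$type %in%
                    c("within_area", "vicariance", "peripheral_isolation")))
  tip_ranges <- frozen$ranges$ranges[seq_len(30)]
  expect_true(all(nzchar(tip_ranges)))

  set.seed(61)
  for (r in 1:10) {
    rh <- simulate_range_history(tr, d = 0.3, e = 0.15)
    expect_true(all(nzchar(rh$ranges$ranges)))
    branch_ev <- rh$log[rh$log$type %in% c("dispersal", "extinction"), ]
    for (i in seq_len(nrow(branch_ev))) {
      ch <- branch_ev$node[i]
      par <- tr$edge[tr$edge[, 2] == ch, 1]
      expect_true(branch_ev$time[i] > ages[[ch]] - 1e-12)
      expect_true(branch_ev$time[i] < ages[[par]] + 1e-12)
    }
  }

  # e = 0: ranges grow monotonically (under inclusion) along every branch
  rh0 <- simulate_range_history(tr, d = 0.4, e = 0, seed = 9)
  for (ch in tr$edge[, 2]) {
    start <- strsplit(rh0$ranges$inherited[ch], "")[[1]]
    end <- strsplit(rh0$ranges$ranges[ch], "")[[1]]
    expect_true(all(start %in% end))
  }
  expect_error(simulate_range_history(tr, areas = "A"), "2 areas")
})

test_that("toy alignments carry recoverable ground-truth indels", {
  a0 <- generate_toy_alignment(5, 40, indel_events = 0, seed = 1)
  expect_false(any(a0 == "-"))
  expect_equal(nrow(find_indels(a0)), 0)

  expect_identical(generate_toy_alignment(6, 50, 3, seed = 2),
                   generate_toy_alignment(6, 50, 3, seed = 2))

  set.seed(71)
  for (r in 1:10) {
    a <- generate_toy_alignment(8, 80, indel_events = 5)
    truth <- attr(a, "truth")
    found <- find_indels(a)
    expect_equal(found[order(found$start), ]$start, truth$start)
    expect_equal(found[order(found$start), ]$end, truth$end)
  }
  expect_error(generate_toy_alignment(4, 10, 1, max_len = 20), "fit")
})
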
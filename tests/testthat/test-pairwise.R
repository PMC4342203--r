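test_that("forced pairings are found and constant predictors rejected", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  ps <- select_independent_pairs(tr, c(A = 1, B = 0, C = 1, D = 0), seed = 1)
  expect_equal(nrow(ps), 2)
  expect_setequal(paste(ps$tip1, ps$tip0), c("A B", "C D"))

  expect_error(select_independent_pairs(tr, c(A = 1, B = 1, C = 1, D = 1)),
               "constant")
})

test_that("caterpillar tree with alternating states yields 3 disjoint pairs", {
  tr <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  tr$edge.length <- rep(1, nrow(tr$edge))
  pred <- c(A = 1, B = 0, C = 1, D = 0, E = 1, F = 0)
  for (s in 1:5) {
    ps <- select_independent_pairs(tr, pred, seed = s)
    expect_equal(nrow(ps), 3)
    paths <- lapply(seq_len(nrow(ps)), function(i)
      pair_path_edges(tr, ps$tip1[i], ps$tip0[i]))
    expect_equal(anyDuplicated(unlist(paths)), 0)
  }
})

test_that("selected pairs are edge-disjoint, contrasting, and seeded", {
  set.seed(401)
  for (r in 1:25) {
    tr <- simulate_yule_tree(sample(10:60, 1), 1)
    pred <- simulate_trait_mk(tr, 0.4, 0.4)$trait
    if (length(unique(pred)) < 2) next
    ps <- select_independent_pairs(tr, pred, seed = r)
    if (!nrow(ps)) next
    expect_true(all(pred[ps$tip1] == 1) && all(pred[ps$tip0] == 0))
    tips <- c(ps$tip1, ps$tip0)
    expect_equal(anyDuplicated(tips), 0)
    paths <- lapply(seq_len(nrow(ps)), function(i)
      pair_path_edges(tr, ps$tip1[i], ps$tip0[i]))
    expect_equal(anyDuplicated(unlist(paths)), 0)
    ps2 <- select_independent_pairs(tr, pred, seed = r)
    expect_identical(ps$tip1, ps2$tip1)
    expect_identical(ps$tip0, ps2$tip0)
  }
})

test_that("sign test matches closed-form binomial tails", {
  tr <- ape::read.tree(text = "(((((((((((A,B),C),D),E),F),G),H),I),J),K),L);")
  tr$edge.length <- rep(1, nrow(tr$edge))
  pred <- stats::setNames(rep(c(1, 0), 6), tr$tip.label)
  ps <- select_independent_pairs(tr, pred, seed = 2)
  expect_equal(nrow(ps), 6)

  dep_all <- stats::setNames(pred, names(pred))          # fully concordant
  r66 <- sign_test(ps, dep_all)
  expect_equal(r66$n_informative, 6)
  expect_equal(r66$n_concordant, 6)
  expect_equal(r66$p, 1 / 64)

  # 4 of 6 concordant: flip the dependent state inside two pairs
  dep42 <- dep_all
  flip <- c(ps$tip1[1:2], ps$tip0[1:2])
  dep42[flip] <- 1 - dep42[flip]
  r46 <- sign_test(ps, dep42)
  expect_equal(r46$n_concordant, 4)
  expect_equal(r46$p, 22 / 64)

  # fully discordant: one-tailed p in the tested direction is 1
  dep06 <- stats::setNames(1 - pred, names(pred))
  expect_equal(sign_test(ps, dep06)$p, 1)

  # direction swap flips the tail: p(-1) computed from n - k
  expect_equal(sign_test(ps, dep42, direction = -1)$p,
               stats::pbinom(2 - 1, 6, 0.5, lower.tail = FALSE))

  # no informative pairs: flagged, not an error
  dep_const <- stats::setNames(rep(1, 12), names(pred))
  r0 <- sign_test(ps, dep_const)
  expect_true(r0$undefined)
  expect_true(is.na(r0$p))
})

test_that("set and tree aggregation collapse to single runs when degenerate", {
  tr <- simulate_yule_tree(40, 1, seed = 31)
  cs <- simulate_correlated_traits(tr, correlated_rates_strong(), seed = 4)
  one <- pairwise_over_sets(tr, cs$trait_a, cs$trait_b, n_sets = 1, seed = 8)
  direct <- sign_test(
    select_independent_pairs(tr, cs$trait_a,
                             seed = phytraits:::derive_seed(8, 1)),
    cs$trait_b)
  expect_equal(one$median_p, direct$p)

  # deterministic topology where only one maximal pairing exists
  tr4 <- ape::read.tree(text = "((A,B),(C,D));")
  tr4$edge.length <- rep(1, nrow(tr4$edge))
  pred <- c(A = 1, B = 0, C = 1, D = 0)
  dep <- c(A = 1, B = 0, C = 0, D = 0)
  many <- pairwise_over_sets(tr4, pred, dep, n_sets = 20, seed = 3)
  expect_equal(length(unique(many$p_values)), 1)
  expect_equal(many$median_p, many$p_values[1])

  trio <- as_tree_sample(list(tr, tr, tr))
  overt <- pairwise_over_trees(trio, cs$trait_a, cs$trait_b, n_sets = 5,
                               seed = 8)
  expect_equal(length(unique(overt$per_tree_median_p)), 1)
  expect_equal(overt$median_p, overt$per_tree_median_p[1])
})

test_that("the test is conservative under independence and powerful under dependence", {
  # size (reduced here; the acceptance suite runs the full design)
  set.seed(402)
  n <- 0; hits <- 0
  for (r in 1:120) {
    tr <- simulate_yule_tree(64, 1)
    a <- simulate_trait_mk(tr, 0.3, 0.3)$trait
    b <- simulate_trait_mk(tr, 0.3, 0.3)$trait
    if (length(unique(a)) < 2) next
    st <- sign_test(select_independent_pairs(tr, a), b)
    if (!st$undefined) { n <- n + 1; hits <- hits + (st$p <= 0.05) }
  }
  expect_lte(hits / n, 0.05 + 2 * sqrt(0.05 * 0.95 / n))

  # power under the strong-dependence generator
  pow <- 0
  for (r in 1:20) {
    tr <- simulate_yule_tree(100, 1, seed = 800 + r)
    cs <- simulate_correlated_traits(tr, correlated_rates_strong(),
                                     seed = 900 + r)
    pw <- pairwise_over_sets(tr, cs$trait_a, cs$trait_b, n_sets = 10,
                             seed = 1000 + r)
    pow <- pow + (pw$median_p < 0.05)
  }
  expect_gt(pow / 20, 0.5)
})
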
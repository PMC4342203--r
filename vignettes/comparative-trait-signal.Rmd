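---
title: "Phylogenetic signal, correlated evolution and biogeographic events for binary traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal, correlated evolution and biogeographic events for binary traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytraits)
```

phytraits is a comparative-phylogenetics toolkit for binary characters on
rooted, dated phylogenies. It grew out of the kind of question asked about
large succulent-plant radiations such as the aloes: is a species property —
documented human use, medicinal use, leaf succulence — clustered on the
phylogeny, does change in one trait accompany change in another, and how do
speciation processes (vicariance, peripheral isolation, dispersal,
extinction) distribute through time? The package implements the statistics,
a forward simulator for every data type it consumes, and an end-to-end
pipeline, so each analysis can be validated against ground truth before it
touches real data.

## The D statistic for binary phylogenetic signal

For a binary trait $x$ on a rooted tree, internal node values are estimated
tips-to-root as the arithmetic mean of child values (tips carry their 0/1
state), and the trait's raw clumping score is

$$d = \sum_{v \ne \mathrm{root}} \bigl| \hat{x}(v) - \hat{x}(\mathrm{parent}(v)) \bigr|,$$

small when the trait falls on few clades and large when it is scattered.
Because $d$ depends on tree size, shape and trait prevalence, it is rescaled
between two simulated expectations computed on the same tree at the same
prevalence $k$:

$$D = \frac{d_{\mathrm{obs}} - \bar d_{\mathrm{Brownian}}}
           {\bar d_{\mathrm{random}} - \bar d_{\mathrm{Brownian}}}.$$

The *random* scenario shuffles the $k$ ones uniformly across tips (no
signal); the *Brownian threshold* scenario evolves a continuous liability by
Brownian motion from the root and assigns state 1 to the $k$ tips with the
largest values (signal as strong as gradual drift produces). A randomly
scattered trait therefore centres on $D = 1$ and a Brownian-threshold trait
on $D = 0$; values below 0 (clumpier than Brownian) or above 1
(overdispersed) are meaningful and reported unclamped.

Two simulation p-values accompany every estimate: `p_vs_random` is the
fraction of random-shuffle replicates at least as clumped as the observed
trait, and `p_vs_brownian` the fraction of Brownian replicates at least as
dispersed. Both use a pseudocount, $(1+b)/(1+n_{\mathrm{sim}})$, so a p-value
is never exactly zero at finite simulation effort; with the default
`n_sim = 1000` the floor is just under $10^{-3}$.

Design notes:

- **Nodal estimator.** The child-mean recursion is stated explicitly because
  published descriptions of the statistic leave the estimator implicit.
  Since observed and null $d$ values use the same estimator, the calibration
  endpoints (1 and 0) are preserved for any consistent estimator — the test
  suite verifies both endpoints to ±0.05 over 100 simulated trees — but raw
  `d_obs` values may differ from other software.
- **Scale invariance.** Multiplying all branch lengths by a constant rescales
  the Brownian liabilities by a rank-preserving factor, so `D` is invariant
  (exactly so under a fixed seed).
- **Missing states.** Tips without data can either be pruned
  (`missing_action = "prune"`, the default) or scored 0
  (`missing_action = "as_zero"`). Both behaviours are exposed because use
  records equate absence of evidence with a 0 score, and the right choice is
  a scientific judgement, not a software default.
- **Degenerate inputs.** Constant traits have no defined signal and are
  rejected; so are trees where the two null means coincide to within
  $10^{-9}$ relative (tiny trees), where the ratio would be noise.

`phylo_d_over_sample()` propagates topological uncertainty by re-running the
statistic over a posterior tree sample and reporting the median D, median
p-values and 2.5/97.5 percentiles. Each tree receives the same seed, so a
sample of identical trees reproduces the single-tree result exactly, and
per-tree failures (e.g. a tree on which the trait is constant after pruning)
are counted rather than silently dropped.

## Parsimony transition counts

`fitch()` computes the minimum number of state changes by the standard
multifurcating extension of Fitch parsimony: at each node the state set is
the set of states minimising the number of disagreeing children, adding that
minimum to the cost. Internally the implementation is a two-state Sankoff
dynamic programme that tracks the exact per-state penalty (which can exceed
1 at polytomies — the reason naive set-based bookkeeping fails there).

Polarity (gain 0→1 versus loss 1→0) is a property of a *resolved*
reconstruction, and most-parsimonious reconstructions (MPRs) generally
disagree about it. Rather than committing silently to one resolution, the
package reports the minimum and maximum number of gains and losses across
all MPRs via a second dynamic programme, validated against exhaustive
enumeration of all ancestral assignments on 500 random instances of up to 10
tips. An accelerated-transformation resolution (`resolution = "acctran"`,
changes placed as close to the root as ties allow) is available when a
single concrete reconstruction is needed; it is always itself an MPR.

`count_transitions_over_sample()` tabulates a chosen count (minimum losses,
by default) across a posterior sample, yielding statements of the form "a
loss count of $c$ is supported by a fraction $f$ of trees".

## Phylogenetically independent pairwise comparisons

The pairwise-comparison test asks whether change in a predictor trait
(e.g. succulence) is associated with change in a dependent trait (e.g.
medicinal use) using pairs of species that contrast in the predictor and
whose connecting paths share no tree edges — each pair is then an
independent evolutionary replicate. Selection is a seeded greedy post-order
pass: every subtree passes at most one unpaired candidate tip up its stem
edge (chosen uniformly among candidates, which provably share the same
predictor state), and candidates from different subtrees with contrasting
states are matched uniformly at random at their meeting node. Edge-
disjointness is re-verified structurally on every run as a hard assertion.
The algorithm is linear-time and maximal for the greedy order; the published
description of the method specifies only that sets are "randomly selected",
so the concrete scheme here is the package's own, chosen for seedability.

Scoring is a sign test: among informative pairs (dependent states differ),
the number concordant with the hypothesised direction is binomial(n, 1/2)
under the null, and the one-tailed tail probability is reported. Pair sets
with no informative pairs return a flagged, undefined p rather than an
error. Because selection is random, `pairwise_over_sets()` repeats the
procedure (default 100 sets) and summarises by the median p — the choice of
median mirrors how median probabilities are reported over posterior tree
samples, and the full per-set distribution is retained.
`pairwise_over_trees()` adds the tree-sample layer (median of per-tree
medians). The test is conservative: its realised size under independently
simulated traits sits well below the nominal level (verified over 400
replicates), a known property of discrete sign tests.

## Biogeographic event classification and binning

`infer_events()` consumes a dated tree plus per-node ancestral ranges over
a small area alphabet (default: eight single-letter codes for the African,
Arabian, Malagasy and Eurasian regions used in aloe biogeography) and emits
a typed event log. At each node the cladogenetic event is classified by set
rules — single-area parent copied to both children: within-area speciation;
disjoint split of the parent range: vicariance; one child keeping the full
range while the other takes a single area: peripheral isolation; anything
else: unclassified, counted, never dropped. Along each branch, the
difference between the branch-start (inherited) range and the child node's
range yields one dispersal per gained area and one extinction per lost
area. Branch events are timed at the branch midpoint by default (uniform
random placement is available for sensitivity checks); node events carry the
node age.

Two operating modes differ in where the inherited range comes from:

- **Simulator mode.** The forward simulator records each branch's true
  starting range, and inference is then an exact inverse of the generative
  process: per-type event counts equal the simulation's truth log on every
  replicate (an acceptance property, checked on 200 random histories, and
  with extinction rate 0 no extinctions are ever inferred).
- **Reconstruction mode.** Real ancestral-range tables carry node ranges
  only. Inheritance is then reconstructed from the classification rules
  (classified patterns imply their own inheritance; otherwise the
  parent–child intersection is used, falling back to the parent range). This
  mode is necessarily approximate: a vicariant split followed by a dispersal
  can be indistinguishable from peripheral isolation at node resolution.

The forward simulator itself makes one deliberate departure from a pure
continuous-time model: each area changes at most once per branch (the first
event is kept; times follow the correctly truncated exponential). Under an
unrestricted model an area gained and lost again within one branch is
invisible at the nodes, so no classifier could recover the true event
counts; restricting to one transition per area per branch keeps the
simulated history identifiable while preserving per-area rates `d` and `e`
to first order. Loss proposals that would empty a range are rejected —
ranges are never empty. The cladogenetic mix is controlled by
`clado_prob_vicariance` (default 0.5), a free simulation parameter: the
empirical mix in real reconstructions is itself an inference output, not a
published constant. All areas are mutually reachable by default; a future
adjacency hook is the natural refinement for systems where dispersal is
constrained to contiguous regions.

`bin_events()` histograms the log in right-open bins running from the root
age down to the present (an event at age 3.2 with unit bins falls in
[4,3)); bin totals always equal log totals per type. Within-area speciation
stays in the log but is excluded from the default four-category histogram,
matching the convention of plotting only dispersal, extinction, vicariance
and peripheral isolation.

## Trait construction and the exact test

`use_records_to_traits()` reduces an ethnobotanical record table (species,
level-1 category, optional level-2 category) to two binary characters:
`any_use` (any documented use) and `medicinal_use` (a record in the
Medicines category, matched against either level so both common table
layouts work). A 0 always means *no reported use* — the ethnobotanical
literature rarely documents non-use. Category tokens are validated against
a configurable vocabulary. `habit_to_succulence()` maps growth-habit
classes to the binary succulence character; scrambling shrubs are variably
succulent and require an explicit per-species override rather than a silent
default. Species labels from all sources are normalised (whitespace to
underscores, quotes stripped) before matching tree tips.

`fisher_exact()` is an exact conditional test computed by direct summation
over the hypergeometric support, with the two-sided p defined by the
minimum-likelihood rule (all tables with point probability not exceeding the
observed, within a relative tolerance of $10^{-7}$ that absorbs floating-
point rounding of exact ties). It agrees with an independent
binomial-coefficient enumeration to $10^{-12}$ on 1000 random tables with
margins up to 30, and with `stats::fisher.test`. Cross-tabulation of two
traits excludes species missing either value and reports how many were
excluded.

## Simple indel coding

`simple_indel_coding()` converts alignment gap runs into appended binary
characters: one character per distinct interior span (s, e); a taxon scores
1 when its own maximal gap run is exactly that span, `?` when a longer run
strictly contains it (presence of the shorter indel is unknowable), and 0
otherwise. Terminal runs are missing data, never indels. A gap run shared
by every taxon codes as a constant all-1 character by default;
`drop_all_gap_columns = TRUE` deletes such columns first instead (both
conventions exist in practice, so both are exposed, with the retaining
behaviour as the default because it preserves the one-character-per-span
contract). `concatenate_partitions()` builds a supermatrix over the union
of taxa, fills absent taxa with `?`, appends indel blocks and records every
block's column range, so the output width always equals the sum of its
parts; `write_supermatrix_nexus()` emits a NEXUS DATA block with a SETS
block of charsets.

## The synthetic-data module

Every consumer in the package has a generator with retained ground truth:

- `simulate_yule_tree()`: forward pure-birth simulation (exponential
  waiting times, exactly ultrametric); the default birth rate of 1 per
  lineage per unit time sets the time scale.
- `simulate_trait_random()` / `simulate_trait_brownian_threshold()`: the
  two scenarios of the D statistic, at exact prevalence (threshold ties are
  broken uniformly at random; the Brownian root value is fixed at 0 and
  rate at 1, since thresholding uses ranks only).
- `simulate_trait_mk()`: two-state Markov evolution with the realised
  per-branch change counts retained, so parsimony counts can be checked
  against (and bounded by) the truth.
- `simulate_correlated_traits()`: a four-state dependent model over joint
  states (00, 01, 10, 11) with eight single-change rates.
  `correlated_rates_independent()` is the null;
  `correlated_rates_strong()` is the power-study preset — the predictor
  flips at rate 0.3 while the dependent trait tracks it (gain rate 3 while
  the predictor is 1, loss rate 3 while it is 0, leak rates 0.02), chosen
  once so that dependence is unambiguous at 100-tip scale.
- `simulate_range_history()`: the identifiable forward range process
  described above, with a complete typed, timed truth log.
- `generate_toy_alignment()`: random nucleotide matrices with gap spans at
  non-adjacent interior positions and the span list retained.

What the generators deliberately do not emulate: extinction in the tree
process (trees are pure-birth), rate heterogeneity across lineages or
sites, sampling biases in which species get studied, spatial adjacency
constraints between areas, and alignment error. Passing tests therefore
demonstrate the *statistics* are implemented correctly and calibrated under
their own model assumptions — not that those assumptions hold for any
particular empirical system.

## Problem sizes and numerical conventions

The validation suite runs at sizes chosen to balance Monte Carlo precision
against desk-scale runtimes: D calibration on 100 trees of 128 tips with
1000 null replicates per scenario (endpoints within ±0.05); parsimony and
exact-test oracles on 500 and 1000 random instances; pairwise size on 400
replicates of 64-tip trees and power on 100 replicates of 100-tip trees;
event-recovery on 200 random histories. The demonstration pipeline
(`run_full_demo()`) uses 96 tips, a 25-tree sample, 1000 null replicates
and 50 pair sets, and completes in well under a minute; it rescales its
tree to a crown depth of 16 time units so that binned event histograms read
like a dated radiation.

Reproducibility conventions: every random procedure takes an explicit seed
and restores the caller's RNG state; derived sub-seeds are generated by a
fixed integer recurrence, so nested procedures (per-tree, per-set) are
independently reproducible; ties anywhere (thresholding, range argmax,
pair matching) are broken either uniformly at random under the operation's
seed or by a documented deterministic rule (smallest range, then
lexicographic, for ancestral-range selection). Outputs carry a manifest
(seed, parameters, input digests) and two runs with the same seed are
byte-identical.

## Known limitations

- The nodal-change estimator makes D comparable within this package across
  trees and prevalences, but raw `d` sums are not interchangeable with
  other implementations of the statistic.
- Reconstruction-mode event inference cannot recover events hidden by
  node-resolution ambiguity; counts from real range tables are lower-bound
  flavoured and the unclassified category should be reported alongside.
- The pairwise test discards tips left unpaired by the greedy pass; on
  trees where the predictor is very unbalanced few pairs exist and the sign
  test has little power regardless of implementation.
- Polytomies are never resolved silently anywhere; operations that require
  bifurcation (none currently) would expose a seeded resolution helper
  rather than guessing.
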
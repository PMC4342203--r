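# Building binary use and succulence characters from ethnobotanical use
# records and growth-habit classes, and cross-tabulating them with Fisher's
# exact test. Use records follow the Economic Botany Data Standard layout:
# one row per documented use with a level-1 category (Medicines, Food,
# Materials, ...) and an optional finer level-2 category. A 0 always means
# "no reported use", never verified absence.

#' Default level-1 use-category vocabulary
#'
#' The broad categories of the Economic Botany Data Standard. The vocabulary
#' is configurable; the standard's full hierarchy is deliberately not
#' reproduced.
#'
#' @return character vector of category tokens.
#' @export
use_categories <- function() {
  c("Medicines", "Food", "Food_additives", "Animal_food", "Materials",
    "Fuels", "Social_uses", "Vertebrate_poisons", "Non-vertebrate_poisons",
    "Environmental_uses", "Gene_sources")
}

#' Binary use traits from a use-record table
#'
#' `any_use` scores 1 for every species with at least one record of any
#' level-1 category; `medicinal_use` scores 1 for species with at least one
#' record in the Medicines category (matched against the level-1 or level-2
#' token). Species in `species` but absent from the records score 0 — a lack
#' of reported use.
#'
#' @param records data frame with columns `species`, `level1` and optionally
#'   `level2`; one row per documented use.
#' @param species character vector of all species to score (e.g. the tree's
#'   tip labels); defaults to the species present in `records`.
#' @param vocabulary allowed level-1 tokens; unknown tokens are a validation
#'   error listing the offenders.
#' @param medicines_token token identifying the Medicines category.
#' @return list with two named 0/1 vectors, `any_use` and `medicinal_use`.
#' @export
use_records_to_traits <- function(records, species = NULL,
                                  vocabulary = use_categories(),
                                  medicines_token = "Medicines") {
  if (!is.data.frame(records) || !nrow(records))
    stop_validation("records must be a nonempty data frame")
  if (!all(c("species", "level1") %in% names(records)))
    stop_validation("records needs columns species, level1")
  lev1 <- gsub(" ", "_", trimws(as.character(records$level1)))
  unknown <- setdiff(unique(lev1), vocabulary)
  if (length(unknown))
    stop_validation("unknown use categories: %s",
                    paste(unknown, collapse = ", "))
  lev2 <- if ("level2" %in% names(records))
    gsub(" ", "_", trimws(as.character(records$level2))) else
      rep("", nrow(records))
  sp <- normalise_label(records$species)
  if (is.null(species)) species <- sort(unique(sp))
  species <- normalise_label(species)
  any_use <- stats::setNames(as.integer(species %in% sp), species)
  med_sp <- unique(sp[lev1 == medicines_token | lev2 == medicines_token])
  medicinal_use <- stats::setNames(as.integer(species %in% med_sp), species)
  list(any_use = any_use, medicinal_use = medicinal_use)
}

#' Succulence trait from growth-habit classes
#'
#' Habit classes map to the binary succulence character: succulent shrubs
#' score 1; barely succulent shrubs (the grass aloes) and branching trees
#' score 0; scrambling shrubs have variably succulent leaves and require a
#' per-species override.
#'
#' @param classes data frame with columns `species` and `habit`, the habit
#'   one of `succulent_shrub`, `barely_succulent_shrub`, `branching_tree`,
#'   `scrambling_shrub`.
#' @param scrambler_override named 0/1 vector giving the score of each
#'   scrambling-shrub species; a scrambler without an override is an error.
#' @return named 0/1 vector over the species.
#' @export
habit_to_succulence <- function(classes, scrambler_override = NULL) {
  if (!all(c("species", "habit") %in% names(classes)))
    stop_validation("classes needs columns species, habit")
  habit <- trimws(as.character(classes$habit))
  allowed <- c("succulent_shrub", "barely_succulent_shrub",
               "branching_tree", "scrambling_shrub")
  bad <- setdiff(unique(habit), allowed)
  if (length(bad))
    stop_validation("unknown habit classes: %s", paste(bad, collapse = ", "))
  sp <- normalise_label(classes$species)
  if (anyDuplicated(sp))
    stop_validation("duplicated species in habit table: %s",
                    paste(unique(sp[duplicated(sp)]), collapse = ", "))
  out <- stats::setNames(integer(length(sp)), sp)
  out[habit == "succulent_shrub"] <- 1L
  scram <- sp[habit == "scrambling_shrub"]
  if (length(scram)) {
    if (is.null(scrambler_override))
      stop_validation("scrambling_shrub species need an override: %s",
                      paste(scram, collapse = ", "))
    names(scrambler_override) <- normalise_label(names(scrambler_override))
    missing <- setdiff(scram, names(scrambler_override))
    if (length(missing))
      stop_validation("scrambling_shrub species need an override: %s",
                      paste(missing, collapse = ", "))
    out[scram] <- as.integer(scrambler_override[scram])
  }
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given fixed margins. The two-sided p-value follows the
#' minimum-likelihood rule: the sum of the probabilities of all tables (with
#' the same margins) whose point probability does not exceed that of the
#' observed table (within a relative tolerance of 1e-7 to absorb floating
#' rounding of exact ties). The reported odds ratio is the sample odds
#' ratio `(a d) / (b c)`.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"` (minimum-likelihood rule), `"greater"`
#'   or `"less"` (one-sided tails for the top-left cell).
#' @return list with `odds_ratio`, `p`, `alternative`, `table`.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))$p   # 1
fisher_exact <- function(table,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop_validation("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_validation("counts must be nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_          # first-column margin
  n <- b + d
  k <- a + b           # first-row margin
  if (m + n == 0) stop_validation("at least one margin must be positive")
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
  list(odds_ratio = (a * d) / (b * c_), p = min(p, 1),
       alternative = alternative, table = tab)
}

#' Cross-tabulate two binary traits and test association
#'
#' Builds the 2x2 table of two binary traits over their shared species,
#' excluding species missing either value (pairwise deletion, with the
#' count reported), and applies [fisher_exact].
#'
#' @param x,y named 0/1 vectors (e.g. succulence and medicinal use).
#' @param alternative passed to [fisher_exact].
#' @return list with `table` (2x2, rows = `x` 1/0, columns = `y` 1/0),
#'   `n_excluded`, `odds_ratio`, `p`, `alternative`.
#' @export
fisher_trait_test <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) x <- stats::setNames(x[[2]], x[[1]])
  if (is.data.frame(y)) y <- stats::setNames(y[[2]], y[[1]])
  names(x) <- normalise_label(names(x))
  names(y) <- normalise_label(names(y))
  shared <- intersect(names(x), names(y))
  if (!length(shared)) stop_validation("traits share no species")
  xs <- x[shared]; ys <- y[shared]
  complete <- !is.na(xs) & !is.na(ys)
  tab <- matrix(c(sum(xs == 1 & ys == 1 & complete),
                  sum(xs == 1 & ys == 0 & complete),
                  sum(xs == 0 & ys == 1 & complete),
                  sum(xs == 0 & ys == 0 & complete)),
                2L, 2L, byrow = TRUE,
                dimnames = list(x = c("1", "0"), y = c("1", "0")))
  ft <- fisher_exact(tab, alternative = alternative)
  list(table = tab, n_excluded = sum(!complete),
       odds_ratio = ft$odds_ratio, p = ft$p, alternative = alternative)
}
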
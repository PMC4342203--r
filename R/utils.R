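#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current RNG stream" (caller manages seeding).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed < 2^31 from a parent seed and an index, or NULL if the
# parent seed is NULL (randomness then flows from the ambient stream).
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + 104729 * as.double(i)) %% 2147483647
}

# Tip labels are normalised once at the I/O boundary: different sources write
# the same species as "Aloe vera", "Aloe_vera" or "ALOE VERA".
normalise_label <- function(x) {
  x <- gsub("[ \t]+", "_", trimws(as.character(x)))
  gsub("'", "", x)
}

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) length(tree$tip.label) + 1L

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("phytraits_validation_error", "error")))
}

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop_validation("expected a 'phylo' tree, got <%s>", class(tree)[1])
  if (anyDuplicated(tree$tip.label))
    stop_validation("duplicate tip labels: %s",
                    paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                          collapse = ", "))
  invisible(tree)
}

# Coerce/validate a binary trait: named 0/1 vector (NA allowed) covering the
# tree's tips. Returns an integer vector ordered as tree$tip.label.
align_trait <- function(tree, trait, allow_missing = FALSE) {
  if (is.data.frame(trait)) {
    if (ncol(trait) < 2)
      stop_validation("trait table needs columns (tip_label, state)")
    trait <- stats::setNames(trait[[2]], normalise_label(trait[[1]]))
  }
  if (is.null(names(trait)))
    stop_validation("trait must be a named vector (names = tip labels)")
  names(trait) <- normalise_label(names(trait))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop_validation("trait lacks states for tips: %s",
                    paste(utils::head(missing, 5), collapse = ", "))
  x <- suppressWarnings(as.integer(trait[tree$tip.label]))
  bad <- !(x %in% c(0L, 1L)) & !is.na(x)
  if (any(bad))
    stop_validation("non-binary states for tips: %s",
                    paste(tree$tip.label[bad], collapse = ", "))
  if (!allow_missing && anyNA(x))
    stop_validation(
      "missing states for tips: %s (prune the tree or impute first)",
      paste(tree$tip.label[is.na(x)], collapse = ", "))
  stats::setNames(x, tree$tip.label)
}

#' Prevalence of a binary trait
#'
#' Number of tips scored 1, recomputed from the data (never cached).
#'
#' @param trait named 0/1 vector (or two-column data frame) keyed by tip label.
#' @return integer count of 1s (missing values ignored).
#' @export
trait_prevalence <- function(trait) {
  if (is.data.frame(trait)) trait <- stats::setNames(trait[[2]], trait[[1]])
  sum(trait == 1, na.rm = TRUE)
}

#' Read and write two-column trait tables
#'
#' Delimited text with columns `tip_label` and `state` (0/1/NA), the exchange
#' format used for all binary characters.
#'
#' @param path file path.
#' @param sep field separator, tab by default.
#' @return `read_trait_table()`: named integer vector; `write_trait_table()`:
#'   the path, invisibly.
#' @export
read_trait_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_validation("trait file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), normalise_label(tab[[1]]))
}

#' @rdname read_trait_table
#' @param trait named 0/1 vector.
#' @export
write_trait_table <- function(trait, path, sep = "\t") {
  utils::write.table(
    data.frame(tip_label = names(trait), state = unname(trait)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
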
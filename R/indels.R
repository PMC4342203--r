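# Simple indel coding: alignment gap runs with identical endpoints become
# binary presence/absence characters appended to the matrix; a taxon whose
# gap run strictly contains a character's span is scored unknown. Terminal
# gap runs are treated as missing data, not indels. Alignments are plain
# character matrices (taxa x columns, uppercase, alphabet A/C/G/T/N/-/?).

#' Read and write aligned FASTA
#'
#' @param path FASTA file path.
#' @param name optional partition name (defaults to the file name).
#' @return `read_alignment()`: character matrix (taxa x columns) with
#'   attribute `name`.
#' @export
read_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) stop_validation("alignment not found: %s", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop_validation("no sequences in %s", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop_validation("unequal sequence lengths in %s (not aligned?)", path)
  aln <- toupper(as.character(as.matrix(dna)))
  rownames(aln) <- normalise_label(rownames(aln))
  if (anyDuplicated(rownames(aln)))
    stop_validation("duplicate taxa in %s", path)
  attr(aln, "name") <- if (is.null(name)) basename(path) else name
  aln
}

#' @rdname read_alignment
#' @param aln character matrix with taxon rownames.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# Maximal gap runs per taxon: data frame taxon/start/end/terminal.
.gap_runs <- function(aln) {
  out <- list()
  nc <- ncol(aln)
  for (i in seq_len(nrow(aln))) {
    r <- rle(aln[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    g <- which(r$values)
    if (length(g))
      out[[length(out) + 1L]] <-
        data.frame(taxon = i, start = starts[g], end = ends[g],
                   terminal = starts[g] == 1L | ends[g] == nc)
  }
  if (!length(out))
    return(data.frame(taxon = integer(), start = integer(),
                      end = integer(), terminal = logical()))
  do.call(rbind, out)
}

#' Find indel characters in an alignment
#'
#' The distinct maximal gap runs across taxa, keyed by their exact
#' `(start, end)` column span (1-based, inclusive). Runs touching the first
#' or last column are terminal gaps — missing data, not indels — and are
#' excluded.
#'
#' @param aln character matrix (taxa x columns).
#' @return data frame `start`, `end`, ordered by start then end.
#' @export
find_indels <- function(aln) {
  if (!nrow(aln) || !ncol(aln)) stop_validation("empty alignment")
  runs <- .gap_runs(aln)
  runs <- runs[!runs$terminal, , drop = FALSE]
  spans <- unique(runs[c("start", "end")])
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Simple indel coding
#'
#' One binary character per distinct interior gap span `(s, e)`: a taxon is
#' scored 1 when its own maximal gap run is exactly `(s, e)`, `?` when a
#' longer gap run strictly contains the span (the indel's presence is
#' unknowable), and 0 otherwise — including partial overlap, which implies
#' residues inside the span. A run shared by every taxon yields a constant
#' all-1 character (parsimony-uninformative but retained); set
#' `drop_all_gap_columns = TRUE` to delete such columns before coding
#' instead (a warning reports the deletion).
#'
#' @param aln character matrix (taxa x columns).
#' @param drop_all_gap_columns delete columns gapped in every taxon before
#'   coding.
#' @return class `"indel_matrix"`: list with `chars` (data frame `start`,
#'   `end` in the coordinates of the coded alignment), `codes` (taxa x
#'   characters matrix of `"0"`, `"1"`, `"?"`) and `alignment` (the coded
#'   alignment).
#' @export
simple_indel_coding <- function(aln, drop_all_gap_columns = FALSE) {
  if (!nrow(aln) || !ncol(aln)) stop_validation("empty alignment")
  if (drop_all_gap_columns) {
    all_gap <- colSums(aln != "-") == 0L
    if (any(all_gap)) {
      warning(sprintf("deleting %d all-gap column(s) before indel coding",
                      sum(all_gap)))
      aln <- aln[, !all_gap, drop = FALSE]
    }
  }
  chars <- find_indels(aln)
  runs <- .gap_runs(aln)
  codes <- matrix("0", nrow(aln), nrow(chars),
                  dimnames = list(rownames(aln),
                                  if (nrow(chars))
                                    sprintf("indel_%d_%d", chars$start,
                                            chars$end)))
  for (j in seq_len(nrow(chars))) {
    s <- chars$start[j]; e <- chars$end[j]
    exact <- runs$taxon[runs$start == s & runs$end == e & !runs$terminal]
    contains <- runs$taxon[runs$start <= s & runs$end >= e &
                             !(runs$start == s & runs$end == e)]
    codes[exact, j] <- "1"
    codes[contains, j] <- "?"
  }
  structure(list(chars = chars, codes = codes, alignment = aln),
            class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat(sprintf("Simple indel coding: %d character(s) over %d taxa\n",
              nrow(x$chars), nrow(x$codes)))
  invisible(x)
}

#' Concatenate alignment partitions into a supermatrix
#'
#' Taxon set is the union over partitions; taxa missing a partition are
#' filled with `?`. Character-set boundaries are recorded per partition and
#' per appended indel block, so the supermatrix width always equals the sum
#' of its parts.
#'
#' @param parts named list of character matrices (separately aligned loci).
#' @param indels optional list of `indel_matrix` objects (one per partition,
#'   `NULL` entries allowed) whose code columns are appended after the
#'   nucleotide blocks.
#' @return class `"supermatrix"`: list with `matrix` (taxa x columns),
#'   `charsets` (data frame `name`, `start`, `end`).
#' @export
concatenate_partitions <- function(parts, indels = NULL) {
  if (!length(parts)) stop_validation("need at least one partition")
  if (is.null(names(parts)) || any(!nzchar(names(parts))))
    names(parts) <- paste0("part", seq_along(parts))
  for (nm in names(parts))
    if (anyDuplicated(rownames(parts[[nm]])))
      stop_validation("duplicate taxa within partition %s", nm)
  taxa <- Reduce(union, lapply(parts, rownames))
  blocks <- list()
  charsets <- data.frame(name = character(), start = integer(),
                         end = integer())
  pos <- 0L
  add_block <- function(m, nm) {
    full <- matrix("?", length(taxa), ncol(m),
                   dimnames = list(taxa, colnames(m)))
    full[rownames(m), ] <- m
    blocks[[length(blocks) + 1L]] <<- full
    charsets <<- rbind(charsets,
                       data.frame(name = nm, start = pos + 1L,
                                  end = pos + ncol(m)))
    pos <<- pos + ncol(m)
  }
  for (nm in names(parts)) add_block(parts[[nm]], nm)
  if (!is.null(indels)) {
    for (i in seq_along(indels)) {
      im <- indels[[i]]
      if (is.null(im) || !nrow(im$chars)) next
      add_block(im$codes, paste0(names(parts)[i], "_indels"))
    }
  }
  structure(list(matrix = do.call(cbind, blocks), charsets = charsets),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d characters in %d block(s)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$charsets)))
  invisible(x)
}

#' Write a supermatrix as NEXUS with charsets
#'
#' DATA block with the full matrix (nucleotides plus any appended 0/1/?
#' indel characters) and a SETS block recording the per-partition column
#' ranges.
#'
#' @param x a `supermatrix`.
#' @param path output file.
#' @export
write_supermatrix_nexus <- function(x, path) {
  m <- x$matrix
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"A C G T N 0 1\" MISSING=? GAP=-;",
               "  MATRIX"), con)
  for (i in seq_len(nrow(m)))
    writeLines(sprintf("    %s  %s", rownames(m)[i],
                       paste(m[i, ], collapse = "")), con)
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  for (i in seq_len(nrow(x$charsets)))
    writeLines(sprintf("  CHARSET %s = %d-%d;", x$charsets$name[i],
                       x$charsets$start[i], x$charsets$end[i]), con)
  writeLines("END;", con)
  invisible(path)
}
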
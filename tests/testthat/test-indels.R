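aln_from_strings <- function(...) {
  seqs <- c(...)
  do.call(rbind, lapply(stats::setNames(strsplit(seqs, ""), names(seqs)),
                        identity))
}

test_that("find_indels keys gap runs by exact span and drops terminal runs", {
  gapfree <- aln_from_strings(s1 = "ACGTAC", s2 = "ACGTAC")
  expect_equal(nrow(find_indels(gapfree)), 0)

  one <- aln_from_strings(s1 = "AC--GT", s2 = "ACTTGT")
  expect_equal(find_indels(one), data.frame(start = 3L, end = 4L))

  two <- aln_from_strings(s1 = "AC--GT", s2 = "A----T")
  got <- find_indels(two)
  expect_equal(got$start, c(2L, 3L))
  expect_equal(got$end, c(5L, 4L))

  terminal <- aln_from_strings(s1 = "--GTAC", s2 = "ACGT--")
  expect_equal(nrow(find_indels(terminal)), 0)
})

test_that("simple indel coding reproduces the hand-worked matrices", {
  a3 <- aln_from_strings(s1 = "AC--GT", s2 = "AC--GT", s3 = "ACTTGT")
  ic3 <- simple_indel_coding(a3)
  expect_equal(ic3$chars, data.frame(start = 3L, end = 4L))
  expect_equal(unname(ic3$codes[, 1]), c("1", "1", "0"))

  a4 <- aln_from_strings(s1 = "AC--GT", s2 = "AC--GT", s3 = "ACTTGT",
                         s4 = "A----T")
  ic4 <- simple_indel_coding(a4)
  expect_equal(ic4$chars$start, c(2L, 3L))
  expect_equal(ic4$chars$end, c(5L, 4L))
  i25 <- which(ic4$chars$start == 2)
  i34 <- which(ic4$chars$start == 3)
  expect_equal(unname(ic4$codes[, i34]), c("1", "1", "0", "?"))
  expect_equal(unname(ic4$codes[, i25]), c("0", "0", "0", "1"))

  same <- aln_from_strings(s1 = "A--T", s2 = "A--T", s3 = "A--T")
  expect_equal(unname(simple_indel_coding(same)$codes[, 1]),
               c("1", "1", "1"))
})

test_that("shared all-gap spans code as constant characters unless dropped", {
  a <- aln_from_strings(s1 = "A-C-GT", s2 = "A-C-GT")
  ic <- simple_indel_coding(a)
  expect_equal(nrow(ic$chars), 2)
  expect_true(all(ic$codes == "1"))
  expect_warning(icd <- simple_indel_coding(a, drop_all_gap_columns = TRUE),
                 "all-gap")
  expect_equal(ncol(icd$alignment), 4)
  expect_equal(nrow(icd$chars), 0)
})

test_that("taxa coded 1 carry the exact gap span with residues adjacent", {
  set.seed(601)
  for (r in 1:10) {
    a <- generate_toy_alignment(8, 60, indel_events = 4)
    ic <- simple_indel_coding(a)
    for (j in seq_len(nrow(ic$chars))) {
      s <- ic$chars$start[j]; e <- ic$chars$end[j]
      for (tx in which(ic$codes[, j] == "1")) {
        expect_true(all(a[tx, s:e] == "-"))
        expect_true(a[tx, s - 1] != "-")    # spans are interior by design
        expect_true(a[tx, e + 1] != "-")
      }
    }
    # idempotence: re-scanning the coded supermatrix finds the same spans
    sm <- concatenate_partitions(list(locus = a), indels = list(ic))
    again <- find_indels(sm$matrix[, 1:ncol(a), drop = FALSE])
    expect_equal(again, ic$chars)
  }
})

test_that("concatenation records charsets and fills absent taxa", {
  p1 <- aln_from_strings(s1 = "ACGTA", s2 = "ACGTA", s3 = "AAGTA")
  p2 <- aln_from_strings(s1 = "TTTTCCC", s2 = "TTTTCCA")
  sm <- concatenate_partitions(list(one = p1, two = p2))
  expect_equal(ncol(sm$matrix), 12)
  expect_equal(nrow(sm$matrix), 3)
  expect_equal(paste(sm$matrix["s3", 6:12], collapse = ""), "???????")
  expect_equal(sm$charsets$start, c(1L, 6L))
  expect_equal(sm$charsets$end, c(5L, 12L))

  # permuting the partition order permutes blocks, tracked by the charsets
  sm2 <- concatenate_partitions(list(two = p2, one = p1))
  cs1 <- sm$charsets[sm$charsets$name == "one", ]
  cs2 <- sm2$charsets[sm2$charsets$name == "one", ]
  expect_equal(sm$matrix[c("s1", "s2"), cs1$start:cs1$end],
               sm2$matrix[c("s1", "s2"), cs2$start:cs2$end])

  dup <- rbind(p1, p1[1, , drop = FALSE])
  expect_error(concatenate_partitions(list(bad = dup)), "duplicate")
})

test_that("alignments and supermatrices round-trip through files", {
  a <- generate_toy_alignment(6, 50, indel_events = 3, seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a, f)
  back <- read_alignment(f)
  expect_setequal(rownames(back), rownames(a))
  expect_equal(back[rownames(a), ], a[, ], ignore_attr = TRUE)

  ic <- simple_indel_coding(a)
  sm <- concatenate_partitions(list(locus = a), indels = list(ic))
  fn <- withr::local_tempfile(fileext = ".nex")
  write_supermatrix_nexus(sm, fn)
  txt <- readLines(fn)
  expect_true(any(grepl("^#NEXUS", txt)))
  expect_true(any(grepl(sprintf("NCHAR=%d", ncol(sm$matrix)), txt)))
  expect_equal(sum(grepl("CHARSET", txt)), nrow(sm$charsets))
})
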
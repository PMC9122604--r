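# reference used by the SAM fixtures: 40 bp, single contig "chr"
ref40 <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"

test_that("mismatch-read selection keeps exactly reads with C/G mismatches", {
  g <- genome(ref40, name = "chr", circular = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, list(
    list(qname = "perfect", pos = 1, cigar = "8M", seq = "ACGTACGT"),
    list(qname = "c_to_t", pos = 1, cigar = "8M", seq = "ATGTACGT"),  # C2>T
    list(qname = "t_to_a", pos = 1, cigar = "8M", seq = "ACGAACGT")   # T4>A only
  ), "chr", 40)
  aln <- read_alignments(sam)
  sel <- select_mismatch_reads(aln, g)
  expect_equal(length(aln), 3L)
  expect_equal(length(sel), 1L)
})

test_that("position tables tabulate depth, bases and selected depth", {
  g <- genome(ref40, name = "chr", circular = FALSE)
  sam <- tempfile(fileext = ".sam")
  # both reads cover position 5 (ref A); second read has T over the ref C
  # at position 6 -> it alone survives the mismatch filter
  write_toy_sam(sam, list(
    list(qname = "r1", pos = 3, cigar = "6M", seq = "GTACGT"),
    list(qname = "r2", pos = 5, cigar = "6M", seq = "ATGTAC")
  ), "chr", 40)
  aln <- read_alignments(sam)
  tab <- build_position_table(aln, g)
  expect_equal(tab$depth_total[5], 2L)
  expect_equal(tab$A[5], 2L)
  expect_equal(tab$depth_total[6], 2L)
  expect_equal(tab$C[6], 1L)
  expect_equal(tab$T[6], 1L)
  expect_equal(tab$depth_selected[6], 1L)
  # invariants
  expect_true(all(tab$A + tab$C + tab$G + tab$T + tab$N <= tab$depth_total))
  expect_true(all(tab$depth_selected <= tab$depth_total))

  # read order must not matter
  write_toy_sam(sam, list(
    list(qname = "r2", pos = 5, cigar = "6M", seq = "ATGTAC"),
    list(qname = "r1", pos = 3, cigar = "6M", seq = "GTACGT")
  ), "chr", 40)
  tab2 <- build_position_table(read_alignments(sam), g)
  attr(tab2, "sample_id") <- attr(tab, "sample_id")
  expect_equal(tab2, tab)
})

test_that("empty input gives an all-zero table and a clean ref mismatch error", {
  g <- genome(ref40, name = "chr", circular = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, list(), "chr", 40)
  tab <- build_position_table(read_alignments(sam), g)
  expect_equal(sum(tab$depth_total), 0L)
  expect_equal(sum(tab$depth_selected), 0L)
  expect_equal(nrow(tab), 40L)

  other <- genome(ref40, name = "other", circular = FALSE)
  write_toy_sam(sam, list(
    list(qname = "r1", pos = 1, cigar = "4M", seq = "ACGT")), "chr", 40)
  expect_error(build_position_table(read_alignments(sam), other), "reference")
})

test_that("total depth equals the sum of aligned reference-space lengths", {
  set.seed(7)
  g <- genome(random_seq(500), name = "chr", circular = FALSE)
  reads <- lapply(1:200, function(i) {
    p <- sample(1:450, 1)
    list(qname = paste0("r", i), pos = p, cigar = "50M",
         seq = substr(g$sequence, p, p + 49))
  })
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, reads, "chr", 500)
  tab <- build_position_table(read_alignments(sam), g)
  expect_equal(sum(tab$depth_total), 200L * 50L)
  # perfect reads: no C>T signal anywhere, and no read passes the filter
  cg <- which(tab$ref %in% c("C", "G") & tab$depth_total > 0)
  fr <- ct_change_fraction(tab, cg, ifelse(tab$ref[cg] == "C", "+", "-"))
  expect_true(all(fr == 0))
  expect_equal(sum(tab$depth_selected), 0L)
})

test_that("plasmid contigs and low-MAPQ reads can be excluded", {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:40", "@SQ\tSN:plasmid\tLN:40")
  rows <- c(
    paste("r1", 0, "chr", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t"),
    paste("r2", 0, "plasmid", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t"),
    paste("r3", 0, "chr", 1, 0, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t"))
  writeLines(c(hdr, rows), sam)
  expect_equal(length(read_alignments(sam)), 3L)  # MAPQ 0 kept by default
  expect_equal(length(read_alignments(sam, exclude_contigs = "plasmid")), 2L)
  expect_equal(length(read_alignments(sam, min_mapq = 1L)), 2L)
})

test_that("C>T change fractions follow the strand complement rule", {
  tab <- toy_table("AACGT", depth = 100,
                   overrides = list(list(pos = 3, C = 99, T = 1),
                                    list(pos = 4, G = 90, A = 10)))
  expect_equal(ct_change_fraction(tab, 3, "+"), 0.01)
  expect_equal(ct_change_fraction(tab, 4, "-"), 0.10)
  expect_error(ct_change_fraction(tab, 1, "+"), "reference base")
  zero <- toy_table("AC", depth = 0)
  expect_true(is.na(ct_change_fraction(zero, 2, "+")))
})

test_that("position tables round-trip through TSV", {
  tab <- toy_table("ACGTACGT", depth = 7,
                   overrides = list(list(pos = 2, C = 6, T = 1)))
  path <- tempfile(fileext = ".tsv")
  write_position_table(tab, path)
  back <- read_position_table(path)
  expect_equal(back$depth_total, tab$depth_total)
  expect_equal(back$T, tab$T)
  expect_equal(attr(back, "sample_id"), "toy")
})
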
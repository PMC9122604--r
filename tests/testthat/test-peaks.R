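test_that("peak calling finds plateaus and applies the sigma-zero rule", {
  expect_equal(nrow(call_peaks(rep(2, 500))), 0L)  # constant track: sigma 0

  # plateau kept narrow relative to the genome: sigma includes the peak
  # region, so the 5-sigma threshold rises with the covered fraction
  nd <- rep(0, 30000)
  nd[2001:2500] <- 1
  pk <- call_peaks(nd, k_sigma = 5, merge_gap = 120, circular = FALSE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 2001L)
  expect_equal(pk$end, 2500L)
  expect_equal(pk$max_ndc2, 1)
  expect_gt(pk$max_ndc2, attr(pk, "threshold_used"))
})

test_that("super-threshold runs merge across small gaps only", {
  nd <- rep(0, 20000)
  nd[1001:1100] <- 1
  nd[1161:1260] <- 1   # 60-bp gap < 120 -> merged
  nd[2001:2100] <- 1   # 741-bp gap -> separate
  pk <- call_peaks(nd, 5, merge_gap = 120, circular = FALSE)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start, c(1001L, 2001L))
  expect_equal(pk$end, c(1260L, 2100L))

  nd2 <- rep(0, 20000)
  nd2[1001:1100] <- 1
  nd2[1401:1500] <- 1  # 300-bp gap > 120 -> two peaks
  expect_equal(nrow(call_peaks(nd2, 5, merge_gap = 120, circular = FALSE)), 2L)

  # brute-force run check: every position above threshold is inside a peak
  thr <- attr(pk, "threshold_used")
  above <- which(nd > thr)
  inside <- unlist(Map(seq, pk$start, pk$end))
  expect_true(all(above %in% inside))
  expect_true(all(pk$max_ndc2 > thr))
  expect_false(is.unsorted(pk$start))
})

test_that("peaks wrap across the origin of a circular track", {
  nd <- rep(0, 10000)
  nd[c(1:50, 9951:10000)] <- 1
  pk <- call_peaks(nd, 5, merge_gap = 10, circular = TRUE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 9951L)
  expect_equal(pk$end, 10050L)  # runs past the origin
})

test_that("peak annotation reports TSS overlap, distances and tRNA counts", {
  peaks <- data.frame(start = 100L, end = 200L)
  genes <- gene_annotations("g1", 150L, 400L, "+", "protein_coding")
  ann <- annotate_peaks(peaks, genes)
  expect_true(ann$peaks$tss_inside)
  expect_equal(ann$peaks$dist_start_tss, -50)
  expect_equal(ann$peaks$dist_end_tss, 50)

  far <- gene_annotations("g2", 500L, 700L, "+", "protein_coding")
  ann2 <- annotate_peaks(peaks, far)
  expect_false(ann2$peaks$tss_inside)
  expect_equal(ann2$peaks$dist_end_tss, -300)

  # 10 peaks sitting on 10 of 30 tRNA genes
  trna <- gene_annotations(paste0("t", 1:30), seq(1000, 30000, by = 1000),
                           seq(1000, 30000, by = 1000) + 80L,
                           rep("+", 30), rep("tRNA", 30))
  pk10 <- data.frame(start = seq(1000, 10000, by = 1000),
                     end = seq(1000, 10000, by = 1000) + 40L)
  ann3 <- annotate_peaks(pk10, trna)
  expect_equal(ann3$summary$n_trna_overlapped, 10L)
  expect_equal(ann3$summary$n_peaks_with_tss, 10L)
})

test_that("overlap test handles identity and degenerate inputs", {
  a <- data.frame(start = c(1000L, 5000L), end = c(1200L, 5300L))
  res <- peak_overlap_test(a, a, 10000L, n_perm = 200, seed = 1)
  expect_equal(res$n_overlap, 2L)
  expect_lte(res$p_value, 0.05)

  empty <- data.frame(start = integer(), end = integer())
  res0 <- peak_overlap_test(a, empty, 10000L, n_perm = 200, seed = 1)
  expect_equal(res0$n_overlap, 0L)
  expect_equal(res0$p_value, 1.0)
})

test_that("exhaustive rotation p-values match the brute-force enumeration", {
  a <- data.frame(start = c(101L, 701L), end = c(200L, 800L))
  b <- data.frame(start = c(151L, 901L), end = c(250L, 950L))
  L <- 1200L
  res <- peak_overlap_test(a, b, L, n_perm = 200, method = "exhaustive")
  oracle_null <- vapply(0:(L - 1L), function(off)
    oracle_overlap_count(a, b, off, L), 0)
  obs <- oracle_overlap_count(a, b, 0, L)
  expect_equal(res$n_overlap, obs)
  expect_equal(res$null_overlaps, as.integer(oracle_null))
  expect_equal(res$p_value, mean(oracle_null >= obs))
})

test_that("per-gene NDC2 vs expression recovers planted monotone coupling", {
  set.seed(21)
  n <- 200
  starts <- seq(1, by = 500, length.out = n)
  expr <- rlnorm(n, 3, 1)
  genes <- gene_annotations(sprintf("g%03d", 1:n), starts, starts + 399L,
                            rep("+", n), "protein_coding", expression = expr)
  nd <- numeric(max(genes$end) + 10)
  for (i in 1:n) nd[genes$start[i]:genes$end[i]] <- expr[i] / 400 + rnorm(400, 0, 1e-4)
  res <- gene_ndc2_vs_expression(nd, genes)
  expect_gt(res$spearman_rho, 0.9)

  # independent expression: weak correlation
  nd2 <- rnorm(length(nd), 1, 0.1)
  res2 <- gene_ndc2_vs_expression(nd2, genes)
  expect_lt(abs(res2$spearman_rho), 0.2)

  # constant track: correlation undefined, reported absent
  res3 <- gene_ndc2_vs_expression(rep(1, length(nd)), genes)
  expect_true(is.na(res3$spearman_rho))
})
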
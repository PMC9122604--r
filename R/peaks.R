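#' Call uracilation peaks from an NDC2 track
#'
#' The peak threshold is `k_sigma` times the standard deviation of the
#' unmasked NDC2 values across the whole genome (peak regions included).
#' Peaks are maximal runs of positions exceeding the threshold; runs
#' separated by at most `merge_gap` positions are merged, since features
#' closer than the local smoothing window are not resolvable. On circular
#' genomes a run touching both ends wraps (reported as a last interval with
#' `end` past `start` of the first merged away). If the track has zero
#' variance an empty peak set is returned.
#'
#' @param ndc2 Numeric NDC2 track (`NA` = masked), e.g. [compute_ndc2()].
#' @param k_sigma Threshold multiplier (default 5).
#' @param merge_gap Merge super-threshold runs separated by `<= merge_gap`
#'   positions (default 120, the local smoothing window).
#' @param circular Merge runs across the origin?
#' @return A `data.frame` of class `peak_set` with columns `start`, `end`
#'   (1-based closed), `width`, `max_ndc2`, `area` (sum of NDC2 over the
#'   peak) and attributes `sigma` and `threshold_used`.
#' @export
call_peaks <- function(ndc2, k_sigma = 5, merge_gap = 120L, circular = TRUE) {
  vals <- ndc2[!is.na(ndc2)]
  if (length(vals) == 0L) stop("track has no unmasked positions")
  sigma <- stats::sd(vals)
  thr <- k_sigma * sigma
  empty <- data.frame(start = integer(), end = integer(), width = integer(),
                      max_ndc2 = numeric(), area = numeric())
  if (!is.finite(sigma) || sigma == 0) {
    return(peak_set(empty, sigma = if (is.finite(sigma)) sigma else 0, threshold = thr))
  }
  above <- !is.na(ndc2) & ndc2 > thr
  if (!any(above)) return(peak_set(empty, sigma = sigma, threshold = thr))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs with small gaps
  if (nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > merge_gap)))
    runs <- data.frame(
      start = tapply(runs$start, grp, min),
      end = tapply(runs$end, grp, max)
    )
  }
  n <- length(ndc2)
  wrapped <- FALSE
  if (circular && nrow(runs) > 1L) {
    circ_gap <- (n - runs$end[nrow(runs)]) + runs$start[1L] - 1L
    if (circ_gap <= merge_gap) wrapped <- TRUE
  }
  if (wrapped) {
    # fold the first run into the last, crossing the origin
    first <- runs[1L, ]; last <- runs[nrow(runs), ]
    runs <- runs[-c(1L, nrow(runs)), , drop = FALSE]
    runs <- rbind(runs, data.frame(start = last$start, end = n + first$end))
  }
  idx <- lapply(seq_len(nrow(runs)), function(i) {
    p <- seq.int(runs$start[i], runs$end[i])
    ((p - 1L) %% n) + 1L
  })
  out <- data.frame(
    start = as.integer(runs$start),
    end = as.integer(runs$end),
    width = as.integer(runs$end - runs$start + 1L),
    max_ndc2 = vapply(idx, function(p) max(ndc2[p], na.rm = TRUE), 0),
    area = vapply(idx, function(p) sum(ndc2[p], na.rm = TRUE), 0)
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  peak_set(out, sigma = sigma, threshold = thr)
}

peak_set <- function(df, sigma, threshold) {
  attr(df, "sigma") <- sigma
  attr(df, "threshold_used") <- threshold
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Export a peak set as BED (0-based half-open, score = max NDC2)
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @param chrom Contig name.
#' @export
write_peaks_bed <- function(peaks, path, chrom = "genome") {
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%.6g", chrom,
                   peaks$start - 1L, peaks$end, seq_len(nrow(peaks)),
                   peaks$max_ndc2)
  writeLines(lines, path)
  invisible(path)
}

#' Annotate peaks with overlapping genes and TSS proximity
#'
#' For each peak, reports the overlapping genes and their types, whether a
#' transcription start site falls inside the peak, and the signed distances
#' from the peak boundaries to the nearest TSS (negative when the TSS lies
#' downstream of the boundary in genome coordinates). The summary counts
#' distinct tRNA genes overlapped by any peak, peaks containing a TSS, and
#' the median and third-quartile absolute boundary-to-TSS distances.
#'
#' @param peaks A [call_peaks()] peak set.
#' @param genes A [gene_annotations()] data.frame.
#' @return A list with elements `peaks` (per-peak annotation data.frame)
#'   and `summary` (list with `n_trna_overlapped`, `n_peaks_with_tss`,
#'   `median_tss_distance`, `q3_tss_distance`).
#' @export
annotate_peaks <- function(peaks, genes) {
  if (nrow(genes) == 0L) {
    return(list(peaks = data.frame(), summary = list()))
  }
  pk <- IRanges::IRanges(start = peaks$start, end = peaks$end)
  gn <- IRanges::IRanges(start = genes$start, end = genes$end)
  hits <- IRanges::findOverlaps(pk, gn)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  per_peak <- lapply(seq_len(nrow(peaks)), function(i) {
    gi <- sh[qh == i]
    tss_in <- genes$tss >= peaks$start[i] & genes$tss <= peaks$end[i]
    nearest <- which.min(abs(genes$tss - (peaks$start[i] + peaks$end[i]) / 2))
    list(
      genes = genes$gene_id[gi],
      gene_types = genes$gene_type[gi],
      tss_inside = any(tss_in),
      dist_start_tss = peaks$start[i] - genes$tss[nearest],
      dist_end_tss = peaks$end[i] - genes$tss[nearest]
    )
  })
  ann <- data.frame(
    start = peaks$start, end = peaks$end,
    n_genes = vapply(per_peak, function(x) length(x$genes), 0L),
    genes = vapply(per_peak, function(x) paste(x$genes, collapse = ","), ""),
    gene_types = vapply(per_peak, function(x) paste(x$gene_types, collapse = ","), ""),
    tss_inside = vapply(per_peak, function(x) x$tss_inside, TRUE),
    dist_start_tss = vapply(per_peak, function(x) x$dist_start_tss, 0),
    dist_end_tss = vapply(per_peak, function(x) x$dist_end_tss, 0)
  )
  trna_ids <- unique(genes$gene_id[sh][genes$gene_type[sh] == "tRNA"])
  bdist <- abs(c(ann$dist_start_tss, ann$dist_end_tss))
  summary <- list(
    n_trna_overlapped = length(trna_ids),
    n_peaks_with_tss = sum(ann$tss_inside),
    median_tss_distance = if (nrow(ann)) stats::median(bdist) else NA_real_,
    q3_tss_distance = if (nrow(ann)) unname(stats::quantile(bdist, 0.75)) else NA_real_
  )
  list(peaks = ann, summary = summary)
}

# circular interval overlap helpers -------------------------------------

rotate_intervals <- function(start, end, offset, L) {
  w <- end - start
  s <- ((start - 1L + offset) %% L) + 1L
  e <- s + w
  wraps <- e > L
  out_s <- c(s[!wraps], s[wraps], rep(1L, sum(wraps)))
  out_e <- c(e[!wraps], rep(L, sum(wraps)), e[wraps] - L)
  id <- c(which(!wraps), which(wraps), which(wraps))
  list(start = out_s, end = out_e, id = id)
}

count_overlapping_peaks <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) return(0L)
  ov <- outer(a_start, b_end, `<=`) & outer(a_end, b_start, `>=`)
  sum(rowSums(ov) > 0L)
}

#' Permutation test for overlap between two peak sets on a circular genome
#'
#' The observed statistic is the number of peaks in `a` intersecting at
#' least one peak in `b`. The null distribution preserves the internal
#' structure of both sets by rigidly rotating `b` around the circular
#' genome: with `method = "sample"`, `n_perm` uniform random offsets give
#' `p = (1 + #[rotations with overlap >= observed]) / (n_perm + 1)`;
#' with `method = "exhaustive"` every one of the `L` rotations is
#' evaluated and `p` is the exact fraction with overlap `>=` observed.
#' This rotation test is an explicit stand-in for interval-correlation
#' suites: it tests co-localization only.
#'
#' @param a,b `peak_set` data.frames (or any data.frame with `start`/`end`).
#' @param genome_length Length of the circular genome.
#' @param n_perm Number of random rotations (`method = "sample"`).
#' @param seed Integer seed for the random offsets.
#' @param method `"sample"` or `"exhaustive"`.
#' @return List with `n_overlap`, `p_value`, and `null_overlaps` (the
#'   permutation statistics).
#' @export
peak_overlap_test <- function(a, b, genome_length, n_perm = 1000L,
                              seed = 1L, method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  L <- as.integer(genome_length)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(n_overlap = 0L, p_value = 1.0, null_overlaps = integer()))
  }
  # normalize wrapped peaks (end may exceed L from call_peaks)
  an <- rotate_intervals(a$start, a$end, 0L, L)
  obs <- local({
    bn <- rotate_intervals(b$start, b$end, 0L, L)
    ov <- outer(an$start, bn$end, `<=`) & outer(an$end, bn$start, `>=`)
    length(unique(an$id[rowSums(ov) > 0L]))
  })
  count_at <- function(offset) {
    bn <- rotate_intervals(b$start, b$end, offset, L)
    ov <- outer(an$start, bn$end, `<=`) & outer(an$end, bn$start, `>=`)
    length(unique(an$id[rowSums(ov) > 0L]))
  }
  if (method == "exhaustive") {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    null_overlaps <- vapply(0:(L - 1L), count_at, 0L)
    p <- mean(null_overlaps >= obs)
  } else {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    offs <- withr_seed(seed, sample.int(L, n_perm, replace = TRUE) - 1L)
    null_overlaps <- vapply(offs, count_at, 0L)
    p <- (1 + sum(null_overlaps >= obs)) / (n_perm + 1)
  }
  list(n_overlap = obs, p_value = p, null_overlaps = null_overlaps)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-gene NDC2 versus expression
#'
#' Sums NDC2 over each gene body and divides by gene length; expression is
#' likewise divided by gene length; reports the Spearman rank correlation
#' across genes (NA when either variable is constant).
#'
#' @param ndc2 NDC2 track.
#' @param genes [gene_annotations()] with an `expression` column.
#' @return List with `table` (gene_id, ndc2_per_bp, expression_per_bp) and
#'   `spearman_rho`.
#' @export
gene_ndc2_vs_expression <- function(ndc2, genes) {
  keep <- !is.na(genes$expression)
  g <- genes[keep, , drop = FALSE]
  nd <- vapply(seq_len(nrow(g)), function(i) {
    v <- ndc2[g$start[i]:g$end[i]]
    sum(v, na.rm = TRUE) / (g$end[i] - g$start[i] + 1L)
  }, 0)
  ex <- g$expression / (g$end - g$start + 1L)
  rho <- if (nrow(g) >= 3L && stats::sd(nd) > 0 && stats::sd(ex) > 0)
    stats::cor(nd, ex, method = "spearman") else NA_real_
  list(table = data.frame(gene_id = g$gene_id, ndc2_per_bp = nd,
                          expression_per_bp = ex),
       spearman_rho = rho)
}
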
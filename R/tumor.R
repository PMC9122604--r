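#' Load an SNV catalog from VCF or a MAF-like TSV
#'
#' Accepts an uncompressed VCF 4.x (columns through ALT are used; the
#' sample id is taken from the first genotype column name, else the file
#' name) or a headered TSV with columns `chrom`, `pos` (1-based), `ref`,
#' `alt` and optionally `sample_id`. Only single-nucleotide substitutions
#' are kept; skipped indel/MNV rows are counted in the `n_skipped`
#' attribute. When a reference [genome()] is supplied, records whose `ref`
#' disagrees with it are dropped with a warning.
#'
#' @param path Input file.
#' @param g Optional reference [genome()] for `ref` validation.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return `data.frame` of class `mutation_catalog`: `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `sample_id`.
#' @export
load_mutation_catalog <- function(path, g = NULL, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines, value = TRUE)
    body <- lines[!grepl("^#", lines)]
    if (length(body) == 0L) {
      muts <- data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         sample_id = character())
      attr(muts, "n_skipped") <- 0L
      class(muts) <- c("mutation_catalog", "data.frame")
      return(muts)
    }
    f <- read.delim(text = body, header = FALSE, stringsAsFactors = FALSE)
    sample_id <- if (length(hdr)) {
      cols <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
      if (length(cols) >= 10L) cols[10L] else basename(path)
    } else basename(path)
    muts <- data.frame(chrom = as.character(f$V1), pos = as.integer(f$V2),
                       ref = toupper(f$V4), alt = toupper(f$V5),
                       sample_id = sample_id, stringsAsFactors = FALSE)
  } else {
    f <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(f))) stop("TSV must have columns ", paste(need, collapse = ", "))
    muts <- data.frame(chrom = as.character(f$chrom), pos = as.integer(f$pos),
                       ref = toupper(f$ref), alt = toupper(f$alt),
                       sample_id = if ("sample_id" %in% names(f))
                         as.character(f$sample_id) else basename(path),
                       stringsAsFactors = FALSE)
  }
  snv <- nchar(muts$ref) == 1L & nchar(muts$alt) == 1L &
    muts$ref %in% c("A", "C", "G", "T") & muts$alt %in% c("A", "C", "G", "T") &
    muts$ref != muts$alt
  n_skipped <- sum(!snv)
  muts <- muts[snv, , drop = FALSE]
  if (!is.null(g) && nrow(muts) > 0L) {
    refbase <- genome_base(g, muts$pos)
    bad <- refbase != muts$ref
    if (any(bad)) {
      warning(sum(bad), " record(s) with reference-base mismatch dropped")
      muts <- muts[!bad, , drop = FALSE]
    }
  }
  rownames(muts) <- NULL
  attr(muts, "n_skipped") <- n_skipped
  class(muts) <- c("mutation_catalog", "data.frame")
  muts
}

#' 95% confidence interval for a count-based rate n/N
#'
#' Default is the Poisson-count normal approximation
#' `n/N +/- 1.96 * sqrt(n)/N`, floored at zero; `method = "poisson_exact"`
#' uses the exact Poisson (gamma-quantile) interval, which gives a
#' non-degenerate upper bound `~3.689/N` when `n = 0`; `"wilson"` is the
#' Wilson binomial score interval.
#'
#' @param n Mutation count (>= 0).
#' @param N Number of representative genomic positions (> 0).
#' @param method `"normal"`, `"poisson_exact"` or `"wilson"`.
#' @return Numeric `c(lo, hi)` on the rate `n/N`.
#' @export
ci95 <- function(n, N, method = c("normal", "poisson_exact", "wilson")) {
  method <- match.arg(method)
  if (N <= 0) stop("N must be > 0")
  if (n < 0) stop("n must be >= 0")
  if (method == "normal") {
    half <- 1.96 * sqrt(n) / N
    c(max(0, n / N - half), n / N + half)
  } else if (method == "poisson_exact") {
    lo <- if (n == 0) 0 else stats::qgamma(0.025, n) / N
    hi <- stats::qgamma(0.975, n + 1) / N
    c(lo, hi)
  } else {
    unlist(stats::prop.test(n, N, correct = FALSE)$conf.int[1:2], use.names = FALSE)
  }
}

# mutations at context cytosines: returns per-mutation index into
# `positions` (NA if the mutated base is not a context C), where a ref C
# mutation is a plus-strand C and a ref G mutation a minus-strand C.
match_context_mutations <- function(muts, positions) {
  mstrand <- ifelse(muts$ref == "C", "+", ifelse(muts$ref == "G", "-", NA))
  match(paste(muts$pos, mstrand), paste(positions$pos, positions$strand))
}

# cohort baseline: total C:G SNVs / total C:G sites among `site_pos`
cohort_baseline <- function(muts, g, site_pos = NULL) {
  cg_muts <- sum(muts$ref %in% c("C", "G"))
  n_sites <- if (is.null(site_pos)) {
    sum(strsplit(g$sequence, "", fixed = TRUE)[[1L]] %in% c("C", "G"))
  } else length(site_pos)
  if (n_sites == 0L) stop("no C:G sites in analyzed regions")
  cg_muts / n_sites
}

rate_row <- function(n_mut, n_sites, baseline, ci_method = "normal") {
  if (n_sites == 0L) {
    return(data.frame(n_mut = n_mut, n_sites = 0L, rate = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_))
  }
  if (baseline == 0) {  # empty catalog: every rate is 0 by convention
    return(data.frame(n_mut = n_mut, n_sites = n_sites, rate = 0,
                      ci_lo = 0, ci_hi = 0))
  }
  ci <- ci95(n_mut, n_sites, ci_method) / baseline
  data.frame(n_mut = n_mut, n_sites = n_sites,
             rate = (n_mut / n_sites) / baseline,
             ci_lo = ci[1L], ci_hi = ci[2L])
}

#' Replicative or transcriptional strand bias of tumor mutations
#'
#' Counts catalog mutations at the target cytosines of a sequence context,
#' split by the strand carrying the C: lagging- vs leading-strand template
#' (replicative mode, restricted to early-replicating regions when
#' `early_regions` is given, as replication-direction calls are most
#' reliable there) or non-transcribed vs transcribed strand
#' (transcriptional mode). Each strand's per-site rate is normalized by
#' the cohort's overall C:G per-site mutation rate; the bias ratio is
#' LGST/LDST or Tx+/Tx-. 95% CIs come from [ci95()] on (n, N).
#'
#' @param muts A [load_mutation_catalog()] catalog.
#' @param g The reference [genome()].
#' @param spec A [context_spec()] or context string.
#' @param mode `"replicative"` or `"transcriptional"`.
#' @param map [replichore_map()] (replicative mode).
#' @param genes [gene_annotations()] (transcriptional mode).
#' @param early_regions Optional `data.frame(start, end)` of
#'   early-replicating intervals; sites and mutations outside are ignored
#'   (replicative mode).
#' @param ci_method Passed to [ci95()].
#' @return List: `rates` (data.frame, one row per strand) and `ratio`
#'   (NA with a `zero_denominator` flag when one strand has no
#'   mutations/sites).
#' @export
strand_bias_rates <- function(muts, g, spec,
                              mode = c("replicative", "transcriptional"),
                              map = NULL, genes = NULL, early_regions = NULL,
                              ci_method = "normal") {
  mode <- match.arg(mode)
  positions <- find_context_positions(g, spec)
  if (mode == "replicative") {
    if (is.null(map)) stop("replicative mode needs a replichore_map")
    if (!is.null(early_regions)) {
      keep <- in_any_interval(positions$pos, early_regions)
      positions <- positions[keep, , drop = FALSE]
      muts <- muts[in_any_interval(muts$pos, early_regions), , drop = FALSE]
    }
    lab <- replicative_role(positions$pos, positions$strand, map, g)
    strata <- c("LGST", "LDST")
  } else {
    if (is.null(genes)) stop("transcriptional mode needs gene annotations")
    lab <- transcriptional_role(positions$pos, positions$strand, genes)
    keep <- lab %in% c("Tx+", "Tx-")
    positions <- positions[keep, , drop = FALSE]
    lab <- lab[keep]
    strata <- c("Tx+", "Tx-")
  }
  baseline <- cohort_baseline(muts, g)
  mi <- match_context_mutations(muts, positions)
  mut_lab <- lab[mi[!is.na(mi)]]
  rows <- do.call(rbind, lapply(strata, function(s) {
    cbind(strand = s,
          rate_row(sum(mut_lab == s), sum(lab == s), baseline, ci_method))
  }))
  r1 <- rows$rate[rows$strand == strata[1L]]
  r2 <- rows$rate[rows$strand == strata[2L]]
  zero <- is.na(r2) || r2 == 0 || is.na(r1)
  list(rates = rows,
       ratio = if (zero) NA_real_ else r1 / r2,
       zero_denominator = zero)
}

in_any_interval <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(TRUE, length(pos)))
  q <- IRanges::IRanges(start = pos, width = 1L)
  s <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  IRanges::overlapsAny(q, s)
}

#' Normalized mutation rates in hairpin loops by stem-strength bin
#'
#' Counts catalog mutations at context cytosines that lie in hairpin loops
#' (loop sizes restricted by the scan, 3-8 nt by default), binned by the
#' cytosine's best stem strength, each bin normalized by its number of
#' genomic sites and by the cohort baseline rate. Optionally sub-divided
#' by replicative strand (rows `both`, `LGST`, `LDST`).
#'
#' @param muts Mutation catalog.
#' @param g Reference [genome()].
#' @param spec Context spec or string.
#' @param assignment [assign_best_hairpin()] table on the same genome.
#' @param bin_edges Stem-strength bin edges (see [ss_bin_labels()]).
#' @param map Optional [replichore_map()] for the LGST/LDST sub-rows.
#' @param ci_method Passed to [ci95()].
#' @return `data.frame`: `ss_bin`, `strand`, `n_mut`, `n_sites`, `rate`,
#'   `ci_lo`, `ci_hi`.
#' @export
hairpin_mutation_rates <- function(muts, g, spec, assignment,
                                   bin_edges = c(4L, 8L, 12L, 16L),
                                   map = NULL, ci_method = "normal") {
  positions <- find_context_positions(g, spec)
  key <- paste(assignment$pos, assignment$strand)
  m <- match(paste(positions$pos, positions$strand), key)
  best_ss <- ifelse(is.na(m), 0L, assignment$best_ss[m])
  bins <- ss_bin_labels(best_ss, bin_edges)
  baseline <- cohort_baseline(muts, g)
  mi <- match_context_mutations(muts, positions)
  mut_idx <- mi[!is.na(mi)]
  groups <- list(both = rep(TRUE, nrow(positions)))
  if (!is.null(map)) {
    role <- replicative_role(positions$pos, positions$strand, map, g)
    groups <- c(groups, list(LGST = role == "LGST", LDST = role == "LDST"))
  }
  out <- list()
  for (gn in names(groups)) {
    sel <- groups[[gn]]
    for (b in levels(bins)) {
      in_bin <- sel & bins == b
      out[[length(out) + 1L]] <- cbind(
        ss_bin = b, strand = gn,
        rate_row(sum(in_bin[mut_idx]), sum(in_bin), baseline, ci_method))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expression-decile normalized mutation rates
#'
#' Genes are ranked by expression (ties broken by `gene_id`) and split
#' into 10 bins of (near-)equal gene counts; in each decile, catalog
#' mutations at context cytosines inside gene bodies are counted and
#' normalized by the decile's context-site count and by the cohort
#' baseline.
#'
#' @param muts Mutation catalog.
#' @param g Reference [genome()].
#' @param spec Context spec or string.
#' @param genes [gene_annotations()] with expression (>= 10 genes).
#' @param n_bins Number of expression bins (default 10).
#' @param ci_method Passed to [ci95()].
#' @return `data.frame`: `decile`, `mean_expression`, `n_mut`, `n_sites`,
#'   `rate`, `ci_lo`, `ci_hi`.
#' @export
expression_binned_rates <- function(muts, g, spec, genes, n_bins = 10L,
                                    ci_method = "normal") {
  genes <- genes[!is.na(genes$expression), , drop = FALSE]
  if (nrow(genes) < n_bins) stop("need at least ", n_bins, " genes with expression")
  o <- order(genes$expression, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  decile <- ceiling(seq_len(nrow(genes)) / nrow(genes) * n_bins)
  positions <- find_context_positions(g, spec)
  baseline <- cohort_baseline(muts, g)
  mi <- match_context_mutations(muts, positions)
  mut_idx <- mi[!is.na(mi)]
  gidx <- IRanges::IRanges(start = genes$start, end = genes$end)
  ppos <- IRanges::IRanges(start = positions$pos, width = 1L)
  hits <- IRanges::findOverlaps(ppos, gidx)
  pos_dec <- rep(NA_integer_, nrow(positions))
  # a position in several genes takes the first (lowest-ranked) gene's bin
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  first <- !duplicated(qh)
  pos_dec[qh[first]] <- decile[sh[first]]
  out <- do.call(rbind, lapply(seq_len(n_bins), function(d) {
    in_bin <- !is.na(pos_dec) & pos_dec == d
    cbind(decile = d,
          mean_expression = mean(genes$expression[decile == d]),
          rate_row(sum(in_bin[mut_idx]), sum(in_bin), baseline, ci_method))
  }))
  rownames(out) <- NULL
  out
}
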
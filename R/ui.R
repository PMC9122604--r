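#' Uracilation Index over a set of context cytosines
#'
#' The Uracilation Index (UI) of a sequence context is the mean
#' per-position C>T change fraction over the occurrences of the context,
#' scaled by 1000:
#'
#' `UI = [ sum( changes(pos) / depth(pos) ) / N ] * 1e3`
#'
#' where the sum runs over the context's target cytosines (both strands)
#' and `N` is, by default, the number of *measured* occurrences
#' (depth > 0). With `denominator = "genomic"` every genomic occurrence is
#' counted in `N` whether measured or not, in which case unmeasured sites
#' deflate the UI as a function of coverage.
#'
#' @param tab A [build_position_table()] table.
#' @param positions A [find_context_positions()] data.frame (`pos`,
#'   `strand`).
#' @param denominator `"measured"` (default) or `"genomic"`.
#' @return A list of class `ui_result`: `ui`, `n_positions`, `n_measured`,
#'   and `NA` placeholders for `subset_uis`/`sd` (see
#'   [ui_with_subset_error()]).
#' @export
compute_ui <- function(tab, positions, denominator = c("measured", "genomic")) {
  denominator <- match.arg(denominator)
  fr <- ct_change_fraction(tab, positions$pos, positions$strand)
  n_pos <- nrow(positions)
  n_meas <- sum(!is.na(fr))
  if (n_meas == 0L) stop("no measurable context positions")
  N <- if (denominator == "measured") n_meas else n_pos
  structure(
    list(ui = sum(fr, na.rm = TRUE) / N * 1e3,
         n_positions = n_pos, n_measured = n_meas,
         subset_uis = NULL, sd = NA_real_),
    class = "ui_result"
  )
}

#' @export
print.ui_result <- function(x, ...) {
  cat(sprintf("UI = %.4g  (n_positions = %d, n_measured = %d%s)\n",
              x$ui, x$n_positions, x$n_measured,
              if (!is.na(x$sd)) sprintf(", sd = %.3g", x$sd) else ""))
  invisible(x)
}

#' Uracilation Index stratified by a per-position label
#'
#' Computes one UI per label; typical label sources are
#' [replicative_role()] (LGST/LDST), [transcriptional_role()] (Tx+/Tx-),
#' or hairpin stem-strength bins ([ss_bin_labels()]). Positions labeled
#' `NA`, `"none"` or `"ambiguous"` are excluded. Strata with no measured
#' position are reported with `ui = NA`, not dropped.
#'
#' @param tab A position table.
#' @param positions Context positions (`pos`, `strand`).
#' @param labels Vector parallel to `positions` rows (or a factor).
#' @param denominator Passed to [compute_ui()].
#' @return Named list of `ui_result` objects (NA-`ui` stubs for empty
#'   strata).
#' @export
ui_stratified <- function(tab, positions, labels,
                          denominator = c("measured", "genomic")) {
  denominator <- match.arg(denominator)
  stopifnot(length(labels) == nrow(positions))
  keep <- !is.na(labels) & !(labels %in% c("none", "ambiguous"))
  lev <- if (is.factor(labels)) levels(droplevels(labels[keep])) else unique(labels[keep])
  out <- lapply(lev, function(l) {
    sub <- positions[keep & labels == l, , drop = FALSE]
    res <- tryCatch(compute_ui(tab, sub, denominator),
                    error = function(e) structure(
                      list(ui = NA_real_, n_positions = nrow(sub),
                           n_measured = 0L, subset_uis = NULL, sd = NA_real_),
                      class = "ui_result"))
    res
  })
  names(out) <- as.character(lev)
  out
}

#' Uracilation Index with subset-based error bars
#'
#' Estimates the statistical robustness of a UI by randomly partitioning
#' the context positions into `k` (default 3) equal subsets, computing the
#' UI in each, and reporting the sample standard deviation across subsets.
#' The partition is a seeded random shuffle split round-robin, so the
#' subsets have near-identical numbers of positions (remainders spread one
#' by one) and, on a homogeneous genome, similar composition.
#'
#' @param tab A position table.
#' @param positions Context positions.
#' @param k Number of subsets (>= 2).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param denominator Passed to [compute_ui()].
#' @return A `ui_result` with `subset_uis` (length `k`) and `sd` filled in;
#'   `ui` is the full-set UI.
#' @export
ui_with_subset_error <- function(tab, positions, k = 3L, seed = 1L,
                                 denominator = c("measured", "genomic")) {
  denominator <- match.arg(denominator)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  full <- compute_ui(tab, positions, denominator)
  if (full$n_measured < k) stop("fewer measured positions than subsets")
  n <- nrow(positions)
  perm <- withr_seed(seed, sample.int(n))
  grp <- rep_len(seq_len(k), n)[order(perm)]  # round-robin over a shuffle
  subset_uis <- vapply(seq_len(k), function(j) {
    compute_ui(tab, positions[grp == j, , drop = FALSE], denominator)$ui
  }, 0)
  full$subset_uis <- subset_uis
  full$sd <- stats::sd(subset_uis)
  full
}

#' Percent uracilation profile across an interval
#'
#' Per-position percentage of C>T conversion (both strands) across a
#' genomic window, e.g. centered on a TSS. Non-C/G positions are absent
#' from the output; unmeasured positions carry `NA`.
#'
#' @param tab A position table.
#' @param start,end 1-based closed interval bounds within the genome.
#' @return `data.frame` with `pos`, `strand`, `percent`.
#' @export
percent_uracilation_profile <- function(tab, start, end) {
  if (start < 1L || end > nrow(tab) || start > end) stop("interval out of range")
  pos <- seq.int(start, end)
  ref <- tab$ref[pos]
  cpos <- pos[ref == "C"]; gpos <- pos[ref == "G"]
  out <- rbind(
    data.frame(pos = cpos, strand = rep("+", length(cpos)),
               percent = 100 * ct_change_fraction(tab, cpos, "+")),
    data.frame(pos = gpos, strand = rep("-", length(gpos)),
               percent = 100 * ct_change_fraction(tab, gpos, "-"))
  )
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
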
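#' Centered moving average
#'
#' Mean over a centered window of `window` positions. Odd windows extend
#' `(window-1)/2` on both sides; even windows take `window/2` positions to
#' the left and `window/2 - 1` to the right. On circular tracks the window
#' wraps; on linear tracks the window is truncated at the ends (the mean is
#' taken over the positions that exist).
#'
#' @param values Numeric vector.
#' @param window Window size in positions, `1 <= window <= length(values)`.
#' @param circular Wrap the window around the ends?
#' @return Numeric vector the same length as `values`.
#' @export
moving_average <- function(values, window, circular = TRUE) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window larger than track length")
  if (window == 1L) return(as.numeric(values))
  left <- window %/% 2L
  right <- window - 1L - left
  if (circular) {
    ext <- c(values[(n - left + 1L):n], values, values[seq_len(right)])
    cs <- cumsum(as.numeric(ext))
    # window covering ext indices [i, i + window - 1] for i = 1..n
    (cs[seq_len(n) + window - 1L] - c(0, cs[seq_len(n - 1L)])) / window
  } else {
    cs <- c(0, cumsum(as.numeric(values)))
    lo <- pmax(seq_len(n) - left, 1L)
    hi <- pmin(seq_len(n) + right, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Normalized differential coverage (NDC2)
#'
#' The uracil pull-down signal statistic: at each position, the ratio of a
#' local (default 120 bp) to a regional (default 100 kb) moving average of
#' the depth of coverage, computed for the sample library and for the
#' empty-vector (EV) control, and differenced:
#'
#' `NDC2 = mav(sample, w_local)/mav(sample, w_regional) -
#'         mav(EV, w_local)/mav(EV, w_regional)`
#'
#' The double ratio cancels both global library-size differences and
#' regional coverage waves, so NDC2 is invariant to independent rescaling
#' of either track. Positions where either regional average is zero are
#' masked (`NA`).
#'
#' @param sample_doc,ev_doc Numeric depth-of-coverage tracks of equal
#'   length (typically the `depth_selected` column of a position table).
#' @param w_local,w_regional Local and regional window sizes (bp).
#' @param circular Wrap windows around the origin?
#' @return Numeric vector of NDC2 values, `NA` at masked positions.
#' @export
compute_ndc2 <- function(sample_doc, ev_doc, w_local = 120L,
                         w_regional = 100000L, circular = TRUE) {
  if (length(sample_doc) != length(ev_doc)) stop("track length mismatch")
  n <- length(sample_doc)
  if (w_regional > n) w_regional <- n
  if (w_local >= w_regional) stop("w_local must be < w_regional")
  s_loc <- moving_average(sample_doc, w_local, circular)
  s_reg <- moving_average(sample_doc, w_regional, circular)
  e_loc <- moving_average(ev_doc, w_local, circular)
  e_reg <- moving_average(ev_doc, w_regional, circular)
  out <- rep(NA_real_, n)
  ok <- s_reg > 0 & e_reg > 0
  out[ok] <- s_loc[ok] / s_reg[ok] - e_loc[ok] / e_reg[ok]
  out
}
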
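#' Scan a genome for potential DNA hairpin (stem-loop) structures
#'
#' For every candidate loop placement and loop length in
#' `[loop_min, loop_max]`, a perfect Watson-Crick stem is extended outward
#' base pair by base pair (left arm 5' of the loop against right arm 3' of
#' it) up to `stem_max` pairs, stopping at the first non-complementary
#' pair. No G:T wobble pairs, bulges or internal mismatches are allowed.
#' Stem strength weights G:C pairs 3 and A:T pairs 1:
#' `SS = 3 * n_gc + 1 * n_at`. One call is emitted per (loop placement,
#' loop length) whose maximal stem has `stem_len >= 2` and
#' `SS >= ss_min`. Circular genomes wrap; on linear genomes stems stop at
#' the sequence ends.
#'
#' @param g A [genome()].
#' @param loop_min,loop_max Loop-length range in nt (defaults 3-8).
#' @param stem_max Maximum stem pairs examined (default 12, capping SS
#'   at 36).
#' @param ss_min Minimum stem strength reported (default 1).
#' @return `data.frame` of class `hairpin_calls`: `loop_start`, `loop_end`
#'   (1-based closed loop coordinates; `loop_end` may exceed the genome
#'   length for loops wrapping the origin), `loop_len`, `stem_len`,
#'   `n_gc`, `n_at`, `ss`.
#' @export
scan_hairpins <- function(g, loop_min = 3L, loop_max = 8L, stem_max = 12L,
                          ss_min = 1L) {
  stopifnot(loop_min >= 1L, loop_max >= loop_min, stem_max >= 2L)
  L <- g$length
  if (L < loop_min + 4L) {
    return(hairpin_calls(data.frame(loop_start = integer(), loop_end = integer(),
                                    loop_len = integer(), stem_len = integer(),
                                    n_gc = integer(), n_at = integer(),
                                    ss = integer())))
  }
  code <- seq_codes(g$sequence)      # A=1 C=2 G=3 T=4, N=NA
  comp <- 5L - code                  # complement codes
  is_gc <- code %in% c(2L, 3L)
  res <- vector("list", loop_max - loop_min + 1L)
  for (ll in loop_min:loop_max) {
    s <- seq_len(L)                  # loop start (1-based)
    alive <- rep(TRUE, L)
    stem_len <- integer(L)
    n_gc <- integer(L)
    for (k in seq_len(stem_max)) {
      li <- s - k                    # left-arm index
      ri <- s + ll + k - 1L          # right-arm index
      if (g$circular) {
        li <- wrap1(li, L); ri <- wrap1(ri, L)
        in_range <- rep(TRUE, L)
        # a stem may not wrap so far that arms collide with the loop
        in_range <- (ll + 2L * k) <= L
      } else {
        in_range <- li >= 1L & ri <= L
        li[!in_range] <- 1L; ri[!in_range] <- 1L
      }
      pair_ok <- in_range & !is.na(comp[li]) & !is.na(code[ri]) &
        comp[li] == code[ri]
      alive <- alive & pair_ok
      stem_len <- stem_len + alive
      n_gc <- n_gc + (alive & is_gc[li])
    }
    ss <- 3L * n_gc + (stem_len - n_gc)
    keep <- stem_len >= 2L & ss >= ss_min
    if (any(keep)) {
      res[[ll - loop_min + 1L]] <- data.frame(
        loop_start = s[keep],
        loop_end = s[keep] + ll - 1L,
        loop_len = ll,
        stem_len = stem_len[keep],
        n_gc = n_gc[keep],
        n_at = stem_len[keep] - n_gc[keep],
        ss = ss[keep]
      )
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(loop_start = integer(), loop_end = integer(),
                      loop_len = integer(), stem_len = integer(),
                      n_gc = integer(), n_at = integer(), ss = integer())
  }
  out <- out[order(out$loop_start, out$loop_len), , drop = FALSE]
  rownames(out) <- NULL
  hairpin_calls(out)
}

hairpin_calls <- function(df) {
  class(df) <- c("hairpin_calls", "data.frame")
  df
}

#' Cytosines within hairpin loops
#'
#' Expands a call set into its loop cytosines: for every call, each loop
#' base that is a C yields a plus-strand entry with its 1-based position in
#' the loop counted 5' to 3'; each loop G is a minus-strand loop C, with
#' the loop position counted 5' to 3' on the minus strand
#' (`loop_len - i + 1`).
#'
#' @param g The [genome()].
#' @param calls A [scan_hairpins()] call set.
#' @return `data.frame`: `pos`, `strand`, `loop_pos`, `loop_len`, `ss`.
#' @export
hairpin_loop_cs <- function(g, calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(pos = integer(), strand = character(),
                      loop_pos = integer(), loop_len = integer(),
                      ss = integer()))
  }
  code <- seq_codes(g$sequence)
  L <- g$length
  idx <- rep.int(seq_len(nrow(calls)), calls$loop_len)
  off <- sequence(calls$loop_len)            # 1..loop_len within each call
  gpos <- calls$loop_start[idx] + off - 1L
  if (g$circular) gpos <- wrap1(gpos, L)
  b <- code[gpos]
  isC <- !is.na(b) & b == 2L
  isG <- !is.na(b) & b == 3L
  out <- rbind(
    data.frame(pos = gpos[isC], strand = rep("+", sum(isC)),
               loop_pos = off[isC],
               loop_len = calls$loop_len[idx][isC], ss = calls$ss[idx][isC]),
    data.frame(pos = gpos[isG], strand = rep("-", sum(isG)),
               loop_pos = calls$loop_len[idx][isG] - off[isG] + 1L,
               loop_len = calls$loop_len[idx][isG], ss = calls$ss[idx][isG])
  )
  rownames(out) <- NULL
  out
}

#' Best hairpin assignment for every cytosine
#'
#' Every C (on either strand: plus-strand C or plus-strand G read as a
#' minus-strand C) that lies in at least one hairpin loop receives the
#' maximum stem strength over the loops containing it, along with that
#' hairpin's loop length and the base's 1-based loop position; ties on SS
#' resolve to the shorter loop, then the leftmost call. Cytosines never in
#' a loop get `best_ss = 0`.
#'
#' @param g The [genome()].
#' @param calls A [scan_hairpins()] call set.
#' @return `data.frame` over all C/G genomic positions: `pos`, `strand`,
#'   `best_ss`, `loop_len`, `loop_pos` (NA when `best_ss == 0`).
#' @export
assign_best_hairpin <- function(g, calls) {
  code <- seq_codes(g$sequence)
  cpos <- which(!is.na(code) & code == 2L)
  gpos <- which(!is.na(code) & code == 3L)
  base <- rbind(
    data.frame(pos = cpos, strand = rep("+", length(cpos))),
    data.frame(pos = gpos, strand = rep("-", length(gpos)))
  )
  base$best_ss <- 0L
  base$loop_len <- NA_integer_
  base$loop_pos <- NA_integer_
  lc <- hairpin_loop_cs(g, calls)
  if (nrow(lc) > 0L) {
    o <- order(lc$pos, lc$strand, -lc$ss, lc$loop_len)
    lc <- lc[o, , drop = FALSE]
    first <- !duplicated(lc[, c("pos", "strand")])
    best <- lc[first, , drop = FALSE]
    key_base <- paste(base$pos, base$strand)
    m <- match(paste(best$pos, best$strand), key_base)
    base$best_ss[m] <- best$ss
    base$loop_len[m] <- best$loop_len
    base$loop_pos[m] <- best$loop_pos
  }
  o <- order(base$pos, base$strand)
  base <- base[o, , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Stem-strength bin labels for stratified statistics
#'
#' Maps each position's best stem strength to a label: `"non-hairpin"`
#' below the first bin edge (including `best_ss == 0`), then one label per
#' half-open bin `[e_i, e_{i+1})`, the last bin open-ended
#' (`"ss>=e_last"`). With no edges, positions split at `ss >= 1` into
#' `"hairpin"` / `"non-hairpin"`.
#'
#' @param best_ss Integer vector of per-position best stem strengths.
#' @param bin_edges Strictly increasing integer vector of lower bin edges.
#' @return Factor with levels from `"non-hairpin"` upward.
#' @export
ss_bin_labels <- function(best_ss, bin_edges = c(12L)) {
  if (length(bin_edges) == 0L) {
    lab <- ifelse(best_ss >= 1L, "hairpin", "non-hairpin")
    return(factor(lab, levels = c("non-hairpin", "hairpin")))
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  nb <- length(bin_edges)
  labs <- c("non-hairpin",
            if (nb > 1L) paste0("ss", bin_edges[-nb], "-", bin_edges[-1L] - 1L),
            paste0("ss>=", bin_edges[nb]))
  bin <- findInterval(best_ss, bin_edges) + 1L   # 1 = below first edge
  factor(labs[bin], levels = labs)
}
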
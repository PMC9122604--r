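# Independent brute-force oracles and tiny fixture builders used across
# the suite. These stay deliberately naive: direct transcriptions of the
# definitions, sharing no code path with the implementation.

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# O(n*w) windowed mean, centered with the even-window convention
# (floor(w/2) left, w - 1 - floor(w/2) right)
oracle_moving_average <- function(x, w, circular = TRUE) {
  n <- length(x)
  left <- w %/% 2
  right <- w - 1 - left
  sapply(seq_len(n), function(i) {
    idx <- (i - left):(i + right)
    if (circular) {
      idx <- ((idx - 1) %% n) + 1
    } else {
      idx <- idx[idx >= 1 & idx <= n]
    }
    mean(x[idx])
  })
}

# brute-force hairpin enumeration: every (loop_start, loop_len) pair,
# stem grown pair by pair by direct base comparison (encoded 1..4 with
# complement 5 - x purely for speed; the logic stays per-placement naive)
oracle_hairpins <- function(seq, loop_min = 3, loop_max = 8, stem_max = 12,
                            ss_min = 1, circular = TRUE) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n <- length(x)
  res_s <- integer(0); res_ll <- integer(0); res_stem <- integer(0)
  res_gc <- integer(0)
  for (s in seq_len(n)) {
    for (ll in loop_min:loop_max) {
      stem <- 0L; ngc <- 0L
      for (k in seq_len(stem_max)) {
        li <- s - k
        ri <- s + ll + k - 1
        if (circular) {
          if (ll + 2 * k > n) break
          li <- ((li - 1) %% n) + 1
          ri <- ((ri - 1) %% n) + 1
        } else {
          if (li < 1 || ri > n) break
        }
        lb <- x[li]; rb <- x[ri]
        if (is.na(lb) || is.na(rb) || lb + rb != 5L) break
        stem <- stem + 1L
        if (lb == 2L || lb == 3L) ngc <- ngc + 1L
      }
      ss <- 3L * ngc + (stem - ngc)
      if (stem >= 2L && ss >= ss_min) {
        res_s <- c(res_s, s); res_ll <- c(res_ll, ll)
        res_stem <- c(res_stem, stem); res_gc <- c(res_gc, ngc)
      }
    }
  }
  out <- data.frame(loop_start = res_s, loop_len = res_ll,
                    stem_len = res_stem, n_gc = res_gc,
                    n_at = res_stem - res_gc,
                    ss = 3L * res_gc + (res_stem - res_gc))
  out[order(out$loop_start, out$loop_len), ]
}

# hand-buildable position table: depth and per-base counts supplied as a
# list of per-position overrides on an all-reference-base background
toy_table <- function(seq, depth = 100, overrides = list()) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(ch)
  tab <- data.frame(pos = seq_len(L), ref = ch,
                    depth_total = rep(depth, L),
                    A = 0L, C = 0L, G = 0L, T = 0L, N = 0L,
                    depth_selected = rep(depth, L),
                    stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) tab[[b]][ch == b] <- depth
  for (ov in overrides) {
    i <- ov$pos
    for (nm in setdiff(names(ov), "pos")) tab[[nm]][i] <- ov[[nm]]
  }
  class(tab) <- c("position_table", "data.frame")
  attr(tab, "sample_id") <- "toy"
  tab
}

# minimal SAM writer for pileup fixtures
write_toy_sam <- function(path, reads, ref_name, ref_len) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  body <- vapply(reads, function(r) {
    paste(r$qname, r$flag %||% 0, ref_name, r$pos, r$mapq %||% 60,
          r$cigar, "*", 0, 0, r$seq, strrep("I", nchar(r$seq)), sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rigid circular rotation of an interval set, wrapped pieces split
rotate_set <- function(df, off, L) {
  w <- df$end - df$start
  s <- ((df$start - 1 + off) %% L) + 1
  e <- s + w
  pieces <- lapply(seq_along(s), function(i) {
    if (e[i] <= L) data.frame(start = s[i], end = e[i])
    else rbind(data.frame(start = s[i], end = L),
               data.frame(start = 1, end = e[i] - L))
  })
  do.call(rbind, pieces)
}

# direct circular-overlap count between two interval sets with b rotated
# by `off`; intervals are (start, end) 1-based closed, end may exceed L
oracle_overlap_count <- function(a, b, off, L) {
  norm <- function(s, e) {
    w <- e - s
    s2 <- ((s - 1) %% L) + 1
    cbind(s2, s2 + w)
  }
  an <- norm(a$start, a$end)
  bn <- norm(b$start + off, b$end + off)
  covered <- logical(L)
  for (j in seq_len(nrow(bn))) {
    idx <- ((bn[j, 1]:bn[j, 2]) - 1) %% L + 1
    covered[idx] <- TRUE
  }
  hit <- 0
  for (i in seq_len(nrow(an))) {
    idx <- ((an[i, 1]:an[i, 2]) - 1) %% L + 1
    if (any(covered[idx])) hit <- hit + 1
  }
  hit
}
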
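#' Simulation parameters for synthetic UPD-seq data
#'
#' Collects the generative knobs for [simulate_updseq()] and
#' [simulate_mutation_catalog()]. Per-cytosine deamination probability is
#' `base_rate` multiplied by the matching context weight, by
#' `strand_bias_beta` when the C lies on the lagging-strand template, by
#' the stem-strength-bin factor when it sits in a hairpin loop, and by the
#' peak enrichment inside planted peak regions; the product is clipped to
#' `[0, 1]`. The empty-vector control is generated with every multiplier
#' at 1 and its own background rate `ev_rate`.
#'
#' @param base_rate Per-site deamination probability before multipliers
#'   (default 0.002).
#' @param ev_rate Background deamination rate of the empty-vector control
#'   (default equal to `base_rate`; genomic uracils from dUTP usage exist
#'   without any deaminase).
#' @param context_weights Named numeric vector of multipliers keyed by
#'   context strings (e.g. `c("TC:2" = 3)`); unnamed sites keep weight 1.
#' @param strand_bias_beta Multiplier applied to lagging-strand-template
#'   cytosines (default 1 = no bias).
#' @param hairpin_factor Named numeric vector of multipliers keyed by the
#'   [ss_bin_labels()] labels generated from `hairpin_bin_edges`
#'   (default none).
#' @param hairpin_bin_edges Stem-strength bin edges used to apply
#'   `hairpin_factor` (default 15, the hairpin/non-hairpin split).
#' @param peak_regions `data.frame(start, end, enrichment)` of planted
#'   pull-down peaks; enrichment scales both the deamination probability
#'   and the sample depth inside the region.
#' @param mean_depth Expected coverage depth (Poisson; default 100).
#' @param error_rate Per-base sequencing error probability, split equally
#'   across the three substitutions (default 1e-4).
#' @param read_len Nominal read length used to model the mismatch-read
#'   selection (default 100).
#' @param seed Integer seed; identical parameters (seed included) give
#'   byte-identical outputs.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(base_rate = 0.002, ev_rate = base_rate,
                       context_weights = NULL, strand_bias_beta = 1,
                       hairpin_factor = NULL, hairpin_bin_edges = c(15L),
                       peak_regions = NULL, mean_depth = 100,
                       error_rate = 1e-4, read_len = 100L, seed = 1L) {
  stopifnot(base_rate >= 0, ev_rate >= 0, strand_bias_beta >= 0,
            mean_depth > 0, error_rate >= 0)
  if (!is.null(context_weights) && any(context_weights < 0))
    stop("context weights must be >= 0")
  if (!is.null(hairpin_factor) && any(hairpin_factor < 0))
    stop("hairpin factors must be >= 0")
  structure(list(base_rate = base_rate, ev_rate = ev_rate,
                 context_weights = context_weights,
                 strand_bias_beta = strand_bias_beta,
                 hairpin_factor = hairpin_factor,
                 hairpin_bin_edges = hairpin_bin_edges,
                 peak_regions = peak_regions, mean_depth = mean_depth,
                 error_rate = error_rate, read_len = as.integer(read_len),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a random circular genome with annotations and planted features
#'
#' Draws an i.i.d. sequence at the requested GC fraction, places
#' non-overlapping genes (protein-coding and tRNA) on alternating random
#' strands with log-normal expression values, puts the replication origin
#' at position 1 and the terminus antipodally, and optionally plants
#' hairpin cassettes of known stem strength (a GC stem of `n_gc` pairs
#' around a fixed loop, flanked by non-pairing bases so the scanned stem
#' strength equals the planted one).
#'
#' @param length Genome length in bp (>= 1e4).
#' @param gc_fraction Target GC content (default 0.5).
#' @param n_genes,n_trna Number of protein-coding / tRNA genes.
#' @param n_planted_hairpins Number of planted hairpin cassettes.
#' @param planted_stem_gc GC pairs in each planted stem (default 6,
#'   SS = 18).
#' @param seed Integer seed.
#' @return List: `genome`, `genes` ([gene_annotations()]), `map`
#'   ([replichore_map()]), `hairpin_truth` (data.frame of planted loops),
#'   `peak_capacity` (free interval list used by callers to plant peaks).
#' @export
generate_genome <- function(length = 1e5, gc_fraction = 0.5, n_genes = 40L,
                            n_trna = 8L, n_planted_hairpins = 0L,
                            planted_stem_gc = 6L, seed = 1L) {
  L <- as.integer(length)
  if (L < 1e4) stop("genome length must be >= 1e4")
  withr_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p)

    n_feat <- n_genes + n_trna
    if (n_feat * 1500L > L) stop("requested genes exceed genome capacity")
    block <- L %/% max(1L, n_feat)
    is_trna <- sample(rep(c(FALSE, TRUE), c(n_genes, n_trna)))
    glen <- ifelse(is_trna, sample(76:90, n_feat, replace = TRUE),
                   sample(600:1200, n_feat, replace = TRUE))
    gstart <- (seq_len(n_feat) - 1L) * block +
      vapply(block - glen - 20L, function(m) sample.int(max(m, 1L), 1L), 0L)
    genes <- gene_annotations(
      gene_id = sprintf("%s%03d", ifelse(is_trna, "trna", "gene"), seq_len(n_feat)),
      start = gstart + 1L, end = gstart + glen,
      strand = sample(c("+", "-"), n_feat, replace = TRUE),
      gene_type = ifelse(is_trna, "tRNA", "protein_coding"),
      expression = stats::rlnorm(n_feat, meanlog = ifelse(is_trna, 4, 2), sdlog = 1)
    )

    truth <- NULL
    if (n_planted_hairpins > 0L) {
      arm <- paste(sample(c("G", "C"), planted_stem_gc, replace = TRUE),
                   collapse = "")
      loop <- "TTCA"
      cassette <- paste0("A", arm, loop, revcomp(arm), "G")
      clen <- nchar(cassette)
      # place cassettes in intergenic space, far apart
      anchor <- floor(seq(block %/% 3, L - clen - 1L,
                          length.out = n_planted_hairpins))
      truth <- data.frame(
        loop_start = anchor + 1L + planted_stem_gc + 1L,
        loop_len = nchar(loop),
        ss = 3L * planted_stem_gc
      )
      for (a in anchor) {
        seq[(a + 1L):(a + clen)] <- strsplit(cassette, "", fixed = TRUE)[[1L]]
      }
    }
    g <- genome(paste(seq, collapse = ""), name = "simchr", circular = TRUE)
    list(genome = g, genes = genes,
         map = replichore_map(1L, L %/% 2L + 1L),
         hairpin_truth = truth)
  })
}

# per-(C/G)-site deamination probabilities under `params`; returns a list
# with the site table (pos, strand) and the probability vector, plus the
# per-position total C>T probability track used for read-selection depth.
site_probabilities <- function(g, map, params, background = FALSE) {
  code <- seq_codes(g$sequence)
  cpos <- which(!is.na(code) & code == 2L)
  gpos <- which(!is.na(code) & code == 3L)
  sites <- rbind(
    data.frame(pos = cpos, strand = rep("+", length(cpos))),
    data.frame(pos = gpos, strand = rep("-", length(gpos)))
  )
  p <- rep(if (background) params$ev_rate else params$base_rate, nrow(sites))
  if (!background) {
    key <- if (!is.null(params$context_weights) || !is.null(params$hairpin_factor))
      paste(sites$pos, sites$strand) else NULL
    if (!is.null(params$context_weights)) {
      for (ctx in names(params$context_weights)) {
        cp <- find_context_positions(g, ctx)
        hit <- key %in% paste(cp$pos, cp$strand)
        p[hit] <- p[hit] * params$context_weights[[ctx]]
      }
    }
    if (params$strand_bias_beta != 1 && !is.null(map)) {
      role <- replicative_role(sites$pos, sites$strand, map, g)
      p[role == "LGST"] <- p[role == "LGST"] * params$strand_bias_beta
    }
    if (!is.null(params$hairpin_factor)) {
      calls <- scan_hairpins(g)
      asg <- assign_best_hairpin(g, calls)
      m <- match(key, paste(asg$pos, asg$strand))
      best_ss <- ifelse(is.na(m), 0L, asg$best_ss[m])
      lab <- as.character(ss_bin_labels(best_ss, params$hairpin_bin_edges))
      for (nm in names(params$hairpin_factor)) {
        p[lab == nm] <- p[lab == nm] * params$hairpin_factor[[nm]]
      }
    }
    if (!is.null(params$peak_regions)) {
      inpk <- in_any_interval(sites$pos, params$peak_regions)
      if (any(inpk)) {
        enr <- peak_enrichment_at(sites$pos, params$peak_regions)
        p <- p * enr
      }
    }
  }
  n_clipped <- sum(p > 1)
  p <- pmin(p, 1)
  list(sites = sites, p = p, n_clipped = n_clipped)
}

peak_enrichment_at <- function(pos, peak_regions) {
  enr <- rep(1, length(pos))
  for (i in seq_len(nrow(peak_regions))) {
    hit <- pos >= peak_regions$start[i] & pos <= peak_regions$end[i]
    enr[hit] <- enr[hit] * peak_regions$enrichment[i]
  }
  enr
}

make_table <- function(g, sites, p, depth, params, sample_id) {
  L <- g$length
  refchr <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  tab <- data.frame(pos = seq_len(L), ref = refchr,
                    depth_total = depth, A = 0L, C = 0L, G = 0L, T = 0L,
                    N = 0L, stringsAsFactors = FALSE)
  # reference-base counts start at full depth, substitutions move reads
  for (b in c("A", "C", "G", "T")) tab[[b]][refchr == b] <- depth[refchr == b]
  err <- params$error_rate
  p_ct <- pmin(p + err / 3, 1)           # deamination plus same-channel error
  n_chg <- stats::rbinom(length(p_ct), depth[sites$pos], p_ct)
  plus <- sites$strand == "+"
  # C>T on the plus strand; G>A for minus-strand cytosines
  tp <- sites$pos[plus]
  tab$T[tp] <- tab$T[tp] + n_chg[plus]
  tab$C[tp] <- tab$C[tp] - n_chg[plus]
  ap <- sites$pos[!plus]
  tab$A[ap] <- tab$A[ap] + n_chg[!plus]
  tab$G[ap] <- tab$G[ap] - n_chg[!plus]
  # per-position probability a read carries >= 1 C/G mismatch anywhere in
  # its span: local mean of the total change probability over read_len
  p_track <- numeric(L)
  p_track[sites$pos] <- p_track[sites$pos] + p_ct
  mav_p <- moving_average(p_track, min(params$read_len, L), circular = g$circular)
  p_sel <- 1 - exp(-min(params$read_len, L) * mav_p)
  tab$depth_selected <- stats::rbinom(L, depth, p_sel)
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("position_table", "data.frame")
  tab
}

#' Simulate a pair of UPD-seq position tables (sample and empty vector)
#'
#' Emulates the measurement process downstream of the pull-down: every
#' cytosine (both strands) deaminates with the probability assembled by
#' [sim_params()]; depth is Poisson with mean `mean_depth`, additionally
#' multiplied by the peak enrichment inside planted peak regions for the
#' sample (uracil-containing fragments are enriched by the pull-down);
#' C>T read counts are binomial in depth. `depth_selected` models the
#' mismatch-read filter: each read is retained with probability
#' `1 - exp(-read_len * p_local)` where `p_local` is the local mean change
#' probability over the read span. The EV table has uniform background
#' rate and no multipliers.
#'
#' @param g A [genome()].
#' @param map A [replichore_map()] (used when `strand_bias_beta != 1`).
#' @param params A [sim_params()].
#' @return List: `sample` and `ev` position tables, `n_clipped`
#'   probability clip count.
#' @export
simulate_updseq <- function(g, map, params) {
  withr_seed(params$seed, {
    sp <- site_probabilities(g, map, params, background = FALSE)
    ep <- site_probabilities(g, map, params, background = TRUE)
    L <- g$length
    depth_mult <- rep(1, L)
    if (!is.null(params$peak_regions)) {
      depth_mult <- peak_enrichment_at(seq_len(L), params$peak_regions)
    }
    depth_s <- stats::rpois(L, params$mean_depth * depth_mult)
    depth_e <- stats::rpois(L, params$mean_depth)
    list(
      sample = make_table(g, sp$sites, sp$p, depth_s, params, "sample"),
      ev = make_table(g, ep$sites, ep$p, depth_e, params, "EV"),
      n_clipped = sp$n_clipped
    )
  })
}

#' Simulate a tumor SNV catalog with planted structure
#'
#' Samples `n_mut` single-nucleotide variants at C:G sites with
#' probability proportional to the same multiplier structure as
#' [simulate_updseq()] (context weight x replicative-strand beta x
#' hairpin-bin factor); plus-strand cytosines yield C>T records,
#' minus-strand cytosines G>A. Recurrent positions are allowed (sampling
#' with replacement).
#'
#' @param g A [genome()].
#' @param map A [replichore_map()] or NULL.
#' @param params A [sim_params()].
#' @param n_mut Number of mutations to draw.
#' @param sample_id Sample label.
#' @return A `mutation_catalog` data.frame; the generative site
#'   probabilities are stored in the `truth` attribute.
#' @export
simulate_mutation_catalog <- function(g, map, params, n_mut,
                                      sample_id = "sim_tumor") {
  withr_seed(params$seed, {
    sp <- site_probabilities(g, map, params, background = FALSE)
    if (n_mut > 0 && all(sp$p == 0)) stop("all site probabilities are zero")
    idx <- if (n_mut > 0)
      sample.int(nrow(sp$sites), n_mut, replace = TRUE, prob = sp$p)
    else integer()
    muts <- data.frame(
      chrom = rep(g$name, n_mut),
      pos = sp$sites$pos[idx],
      ref = ifelse(sp$sites$strand[idx] == "+", "C", "G"),
      alt = ifelse(sp$sites$strand[idx] == "+", "T", "A"),
      sample_id = rep(sample_id, n_mut),
      stringsAsFactors = FALSE
    )
    attr(muts, "n_skipped") <- 0L
    attr(muts, "truth") <- list(params = params)
    class(muts) <- c("mutation_catalog", "data.frame")
    muts
  })
}

#' Write a mutation catalog as a minimal VCF 4.2 file
#' @param muts A `mutation_catalog`.
#' @param path Output path.
#' @export
write_catalog_vcf <- function(muts, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                   muts$chrom, muts$pos, muts$ref, muts$alt)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
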
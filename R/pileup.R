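#' Read primary alignments from a SAM/BAM file
#'
#' Unmapped, secondary and supplementary alignments are dropped, as are
#' reads mapping to any contig named in `exclude_contigs` (plasmid
#' decontamination) and reads below `min_mapq` (default keeps MAPQ 0).
#'
#' @param path SAM (plain or gzipped) or BAM file.
#' @param exclude_contigs Character vector of contig names whose reads are
#'   discarded before any counting.
#' @param min_mapq Minimum mapping quality retained; default 0.
#' @return A `GAlignments` object with the read sequence in `mcols(.)$seq`.
#' @export
read_alignments <- function(path, exclude_contigs = character(), min_mapq = 0L) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- path
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("seq", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(exclude_contigs)) {
    aln <- aln[!(as.character(GenomicAlignments::seqnames(aln)) %in% exclude_contigs)]
  }
  mq <- S4Vectors::mcols(aln)$mapq
  keep <- is.na(mq) | mq >= min_mapq
  aln[keep]
}

# Read sequences laid out in reference space: soft clips and insertions
# removed, deletions filled with "-". One DNAStringSet parallel to aln.
layered_seqs <- function(aln) {
  GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(aln)$seq, GenomicAlignments::cigar(aln),
    from = "query", to = "reference"
  )
}

#' Select reads with a mismatch at a reference C or G
#'
#' The uracil signal comes from reads that carry at least one aligned base
#' differing from the reference where the reference base is C or G (a
#' deaminated C read as T, or its minus-strand G>A image). Reads matching
#' the reference everywhere, or mismatching only at A/T reference bases,
#' are discarded. Reads without a stored sequence are dropped with a
#' warning.
#'
#' @param aln `GAlignments` from [read_alignments()].
#' @param g The reference [genome()].
#' @return The subset of `aln` with >= 1 mismatch at a C/G reference base.
#' @export
select_mismatch_reads <- function(aln, g) {
  if (length(aln) == 0L) return(aln)
  has_seq <- Biostrings::width(S4Vectors::mcols(aln)$seq) > 0L
  if (any(!has_seq)) {
    warning(sum(!has_seq), " read(s) without sequence dropped")
    aln <- aln[has_seq]
    if (length(aln) == 0L) return(aln)
  }
  lay <- layered_seqs(aln)
  st <- GenomicAlignments::start(aln)
  en <- GenomicAlignments::end(aln)
  keep <- vapply(seq_along(aln), function(i) {
    ref <- strsplit(substr(g$sequence, st[i], en[i]), "", fixed = TRUE)[[1L]]
    rd <- strsplit(as.character(lay[[i]]), "", fixed = TRUE)[[1L]]
    any(ref %in% c("C", "G") & rd != ref & rd %in% c("A", "C", "G", "T"))
  }, logical(1L))
  aln[keep]
}

#' Build a per-position depth and base-count table
#'
#' For one library, tabulates at every genomic position the total depth of
#' coverage from primary alignments, the counts of each base among aligned
#' read bases (insertions ignored, deletions contribute depth but no base),
#' and the depth from the subset of reads retained by
#' [select_mismatch_reads()] (`depth_selected`), which carries the
#' uracilation enrichment signal.
#'
#' @param aln `GAlignments` from [read_alignments()].
#' @param g The reference [genome()].
#' @param sample_id Library label stored on the table.
#' @return A `data.frame` of class `position_table` with one row per
#'   genomic position and columns `pos`, `ref`, `depth_total`, `A`, `C`,
#'   `G`, `T`, `N`, `depth_selected`.
#' @export
build_position_table <- function(aln, g, sample_id = "sample") {
  L <- g$length
  if (length(aln) > 0L) {
    rn <- unique(as.character(GenomicAlignments::seqnames(aln)))
    if (!all(rn == g$name)) {
      stop("alignments reference '", paste(rn, collapse = ","),
           "' but genome is '", g$name, "'")
    }
  }
  zero <- integer(L)
  counts <- list(A = zero, C = zero, G = zero, T = zero, N = zero)
  depth_total <- zero
  depth_selected <- zero
  if (length(aln) > 0L) {
    cov <- GenomicAlignments::coverage(aln)[[1L]]
    depth_total <- as.integer(cov)[seq_len(L)]
    lay <- layered_seqs(aln)
    st <- GenomicAlignments::start(aln)
    pos <- unlist(lapply(seq_along(aln), function(i)
      seq.int(st[i], st[i] + Biostrings::width(lay)[i] - 1L)))
    base <- strsplit(paste(as.character(lay), collapse = ""), "", fixed = TRUE)[[1L]]
    ok <- pos >= 1L & pos <= L
    pos <- pos[ok]; base <- base[ok]
    for (b in c("A", "C", "G", "T", "N")) {
      counts[[b]] <- tabulate(pos[base == b], nbins = L)
    }
    sel <- select_mismatch_reads(aln, g)
    if (length(sel) > 0L) {
      depth_selected <- as.integer(GenomicAlignments::coverage(sel)[[1L]])[seq_len(L)]
    }
  }
  tab <- data.frame(
    pos = seq_len(L),
    ref = strsplit(g$sequence, "", fixed = TRUE)[[1L]],
    depth_total = depth_total,
    A = counts$A, C = counts$C, G = counts$G, T = counts$T, N = counts$N,
    depth_selected = depth_selected,
    stringsAsFactors = FALSE
  )
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("position_table", "data.frame")
  tab
}

#' Fraction of C:G to T:A changes at a cytosine
#'
#' For a plus-strand C this is the T count over total depth at the
#' position; for a minus-strand C (a G on the reference plus strand) it is
#' the A count over depth, since a C>T on the minus strand reads as G>A on
#' the plus strand. Positions with zero depth are unmeasured and return
#' `NA`.
#'
#' @param tab A [build_position_table()] table.
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector of `"+"`/`"-"` (recycled).
#' @return Numeric vector in `[0, 1]`, `NA` where depth is 0.
#' @export
ct_change_fraction <- function(tab, pos, strand) {
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  ref <- tab$ref[pos]
  bad <- (strand == "+" & ref != "C") | (strand == "-" & ref != "G")
  if (any(bad)) {
    stop("reference base is not C (+) / G (-) at position(s) ",
         paste(utils::head(pos[bad], 5L), collapse = ", "))
  }
  depth <- tab$depth_total[pos]
  chg <- ifelse(strand == "+", tab$T[pos], tab$A[pos])
  ifelse(depth > 0L, chg / depth, NA_real_)
}

#' Write / read a position table as TSV
#' @param tab A `position_table`.
#' @param path Output path.
#' @export
write_position_table <- function(tab, path) {
  con <- file(path, "w")
  writeLines(paste0("# sample_id=", attr(tab, "sample_id")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_position_table
#' @export
read_position_table <- function(path) {
  first <- readLines(path, n = 1L)
  sample_id <- if (grepl("^# sample_id=", first)) sub("^# sample_id=", "", first) else "sample"
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("position_table", "data.frame")
  tab
}
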
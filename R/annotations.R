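#' Gene annotation table
#'
#' Annotations are held as a data.frame with one row per gene and columns
#' `gene_id`, `start`, `end` (1-based, closed), `strand` (`"+"`/`"-"`),
#' `gene_type` (`"tRNA"`, `"protein_coding"` or `"other"`), `tss` (the
#' transcription start site: `start` on the plus strand, `end` on the
#' minus strand) and `expression` (non-negative or `NA`).
#'
#' @param gene_id Character vector of identifiers.
#' @param start,end Integer vectors, 1-based closed coordinates, `start <= end`.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param gene_type Character vector; values outside the vocabulary map to
#'   `"other"`.
#' @param expression Numeric vector or `NULL` (all `NA`).
#' @return A `data.frame` of class `gene_annotations`.
#' @export
gene_annotations <- function(gene_id, start, end, strand,
                             gene_type = "other", expression = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("gene with start > end")
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol")
  n <- length(gene_id)
  gene_type <- rep_len(ifelse(gene_type %in% c("tRNA", "protein_coding"),
                              gene_type, "other"), n)
  expression <- if (is.null(expression)) rep(NA_real_, n) else as.numeric(expression)
  if (any(!is.na(expression) & expression < 0)) stop("negative expression")
  df <- data.frame(
    gene_id = as.character(gene_id),
    start = start, end = end, strand = strand,
    gene_type = gene_type,
    tss = ifelse(strand == "+", start, end),
    expression = rep_len(expression, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_annotations", "data.frame")
  df
}

map_gff_type <- function(type) {
  ifelse(type %in% c("tRNA", "tRNA_gene"), "tRNA",
         ifelse(type %in% c("CDS", "gene", "mRNA", "protein_coding"),
                "protein_coding", "other"))
}

parse_gff_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' Read gene annotations from GFF3 or a BED-like TSV
#'
#' GFF3 coordinates are 1-based inclusive and are kept as-is; BED-like input
#' is 0-based half-open and is shifted to the internal 1-based closed
#' convention. The BED-like dialect is a headered TSV with columns
#' `gene_id`, `start`, `end`, `strand` and optionally `gene_type` and
#' `expression`. GFF gene ids come from the `ID` attribute (falling back to
#' `Name`, then a running number); an `expression` attribute is honoured
#' when present.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"gff"` or `"bed"`.
#' @return A [gene_annotations()] data.frame.
#' @export
load_annotations <- function(path, format = c("auto", "gff", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff" else "bed"
  }
  if (format == "gff") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L) stop("no feature rows in ", path)
    f <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(f) < 9L) stop("malformed GFF: expected 9 columns")
    ids <- parse_gff_attr(f$V9, "ID")
    ids[is.na(ids)] <- parse_gff_attr(f$V9[is.na(ids)], "Name")
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
    expr <- suppressWarnings(as.numeric(parse_gff_attr(f$V9, "expression")))
    if (!all(f$V7 %in% c("+", "-"))) stop("unknown strand symbol in GFF")
    ann <- gene_annotations(ids, f$V4, f$V5, f$V7, map_gff_type(f$V3), expr)
  } else {
    f <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "start", "end", "strand")
    if (!all(need %in% names(f))) stop("BED-like TSV must have columns ",
                                       paste(need, collapse = ", "))
    if (any(f$start >= f$end)) stop("BED interval with start >= end")
    ann <- gene_annotations(
      f$gene_id, f$start + 1L, f$end, f$strand,
      if ("gene_type" %in% names(f)) f$gene_type else "other",
      if ("expression" %in% names(f)) f$expression else NULL
    )
  }
  ann
}

#' Write gene annotations as GFF3
#'
#' Emits 1-based inclusive coordinates; round-trips with
#' [load_annotations()].
#'
#' @param ann A [gene_annotations()] data.frame.
#' @param path Output path.
#' @param seqid Contig name for column 1.
#' @export
write_annotations_gff <- function(ann, path, seqid = "genome") {
  type <- ifelse(ann$gene_type == "tRNA", "tRNA",
                 ifelse(ann$gene_type == "protein_coding", "gene", "region"))
  attr9 <- paste0("ID=", ann$gene_id,
                  ifelse(is.na(ann$expression), "",
                         paste0(";expression=", format(ann$expression, trim = TRUE))))
  lines <- paste(seqid, "uracilome", type, ann$start, ann$end, ".",
                 ann$strand, ".", attr9, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Replication origin/terminus map of a circular chromosome
#'
#' The two replication forks start at `ori` and meet at `ter`, splitting the
#' chromosome into two replichores. The right replichore is the arc from
#' `ori` to `ter` in increasing (mod-length) coordinates, where the fork
#' moves towards increasing coordinates; the left replichore is the
#' complementary arc. Arcs are half-open: a position exactly at `ori`
#' belongs to the right replichore, one exactly at `ter` to the left.
#'
#' @param ori,ter 1-based coordinates of the origin and terminus; must differ.
#' @return A list of class `replichore_map`.
#' @export
replichore_map <- function(ori, ter) {
  ori <- as.integer(ori); ter <- as.integer(ter)
  if (ori == ter) stop("ori and ter must differ")
  if (ori < 1L || ter < 1L) stop("ori/ter must be positive 1-based coordinates")
  structure(list(ori = ori, ter = ter), class = "replichore_map")
}

#' Which replichore contains a position?
#'
#' @param pos Integer vector of 1-based positions.
#' @param map A [replichore_map()].
#' @param g The [genome()] (supplies the circular length).
#' @return Character vector, `"right"` or `"left"`.
#' @export
replichore_of <- function(pos, map, g) {
  L <- g$length
  if (any(pos < 1L | pos > L)) stop("position out of range")
  span <- (map$ter - map$ori) %% L
  d <- (as.integer(pos) - map$ori) %% L
  ifelse(d < span, "right", "left")
}

#' Replicative-strand role of a base
#'
#' Classifies a (position, strand) base as lying on the lagging-strand
#' template (LGST, transiently single-stranded at the fork) or the
#' leading-strand template (LDST). On the right replichore the fork moves
#' towards increasing coordinates and the plus strand is the lagging-strand
#' template; roles swap on the left replichore and between strands.
#'
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector of `"+"`/`"-"` (recycled).
#' @param map A [replichore_map()].
#' @param g The [genome()].
#' @return Character vector of `"LGST"`/`"LDST"`.
#' @export
replicative_role <- function(pos, strand, map, g) {
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol")
  rep_side <- replichore_of(pos, map, g)
  strand <- rep_len(strand, length(pos))
  ifelse((rep_side == "right") == (strand == "+"), "LGST", "LDST")
}

#' Transcriptional-strand role of a base
#'
#' `Tx+` marks a base on the non-transcribed (coding) strand of a gene,
#' `Tx-` one on the transcribed (template) strand, `"none"` an intergenic
#' position. Positions covered by overlapping genes on opposite strands
#' are `"ambiguous"` and should be excluded from strand statistics.
#'
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector of `"+"`/`"-"` (recycled).
#' @param genes A [gene_annotations()] data.frame.
#' @return Character vector over `{"Tx+", "Tx-", "none", "ambiguous"}`.
#' @export
transcriptional_role <- function(pos, strand, genes) {
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol")
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (nrow(genes) == 0L) return(rep("none", length(pos)))
  q <- IRanges::IRanges(start = pos, width = 1L)
  s <- IRanges::IRanges(start = genes$start, end = genes$end)
  hits <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  gstr <- genes$strand[S4Vectors::subjectHits(hits)]
  n_plus <- tabulate(qh[gstr == "+"], nbins = length(pos))
  n_minus <- tabulate(qh[gstr == "-"], nbins = length(pos))
  out <- rep("none", length(pos))
  amb <- n_plus > 0L & n_minus > 0L
  covered <- (n_plus > 0L) != (n_minus > 0L)
  gene_strand <- ifelse(n_plus > 0L, "+", "-")
  out[covered] <- ifelse(strand[covered] == gene_strand[covered], "Tx+", "Tx-")
  out[amb] <- "ambiguous"
  out
}

#' Replication-transcription conflict class of a gene
#'
#' Genes are codirectional when transcription proceeds in the same direction
#' as the local replication fork (plus strand on the right replichore, minus
#' strand on the left), head-on ("conflict") otherwise. Genes straddling
#' ori or ter are excluded (`NA` with a warning).
#'
#' @param genes A [gene_annotations()] data.frame.
#' @param map A [replichore_map()].
#' @param g The [genome()].
#' @return Character vector over `{"right-codirectional", "right-conflict",
#'   "left-codirectional", "left-conflict"}`, `NA` for straddling genes.
#' @export
conflict_class <- function(genes, map, g) {
  side_start <- replichore_of(genes$start, map, g)
  side_end <- replichore_of(genes$end, map, g)
  out <- rep(NA_character_, nrow(genes))
  ok <- side_start == side_end
  if (any(!ok)) warning(sum(!ok), " gene(s) straddle ori/ter; excluded")
  codir <- (side_start == "right") == (genes$strand == "+")
  out[ok] <- paste0(side_start[ok],
                    ifelse(codir[ok], "-codirectional", "-conflict"))
  out
}
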
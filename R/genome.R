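#' Construct a genome object
#'
#' A `Genome` holds one contig as an uppercase `A/C/G/T/N` string together
#' with its name, length and circularity flag. Bacterial chromosomes are
#' circular; index arithmetic on circular genomes wraps modulo the length.
#'
#' @param sequence Character scalar, the nucleotide sequence. Lowercase is
#'   accepted and uppercased; characters outside `A/C/G/T/N` become `N`
#'   with a warning.
#' @param name Contig name.
#' @param circular Logical; treat the sequence as circular (default `TRUE`).
#' @return An object of class `Genome` with fields `name`, `sequence`,
#'   `circular` and `length`.
#' @export
genome <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence")
  if (grepl("[^ACGTN]", sequence)) {
    warning("non-ACGTN characters replaced by N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(
    list(name = name, sequence = sequence, circular = isTRUE(circular),
         length = nchar(sequence)),
    class = "Genome"
  )
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param circular Logical flag applied to every record.
#' @return A single [genome()] object if the file holds one record, else a
#'   named list of `Genome` objects (one per record).
#' @export
load_genome <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  gs <- lapply(seq_along(set), function(i) {
    nm <- sub("\\s.*$", "", names(set)[i])
    genome(as.character(set[[i]]), name = nm, circular = circular)
  })
  names(gs) <- vapply(gs, `[[`, "", "name")
  if (length(gs) == 1L) gs[[1L]] else gs
}

#' Write a genome to FASTA
#'
#' @param g A [genome()].
#' @param path Output path.
#' @export
write_genome <- function(g, path) {
  set <- Biostrings::DNAStringSet(g$sequence)
  names(set) <- g$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Integer encoding A=1 C=2 G=3 T=4, N/other = NA; complement is 5 - code.
seq_codes <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  x
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# 1-based circular index
wrap1 <- function(i, L) ((i - 1L) %% L) + 1L

#' Base(s) of a genome at 1-based positions, wrapping if circular
#' @param g A [genome()].
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of single bases.
#' @export
genome_base <- function(g, pos) {
  if (g$circular) pos <- wrap1(as.integer(pos), g$length)
  if (any(pos < 1L | pos > g$length)) stop("position out of range on linear genome")
  substring(g$sequence, pos, pos)
}
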
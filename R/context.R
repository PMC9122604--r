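#' IUPAC sequence-context specification
#'
#' A context such as `TC`, `WRC` or `WRCY` with the index of the target
#' cytosine inside the pattern (1-based). `W = {A,T}`, `R = {A,G}`,
#' `Y = {C,T}`, `N = {A,C,G,T}`.
#'
#' @param pattern IUPAC string over `A/C/G/T/N/W/R/Y`.
#' @param c_index 1-based index of the target C within `pattern`; defaults
#'   to the last literal `C`.
#' @return A list of class `context_spec`.
#' @export
context_spec <- function(pattern, c_index = NULL) {
  pattern <- toupper(pattern)
  if (grepl("[^ACGTNWRY]", pattern)) stop("pattern alphabet restricted to A,C,G,T,N,W,R,Y")
  if (is.null(c_index)) {
    cs <- gregexpr("C", pattern, fixed = TRUE)[[1L]]
    if (cs[1L] == -1L) stop("pattern has no C")
    c_index <- cs[length(cs)]
  }
  c_index <- as.integer(c_index)
  if (c_index < 1L || c_index > nchar(pattern)) stop("c_index outside pattern")
  if (substr(pattern, c_index, c_index) != "C") stop("pattern[c_index] must be 'C'")
  structure(list(pattern = pattern, c_index = c_index), class = "context_spec")
}

#' Parse `"WRCY:3"`-style context strings
#' @param x Character like `"TC:2"` or `"WRCY"` (target C inferred).
#' @return A [context_spec()].
#' @export
parse_context <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) context_spec(parts[1L], as.integer(parts[2L]))
  else context_spec(parts[1L])
}

#' Locate all context cytosines on both strands of a genome
#'
#' Scans the plus strand for the pattern (giving plus-strand target Cs) and
#' for its reverse complement (giving minus-strand target Cs, i.e. plus-
#' strand Gs). Circular genomes wrap across the origin; on linear genomes
#' windows extending past either end are skipped. Matching of IUPAC
#' degeneracy is delegated to `Biostrings::matchPattern(fixed = FALSE)`;
#' reference `N`s never match.
#'
#' @param g A [genome()].
#' @param spec A [context_spec()] (or a string accepted by
#'   [parse_context()]).
#' @return A `data.frame` with columns `pos` (1-based position of the
#'   target C on the plus-strand coordinate system) and `strand`, sorted
#'   and unique; attribute `spec` carries the context.
#' @export
find_context_positions <- function(g, spec) {
  if (is.character(spec)) spec <- parse_context(spec)
  plen <- nchar(spec$pattern)
  if (plen > g$length) stop("pattern longer than genome")
  subj_seq <- g$sequence
  if (g$circular && plen > 1L) {
    subj_seq <- paste0(subj_seq, substr(g$sequence, 1L, plen - 1L))
  }
  subj <- Biostrings::DNAString(subj_seq)
  fwd <- Biostrings::matchPattern(spec$pattern, subj, fixed = FALSE)
  pos_plus <- Biostrings::start(fwd) + spec$c_index - 1L
  rcpat <- revcomp(spec$pattern)
  rev <- Biostrings::matchPattern(rcpat, subj, fixed = FALSE)
  # target C sits at offset (plen - c_index) inside the revcomp pattern
  pos_minus <- Biostrings::start(rev) + (plen - spec$c_index)
  if (g$circular) {
    pos_plus <- wrap1(pos_plus, g$length)
    pos_minus <- wrap1(pos_minus, g$length)
  }
  out <- rbind(
    data.frame(pos = pos_plus, strand = rep("+", length(pos_plus))),
    data.frame(pos = pos_minus, strand = rep("-", length(pos_minus)))
  )
  out <- unique(out)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  # matchPattern with fixed=FALSE lets reference N match pattern N; the
  # target position itself must be a literal C/G, which the pattern forces.
  attr(out, "spec") <- spec
  out
}
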
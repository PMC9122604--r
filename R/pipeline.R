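#' Run the full uracilome analysis pipeline
#'
#' Orchestrates the stages end to end on in-memory objects or file paths:
#' position tables (from SAM via [build_position_table()], TSV via
#' [read_position_table()], or supplied directly) feed NDC2
#' ([compute_ndc2()]), peak calling ([call_peaks()]), peak annotation
#' ([annotate_peaks()]), the context UI stratified by replicative and
#' transcriptional strand, and the hairpin-stratified UI. Outputs and a
#' plain-text run manifest (parameters, seed, stage completion) are
#' written under `config$out_dir` when it is set.
#'
#' @param config A list with elements:
#'   `genome` ([genome()] or FASTA path), `genes` ([gene_annotations()] or
#'   annotation path), `map` ([replichore_map()] or `c(ori, ter)`),
#'   `sample_table`/`ev_table` (position tables or TSV paths),
#'   `w_local` (120), `w_regional` (1e5), `k_sigma` (5),
#'   `contexts` (character vector, default `c("NC:2","TC:2","WRCY:3")`),
#'   `ss_split` (15), `doc` (`"selected"` or `"total"`), `seed` (1),
#'   `out_dir` (optional output directory).
#' @return List with `ndc2`, `peaks`, `peak_annotation`, `ui` (per context:
#'   overall / replicative / transcriptional / hairpin strata) and
#'   `manifest` (character vector of completed stages).
#' @export
run_pipeline <- function(config) {
  need <- c("genome", "sample_table", "ev_table")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config missing: ", paste(missing, collapse = ", "))
  cfg <- utils::modifyList(
    list(w_local = 120L, w_regional = 100000L, k_sigma = 5,
         contexts = c("NC:2", "TC:2", "WRCY:3"), ss_split = 15L,
         doc = "selected", seed = 1L, genes = NULL, map = NULL,
         out_dir = NULL),
    config)

  g <- if (is.character(cfg$genome)) load_genome(cfg$genome) else cfg$genome
  genes <- if (is.character(cfg$genes)) load_annotations(cfg$genes) else cfg$genes
  map <- if (is.numeric(cfg$map)) replichore_map(cfg$map[1L], cfg$map[2L]) else cfg$map
  stab <- if (is.character(cfg$sample_table)) read_position_table(cfg$sample_table) else cfg$sample_table
  etab <- if (is.character(cfg$ev_table)) read_position_table(cfg$ev_table) else cfg$ev_table
  manifest <- character()
  done <- function(stage) {
    manifest <<- c(manifest, stage)
    message("[uracilome] stage complete: ", stage)
  }
  doc_col <- if (cfg$doc == "selected") "depth_selected" else "depth_total"
  done("load")

  ndc2 <- compute_ndc2(stab[[doc_col]], etab[[doc_col]],
                       cfg$w_local, cfg$w_regional, circular = g$circular)
  done("ndc2")

  peaks <- call_peaks(ndc2, cfg$k_sigma, merge_gap = cfg$w_local,
                      circular = g$circular)
  done("peaks")

  peak_ann <- if (!is.null(genes)) annotate_peaks(peaks, genes) else NULL
  done("annotate")

  ui <- lapply(cfg$contexts, function(ctx) {
    pos <- find_context_positions(g, ctx)
    res <- list(overall = ui_with_subset_error(stab, pos, seed = cfg$seed))
    if (!is.null(map)) {
      res$replicative <- ui_stratified(
        stab, pos, replicative_role(pos$pos, pos$strand, map, g))
    }
    if (!is.null(genes)) {
      res$transcriptional <- ui_stratified(
        stab, pos, transcriptional_role(pos$pos, pos$strand, genes))
    }
    res
  })
  names(ui) <- cfg$contexts
  done("ui_strata")

  calls <- scan_hairpins(g)
  asg <- assign_best_hairpin(g, calls)
  hp_ui <- lapply(cfg$contexts, function(ctx) {
    pos <- find_context_positions(g, ctx)
    m <- match(paste(pos$pos, pos$strand), paste(asg$pos, asg$strand))
    best_ss <- ifelse(is.na(m), 0L, asg$best_ss[m])
    ui_stratified(stab, pos, ss_bin_labels(best_ss, cfg$ss_split))
  })
  names(hp_ui) <- cfg$contexts
  done("hairpin_strata")

  out <- list(ndc2 = ndc2, peaks = peaks, peak_annotation = peak_ann,
              ui = ui, hairpin_ui = hp_ui, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peaks_bed(peaks, file.path(cfg$out_dir, "peaks.bed"), chrom = g$name)
    writeLines(
      c(sprintf("uracilome run manifest"),
        sprintf("genome: %s (%d bp)", g$name, g$length),
        sprintf("w_local=%d w_regional=%d k_sigma=%g doc=%s seed=%d",
                cfg$w_local, cfg$w_regional, cfg$k_sigma, cfg$doc, cfg$seed),
        sprintf("contexts: %s", paste(cfg$contexts, collapse = " ")),
        paste("completed stages:", paste(manifest, collapse = " -> "))),
      file.path(cfg$out_dir, "manifest.txt"))
  }
  out
}
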
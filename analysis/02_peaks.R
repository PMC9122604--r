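#!/usr/bin/env Rscript
# Stage 2: NDC2 and uracilation peaks.
#
# Computes the NDC2 track from the mismatch-selected depth of coverage of
# the sample and empty-vector libraries (120-bp local over 100-kb regional
# moving-average ratios, differenced), calls peaks above 5 sigma, checks
# them against the planted enrichment regions, and annotates them with
# genes and TSS distances.

suppressPackageStartupMessages(library(uracilome))

dat <- "results/data"
g <- load_genome(file.path(dat, "genome.fa"))
genes <- load_annotations(file.path(dat, "genes.gff"))
sample_tab <- read_position_table(file.path(dat, "updseq_sample.tsv"))
ev_tab <- read_position_table(file.path(dat, "updseq_ev.tsv"))
planted <- read.delim(file.path(dat, "planted_peaks.tsv"))

nd <- compute_ndc2(sample_tab$depth_selected, ev_tab$depth_selected,
                   w_local = 120L, w_regional = 100000L)
peaks <- call_peaks(nd, k_sigma = 5, merge_gap = 120L)
write_peaks_bed(peaks, "results/peaks.bed", chrom = g$name)

hit <- vapply(seq_len(nrow(planted)), function(i)
  any(peaks$start <= planted$end[i] & peaks$end >= planted$start[i]), TRUE)
message(sprintf("called %d peaks at 5 sigma (sigma = %.4g); %d/%d planted regions recovered",
                nrow(peaks), attr(peaks, "sigma"), sum(hit), nrow(planted)))

ann <- annotate_peaks(peaks, genes)
write.table(ann$peaks, "results/peak_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("peaks containing a TSS: %d; tRNA genes overlapped: %d; median |boundary-TSS| = %.0f bp",
                ann$summary$n_peaks_with_tss, ann$summary$n_trna_overlapped,
                ann$summary$median_tss_distance))

expr <- gene_ndc2_vs_expression(nd, genes)
message(sprintf("per-gene NDC2 vs expression: Spearman rho = %.3f over %d genes",
                expr$spearman_rho, nrow(expr$table)))
write.table(expr$table, "results/gene_ndc2_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
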
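#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# Generates a 500-kb circular genome with gene/tRNA annotations, a
# replication origin/terminus map, and planted ground truth: ten 200-bp
# pull-down enrichment regions (20x), a 1.6x lagging-strand-template
# deamination bias, a 4x preference for cytosines in strong hairpin loops
# (stem strength >= 15, aided by 500 planted hairpin cassettes), and a
# matched empty-vector control. Also draws a 20k-SNV tumor catalog with a
# planted 1.5x replicative bias. Everything downstream reads only the
# files written here.

suppressPackageStartupMessages(library(uracilome))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260930L

sim <- generate_genome(5e5, gc_fraction = 0.5, n_genes = 40, n_trna = 8,
                       n_planted_hairpins = 500, seed = seed)
write_genome(sim$genome, file.path(out, "genome.fa"))
write_annotations_gff(sim$genes, file.path(out, "genes.gff"),
                      seqid = sim$genome$name)
writeLines(sprintf("ori\t%d\nter\t%d", sim$map$ori, sim$map$ter),
           file.path(out, "replichore.tsv"))
write.table(sim$hairpin_truth, file.path(out, "planted_hairpins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted_peaks <- data.frame(start = seq(30001, by = 5e4, length.out = 10),
                            end = seq(30001, by = 5e4, length.out = 10) + 199L,
                            enrichment = 20)
write.table(planted_peaks, file.path(out, "planted_peaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

params <- sim_params(base_rate = 0.002, mean_depth = 100,
                     strand_bias_beta = 1.6,
                     hairpin_factor = c("ss>=15" = 4),
                     hairpin_bin_edges = 15L,
                     peak_regions = planted_peaks, seed = seed)
tabs <- simulate_updseq(sim$genome, sim$map, params)
write_position_table(tabs$sample, file.path(out, "updseq_sample.tsv"))
write_position_table(tabs$ev, file.path(out, "updseq_ev.tsv"))

muts <- simulate_mutation_catalog(
  sim$genome, sim$map, sim_params(strand_bias_beta = 1.5, seed = seed), 2e4)
write_catalog_vcf(muts, file.path(out, "tumor_catalog.vcf"))

message(sprintf("genome: %d bp, %d genes (%d tRNA), ori=%d ter=%d",
                sim$genome$length, nrow(sim$genes),
                sum(sim$genes$gene_type == "tRNA"),
                sim$map$ori, sim$map$ter))
message(sprintf("sample mean depth %.1f (EV %.1f); %d planted peaks, %d planted hairpins",
                mean(tabs$sample$depth_total), mean(tabs$ev$depth_total),
                nrow(planted_peaks), nrow(sim$hairpin_truth)))
message(sprintf("tumor catalog: %d SNVs with planted LGST bias 1.5", nrow(muts)))
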
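#!/usr/bin/env Rscript
# Stage 5: tumor-style mutation analyses on the simulated SNV catalog.
#
# Reproduces the mutation-side statistics: replicative and
# transcriptional strand bias of C:G mutations at TC and WRCY contexts
# (normalized per strand by site counts and the cohort baseline rate,
# 95% CIs from n and N), hairpin stem-strength-binned normalized rates,
# and expression-decile rates. The catalog planted a 1.5x LGST bias and
# nothing else.

suppressPackageStartupMessages(library(uracilome))

dat <- "results/data"
g <- load_genome(file.path(dat, "genome.fa"))
genes <- load_annotations(file.path(dat, "genes.gff"))
rep_cfg <- read.delim(file.path(dat, "replichore.tsv"), header = FALSE)
map <- replichore_map(rep_cfg$V2[rep_cfg$V1 == "ori"],
                      rep_cfg$V2[rep_cfg$V1 == "ter"])
muts <- load_mutation_catalog(file.path(dat, "tumor_catalog.vcf"), g = g)
message(sprintf("catalog: %d SNVs (%d non-SNV rows skipped)",
                nrow(muts), attr(muts, "n_skipped")))

rows <- list()
for (ctx in c("TC:2", "WRCY:3")) {
  rep_bias <- strand_bias_rates(muts, g, ctx, "replicative", map = map)
  tx_bias <- strand_bias_rates(muts, g, ctx, "transcriptional", genes = genes)
  message(sprintf("%-6s replicative LGST/LDST = %.3f; transcriptional Tx+/Tx- = %.3f",
                  ctx, rep_bias$ratio, tx_bias$ratio))
  for (res in list(rep_bias, tx_bias)) {
    res$rates$context <- ctx
    rows[[length(rows) + 1]] <- res$rates
  }
}
write.table(do.call(rbind, rows), "results/tumor_strand_bias.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

asg <- read.delim("results/hairpin_assignment.tsv")
hp <- hairpin_mutation_rates(muts, g, "TC:2", asg,
                             bin_edges = c(4L, 8L, 12L, 16L), map = map)
write.table(hp, "results/tumor_hairpin_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
both <- hp[hp$strand == "both", ]
message("normalized TC mutation rate by stem-strength bin (both strands):")
for (i in seq_len(nrow(both))) {
  message(sprintf("  %-12s rate = %.3f [%.3f, %.3f] (n_mut = %d, n_sites = %d)",
                  both$ss_bin[i], both$rate[i], both$ci_lo[i], both$ci_hi[i],
                  both$n_mut[i], both$n_sites[i]))
}

expr <- expression_binned_rates(muts, g, "TC:2", genes)
write.table(expr, "results/tumor_expression_deciles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("expression deciles: rate range %.3f-%.3f (planted: flat)",
                min(expr$rate, na.rm = TRUE), max(expr$rate, na.rm = TRUE)))
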
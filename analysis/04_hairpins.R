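#!/usr/bin/env Rscript
# Stage 4: hairpin landscape and hairpin-stratified UI.
#
# Scans the genome for potential stem-loop structures (loops 3-8 nt,
# perfect Watson-Crick stems up to 12 pairs, SS = 3*GC + AT), assigns
# every cytosine its best stem strength, and computes the UI in
# stem-strength bins. The simulation planted a 4x deamination preference
# for loop cytosines with SS >= 15; the empty vector has none.

suppressPackageStartupMessages(library(uracilome))

dat <- "results/data"
g <- load_genome(file.path(dat, "genome.fa"))
tab <- read_position_table(file.path(dat, "updseq_sample.tsv"))
ev <- read_position_table(file.path(dat, "updseq_ev.tsv"))
truth <- read.delim(file.path(dat, "planted_hairpins.tsv"))

calls <- scan_hairpins(g)
asg <- assign_best_hairpin(g, calls)
write.table(asg, "results/hairpin_assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
key <- paste(calls$loop_start, calls$loop_len)
recovered <- sum(paste(truth$loop_start, truth$loop_len) %in% key)
message(sprintf("%d hairpin calls; %d/%d planted cassettes recovered",
                nrow(calls), recovered, nrow(truth)))

nc <- find_context_positions(g, "NC:2")
m <- match(paste(nc$pos, nc$strand), paste(asg$pos, asg$strand))
best_ss <- ifelse(is.na(m), 0L, asg$best_ss[m])

# hairpin / non-hairpin split at SS >= 15, then a graded profile
split_ui <- ui_stratified(tab, nc, ss_bin_labels(best_ss, 15L))
ev_ui <- ui_stratified(ev, nc, ss_bin_labels(best_ss, 15L))
message(sprintf("UI(SS>=15)/UI(non-hairpin): sample %.2f, EV %.2f",
                split_ui[["ss>=15"]]$ui / split_ui[["non-hairpin"]]$ui,
                ev_ui[["ss>=15"]]$ui / ev_ui[["non-hairpin"]]$ui))

edges <- c(4L, 8L, 12L, 16L, 20L)
prof <- ui_stratified(tab, nc, ss_bin_labels(best_ss, edges))
res <- data.frame(
  ss_bin = names(prof),
  ui = vapply(prof, `[[`, 0, "ui"),
  n_positions = vapply(prof, `[[`, 0L, "n_positions"))
write.table(res, "results/ui_by_stem_strength.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("UI profile over stem-strength bins:")
for (i in seq_len(nrow(res))) {
  message(sprintf("  %-12s UI = %.3f  (n = %d)",
                  res$ss_bin[i], res$ui[i], res$n_positions[i]))
}
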
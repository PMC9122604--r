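# uracilome

Analysis of genome-wide uracilation from uracil pull-down sequencing
(UPD-seq) of bacterial genomes expressing ssDNA cytosine deaminases
(AID/APOBEC family), together with the parallel analyses of somatic SNV
catalogs from B-cell tumors. The package is aimed at researchers mapping
deaminase target preferences — sequence context, replication strand,
transcription strand, and DNA secondary structure — from per-position
coverage/mismatch data.

## What it computes

**NDC2 (normalized differential coverage).** Uracil-containing fragments
are enriched by the pull-down, so uracilation shows up as localized excess
coverage. For the sample and the empty-vector (EV) control library,

```
NDC2 = mav(sample DOC, 120 bp) / mav(sample DOC, 100 kb)
     - mav(EV DOC, 120 bp)     / mav(EV DOC, 100 kb)
```

where `mav` is a centered moving average of the depth of coverage (by
default the depth from reads carrying at least one mismatch at a C:G
reference position). The double ratio cancels library size and regional
coverage waves. *Uracilation peaks* are maximal runs of positions with
NDC2 above 5σ (σ = genome-wide standard deviation of NDC2), merged across
gaps smaller than the 120-bp smoothing window.

**Uracilation Index (UI).** For a sequence context (NC, TC, WRC, WRCY, …
with a designated target C, scanned on both strands),

```
UI = [ Σ (C→T changes at site / depth at site) / N sites ] × 10³
```

Error bars come from randomly splitting the genome's context sites into
three equal subsets and recomputing the UI in each. The UI is stratified
by replicative strand (lagging-strand template LGST vs leading-strand
template LDST, from the ori/ter replichore structure), by transcriptional
strand (coding Tx+ vs template Tx−), and by hairpin stem strength.

**Hairpin scan.** Every candidate loop of 3–8 nt is tested for a perfect
Watson–Crick stem grown outward up to 12 pairs; stem strength
SS = 3·(G:C pairs) + 1·(A:T pairs). Each cytosine in a loop gets the best
SS over the loops containing it.

**Tumor mutation rates.** From an SNV catalog, normalized C:G mutation
rates (per strand / per stem-strength bin / per expression decile,
divided by the cohort's overall per-site C:G rate) with 95% confidence
intervals computed from the mutation count n and site count N.

**Synthetic data.** A generator plants all of the above — enrichment
peaks, context weights, a LGST multiplier β, hairpin-loop factors — into
simulated position tables and catalogs so every stage can be validated
against known ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a 500-kb circular genome with 10 planted 200-bp pull-down peaks
(20×), a 1.6× LGST bias, and a 4× preference for loop cytosines with
SS ≥ 15; stages 2–5 analyze it from the written files alone:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_peaks.R
Rscript analysis/03_uracilation_index.R
Rscript analysis/04_hairpins.R
Rscript analysis/05_tumor_mutations.R
```

Output from a run:

```
called 10 peaks at 5 sigma (sigma = 5.09); 10/10 planted regions recovered
NC:2   UI = 2.898 +/- 0.012 | LGST/LDST = 1.595 (EV 1.006) | Tx+/Tx- = 0.800
TC:2   UI = 2.886 +/- 0.022 | LGST/LDST = 1.609 (EV 1.009) | Tx+/Tx- = 0.762
188968 hairpin calls; 500/500 planted cassettes recovered
UI(SS>=15)/UI(non-hairpin): sample 4.07, EV 1.10
TC:2   replicative LGST/LDST = 1.437; transcriptional Tx+/Tx- = 0.835
```

Reading this: peak calling recovered every planted enrichment region with
no false calls; the UI-based replicative strand ratio reproduces the
planted 1.6× bias (and is null, ≈1.0, in the EV control); the
hairpin/non-hairpin UI ratio reproduces the planted 4×; the tumor catalog
recovers its planted 1.5× LGST bias (1.44 ± sampling error on 20k SNVs).
The Tx+/Tx− ratios drift from 1 because a finite random gene set couples
the replicative bias into the transcriptional stratification — a real
effect of the layout, not a planted transcriptional preference. Tables
land under `results/`.

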
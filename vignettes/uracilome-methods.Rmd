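---
title: "Mapping deaminase uracilomes: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping deaminase uracilomes: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

UPD-seq tags genomic uracils and enriches uracil-containing fragments
before sequencing, so a deaminase's targets appear in two complementary
signals: *localized excess coverage* (pulled-down fragments pile up where
uracils cluster) and *C→T mismatches* in reads (uracil templates as
thymine). `uracilome` consumes per-position depth and base counts (built
from SAM alignments by `build_position_table()`, which also records the
depth from reads carrying at least one mismatch at a C:G reference base —
the `depth_selected` channel that carries the enrichment signal) and an
empty-vector (EV) control library measured the same way. The EV matters:
bacterial genomes carry background uracils from dUTP incorporation during
replication, so "signal" is always sample relative to EV.

## NDC2 and peak calling

The normalized differential coverage statistic divides a 120-bp local
moving average of depth by a 100-kb regional one, for sample and EV, and
subtracts. Both window sizes are tunable (`w_local`, `w_regional`, in
bp); the local window sets the feature scale, the regional one absorbs
slow coverage waves (replication-associated gradients, GC bias). The
double ratio makes NDC2 exactly invariant to independent global rescaling
of either library — the package tests this to 1e-9.

Choices a user should know:

* **Which depth feeds NDC2** is a flag (`doc` in `run_pipeline()`);
  the default is the mismatch-selected depth, since the filtered
  alignment is what carries uracilation enrichment. Raw total depth is
  available for sensitivity checks.
* **Even windows** are centered with `w/2` positions to the left and
  `w/2 − 1` to the right; circular genomes wrap, linear tracks truncate
  at the ends.
* **Masking, not pseudocounts**: positions where either regional average
  is zero are masked (`NA`) rather than patched, so uncovered regions can
  never fabricate signal.
* **Peaks** are runs of NDC2 above `k_sigma` (default 5) times the
  genome-wide standard deviation of unmasked NDC2, *including* peak
  regions — no iterative masking. A practical consequence: σ grows with
  the fraction of genome covered by signal, so a plateau occupying more
  than ~4% of the genome can rise above its own 5σ threshold only if it
  towers over the background. Runs separated by fewer than `merge_gap`
  positions (default = `w_local`, since features closer than the
  smoothing scale are unresolvable) are merged, wrapping across the
  origin on circular genomes.
* **Replicate peak concordance** is assessed by any-overlap matching and
  a circular rotation permutation test (`peak_overlap_test()`): the null
  preserves each set's internal clustering by rigidly rotating one set.
  This is deliberately a co-localization test only, an explicit stand-in
  for fuller interval-correlation suites; an exhaustive mode enumerates
  all rotations for exact p-values on small genomes.

## The Uracilation Index

For a context (an IUPAC pattern with a designated target C, located on
both strands with wrapping on circular genomes), the UI is the mean
per-site C→T change fraction × 10³. A minus-strand C is a plus-strand G
and its deamination reads as G→A. Only C→T/G→A changes count; other
substitutions are ignored.

One deliberate deviation from the plain formula: sites with zero depth
are excluded from both numerator and denominator by default
(`denominator = "measured"`). Dividing by *all* genomic occurrences
(`"genomic"`, also available) makes the UI shrink with falling coverage,
which conflates enzymology with sequencing depth. At the simulated depths
used for validation (≥100×, Poisson) the two differ negligibly because
essentially every site is measured.

Error bars follow the three-subset scheme: context sites are randomly
shuffled (seeded) and dealt round-robin into `k = 3` near-equal subsets;
the spread of the per-subset UIs is the reported sd. On a homogeneous
genome the subsets automatically balance composition (GC, hairpin,
strand); the package asserts that the subset mean stays within 2% of the
full-set UI at 10⁵ sites.

Stratification is by label: replicative strand, transcriptional strand,
stem-strength bin, or arbitrary user labels. Positions inside overlapping
genes on opposite strands are labeled ambiguous and excluded from
transcriptional statistics — the alternative double-counts. Empty strata
are reported with `ui = NA`, never silently dropped.

### Strand conventions

The right replichore is the arc `[ori, ter)` in increasing coordinates
(half-open arcs make the two replichores a deterministic partition of the
circle; a position exactly at `ori` belongs to the arc starting there).
There the fork moves toward increasing coordinates and the plus strand is
the lagging-strand template (LGST); roles swap on the left replichore and
between strands. The LGST/plus-strand sign convention is fixed and
documented here rather than inferred — only the *split* is physically
forced, and all downstream ratios simply invert if the convention is
flipped (an equivariance the tests check). Tx+ is the coding
(non-transcribed) strand: a base is Tx+ when its strand equals the
containing gene's strand.

## Hairpin scanning

The scanner enumerates every loop placement of 3–8 nt and grows a perfect
Watson–Crick stem outward up to 12 pairs, stopping at the first
non-complementary pair; stem strength is `3·GC + 1·AT`, so 12 pairs cap
SS at 36, comfortably above the ≥20 regime of interest. No G:T wobble, no
bulges, no thermodynamics — the scoring sits behind one function and can
be swapped, but the strict-pairing convention is this package's own
documented assumption. A loop-boundary C belongs to the loop, not the
stem. Loop positions are counted 5′→3′ on the strand where the base reads
as C (a loop G is a minus-strand loop C at mirrored position). Each C's
`best_ss` is the maximum over containing loops (ties: shorter loop, then
leftmost call — arbitrary but deterministic). The E. coli-style analyses
split hairpin/non-hairpin at SS ≥ 15; the tumor analyses use SS ≥ 12 with
loop sizes already restricted to 3–8 by the scan. The scanner is held
equal, call for call, to a brute-force per-placement enumeration on 200
random 2-kb sequences, and the call set must map onto itself under
reverse complement.

## Tumor mutation rates

Catalog SNVs at context cytosines are counted per stratum and divided by
the stratum's site count, then by the cohort baseline (total C:G SNVs /
total C:G sites in the analyzed regions — the "overall mutation rate of
the cohort"). Because the baseline is shared, strand *ratios* are
insensitive to it; each strand's normalized rate is still reported so
strata can be compared across cohorts. Replicative-bias counting can be
restricted to supplied early-replicating intervals, where
replication-direction calls are most reliable. Expression deciles rank
genes by expression with ties broken by gene id (stable, seedless).

The 95% CI on a rate n/N uses the Poisson-count normal approximation
`n/N ± 1.96·√n/N` floored at zero — the natural reading of an interval
"estimated from n and N". It degenerates to a point at `n = 0`, so the
exact Poisson (gamma-quantile) interval, whose zero-count upper bound is
3.689/N, and the Wilson score interval are selectable alternatives.
Calibration is checked by simulation: across 200 seeded null catalogs the
CIs cover the normalized rate 1 in well over 90% of strata.

## The synthetic-data generator

`generate_genome()` draws an i.i.d. circular sequence at a target GC
fraction (0.5 by default), places non-overlapping genes and tRNAs with
log-normal expression, puts ori at position 1 and ter antipodally, and
optionally plants hairpin cassettes — a GC stem around a fixed `TTCA`
loop, flanked by deliberately non-pairing bases so the scanned SS equals
the planted SS exactly.

`simulate_updseq()` composes the per-cytosine deamination probability
multiplicatively: base rate × context weight × β on LGST × stem-strength
bin factor × peak enrichment, clipped to [0, 1] (clip events counted).
Depth is Poisson (mean 100 by default); inside planted peak regions the
*sample* depth is additionally multiplied by the enrichment — pull-down
peaks are modeled as both excess coverage and excess deamination, which
is what the assay produces. C→T read counts are binomial. The
mismatch-read selection channel is modeled at the table level: a read is
retained with probability `1 − exp(−read_len · p̄_local)` where `p̄_local`
is the local mean change probability over the read span (default read
length 100 nt). Sequencing error (default 1e-4 per base after quality
filtering, split equally over the three substitutions) enters all
channels but only the C→T/G→A channel reaches the UI, mirroring the
analysis's selectivity. The EV library gets uniform background
(`ev_rate`, defaulting to the base rate — dUTP background exists without
any deaminase) and no multipliers.

What the generator does *not* emulate, and therefore what passing tests
do not certify on real data: alignment artifacts and mapping bias,
GC-dependent coverage waves, overdispersed (non-Poisson) depth,
strand-asymmetric library chemistry, clustered/processive deamination,
and real genome composition (repeats, skews, operon structure). The
Poisson choice is the simplest adequate depth model; swapping in a
negative binomial would only widen the validation bands.

## Validation scales and determinism

All stochastic steps run from explicit integer seeds; identical
parameters give byte-identical tables, catalogs and subset partitions.
The standing validation suite uses these problem sizes, chosen as the
smallest at which the planted effects are estimated with a few-percent
standard error: 1-Mb genome for peak recovery (10 planted 200-bp regions,
20×, depth 100, base rate 0.002 — ≥9/10 recovered, ≤2 false calls);
500-kb genome for WRCY UI calibration (uniform p = 0.005, depth 200 —
UI within 5% of p·10³); 300-kb for strand-bias recovery (β = 1.6 → ratio
in [1.5, 1.7]; β = 1 → [0.95, 1.05]); 1-Mb with 1000 planted cassettes
for hairpin preference (factor 4 → ratio in [3.4, 4.6]; EV in
[0.9, 1.1]); 100-kb genomes with 2 000–20 000 SNVs for the tumor-side
calibration and recovery checks. `scripts/acceptance.R` re-runs all of
these from a single command-line seed and writes the measured values as
JSON.

## Known limitations

* Peak calling assumes a single contig; multi-replicon genomes are
  processed per contig.
* The rotation overlap test conditions on both peak sets' internal
  structure but knows nothing of covariates (GC, gene density); a
  significant overlap is co-localization, not mechanism.
* `ct_change_fraction()` uses total depth at the position, not
  strand-resolved depth; at the simulated and typical real depths the
  difference is negligible, but heavily strand-skewed coverage would
  bias per-strand UIs.
* The hairpin model scores only contiguous perfect stems; structures
  with bulges or wobble pairs are invisible to it.
* Cohort assembly (signature deconvolution, sample filtering) is out of
  scope: catalogs are taken as given, and a provenance note on the
  catalog object is the only record of how they were selected.
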
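---
title: "divscan: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divscan: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

divscan implements the computational chain of a population-genomic
selection scan for a small resequencing cohort — 18 diploid females plus
one haploid male, the natural design for a haplodiploid bee — together
with a regulatory-motif scoring and enrichment pipeline. This vignette
is the package's own account of the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the design was
genuinely open.

## The synthetic cohort generator

Downstream statistics depend on the data only through genotypes, site
annotations, coverage, and sequence composition, so the generator
produces exactly those, not reads.

**Variants.** Let `C = 2·n_diploid + n_haploid` be the number of
sampled chromosomes (37 by default). Segregating sites are placed by a
Poisson process with per-bp rate `θ·a₁(C)`, where
`a₁(C) = Σ_{i=1}^{C−1} 1/i`. Each site draws a derived-allele count `i`
with probability ∝ `1/i` (the neutral infinite-sites spectrum), assigns
the `i` derived copies to chromosomes uniformly, and pairs chromosomes
into diploid genotypes (random union of gametes). Two consequences are
exact, not asymptotic:

* the expected per-site heterozygosity under the 1/i spectrum is
  `Σ_i (1/i)/a₁ · 2i(C−i)/(C(C−1)) = 1/a₁`, so the expected windowed π
  equals `θ` (default 0.0015/bp, the diversity scale of a low-diversity
  solitary bee population);
* the expected value of the Tajima's D numerator `π̂ − S/a₁` is zero on
  neutral sequence, so neutral calibration of D tests the estimator, not
  a tuned generator.

**Sweeps.** Inside a sweep region the site density is multiplied by
`diversity_reduction` and counts are drawn with probability ∝
`1/i^skew`, skewing the spectrum toward rare alleles. This reproduces
the two signatures the scan targets — depressed π and negative D —
without a coalescent simulation with selection, which desk-scale tests
do not need. `sweep_recovery_config()` plants sweeps over a fraction of
the deterministic gene grid, extending each swept gene by a 2 kb
hitchhiking flank: real sweeps extend well beyond the selected locus,
and a flank narrower than the window grid would leave a gene's outer
windows mostly neutral even though the ≥ 1 bp intersection rule pulls
them into the gene's mean. The default planted fraction is 5%, matching
the scan's 5% detection tail — the standard sizing for a recovery
experiment; with a larger planted fraction than the call band,
sensitivity is bounded above by `tail/fraction` by arithmetic alone.

**Cohort layout.** Genes sit on a deterministic grid (about one gene
per 5 kb by default, compact-insect-genome spacing) with random strands;
the last 6 kb of each scaffold stays gene-free so the non-genic regions
the motif background is trained on exist under the default layout. The
haploid male carries one chromosome but is written as a homozygous
diploid genotype, as a ploidy-2 caller emits it; a configurable fraction
of sites is written heterozygous in the male to exercise the
haploid-consistency filter. Site annotations (QD, FS, MQ,
ReadPosRankSum) are drawn from labelled passing/failing distributions
rather than computed from reads — the filter module tests predicates,
not caller internals. Depth is Poisson around 30×; coverage-dip regions
use a Poisson mean of 2, putting the fraction of sites with ≥ 5 reads
below 0.06.

**What is not emulated.** Read-level error, mapping artifacts, indels,
linkage disequilibrium (sites are unlinked), recombination maps, and
demographic history. Passing tests therefore demonstrates correctness of
the estimators and the recovery behaviour of the scans under their own
model assumptions — not robustness to misspecification on real data.

## The filter cascade

Stage order: site hard filters → haploid consistency → genotype masking
→ cohort filters. Conventions, each chosen to match the de facto
semantics of the tools practitioners use:

* all removals are strict inequalities (`QD < 2` removes; `QD = 2`
  survives), and a missing INFO annotation passes its predicate, as in
  GATK VariantFiltration; the event is counted in the report;
* `max_missing_count` counts missing genotypes, not alleles;
* MAF is computed from post-masking called dosages, and the cohort
  statistics (mean DP, missingness, MAF) run over the diploid cohort
  only — the haploid male is a consistency probe, not a cohort member;
* the cohort filters are applied in one pass; with all three given
  together, one-pass and sequential application select the same sites;
* presets `round1` (no missing genotypes), `round2_gatk` (≤ 8 missing)
  and `round2_final` (the stringent set) reproduce the two calling
  rounds as configurations of a single cascade.

A 20-record hand-evaluated fixture (`filter_demo_records()`) pins each
rule including every boundary case; the cascade is idempotent and is
property-tested against a brute-force per-record evaluator.

## Windowed statistics

Windows are tiled, non-overlapping, anchored at scaffold position 0;
trailing partial windows are kept and flagged. π is reported both per
window length and with the coverage-corrected denominator — the *count*
of sites with depth ≥ 5. The coverage track stores a per-window
fraction, but dividing by the fraction itself would not yield a per-bp
rate, so the count (fraction × window length) is the denominator; both
uncorrected and corrected columns are always written.

For Tajima's D with missing genotypes, each site contributes its
called-allele count; the `n` used for the constants is the per-window
median of those counts — a fixed cohort-wide `n` would be wrong under
per-site missingness, and the median is stable against a few low-call
sites. `D` is undefined (serialized as `nan`, never 0) when `S = 0`.
Two degenerate boundaries are worth knowing: at `n = 2` and `n = 3` the
variance constants `e₁, e₂` are exactly zero (so D is 0/0); they are
strictly positive from `n = 4`.

The unadjusted Ajk relatedness uses in-sample allele frequencies, as the
standard implementation does. For unrelated pairs its finite-sample
expectation is ≈ `−2/(2n−1)` — about −0.057 at n = 18 — because
centring on the in-sample frequency introduces a −1/n-scale covariance.
The package reports the estimator as defined; the calibration tests at
n = 100 (bias −0.01) confirm the implementation, and the n = 18 value
observed on synthetic data (−0.076 to −0.039 across pairs) has the same
narrow, slightly negative signature one sees in real small unrelated
cohorts.

## The selection scan

Genes map to windows by ≥ 1 bp interval overlap (half-open coordinates
throughout); π and D are unweighted means over a gene's windows, with
undefined windows dropped from the affected mean only, and genes whose
windows are all undefined excluded and counted. Percentiles are the
standard weak-inequality empirical CDF (`stats::ecdf`). The joint score
is the product of the π and D percentiles, re-percentiled over genes
("recalculated" as: read each gene's percentile from the ECDF of the
products — on distinct values this is identical to re-ranking); genes
with joint percentile ≤ 0.05 are selected, ties all-in. The scan is
rank-based, hence invariant to monotone transforms of either statistic,
and permutation-equivariant in gene labels.

The recovery experiment scans the generator's call set directly rather
than the MAF-filtered one: a MAF ≥ 0.05 filter removes precisely the
rare variants that carry the sweep signature and empties many sweep
windows entirely (S = 0 → D undefined). The filter's effect is real and
is shown in the analysis workflow (mean D shifts from ≈ 0 to ≈ +0.6 on
the same cohort); it is a property of the filter, exercised by its own
tests, not part of the scan's definition. At the default effect sizes
(reduction 0.2, skew 2, θ = 0.0015, 18 diploids, 1 kb windows) the
matched 5% design recovers planted sweeps with sensitivity and precision
both ≈ 0.8 — the intrinsic power of the joint-percentile statistic at
this signal-to-noise, dominated by the variance of window-mean D.

## The motif pipeline

**Window scoring.** Windows are 500 bp with 250 bp step; externally
supplied mask intervals (e.g. tandem repeats) are hard-masked; windows
more than half masked are excluded. Each PWM is scored with a two-state
(background/motif) HMM partition function: at each position the chain
emits one background base with probability `1 − t` or enters the motif
state with probability `t` (split evenly across strands) and emits a
full PWM instance. The score is `log f(L) − Σ log b(sᵢ)`; the
implementation runs the forward recursion on probability *ratios*
(`g(i) = (1−t)g(i−1) + (t/2)(Rf+Rr)g(i−w)`), which cancels the
background product and avoids underflow in 500 bp windows without
log-space arithmetic; a rescaling guard handles pathological
accumulations. `t = 0.0025` is fixed; at `t = 0` every score is exactly
0, a limit the tests pin. Masked bases emit ratio 1 in the background
state and void any motif placement covering them. The recursion is
verified against an independent placement-enumeration oracle to 1e-9.
The background is mononucleotide, estimated from non-genic regions
≥ 5 kb on scaffolds ≥ 22 kb with a 0.001 frequency floor; a dinucleotide
background and EM re-estimation of `t` are deliberately out of scope.
PWMs get a 0.01 per-cell pseudocount so no placement has probability
zero.

**Normalization.** Global rank normalization maps descending scores to
`(r−1)/(N−1)` (0 best, 1 worst, mean ranks for ties). The GC-binned
variant sorts windows by GC, splits them into 20 equal-count bins (the
remainder spread one-per-bin over the first bins — with 41 windows the
first bin has 3) and rank-normalizes within bins; equal counts rather
than equal GC spans keep the within-bin rank scale comparable. A
constructed test (scores made a pure function of GC) shows the rank
pipeline drags the selected genes' GC more than 0.1 from the mean while
the GC-binned pipeline stays within 0.02.

**Regions and gene scores.** Five strand-oriented region definitions
(5Kup2Kdown, 5Kup, 1Kup, NearStartSite by TSS bisector over window
midpoints with ties shared, GeneTerr between non-overlapping neighbour
boundaries extended to ≥ 5 kb upstream), all clipped to scaffold bounds.
For minus-strand genes the TSS is the half-open feature end, so "1 kb
upstream" is `[TSS, TSS+1000)` in genome coordinates. `Ngm` is the
minimum normalized score among the `Wg` windows overlapping the region
(0 is best on both scales), and `Pgm = 1 − (1 − Ngm)^Wg` — a
Šidák-style correction that prevents genes with large regulatory
territories from winning by window count alone. Target sets order genes
by ascending Pgm, ties by gene id; 223 motifs × 2 normalizations × 2
regions (1Kup, GeneTerr) × 2 sizes (100, 800) gives 1,784 sets.

**Enrichment.** One upper-tail hypergeometric (one-sided Fisher) test
per target set, `P(X ≥ k)`; Benjamini–Hochberg across the whole battery
jointly (per-motif correction would change the multiplicity `m`);
significance at adjusted-P < 6e-4. The universe is the set of genes
scored for the relevant motif/region/normalization — the domain the
target sets were built from; using all annotated genes would mix in
genes that never could have entered a set. The BH step-up transform is
not idempotent (re-applying multiplies by `m/j` again), so the tests
assert single-pass behaviour, monotonicity and agreement with a
hand-written step-up oracle. The odds ratio is reported with a 0.5
Haldane correction for zero cells; p-values are always exact.

## Problem sizes and determinism

The default synthetic cohort is a 2 Mb genome on 4 scaffolds with 400
genes — large enough for ≥ 500 analyzable 1 kb windows, ≥ 10,000
polymorphic sites for relatedness, and stable percentile resolution for
a 400-gene scan, while a full pipeline run stays in tens of seconds.
Recovery experiments use 5 seeds; the 223-motif battery runs on a
200 kb genome since set cardinality does not depend on genome size.
Every generator stage derives its own sub-seed from `cfg$seed`, so each
stage is independently reproducible and identical configurations give
byte-identical FASTA/VCF/GFF3/BED outputs.

## Known limitations

* Sites are unlinked; there is no LD structure, so window statistics are
  slightly less variable than on real data at equal S.
* The sweep model is a density/SFS caricature; it creates the scan's
  target signature but no hitchhiking haplotype structure.
* The Ajk estimator's −2/(2n−1) finite-sample offset at n = 18 is
  reported as-is, matching the field tool, not re-centred.
* The motif scorer omits the dinucleotide background and transition
  re-estimation of the original cis-regulatory scanner; scores are
  comparable within this implementation, not across tools.
* Multiallelic records are carried through I/O and the biallelic filter
  but all diversity statistics assume biallelic sites.
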
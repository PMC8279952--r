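---
title: "dyadkin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dyadkin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkin)
```

dyadkin quantifies de novo DNA-methylation activity of Dnmt1 in
methylation-depleted mouse ESC rescue systems. This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
generators do and do not emulate, and the design choices made where the
field offers no single convention.

## The dyad inheritance model

A CpG dyad is the pair of complementary-strand cytosines at one CpG; its
state is one of UU (unmethylated), MU/UM (hemimethylated on the plus/minus
strand) or MM (fully methylated). Hairpin-bisulfite sequencing covalently
links the two strands of a molecule, so both strands are read from one
amplicon and the dyad state is observed directly (`classify_dyads`).

Semiconservative replication halves each dyad: a daughter keeps one
parental strand (either, with probability 1/2) and synthesizes a nascent
strand. Per division, in order:

1. an existing methyl mark on the inherited strand persists with
   probability `1 - lam` (loss rate `lam`, default 0);
2. the nascent cytosine is methylated with probability `mu`
   (**maintenance efficiency**) if the post-loss template cytosine is
   methylated, else with probability `delta_n` (**nascent-strand de novo
   efficiency**);
3. an unmethylated template cytosine gains methylation with probability
   `delta_p` (parental-strand de novo, default 0), independently of the
   nascent outcome.

The ordering matters only when `delta_p > 0`: the nascent strand reads the
post-loss, pre-gain template state. This makes the per-strand methylation
marginal `f` obey

```
f' = [ f (1 - lam) (1 + mu) + (1 - f (1 - lam)) (delta_p + delta_n) ] / 2
```

which with `delta_p = lam = 0` reduces to
`f' = (f (1 + mu) + (1 - f) delta_n) / 2` and has the fixed point

```
f* = delta_n / (1 - mu + delta_n)
```

(`stationary_marginal`). High maintenance alone (`mu` near 1,
`delta_n = 0`) preserves existing methylation but can never create it; a
small `delta_n` with high `mu` yields high stable levels — the signature
of the focal IAP gains this package is built to quantify. The corner
`mu = 1, delta_n = 0` conserves every marginal and has no unique fixed
point; `stationary_marginal` reports this instead of iterating forever.

Bisulfite errors act per strand: an unmethylated cytosine is read as
methylated with probability `e` (conversion failure) and a methylated one
as unmethylated with probability `c` (inappropriate conversion). The 4x4
observation matrix is the per-strand product (`observation_matrix`).
Defaults are `e = c = 0.005`, typical of modern bisulfite protocols; when
non-CpG conversion context is available the rates should be estimated from
it instead and passed explicitly.

### Fitting

`dyad_loglik` propagates a hidden dyad distribution from `p0` through
`divisions_since_previous` transitions per timepoint and scores observed
dyad counts as multinomial draws from the error-convolved state.
`fit_kinetics` maximizes this over bounded parameters (logit-scale
L-BFGS-B, multi-start, seeded); `p0` is fixed to the first timepoint's
observed frequencies by default. With a single timepoint `mu` and
`delta_n` are not jointly identifiable (any mixture reproducing the
observed marginal fits equally well) and the fit refuses unless one is
constrained.

**Divisions per passage.** The rescue time course samples passages P1, P5,
P15, P25, not divisions. We default to `g = 6` divisions per passage
(mouse ESCs divide roughly twice a day and are split on a ~3-day cycle);
`g` multiplies time, so `mu` and `delta_n` estimates shift with it —
sensitivity runs over `g` in {4, 6, 8} are recommended and cheap. All
package-level checks use `g = 6`.

At 50,000 dyads per timepoint and three timepoints (baseline, P1, P5),
parameter-recovery simulations return `mu` and `delta_n` within ±0.03 of
truth in over 90% of seeds (the test suite asserts this across 20 seeds).

### log2 fold changes

`dyad_log2fc` compares per-state frequencies against a reference with a
frequency-scale pseudocount, default `1/min(total)` — small enough not to
bias well-covered states, large enough to keep empty states finite. No
convention exists for this pseudocount; it is exposed.

## DMR calling and matched control regions

`call_dmrs` is a window-scan caller for focal gains between a near-zero
baseline and a rescue methylome:

- sliding windows of 5 consecutive co-covered CpGs (coverage >= 5 in both
  samples), stepping one CpG;
- per window, a two-proportion z-test on pooled counts, Benjamini-Hochberg
  corrected across all windows (q < 0.05);
- significant gain windows merged when separated by <= 250 bp;
- each merged region trimmed to the outermost CpG whose own gain reaches
  `min_delta` (windows straddling a focal gain drag flanking CpGs into the
  merged span; trimming removes that overhang);
- regions kept with >= 10 co-covered CpGs and unweighted mean beta gain
  >= 0.1.

These defaults are this package's own; every one is exposed in
`dmr_params`. The caller is deliberately one-sided (gains), matching its
purpose of detecting de novo activity on a depleted background; swap the
arguments to hunt losses.

**Control regions.** `generate_control_regions` draws, per DMR, 1000
regions of identical length uniformly over the non-gap genome, sampled
with replacement (collision-free placement is impossible at 1000x on small
genomes). Gap exclusion applies to CR placement only — DMR calling is
already protected by its coverage filters. Enrichment over an annotation
class compares per-region overlap fractions (base pairs of the region
covered by the merged class features, divided by region length) between
DMRs and CRs with a one-sided rank-sum test.

**Rank-sum details.** `enrichment_test` uses midranks for ties. Overlap
fractions are heavily tied (many exact 0s and 1s), and classical
implementations fall back to a normal approximation under ties, which is
unreliable at small n; we therefore enumerate the exact permutation
distribution of the midrank statistic whenever the number of group
assignments is at most 2e5, and use the tie-corrected normal approximation
with continuity correction otherwise. Zero-variance input degenerates to
p = 1. The common-language effect size `U / (n1 n2)` is reported alongside.

## Long-read cross-validation

Long reads map uniquely across repeats and carry methylation without
bisulfite conversion, so they validate short-read DMRs and expose
cell-line deletions that would masquerade as methylation differences.

- `detect_deletions` calls maximal intervals where at least 5 reads have
  an alignment gap covering the whole interval and no read has aligned
  sequence inside. Both thresholds are ours (the support default guards
  against chimeric alignments) and are exposed.
- `mask_cpgs` removes CpGs inside deletions (half-open: a CpG exactly at a
  deletion start is inside).
- `nanopore_region_methylation` averages per-CpG call fractions over a
  region and is undefined below 10 covered CpGs — too few CpGs make a
  region mean meaningless in repeat sequence.
- `high_confidence_filter` excludes DMRs whose long-read methylation
  difference (rescue - baseline) is below 0.05; a difference of exactly
  0.05 is retained. DMRs without defined long-read means are retained with
  a flag by default ("if covered" semantics); strict mode drops them. The
  three output sets always partition the input exactly.
- `coverage_normalization` reports per-DMR mean aligned depth divided by
  the mean depth over that DMR's own CRs; ratios near 1 indicate no
  mapping bias against the DMRs.

Per-CpG long-read betas use hard M/U calls; probabilistic call weights
(log-likelihood-ratio thresholding) are out of scope.

## Interaction proteomics

Label-free co-IP intensities are log2-transformed; missingness is
missing-not-at-random (proteins near the detection limit drop out).
`impute_downshift` draws missing values per sample column from
`Normal(mean - 1.8 sd, (0.3 sd)^2)` — the widely used down-shifted
imputation, with the width and shift exposed. Columns with fewer than 3
observed values fall back to global moments, flagged.

`two_sample_test` is an equal-variance t by default (Welch behind a flag).
`permutation_fdr` computes the SAM-style moderated statistic
`d = diff / (se + s0)` with `s0 = 0.1` by default, permutes group labels
(the observed partition and its mirror are excluded — they reproduce the
observed statistics and carry no null information; remaining distinct
assignments are enumerated exactly when few, e.g. 18 for a 3v3 design),
and selects the lowest |d| cutoff whose estimated FDR stays within the
target. The estimate uses an add-one correction (the observed labeling
counts as one more permutation), so it is never exactly zero; with 18
permutations this makes a single discovery require an estimate of 1/19,
which keeps pure-null matrices almost always empty of calls while leaving
strong spike-ins (4 log2 units) essentially always detected. With no
informative permutation at all the procedure falls back to Bonferroni on
the t-test p-values, flagged. `s0` and the permutation count are not
standardized anywhere; both are exposed.

## Synthetic data: what it does and does not emulate

`build_toy_genome` tiles one ~3 Mb contig with labelled features —
24 IAPEz_int-like elements of 5–7 kb flanked by LTRs, plus ERV1, LINE,
SINE, CpG-island, gene and intergenic segments and two CpG-free assembly
gaps — with class-specific CpG densities (CpG islands 8x denser than
intergenic). `simulate_wgbs` draws Poisson(30) coverage per CpG and
binomial methylated counts at
`p_obs = p_true (1 - c) + (1 - p_true) e`. `simulate_passage_series` uses
the dyad model itself as the single source of truth: hairpin tables are
multinomial draws from the error-convolved dyad distribution and WGBS
tables are binomial draws at its per-strand marginal, so downstream
consistency between the two data types is exact by construction.
`simulate_long_reads` draws lognormal read lengths (median 25 kb) and
makes aligned blocks jump over injected deletions, which are specified
explicitly so tests have exact ground truth. `simulate_lfq` spikes
interactors into a Gaussian log2 abundance background with logistic
MNAR dropout.

Not emulated: sequence-level reads (no FASTQ), alignment artifacts,
coverage overdispersion beyond Poisson, PCR duplicates, chromosome-scale
genome structure, basecaller error profiles, and correlated protein
abundances. Passing tests on this synthetic data therefore demonstrate
the correctness of the statistics and bookkeeping, not robustness to
real-data artifacts such as mapping bias — which is exactly why the
long-read cross-validation stage exists.

Problem sizes in the test suite and acceptance script (one ~3 Mb contig,
~20,000 CpGs, 50,000 dyads per timepoint, 1000-protein LFQ matrices,
2,573 input regions for the control-region cardinality check) were chosen
as the smallest scales at which every statistical property under test is
comfortably identified.

## Conventions and degenerate inputs

- Internal coordinates are uniformly 0-based half-open; Bismark coverage
  files are converted from 1-based inclusive on read/write, BED is
  0-based half-open. CpGs are keyed by the plus-strand C.
- Contig name matching is exact; no silent "chr" aliasing.
- Parsers reject malformed records with the line number; unsorted
  methylome input is sorted on load with a message, never silently.
- Region means are unweighted means of per-CpG betas (a pooled-count mode
  exists behind a flag); whether published region means are
  coverage-weighted is generally unstated, so both are available.
- Windows/regions with no qualifying CpGs are undefined (`NA`) and
  excluded from summary denominators, with the exclusion count reported.
- Gain/loss classification uses strict inequality (`delta > threshold`)
  symmetrically for both directions; published phrasing mixes ">" and
  ">=", and the comparator sits in one documented place.
- Fixed-point iteration tolerance is 1e-12 on the dyad distribution;
  optimizer bounds are ±12 on the logit scale; the likelihood returns
  -Inf (never NaN) for impossible observations under zero error rates.

## Known limitations

- The DMR caller assumes a depleted baseline and focal gains; it is not a
  general two-condition segmentation method.
- The dyad model is per locus class, not per CpG position; within-class
  heterogeneity in efficiency is averaged.
- Deletion detection handles simple deletions only, not general
  structural variation.
- `p0` fixed to observed first-timepoint frequencies ignores measurement
  error in `p0` itself; with 50,000 dyads this is negligible, at low
  depth prefer `p0_free = TRUE`.
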
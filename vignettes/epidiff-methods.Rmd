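---
title: "Methods: differential modification calling, metagene analysis and the synthetic world"
author: "epidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential modification calling, metagene analysis and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidiff)
options(epidiff.quiet = TRUE)
```

# Scope and model

`epidiff` analyses per-position RNA-modification evidence from nanopore
direct RNA sequencing in a two-condition, replicated design. The observable
at one transcript position in one sample is a pair (coverage, modified-read
count) produced upstream by a per-read caller; this package deliberately
treats that caller as a black box and begins at its text-track output.

## The differential caller

Replicates are **pooled**: per position, per condition, coverages and
modified counts are summed into one 2x2 table. Upstream trackers report
counts per sample but give no per-replicate error model; pooling treats
reads, not replicates, as the unit of evidence. This is a design choice with
a known cost — biological replicate variability is absorbed rather than
modelled — and a variance-aware per-replicate test is explicitly out of
scope. The pooled table is tested with a **two-sided Fisher exact test**
conditioning on all margins, summing hypergeometric probabilities no larger
than the observed table's (probability-mass ordering). Ties are included
within a relative tolerance of 1e-7, the common convention; the suite checks
the implementation exhaustively against an independent enumeration oracle
for every table with margins up to 25 and spot-checks `stats::fisher.test`
on random large tables.

The depth filter of at least 50 pooled reads is applied **per condition**
(both sides must qualify). A pooled-only reading of the same threshold would
admit tables with one empty side, where the Fisher test is powerless and the
fold change undefined in all but name; requiring both sides is stricter and
self-consistent.

Effect size is a pseudocounted log2 ratio of modified fractions, with the
Haldane-style constant 0.5 added to each modified count and 1.0 to each
depth. This keeps the statistic finite at 0% and 100% modification and makes
it exactly antisymmetric under swapping conditions (a property test). A
position is `over`/`under` when `p < alpha` (default 0.05) **and**
`|log2FC| > 0.5`. Raw p-values replicate the gating convention of the DRS
studies this pipeline targets; Benjamini–Hochberg q-values are always
computed and can drive the gate via `adjust = "BH"`. Because the lfc gate is
applied on top of the alpha gate, the realised type-I error of the full
caller sits below alpha (measured on 10,000 simulated null positions in the
acceptance suite).

## Coordinates and regions

Internally every position is a 0-based offset; every file and report uses
1-based inclusive positions. An annotation is a CDS interval on the
transcript, giving 5'UTR = `[0, cds_start)`, CDS = `[cds_start, cds_end)`,
3'UTR = `[cds_end, length)`; membership is start-inclusive, end-exclusive,
so a site exactly at `cds_start` is CDS and one at `cds_end` is 3'UTR.
Tombo-style fraction tracks are converted to integer modified counts by
`round(fraction * coverage)` with ties away from zero — fractions must
become counts for an exact test, the choice is logged, and re-deriving the
fraction from the count is accurate to half a read (an I/O invariant test).

## Metagene profiles

RRACH sites (R R **A** C H) are matched degenerately, overlapping matches
included, and validated against a regex-lookahead oracle. Profiles are
**per-site densities**, not coverage-weighted: each site contributes once at
`position/(length-1)` on the full axis, or at
`r + (position - region_start)/region_length` on the three-region axis.
Densities are area-normalised per condition so conditions with different
site totals are comparable; bin counts (30 full-length, 20 per region) are
configurable and of no inferential consequence. In the orchestrated
pipeline, a RRACH site counts as methylated in a condition when its pooled
modified fraction there reaches `min_mod_frac` (default 0.1) after the depth
filter — a pragmatic presence call, made explicit as a parameter because
upstream site callers differ in how they binarise sites.

## Poly(A) and integration

Only nanopolish-style `PASS` records enter summaries by default; other tags
mark segmentation problems and are counted, not used. Per-transcript and
per-condition means and medians are both emitted (published "mean tail
lengths" are ambiguous between read-level and transcript-level averaging, so
both levels are reported). Abundance enters all correlations as
`log2(CPM + 1)` averaged within condition — raw CPM correlations are
dominated by a handful of abundant transcripts — and protein abundance on
the log2 scale likewise. Correlation p-values use the exact t transform on
n-2 degrees of freedom. Differential-expression and proteomics significance
sets are **consumed as inputs** (the respective models are out of scope);
the overlap report gives exclusive pairwise counts, the triple count, and
their sum, with inclusion–exclusion verified by property tests.

# The synthetic world

The generator emulates the statistical structure such a study reports, at
desk scale, with defaults chosen once:

- 2 conditions x 3 replicates; 1000 transcripts of 500–3000 nt with 15%/60%/25%
  5'UTR/CDS/3'UTR splits.
- Per-site, per-sample coverage ~ NB(mean 30, size 10), so pooled
  per-condition depth sits near 90 and the 50-read filter bites realistically.
- Each transcript carries a latent modification propensity `f_i`,
  logit-normal around `f0 = 0.05` (spread 1.0). All of its sites share `f_i`
  in both conditions except **planted** sites (default 100, one per chosen
  transcript), which are implanted RRACH 5-mers drawn at `f1 = 0.4` in the
  treatment condition and placed in the 3'UTR with probability 0.8 —
  the treatment-biased 3'UTR deposition the pipeline must detect. Two
  constitutive RRACH sites per transcript plus five generic sites complete
  the modification landscape. A flat `f0` alone cannot carry cross-transcript
  correlation targets, hence the per-transcript propensity; planted sites
  use exactly `f1` so their pooled treatment fraction is binomial around it.
- Poly(A) tails are truncated-Gamma (shape 6) on [40, 250] nt with the scale
  solved numerically so the truncated mean is 91 nt; each transcript's reads
  are shifted by a coupling term (sd 10 nt) tied to its propensity.
- Couplings (abundance r = -0.4, poly(A) r = +0.2, protein r = +0.18 in
  treatment only) use an **exact-correlation construction**: the Gaussian
  noise is orthogonalised against the standardized propensity, so the latent
  sample correlation equals the target for any seed, and the control-side
  protein latent is orthogonalised to make "no correlation in control" hold
  robustly rather than on average. The poly(A) coupling inflates its latent
  correlation by an analytic attenuation factor computed from the
  truncated-Gamma read variance at run time, compensating for read-sampling
  noise in per-transcript means. These are simulation-design choices fixed
  before any acceptance measurement.

What a green test does **not** establish: the generator draws coverage
independently of abundance (real DRS coverage scales with expression, which
couples the depth filter to the abundance axis), sequences are i.i.d.
letters with no composition structure beyond implanted motifs, there is no
isoform, splicing or sequencing-error structure, and replicate effects are
absent — exactly the variability the pooled Fisher test cannot see. Green
acceptance means the machinery is correct on the stated world, not that the
pooled test is optimal on real data.

# Numerical choices and degenerate inputs

- Reported grand means round half **away** from zero at two decimals
  (`round_away`); IEEE half-to-even would disagree with printed summary
  tables at exact halves.
- Fisher p-values are clamped into (0, 1]; single-table supports return 1.
- Empty inputs: the scan refuses an empty modcall table naming the stage;
  base composition refuses an empty position set (no 0/0); the kmer table
  returns an all-zero, flagged table; histograms conserve totals through an
  overflow bin.
- Exactly two conditions are enforced at construction; sample order and
  replicate relabeling within a condition cannot change results (tested).
- Seeds: every simulator runs under its own restored RNG state
  (`with_rng`), so bundles are bit-reproducible and library loading order
  cannot perturb them.

# Known limitations

The caller identifies *differential* modification, not modification
identity; per-read probabilities, signal-space models and the neural m6A
caller it consumes are out of scope, as are alignment, basecalling QC and
the negative-binomial DE model for counts (DE sets are inputs). Published
transcript-level tallies in this field can disagree with their own
inclusion–exclusion arithmetic; the report therefore emits both the union
count and the over/under/both components and checks only internal
consistency.
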
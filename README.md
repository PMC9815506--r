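# epidiff

Differential epitranscriptome analysis for nanopore direct RNA sequencing
(DRS), in R.

DRS reads native RNA, so chemical modifications such as N6-methyladenosine
(m6A) leave signatures that per-position callers (Tombo, Nanom6A) turn into
coverage and fraction-modified tracks. `epidiff` takes it from there: given
per-position modified/unmodified read counts for two conditions with
replicates, it answers *which transcript positions change their modification
level between conditions*, and integrates those calls with m6A motif
topology, poly(A) tail lengths, transcript abundance and protein abundance.
It is aimed at plant (or any non-model) epitranscriptomics studies with a
two-group design and a transcriptome-space reference.

## The statistics at the core

For every transcript position the replicate counts of each condition are
pooled into a 2x2 table (modified/unmodified x control/treatment). Positions
with pooled coverage `N >= 50` in **both** conditions are tested with a
two-sided Fisher exact test (probability-mass ordering, hypergeometric
enumeration). The effect size is a Haldane-pseudocounted log2 ratio of
modified fractions,

    f_c = (m_c + 0.5) / (N_c + 1),   f_t = (m_t + 0.5) / (N_t + 1)
    log2FC = log2(f_t / f_c)

and a position is called differentially modified when `p < 0.05` and
`|log2FC| > 0.5` (Benjamini-Hochberg q-values are always reported and can
replace p in the gate with `adjust = "BH"`). Around this caller sit:

- **RRACH m6A analysis** — scanning of the m6A consensus 5-mer
  (R R **A** C H; R = A/G, H = A/U/C), kmer frequency tables over the 12
  variants, and unit-area metagene density profiles on a full-length `[0,1]`
  axis or a three-region 5'UTR/CDS/3'UTR `[0,3]` axis.
- **Poly(A)** — nanopolish-style per-read tail lengths, QC-tag filtering,
  per-transcript/condition summaries and binned distributions.
- **Integration** — CPM normalisation (`>= 2` cpm in `>= 2` samples filter),
  Pearson correlations (with two-sided t-transform p-values) across
  modification ratio, m6A ratio, poly(A) length, `log2(CPM+1)` abundance and
  log2 protein abundance, and exclusive-overlap counts of significant sets
  from three omics approaches.
- **Synthetic data** — a seeded generator that emits every input with
  planted ground truth (negative-binomial coverage, per-transcript
  modification propensities, treatment effects placed preferentially in
  3'-UTR RRACH sites, truncated-Gamma poly(A) tails with mean 91 nt in
  40-250 nt, and configurable couplings between the layers), so the whole
  pipeline is validated without external data.

## Worked example

```r
library(epidiff)
cfg    <- sim_config(n_transcripts = 300, n_planted = 60, seed = 42)
bundle <- simulate_dataset(cfg)

res <- diffmod_scan(bundle$modcalls, min_cov = 50, alpha = 0.05, lfc_min = 0.5)
head(res[status != "ns"], 3)
#>    transcript_id position ref_base   m_c   N_c   m_t   N_t        f_c
#> 1:       tx00007      771        A    10    92    31   103 0.11290323
#> 2:       tx00010      682        A     3    85    50   113 0.04069767
#> 3:       tx00011     1005        C     4    85     0   103 0.05232558
#>            f_t    log2fc      p_value      q_value status
#> 1: 0.302884615  1.423682 1.348353e-03 5.308517e-02   over
#> 2: 0.442982456  3.444231 1.019464e-11 1.667216e-09   over
#> 3: 0.004807692 -3.444100 4.017039e-02 8.474446e-01  under
```

Position `682` of `tx00010` jumps from ~4% to ~44% modified reads under
treatment (log2FC 3.44, q = 1.7e-9): a planted m6A gain the caller recovers.
The per-transcript tallies mirror the way such studies summarise results:

```r
t <- attr(res, "tally")
#> positions tested: 2126; over: 85, under: 26
#> modified transcripts: 94 (over 79, under 23, both 8)

out <- run_pipeline(bundle)   # diffmod + m6a + polya + integrate + report
out$report$recovery$sensitivity
#> [1] 0.983                  # fraction of planted sites flagged "over"

out$integrate$correlations[pair %in% c("mod_ratio~abundance", "polya~m6a_ratio")]
#>                   pair condition          r      p_value     n
#> 1: mod_ratio~abundance   control -0.3903638 2.327921e-12   300
#> 2: mod_ratio~abundance   treated -0.3795526 1.025710e-11   300
#> 3:     polya~m6a_ratio   control  0.1588148 5.837223e-03   300
#> 4:     polya~m6a_ratio   treated  0.1433577 1.293645e-02   300
```

The generator's couplings (abundance falls with modification ratio, target
r = -0.4; poly(A) length rises with it, target r = +0.2) come back out of
the estimated quantities — negative abundance correlations near -0.39 and
positive poly(A) correlations, attenuated at n = 300 as expected. The most
frequent RRACH variant in this A-rich synthetic transcriptome is `AAACA`
(14.2%), matching what is reported for real plant roots.

A command-line front end with `simulate`, `diffmod` and `run` subcommands
ships in `inst/cli/epidiff-cli.R`.

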
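---
title: "Models and design choices in checs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in checs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checs)
```

`checs` implements the statistics of a pooled shRNA reporter screen together
with the two companion quantifications such a study relies on: equilibrium
binding fits and relative qPCR quantification. This vignette explains the
models, the parameters that matter, what the synthetic-data generators do and
do not emulate, and the choices made where the design was genuinely open.

## The screen and its scoring model

A reporter of an effector's silencing activity is integrated in every cell;
cells carry one shRNA each. After induction, cells in which silencing failed
remain reporter-positive. FACS sorts the top slice of the reporter
distribution (positive gate) and a large bottom slice (negative gate), and
the shRNA cassettes of both populations are sequenced. An shRNA enriched in
the positive gate marks a gene required for silencing.

Scoring proceeds in five steps, each its own exported function:

1. **Normalization** (`normalize_counts`): counts become fractions of the
   library-matched reads per lane, cancelling sequencing depth.
2. **Enrichment ratios** (`enrichment_scores`): per replicate,
   positive-gate fraction over negative-gate fraction. A zero numerator
   count receives the depletion floor `1e-3`; a zero denominator the cap
   `1e3`. The floor is the published convention for fully depleted shRNAs;
   the cap is its symmetric counterpart (the choice matters only for guides
   absent from the large negative gate, which is rare at realistic depth).
   Both applications are logged. The average enrichment score (AES) is the
   geometric mean over replicates, so a single outlier replicate cannot
   dominate and reciprocal screens invert scores exactly.
3. **Gene scores** (`gene_scores`): the sum of a gene's guide AES values,
   reported as its natural log. A `mode = "mean"` switch divides by the
   guide count; the two differ by `log(n_guides)` and can reorder genes when
   guide counts are unequal, so the mode is explicit rather than implicit.
   Control shRNAs are never scored as a gene; they are reported separately.
4. **Per-guide significance** (`poisson_pvalues`): in each replicate the
   positive-gate count is tested against `lambda = neg_count / neg_total *
   pos_total`, the expectation if the guide behaved in the positive gate as
   it does in the negative reference; the P-value is the upper Poisson tail
   (enrichment direction — the screen's readout is persistence of the
   reporter). A zero reference count floors `lambda` at 0.5 so P-values stay
   inside (0, 1]; underflowing tails are clamped at the smallest positive
   double for the same reason.
5. **Combination and correction** (`fisher_combine`, `gene_pvalues`,
   `rank_genes`): all of a gene's guide-by-replicate P-values enter one
   Fisher combination (`-2 Σ ln p`, chi-squared with `2k` df), Bonferroni-
   corrected over the genes scored. Ranking is by descending log gene score
   with ties broken by smaller combined P, then gene id.

Two constructions were open. The gene-level combination could be staged
(per-guide across replicates, then across guides); both are valid chi-squared
statistics and the pooled form is used because it is the minimal single-step
reading of the procedure. The Poisson reference could be an input (T0)
library; the negative gate is used because the sorted design carries no T0
sample, and the negative gate holds the overwhelming majority of cells.

### What the P-values are, and are not

The Poisson test is a plug-in test: it treats `lambda` as known, although it
is estimated from an equally deep negative sample, and it ignores that gate
composition is itself a cell-level sample. Under a true null with equal
depths, `Var(pos − lambda_hat) ≥ 2 lambda`, plus an overdispersion factor of
roughly `1 + reads per gate cell` from FACS subsampling, while the test
assumes `Var = lambda`. Combined P-values are therefore anticonservative on
null screens — a property of the published construction itself, reproduced
faithfully here — and should be read as a ranking signal alongside the gene
score rather than as calibrated error rates. Hit calling in practice relies
on the score ranking and the Bonferroni cut; the planted-hit recovery tests
show that this is robust: strong hits separate by orders of magnitude.

## The screen simulator

`simulate_screen` models exactly the structure the scoring assumes, plus the
one noise source the scoring does not model (gate subsampling):

* cells are assigned guides uniformly at random;
* each cell escapes silencing with its guide's escape probability
  (`hit_escape_prob` for planted hit genes, `background_escape_prob`
  otherwise; controls are neutral);
* the latent reporter value is 1 (escaper) or 0 (silenced) plus Gaussian
  noise (sd 0.1) — the minimal model that makes rank-based gates meaningful
  without modelling fluorescence physics;
* the positive sample is the top `pos_gate_fraction` of cells, the negative
  sample the bottom `neg_gate_fraction`, and reads are a multinomial draw
  over the gated cells' guide frequencies.

Defaults are the study conditions: five replicates, gates 0.07 and 0.775
(midpoints of the 6–8% and 75–80% sorting windows), 550 cells per guide
(the coverage implied by 30e6 cells at 10% transduction over 5459 shRNAs),
2e6 reads per sample, background escape 0.05 with hits at 0.9 on 5% of
genes. The simulator does **not** model retroviral copy number, growth
dropout over the induction period, sort impurity, PCR amplification bias or
sequencing error; multinomial reads are the simplest model under which the
Poisson statistic is approximately right at the read level. Passing tests
therefore validate the scoring arithmetic and its behaviour under sampling
noise, not robustness to those unmodelled effects in real libraries.

`emit_fastq` embeds each guide's 22-nt strand at a fixed offset (default 31)
inside 150-nt reads, flanked by fixed 8-nt vector anchors with random filler
elsewhere, matching the sequencing layout in which a 150-bp read contains
the 22-nt guide strand. `count_guides` inverts this by exact matching — no
mismatch tolerance, since 22-mers distinguish library guides and the
quantification is defined by "matching reads" — either at a fixed offset or
by scanning all windows (the default, because vector context offsets differ
between preparations), leftmost match winning. Reverse-complement search is
an explicit option, off by default for a guide-strand readout.

## Binding fits

`fit_binding` estimates `(BL, F, K_D)` in `Signal = BL + F·c/(c + K_D)` by
Levenberg–Marquardt with the box constraint `K_D > 0`; `F` may be negative
because anisotropy can fall on binding. Initialization is `BL₀ = min`,
`F₀ = max − min`, `K_D₀` the half-rise concentration by interpolation, which
is robust for monotone saturation curves; degenerate (constant) signals and
fewer than four distinct concentrations are rejected, and non-convergence is
returned as a flagged result, not an exception. Free protein is equated with
total protein (no ligand-depletion correction), the form in which the
titration is fit in practice at these concentrations. Standard errors use a
bootstrap over replicates by default — the published ±SE on K_D does not
state its derivation, and the bootstrap makes the fewest distributional
assumptions — with curvature-based SEs available where many fits are made.
When the estimate exceeds five times the largest titrated concentration the
fit is flagged so the result is reported as a lower bound (the convention
behind "K_D > 1000 nM" statements), since the data cannot localize a plateau
beyond the range.

The K_D-recovery checks use 100 titrations on a 12-point grid spanning
1–2000 nM with noise at 2% of the amplitude and 3 replicates — sizes chosen
to exercise the estimator well into its asymptotic regime while keeping the
default test run fast.

## qPCR relative quantification

`percent_input` computes `efficiency^(adjusted input Cq − IP Cq)` with the
input Cq adjusted by `log_efficiency(1/input_fraction)` (10% input ≈ 3.32
cycles at perfect doubling). Spike-in normalization divides by the same
quantity computed for a foreign-genome spike-in amplicon — a ratio of ratios,
which cancels IP-efficiency factors shared between target and spike-in. The
published normalization states input and spike-in but not the algebra; the
ratio-of-ratios is the standard construction. Amplification efficiency
defaults to 2 (no calibration data is assumed) and is configurable. IgG
wells are carried through for reporting but not subtracted. The Cq table
schema adds a `material` column ({IP, input}) because the spike amplicon
must be measured in both materials while the role column identifies it as
the spike-in.

`scale_to_control` implements the two-step replicate scaling: each
replicate's values are divided by that replicate's mean, then all values by
the untreated mean, which is exactly 1 afterwards. `one_tailed_ttest` is the
pooled-variance unpaired test (the plain reading of "unpaired t-test"), with
the one-tailed P taken in the direction of the observed difference and stars
at ≤0.05, ≤0.01, ≤0.001, ≤0.0001.

## Numerical and engineering choices

* All generators take an explicit seed, run under a saved/restored RNG
  state, and are bit-reproducible; the pipeline writes byte-identical
  outputs for identical configs.
* Fisher statistics are validated against the closed-form even-df
  chi-squared survival function (Erlang tail) rather than against the same
  library call that computes them.
* Count matrices are integer, column sums are checked against read totals,
  and TSV schemas reject non-integer cells, duplicate rows and unknown
  column patterns by name.
* The depletion floor/cap and the `lambda` floor are applied to flagged,
  logged cells only; no global pseudocounts are added anywhere.

## Limitations

The screen statistics inherit the anticonservativeness of the plug-in
Poisson construction discussed above. The simulator's escape-probability
model collapses knockdown efficiency, reporter kinetics and sort purity into
a single per-guide parameter, so absolute effect sizes do not translate to
any particular biological system. Binding fits assume a single site and no
cooperativity; competition formats need a different model. qPCR
quantification assumes a shared amplification efficiency across amplicons
unless told otherwise and does not estimate efficiencies from standard
curves.
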
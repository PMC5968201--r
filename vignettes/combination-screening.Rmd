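---
title: "Methods: miRNA/drug combination screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA/drug combination screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiscreen)
```

combiscreen analyses plate-based viability screens in which miRNA mimics
are transfected into panels of cancer cell lines, alone and in combination
with drugs. This vignette explains each stage's model and assumptions, the
parameters that matter, the numerical choices, and what the synthetic
benchmarks do — and do not — demonstrate.

## Data model

One row of the well table is one well: cell line, miRNA (empty for none,
`NEG_CONTROL` for a control transfection), drug, dose with unit, repeat
and well indices, assay (`MTS`, an absorbance readout, or `ALAMAR`, a
percent-reduction readout), and a non-negative signal. Doses are stored in
molar and converted on load; assays mix nM and µM ranges. alamarBlue
signals are consumed as already-computed percent reduction — the
dual-wavelength reduction formula is an instrument-side computation, out
of scope here. Signals are assumed final (no blank correction is applied).

**Observational unit.** Rank tests need replicates, and plate experiments
here are duplicates repeated in three independent runs. We pool wells
across runs, so a typical arm has n = 6 observations. This treats wells
from different runs as exchangeable; run-level effects would make these
pseudo-replicates and anti-conservative. We document rather than model
this, because with n = 6 per arm no mixed model is estimable and the exact
rank test is the analysis the screen is designed around.

## Single-agent MAD screen

Per cell line, each miRNA's mean over its (typically quadruplicate) wells
is divided by the global median signal of *all* miRNA-transfected wells of
that line — controls are excluded from the reference, so the ratio scale
is anchored at the typical transfection, not at untreated growth. Hits are
called from the ratio distribution across miRNAs: with `m` the median of
the ratios and `MAD` their raw median absolute deviation, a miRNA is
anti-proliferative below `m − k·MAD` and proliferative above `m + k·MAD`.

Choices worth stating explicitly:

* **The MAD referent is the ratio distribution, per cell line.** A
  per-miRNA "absolute deviation from the median" of a single ratio is not
  a dispersion statistic, so the ±k·MAD rule is only well-posed when MAD
  summarises the spread of ratios across miRNAs within a line.
* **Raw MAD**, without the 1.4826 normal-consistency factor: applying the
  factor would silently widen the bounds by ~50%.
* **Bounds are centred on the ratio median**, which is ≈ 1 by construction
  when the same wells define the global median.
* **Degenerate dispersion**: if more than half the ratios equal the
  median, MAD = 0 and the rule would call everything or nothing. We then
  call any ratio strictly different from the median a hit and flag the
  table (`degenerate_flag`), keeping the rule total on pathological data.

**The k = 2 rule is deliberately liberal.** For approximately normal
ratios, 2·MAD ≈ 1.35 standard deviations, so ~18% of null miRNAs per line
fall outside the bounds. That is a property of the published rule, not a
bug — a single-agent pre-screen is meant to be permissive. Error control
comes from the *recurrence filter*: `select_candidates()` keeps miRNAs hit
in the same direction in at least `min_cell_lines` lines. At the default
`min_cell_lines = 2` the candidate list is still permissive; on the
12-line benchmark screen we select at `min_cell_lines = 6`, where the
probability of a null miRNA recurring by chance is below 10^-3 and the
planted miRNAs (active in all lines) are found with sensitivity ~1 and
false-discovery proportion ~0. A false-discovery proportion ≤ 0.1 at the
single-line call level is unattainable under the ±2·MAD rule itself;
any benchmark claiming it must operate at the candidate stage.

## Dose–response and the working concentration

Inhibition curves are the four-parameter logistic
`y = bottom + (top − bottom)/(1 + (x/IC50)^hill)` with a *relative* IC50
(the curve midpoint, at which the fitted response equals
`(top + bottom)/2` exactly). Fitting is least squares in log-dose via
Levenberg–Marquardt, with starting values taken from the data (asymptotes
from the response extremes, IC50 from the dose nearest the midpoint,
hill = 1) and a multi-start over hill ∈ {0.5, 1, 2} on failure. Box
constraints — `bottom ≥ 0`, `hill ∈ [0.1, 10]`, IC50 within two decades of
the dosed range — prevent pathological extrapolation from sparse 8-point
series. A fit of constant responses is refused (no IC50 is definable), and
an unconverged fit is returned honestly flagged rather than silently.

The working concentration for combination assays is `min(IC50, 1 µM)`;
the cap applies strictly above 1 µM, so an IC50 of exactly 1 µM is used
uncapped. Dilution series are explicit geometric grids
(`make_dilution_series(100e-6, 5, 8)` reproduces the standard
100 µM → 1.28 nM assay range); the builder takes endpoints and factor
because not every drug's range is an integer power of one factor.

## Interaction calling

The decision procedure for a (miRNA, drug) pair is a conjunction of three
two-sided Mann–Whitney rank-sum tests against the combination arm:
miRNA-only vs combination, drug-only vs combination, untreated vs
combination. P-values are **exact**: all `choose(n+m, n)` labelings of the
pooled observations are enumerated (mid-ranks for ties, so tied data need
no correction), whenever that count is ≤ 50,000 — which covers every
plate-scale group (n = m = 6 gives 924). Larger groups fall back to the
normal approximation with tie and continuity corrections. The two-sided
p-value is `min(1, 2·min(one-sided p))`.

The per-comparison alpha is Bonferroni: `0.05 / n_comparisons` for the
experiment's drug family (0.005 for a 10-drug family; 0.05/7 ≈ 0.00714 for
a 7-drug family, displayed as 0.007 but compared unrounded, since rounding
would flip borderline verdicts). Single-agent miRNA tests are corrected by
the number of miRNAs in the experiment (e.g. 0.05/3, displayed 0.017).

A pair is a *true interaction* only if all three p-values are below alpha
**and** the combination's median signal is strictly below the medians of
all three other arms. The direction requirement is a design choice: three
significant differences alone would also label antagonism (combination
worse than a single agent) an interaction. We default to two-sided tests —
the conservative reading when no alternative is stated — with one-sided
available via `rank_sum_p()`'s `alternative` argument. An exploratory
relaxed flag (`relaxed_all_p05`) records pairs whose three tests pass at
p < 0.05 without meeting the strict family alpha.

With six wells per arm the smallest attainable two-sided exact p-value is
2/924 ≈ 0.00216. That sits below 0.005 — so a 10-comparison family can in
principle produce significant calls — but above 0.05/21, which bounds how
large a family this plate format can support. With only two wells per arm
the floor is 2/6 ≈ 0.33: no call is ever significant, which the
single-agent tests surface honestly.

## Expression association

The downstream stage links a miRNA to genome-wide mRNA expression in a
cohort. Genes first pass a variation filter: at least 20% of samples must
deviate at least 1.5-fold from the gene's median, on the linear scale,
boundaries inclusive ("at least" on both counts). Zero-median genes are
assessed after adding the smallest positive matrix value as a pseudocount,
keeping the ratio rule total for count-like data. The filter runs before
correction, so the Bonferroni multiplier is the number of genes actually
screened — filtering after correction would only make the screen more
conservative.

Per gene, Spearman's rho (mid-ranks) is computed against the driver, with
a two-sided p-value from the t approximation
`t = rho·sqrt((n−2)/(1−rho²))`; at toy sample sizes (n ≤ 9) the exact
permutation null over all n! driver orderings replaces it. Constant genes
have no defined correlation and are reported with `p = 1` and a flag
rather than dropped, so output rows align with input genes. A gene passes
at Bonferroni-corrected p < 0.05 with the requested correlation sign.

The lentiviral stage is a **concordance filter, not inference**: with
three coded conditions (1 over-expression, −1 knock-down, 0 control) it
keeps genes whose expression decreases as the level rises *and* that
already pass the cohort screen. Three points cannot support a p-value; a
gene concordant in the lentiviral data but absent from the cohort passes
is excluded. Candidate-target lists intersect case-normalized, sorted.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic functions of (config, seed) and restore
the caller's RNG state.

* **Viability noise is multiplicative log-normal**, mean-preserving
  (`exp(N(−σ²/2, σ²))` with `σ² = log(1 + CV²)`): signals are positive and
  plate CVs are roughly constant across magnitudes, and the
  parameterization makes a planted effect equal the expected ratio.
  Default well CV is 10% for the MTS screen and 5% for the alamarBlue
  combination arms, typical plate-reader repeatability.
* **The default screen** is 38 miRNAs × 12 cell lines × quadruplicates at
  baseline OD 1.0, with six planted miRNAs — three at effect 0.5, three at
  1.5 — active in every line. Balanced planting keeps the per-line ratio
  median near 1, so the planted truth does not shift the normalization it
  is benchmarked against.
* **Combination experiments** default to single-agent effects 0.8 and a
  combination effect 0.4 at six wells per arm — an interaction clearly
  stronger than either agent, the regime the conjunction rule is meant to
  detect.
* **Expression cohorts** plant driver-correlated genes through a Gaussian
  copula (latent Pearson `2·sin(π·rho_s/6)` for target Spearman `rho_s`),
  because the screen is rank-based and linear-Gaussian planting would
  calibrate the wrong correlation; values are exponentiated
  (rank-preserving) to be non-negative.

The generators do **not** model plate spatial or edge effects, batch
drift, run-level random effects, transfection-efficiency differences
between cell lines, or correlated gene–gene expression structure. Passing
benchmarks therefore show that the statistics are implemented correctly
and behave as designed under their own assumptions — not that those
assumptions hold on any particular laboratory's plates.

## Benchmark problem sizes

The test suite and the acceptance script use: an exact-test oracle sweep
over all group sizes with n + m ≤ 12; 500 null and 200 planted
combination experiments at six wells per arm; 100 noisy dose–response
fits (5%-of-top Gaussian noise, triplicate wells, 8 points over ~3.3
decades centred on the true IC50 — the triplicate design mirrors the
titration protocol, and a single-well series leaves the median IC50 error
near 16%, above what triplicates deliver); 50–100 replicates of the
default screen; and 2,000-gene × 300-sample cohorts with 50 planted genes
at Spearman −0.5. These sizes make every benchmark a few seconds to a
couple of minutes on one CPU while keeping Monte-Carlo error well inside
the asserted margins.

## Known limitations

* Pooling wells across experiment repeats ignores run effects
  (pseudo-replication); with larger designs a stratified or mixed analysis
  would be preferable.
* The ±2·MAD rule's per-line false-call rate is ~18% by construction;
  downstream control relies entirely on cross-line recurrence.
* The interaction verdict is a rank-test conjunction, not a synergy
  surface model (Bliss, Loewe, HSA); it detects "combination beats both
  agents", not pharmacological synergy in the dose–response sense.
* Pathway/GO enrichment of correlated gene sets is out of scope (external
  services); the pipeline stops at gene lists.
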
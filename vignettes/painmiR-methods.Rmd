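---
title: "Methods: how painmiR screens, quantifies and reduces cancer-pain miRNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how painmiR screens, quantifies and reduces cancer-pain miRNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmiR)
```

painmiR implements the computational workflow used to discover and validate
miRNA signatures of bone-metastatic cancer pain in dorsal root ganglia (DRG):
a replicate-consistency dysregulation screen on miRNA expression arrays,
ΔΔCt relative quantification of qPCR validation data, consensus aggregation
of in-silico target predictions with an in-vivo expression-response filter,
and reduction of von Frey withdrawal psychophysics. Because studies of this
design rarely deposit raw animal data, the package ships a first-class
synthetic-data module that generates every input with planted, recorded
ground truth, so the whole pipeline is testable end to end.

## The dysregulation screen

Arrays report nonnegative intensities for roughly 615–655 mouse miRNAs over
three biological replicates per group (sham vs tumour-bearing) at each
post-implantation timepoint. The screen has three parts.

**Quantile normalization** (`quantile_normalize()`) forces all arrays to
share one empirical intensity distribution while preserving within-array
ranks: each column's sorted values are replaced by the across-array mean of
sorted values. Ties within a column receive the mean of the reference values
their sorted positions span, which preserves the matrix total and makes the
transform idempotent. This is the standard correction for between-array
technical differences in bead-array data.

**The replicate-consistency criterion** (`screen()`): a miRNA is called
dysregulated when the distance between group means is at least *k* times the
sum of the two group standard deviations,

$$|\bar{x}_T - \bar{x}_S| \ge k\,(s_T + s_S), \qquad k = 5,$$

and its fold change $FC = \bar{x}_T / \bar{x}_S$ is at least 2.5 (up) or at
most $1/2.5$ (down). Both boundaries are inclusive ("at least" semantics). A
looser 2.0-fold tier is reported for context but does not drive selection.
SDs use the sample ($n-1$) denominator by default (`sd_mode` is
configurable). miRNAs with a nonpositive group mean are flagged unevaluable
and reported rather than dropped. Because both criterion sides and the fold
change are homogeneous of degree one, selection is invariant to global
intensity scaling.

**The implied t-test bound** (`implied_t_bound()`): the criterion is not a
per-miRNA hypothesis test, but it implies one. At criterion equality the
pooled equal-variance two-sample t statistic with $n$ replicates per group is

$$t = \frac{k\,(s_S + s_T)}{\sqrt{(s_S^2 + s_T^2)\,/\,n}},$$

minimized over SD configurations as one SD tends to zero, giving
$t_{\min} = k\sqrt{n}$ on $2n-2$ degrees of freedom. For $k=5$, $n=3$:
$t_{\min} = 5\sqrt{3} \approx 8.66$, $p \approx 9.8\times10^{-4}$ — every
selected miRNA is at least this significant under that test. With equal SDs
the statistic is $k\sqrt{2n}$, strictly larger. The test suite confirms the
supremum by a 100×100 grid search over SD configurations.

## ΔΔCt relative quantification

qPCR Ct values arrive in long format (sample, group, assay, technical
replicate, Ct). `aggregate_technical()` averages technical triplicates and
flags (without excluding) pairs whose replicate SD exceeds 0.5 cycles, a
conventional qPCR QC limit. `ddct()` then computes per-sample
$\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$ (reference:
sno202 for miRNAs, Gapdh for mRNAs), group-averages them, and reports
$\Delta\Delta C_t$ and the fold change $2^{-\Delta\Delta C_t}$. Choices:

* ΔΔCt is computed from per-sample ΔCt means, not pooled Ct means — this
  respects the biological-replicate structure; with balanced data the two
  agree.
* Amplification efficiency is fixed at 2.0 (perfect doubling), as the
  reference method assumes; no efficiency calibration is attempted.
* Undetermined Cts are treated as missing and counted, never imputed at a
  ceiling.

Consequences worth knowing: fold changes are invariant to adding a constant
to every Ct, and swapping treatment and control inverts the fold change
exactly. `timecourse_fc()` runs the comparison per timepoint (each timepoint
against its own sham control) to produce regulation trajectories.

## Target consensus and the response funnel

Target predictions from up to 14 algorithms are consumed as long-format
tables; the algorithms themselves are never executed (availability and
versioning of external predictors is outside reproducibility scope).
`tally()` counts *distinct* algorithms per (miRNA, gene) pair — duplicate
records collapse with a warning — and flags consensus at ≥ 2 of 14.

Digital (NanoString-style) counts for candidate targets are normalized by
the geometric mean of each sample's five housekeeping genes (Cltc, Gapdh,
Gusb, Hprt, Tubb5), the standard multi-reference normalization; the result
is exactly invariant to per-sample scaling. `response_filter()` calls a gene
a responder when its inhibitor/control ratio of mean normalized expression
is at least 1.5 — i.e. at least 50% up-regulation when the suppressing miRNA
is inhibited. The boundary is inclusive and applied with a 1e-9 relative
numeric tolerance: a planted ratio of exactly 1.5 travels through exp/log
normalization arithmetic and can land one ulp below the threshold otherwise.

`reciprocal_check()` scores a miRNA–target pair over a shared time course: a
timepoint is concordant when the two log2 fold changes have strictly
opposite signs. The default `min_concordant` of
$\lceil n_{\text{shared}}/2 \rceil + 1$ (a strict majority with margin) is a
package decision; the score itself is threshold-free.

## Von Frey reduction

Withdrawal data are trial counts per (mouse, day, filament) for the graded
filament set 0.02, 0.07, 0.16, 0.4, 1.0 g, five stimulations each.
Frequency is $100\,w/n$ percent; with $n=5$ all frequencies are multiples
of 20.

**Thresholds** (`vf_threshold()`): the force at which the frequency curve
first reaches a quantile $q$ (50% by default; 80% supported). Interpolation
is linear in $\log_{10}$ force, because filament sets are log-spaced and
psychometric functions are conventionally modeled on log stimulus; the
first-crossing rule makes non-monotone curves deterministic and
order-independent. Curves already at $\ge q$ on the smallest filament are
left-censored there; curves never reaching $q$ are right-censored at the
largest filament, with flags emitted — group summaries include censored
animals at their bound and report the censored fraction.

**AUC** (`vf_auc()`): trapezoidal integral of frequency over
$\log_{10}$ force across the full filament range, bounded by
$100 \log_{10}(F_{\max}/F_{\min}) \approx 169.90$; a linear-force abscissa
is available (`scale = "linear"`) for sensitivity analysis, and the scale
used is recorded in the result.

`group_timecourse()` always reduces per animal first, then averages across
animals (mean ± SEM), matching the per-mouse reporting granularity of
behavioural studies; SEM is reported missing for single-animal cells.

## What the synthetic data emulate — and what they do not

* **Arrays** (`gen_expression()`): per-miRNA baselines are log-normal
  (log2 mean 8, SD 1.5 — a typical array intensity spread); within-group
  noise is multiplicative log-normal with a linear-scale CV, so expected
  linear-scale group means equal the planted means at any noise level, and
  zero-noise data are exact. Defaults plant 26 up- and 31 down-regulated
  miRNAs at fold change 3 among 615 (the count is configurable; array
  designs of this generation carried 615–655 probes). Not emulated:
  probe-level artefacts, background correction, bead-level variance, or
  between-array technical effects.
* **Ct tables** (`gen_ct()`): the planted fold change $f$ is encoded as a
  $-\log_2 f$ cycle shift of the treatment-group target Ct; the reference
  assay is group-invariant. Gaussian cycle noise is optional.
* **Predictions** (`gen_predictions()`): planted genes are predicted by
  exactly their requested number of distinct algorithms; background genes
  independently at a per-algorithm rate.
* **Counts** (`gen_counts()`): expected counts with per-sample library-size
  factors; responders scaled by the response ratio in the inhibitor
  condition only; negative-binomial sampling above zero dispersion, exact
  expectations at zero.
* **Behaviour** (`gen_behavior()`): binomial withdrawals from a logistic
  psychometric in $\log_{10}$ force with floor/ceiling asymptotes (the
  standard psychophysics form; slope 4 per log10-gram by default), sham
  thresholds constant at 0.6 g and tumour thresholds declining 0.6 → 0.05 g
  over post-implantation days 0–8, six mice per group — the trajectory of a
  model in which mechanical hypersensitivity is established by day 8.

Every generator takes a seed and is byte-deterministic; ground truth is
emitted separately (`truth.json`), never embedded in the data tables.
Passing tests on these data demonstrate correctness of the *computations*
under a clean generative model, not robustness to the artefacts of real
arrays, plates or animals.

### Normalization and the recovery benchmark

One subtlety is documented here deliberately. Quantile normalization removes
between-array technical differences; the generator does not create any — it
plants exact group means on a common scale. Applying quantile normalization
across both groups to such data compresses the fold changes of dysregulated
miRNAs at extreme ranks (a miRNA occupying the top rank in both groups maps
to the identical reference value in both, erasing its fold change
entirely). The planted-recovery benchmark therefore feeds generated
intensities directly to `group_stats()`/`screen()`; under the default study
conditions (615 miRNAs, 26 + 31 planted at FC 3, noise CV 0.05, n = 3 per
group) the screen attains sensitivity ≈ 0.99 and specificity 1.0 over 20
seeds, and recovers exactly 26 up and 31 down at zero noise. The pipeline's
screen stage still normalizes by default, which is the correct preprocessing
for real arrays. Users simulating array-specific technical effects should
keep normalization on; users benchmarking the selection criterion itself
should be aware of the tail-compression artefact.

## Worked example

```{r}
sim <- gen_expression(array_sim_config(n_mirnas = 615, n_up = 26,
                                       n_down = 31, planted_fc = 3,
                                       noise_cv = 0.05, seed = 1))
res <- screen(group_stats(sim$matrix), screen_config())
print(screen_report(res, screen_config(), matrix = sim$matrix))

implied_t_bound(k = 5, n = 3)$p_value

ct <- gen_ct("miR-1a-3p", c("miR-1a-3p" = 4), ct_noise_sd = 0, seed = 1)
ddct(ct, "miR-1a-3p", "sno202", "tumour", "sham")[, c("ddct", "fold_change")]

vf_threshold(c(0.02, 0.07, 0.16, 0.4, 1.0), c(0, 20, 60, 80, 100), q = 50)
```

## Numerical choices and problem sizes

* Quantile-normalization ties: mean of spanned reference values (exact
  sum preservation and idempotence); verified against limma's
  implementation on tie-free matrices and a brute-force oracle otherwise.
* All inclusive boundaries are exact comparisons except the response
  filter's (1e-9 relative tolerance, reason above).
* Threshold interpolation is verified against a brute-force oracle over all
  $5^5$ quantized five-filament curves at both supported quantiles.
* Test and benchmark problem sizes — 615 × 6 arrays over 20 seeds, 100-seed
  Ct Monte Carlo, 1000-mice behavioural recovery, two full pipeline runs
  for byte-determinism — were chosen so the whole suite completes in a few
  minutes on one CPU while keeping Monte-Carlo standard errors well inside
  the asserted tolerances.

## Limitations

* The screen implements the published selection rule; it does not compute
  per-miRNA moderated statistics or multiple-testing-corrected p-values
  (limma-style modeling is deliberately out of scope).
* No efficiency correction in ΔΔCt; strongly divergent amplification
  efficiencies would bias fold changes.
* The response filter compares condition means; with very few samples a
  single outlier can flip a gene across the 1.5 boundary.
* Censored thresholds are summarized at their bounds, which biases group
  means toward the censoring limit when censoring is frequent; the censored
  fraction is always reported so users can judge.
* Inferential statistics on the reduced tables (repeated-measures ANOVA,
  post-hoc corrections) are left to standard tools; the pipeline emits tidy
  per-animal and per-group tables for exactly that purpose.
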
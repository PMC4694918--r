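---
title: "Models and methods behind mirunmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirunmask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirunmask)
```

`mirunmask` chains four analyses: a pharmacologic-unmasking screen for
epigenetically silenced miRNAs, a tumor-versus-normal methylation
comparison around their transcription start sites, consensus target
prediction intersected with tumor-upregulated genes, and a
median-difference risk-score survival signature. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions taken where the analysis convention was genuinely open.

## The unmasking screen

Demethylating-agent treatment re-expresses genes silenced by promoter
hypermethylation. The screen takes paired treated/control linear
intensities per cell line and computes the fold change
$FC_{m,\ell} = \bar{x}^{\mathrm{trt}}_{m,\ell} / \bar{x}^{\mathrm{ctl}}_{m,\ell}$.
A miRNA is a candidate when $FC \ge f$ in at least $k$ cell lines
(defaults $f = 1.5$, $k = 2$, both inclusive — "1.5-fold or more").

Three conventions matter and are parameters:

* **Detection.** An intensity below `detection_floor` is *not detected*;
  a pair with an undetected arm is `n.d.` and is **neutral**: it neither
  counts toward nor disqualifies a candidate. This is forced by the data
  the rule must reproduce — a miRNA can qualify on two numeric lines while
  being absent on the other two. The default floor is 0 (everything
  detected), so users without detection calls lose nothing.
* **Scale.** Fold changes are ratios of normalized *linear* intensities.
  Whether a screen applies its cutoff on linear or log2 intensities is a
  reporting convention; ratios are identical either way, and the threshold
  here is on the linear ratio. An optional per-sample 75th-percentile
  scaling (`normalize_upper_quartile()`) stands in for upstream array
  normalization when only raw intensities are available; the screen
  consumes ratios, so only per-sample offsets matter.
* **Ties at the threshold.** Inclusive ($\ge$), so a fold of exactly 1.5
  qualifies; a fold of 1.49 in every line never does.

`ddct_relative_quantity()` implements comparative-Ct qPCR quantification
($2^{-\Delta\Delta C_t}$) used when validating screen hits.

## Methylation comparison

Probes are linked to features when within `tss_window` bp of the TSS
(default 2000 bp — "near the TSS" is never quantified in practice, and
±2 kb covers the promoter plus CpG-island shores; it is configurable).
Distances are signed relative to strand, negative upstream. Linking uses
interval overlap (GenomicRanges); the test suite checks it against an
all-pairs distance scan.

Group tests are classic pooled-variance Student's t (the convention in
methylation box-plot panels; Welch is an option) or the two-sided
Mann-Whitney U. Degenerate inputs are resolved explicitly: two zero-variance
groups give p = 1 when their means agree and p = 0 (flagged) when they
differ — this keeps noiseless simulations exact instead of erroring.
Because per-probe panels are conventionally annotated with raw-p asterisks,
no multiple-testing correction is applied by default; a Benjamini–Hochberg
column is a toggle. Tests run per probe or per region (per-sample mean of a
feature's linked probes — the simplest aggregation consistent with
per-miRNA reporting; whether published panels tested probes or regions is
ambiguous, so both levels are provided). Box-plot summaries use min/max
whiskers and type-7 (linear-interpolation) quartiles, stated explicitly
because quartile conventions differ.

## Target consensus and upregulation intersection

Prediction databases expose different algorithm panels per miRNA, so the
tensor of binary calls carries an availability mask, and "at least half of
available algorithms" uses a **per-miRNA denominator**: gene $g$ is a
target of miRNA $m$ iff
$\sum_a \mathrm{call}_{a,m,g} \ge \rho \cdot |A_m|$ with $\rho = 0.5$ and
$A_m$ the available algorithms. The threshold is the exact rational value
(4-of-7, not 3-of-7); a global-denominator mode exists for comparison.
Masked cells are `NA`, never zero — an unavailable algorithm must not
deflate a miRNA's vote fraction.

The pooled (deduplicated) target list is intersected with genes
upregulated in tumor versus normal. The upregulation test is not uniquely
determined by the reported cutoffs ("1.5 fold, corrected p 0.005"); the
minimal defensible default used here is a two-sample t on log2 intensities
with fold change taken on linear group means and Benjamini–Hochberg
adjustment, with the correction method pluggable. The fold gate is
inclusive, the p gate strict.

## The survival signature

Each gene is screened by a univariate Cox proportional-hazards fit
(Breslow tie handling; fits delegated to the `survival` package, verified
in tests against a hand-coded partial-likelihood maximizer). Genes with
Wald p below `alpha` (default 0.05) form the signature: C+ if the log
hazard ratio is positive, C− if negative. The per-sample risk score is

$$RS = U - D, \qquad U = \mathrm{median}(E_{C+}), \quad D = \mathrm{median}(E_{C-}),$$

medians taken over each group's genes within the sample. Medians make the
score robust to single-gene outliers and give it simple algebra: shifting
every C+ gene of a sample by $c$ shifts its RS by exactly $c$, and gene
order within a group is irrelevant (both are tested properties). When
several probesets map to one gene their per-sample median is collapsed
first; signature genes missing from a validation cohort are dropped from
their group with a logged count (necessary across array platforms).

"4 equally-spaced levels" is read as **equal-width bins** over the observed
RS range — equally spaced describes the score scale, not the group sizes;
an equal-count (quantile) mode is provided for sensitivity analysis. Level
$k$ covers $[\min + (k-1)w, \min + kw)$ with $w = \mathrm{range}/L$ and a
right-closed last bin, making assignments invariant to affine transforms
of RS. The association model enters the level as a single numeric
(ordinal-trend) covariate, because a single hazard ratio per cohort is the
quantity of interest; a categorical mode is available. Kaplan–Meier
coordinates per level are exported for plotting.

Numerical choices: Cox fits use `survival::coxph` defaults (Newton
iterations with its standard convergence tolerance); confidence intervals
are Wald, $\exp(\hat\beta \pm 1.96\,SE)$. Covariates that perfectly
separate early from late deaths have a monotone partial likelihood and no
finite estimate; such fits are rejected upstream (constant covariate) or
surface as the usual infinite-coefficient warnings, and the test fixtures
deliberately avoid them.

## What the synthetic generators emulate

The generators produce every pipeline input with planted, recoverable
truth; their defaults are the simulation conditions used throughout the
tests and the acceptance script.

* **Unmasking experiment** — baseline log2 intensities normal (mean 7,
  sd 1.5: linear intensities log-normal, matching single-channel array
  behavior), noise on the log2 scale (sd 0.2), four cell lines, planted
  miRNAs multiplied by a per-line effect drawn from 2–8× in a random
  subset of ≥ 2 lines, so the headline filter is recoverable by
  construction. No published effect-size distribution for demethylation
  response exists; 2–8× spans the weak-to-strong range seen on the
  candidate table's lower end and is a plumbing choice, not a biological
  claim.
* **Methylation cohort** — per-probe baselines uniform in 0.05–0.15
  (unmethylated normal tissue), Gaussian measurement noise (sd 0.05),
  tumor candidates shifted by `delta_beta` (default 0.3) before clipping
  to [0, 1]; 17 tumor vs 5 normal samples, the study-design shape. With a
  low baseline and moderate shift, clipping is rare, so the recovered
  group delta is unbiased to well within ±0.05.
* **Prediction tensor** — availability drawn per (algorithm, miRNA)
  (probability 0.8), since databases expose different panels per miRNA;
  available algorithms call true pairs with sensitivity 0.9 and false
  pairs at fpr 0.05; 12 algorithms, a typical aggregated panel size. Every
  miRNA is guaranteed one available algorithm so denominators are defined.
* **Survival cohort** — gene expression standard normal; the true RS is
  computed from planted C+/C− sets of **10 genes each**; event times are
  exponential with hazard $\lambda_0 \exp(\beta_{RS} \cdot RS)$
  ($\lambda_0 = 0.05$/month, $\beta_{RS} = 0.7$); censoring times are
  uniform on $(0, \tau)$ with $\tau$ solved numerically so the expected
  censored fraction equals `censor_rate` (default 0.3) — uniform censoring
  over the observed range that stays independent of the event process.
  Planted sets of 10 (rather than the 19/14 a derived signature might
  have) keep each gene's marginal hazard signal detectable: a gene
  influences RS through a median of $k$ genes, with covariance roughly
  $1/k$, so its marginal log-HR is $\approx \beta_{RS}/k$ and its Wald
  z at $n = 1000$ is $\approx \beta_{RS} \cdot (1/k)\sqrt{\text{events}}
  \approx 1.9$ — strong enough for sign recovery, weak enough that
  selection stays a genuine statistical screen.

What these simulations do **not** contain: batch and platform effects,
correlated gene blocks, probe cross-reactivity, informative censoring,
non-proportional hazards, or miRNA–target expression coupling. Passing
tests therefore demonstrate that the estimators implement their models
correctly and recover planted structure under the models' own
assumptions — not that the models are robust to real-data pathologies.

## Calibration and recovery checks

Three properties anchor the test suite at fixed problem sizes (chosen as
desk-scale cohorts that keep the full suite fast while leaving each check
well-powered):

* **Sign recovery** — on 20 cohorts of $n = 1000$ with $\beta_{RS} = 0.7$,
  univariate Cox coefficients recover the planted sign for ≥ 90% of
  planted genes, and the derived signature's risk levels associate with
  survival (positive log HR, p < 0.01) in ≥ 95% of cohorts.
* **Null calibration** — with $\beta_{RS} = 0$, scoring *fresh* cohorts
  with the planted signature and testing the binned levels rejects at
  ≤ 0.07 against nominal 0.05 over 200 cohorts of $n = 150$. The planted
  signature (not one re-derived on the same cohort) is essential: deriving
  and testing a signature on the same null cohort selects on noise and is
  anti-conservative by construction, which is exactly why validation
  cohorts independent of the derivation cohort are the appropriate test of
  a signature's prognostic value.
* **Oracle equivalence** — Cox fits on random ≤ 10-sample cohorts match a
  brute-force Breslow partial-likelihood maximization to $10^{-4}$;
  Mann-Whitney p-values match exhaustive enumeration for group sizes ≤ 5;
  consensus voting matches nested-loop counting on random tensors.

## Known limitations

* The upregulation test and correction method behind the published
  intersection counts are not uniquely specified; defaults are stated
  above and pluggable, so exact external counts depend on those choices.
* The Cox association treats risk level as numeric; with strongly
  non-linear level effects the categorical mode is more faithful.
* Region-level methylation aggregation is an unweighted probe mean;
  probes are not weighted by CpG density or distance to TSS.
* The pipeline assumes pre-normalized inputs (betas, intensities);
  normalization from raw array files is out of scope.
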
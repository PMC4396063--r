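---
title: "From drug-screen plates to clinical resistance signatures: the methods behind regsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From drug-screen plates to clinical resistance signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regsig` implements a complete workflow for deriving resistance gene
signatures (REGS) from an in vitro drug screen of cancer cell lines and
evaluating them against survival endpoints in patient cohorts. This
vignette explains the statistical model at each stage, the parameters that
matter, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## 1. Growth-rate dose-response curves and AUC0

### Model

Viability screens conventionally compare net cell counts of treated versus
untreated cultures, which biases fast-growing lines towards apparent
sensitivity. `regsig` instead works on growth *rates*: assuming exponential
growth over the exposure window, the per-well rate is

$$ g = \frac{\ln(A_{48} - b) - \ln(A_0 - b)}{\Delta t}, $$

with $A_0, A_{48}$ the optical densities at drug addition and after
exposure, $b$ the plate blank and $\Delta t$ the exposure time (48 h by
default). Per dose, $g(d)$ is the mean over replicate wells; $g_0$ is
computed identically from untreated wells. The relative growth
$R(d) = 100\, g(d)/g_0$ (percent of untreated) is free of seeding-level
and growth-speed effects: multiplying every OD by a constant changes
nothing, a property the test suite asserts.

A four-parameter logistic in $x = \log_2(\text{dose})$ is fitted to
$R(d)$ by weighted least squares (weights $1/\mathrm{se}^2$ when replicate
spread is available):

$$ R(x) = \text{bottom} + \frac{\text{top} - \text{bottom}}
          {1 + 2^{\,\text{slope}\,(x - \log_2 \mathrm{EC}_{50})}}. $$

The slope is per log2-dose unit, the natural unit for two-fold dilution
series. The resistance summary is the area under the positive part of the
curve over the tested span,

$$ \mathrm{AUC}_0 = \int_{x_{\min}}^{x_{\max}} \max(R(x), 0)\, dx, $$

in percent × log2-dose units; higher values mean more resistance. The
positive part matters because $R$ can go negative (net cell kill), and
integrating the kill region would reward cytotoxicity twice.

### Numerical choices

* **Multistart fitting.** Nonlinear least squares is run from a
  deterministic grid — slope ∈ {0.5, 1, 2, 4}, log2 EC50 at the quartiles
  of the dose span, top/bottom started at the data extremes — and the
  smallest weighted SSE wins, ties going to the smallest starting slope.
  The fit is therefore reproducible without randomness.
* **Degenerate plates.** Exactly flat data (an inert drug) has no logistic
  information; the fit returns the constant curve rather than failing.
  Wells whose blank-corrected OD is non-positive are treated as missing,
  never imputed; a dose where every replicate is missing is dropped, and
  fewer than five usable doses is an error.
* **Quadrature.** AUC0 uses adaptive quadrature at relative tolerance
  1e-8, splitting the integral at sign changes located by root-finding so
  each piece is smooth. The tests compare against a 10⁴-point trapezoid
  oracle.
* **Bootstrap.** Replicate wells are resampled with replacement within
  each dose (and within controls), the whole estimate–fit–integrate chain
  is re-run, and the 2.5/97.5 percentiles are reported. Resampling wells
  rather than residuals makes no assumption about the error model. With
  identical replicates the interval provably collapses to the point.

## 2. Expression harmonisation

The pipeline is collapse → centre → scale → merge, with state flags that
make out-of-order calls an error:

1. **Collapse:** each gene measured by several probe-sets is represented
   by the most variable probe-set *within the dataset at hand* (variance
   computed with the unbiased $n-1$ denominator; ties broken by the
   lexicographically smallest probe-set id, so the result is
   deterministic).
2. **Median-centre:** each gene's row median becomes zero. Medians resist
   the outliers common in expression data.
3. **Variance-match:** each gene is multiplied by
   $\mathrm{sd}_{\text{ref}}/\mathrm{sd}_{\text{self}}$ so its spread
   equals the reference panel's. Genes with zero own variance are left
   (they are identically zero after centring); genes with zero reference
   variance are zeroed.
4. **Merge:** column-concatenation on the gene intersection; the second
   panel must already be matched to the first, which the state flags
   enforce.

Patient cohorts are centred and variance-matched to the *reference
disease sub-panel* of the training screen (the DLBCL-like group), exactly
as the training panel's second group was. When a signature gene is absent
from a cohort it contributes zero — i.e. it is imputed at the reference
median — with a warning; more than 20% of a signature missing aborts the
transfer.

## 3. Elastic-net signatures

### Objective

For the predictor (outcome = AUC0, all cell lines) the coefficients
minimise

$$ \frac{1}{2n}\sum_i (y_i - \beta_0 - \delta z_i - x_i^\top\beta)^2
   + \lambda\Big[\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2
   + \alpha\lVert\beta\rVert_1\Big], $$

where $z_i$ is a disease-group indicator (0 = reference group, 1 = other)
whose coefficient $\delta$ is never penalised and never standardised —
it absorbs the systematic resistance difference between the two disease
groups so the genes do not have to. The classifier (outcome = resistant
vs sensitive tertiles, intermediate dropped) replaces the quadratic loss
with the mean negative log-likelihood of a logistic model and has no
indicator. Predictors are standardised internally (mean 0, variance 1
with the 1/n convention) before penalisation; reported coefficients are
on the original scale.

**Exact-objective reparameterisation.** The underlying coordinate-descent
solver standardises a gaussian response internally, which silently
rescales the *ridge* part of the penalty by $1/\mathrm{sd}(y)$ — for an
AUC0-scale outcome (sd in the tens) that all but removes the ridge
component. `fit_elastic_net()` therefore fits $y/s$ (with
$s = \mathrm{sd}(y)$, 1/n convention) at
$\alpha_g = \alpha / (s(1-\alpha)+\alpha)$ and
$\lambda_g = \lambda\,((1-\alpha)+\alpha/s)$, which is an exact
reparameterisation of the objective above: both substitutions are constant
along a $\lambda$ path, and the returned coefficients (rescaled by $s$)
satisfy the objective's KKT conditions to solver tolerance. The test suite
verifies this against an independently written coordinate-descent oracle
and against the closed-form soft-threshold solution on an orthonormal
design.

### Tuning

* $\alpha \in (0, 1]$ — lasso/ridge mixing; default grid 0.1 to 1 in
  steps of 0.05. Values near 0 select correlated genes in groups; 1 is
  the lasso.
* $\lambda$ — penalty strength; 100 points log-spaced (natural log) over
  $[-6, 3]$ for classifiers and $[-0.17, 7.63]$ for predictors. The
  predictor range is wider and higher because the outcome is on the AUC0
  scale rather than the logit scale.
* Cross-validation: leave-one-out by default (the realistic regime for a
  two-dozen-line screen), or k-fold with class-stratified deterministic
  folds for larger screens. Loss = held-out misclassifications at
  probability 0.5 (classifier) or MSPE (predictor). Ties prefer the
  smallest $\alpha$, then the smallest $\lambda$ — i.e. the most ridge-like,
  most parsimonious model among equals. The final model is refitted on all
  data at the chosen pair.

Tertile labels are assigned within each disease group separately (so the
classifier learns resistance, not disease of origin): ranks split into
three contiguous blocks as equal as possible, remainders going to the
sensitive and resistant extremes first (12 → 4/4/4, 14 → 5/4/5, 13 →
5/4/4). AUC0 ties straddling a boundary are broken by cell-line id.

## 4. Multidrug fusion

Per-drug probabilities $p_1,\dots,p_k$ combine by the odds-product
formula

$$ P = \frac{\prod_j p_j}{\prod_j p_j + \prod_j (1-p_j)}, $$

the posterior probability of resistance to the combination under
independence of drug effects with equal weights. It is symmetric, strictly
increasing in each argument, fixes $({1/2},\dots,{1/2})$ at $1/2$, and
reduces to the identity for one drug. The naive product $\prod_j p_j$
(optimistic: two coin-flips yield 0.25) and the count of drugs with
$p > 0.5$ (discards probability magnitudes) are provided for comparison.
Indices combine by the geometric mean — appropriate because per-drug AUC0
scales differ — and must be positive; a non-positive predicted index is an
error naming the sample, since silently dropping or clamping it would bias
the combined index.

Patient categorisation uses equal-width thirds of the observed score
*range* (cut-points at min + (max−min)/3 and min + 2(max−min)/3), not
empirical percentiles: the range-based reading keeps the cohort's
categorisation affine-equivariant in the score and distinguishes this step
from the percentile tertiles used on the cell lines. Percentile cuts are
available behind `method = "percentile"`. A zero range labels everyone
intermediate with a warning.

## 5. Survival evaluation

* **Cox models** (Breslow ties by default, Efron behind a flag) report
  the HR with Wald 95% CI, either per `unit_scale` index units (e.g. per
  +10 AUC0) or resistant-vs-sensitive with intermediates excluded. IPI
  enters adjusted models as a single linear 0–5 covariate by default
  (factor coding behind `ipi_factor`); with 67–700-patient cohorts the
  linear coding spends fewer degrees of freedom.
* **Restricted cubic splines**: Harrell's truncated-power basis, linear
  beyond the boundary knots, 4 knots at the 0.05/0.35/0.65/0.95 index
  quantiles; the log-relative-hazard curve is centred at the index median
  (so it is exactly zero there) with pointwise CI from the coefficient
  covariance.
* **Time-dependent ROC**: cumulative-case/dynamic-control AUC(t) with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate
  of the censoring distribution ($1/\hat G(T_i^-)$ for cases,
  $1/\hat G(t)$ for controls). With no censoring this reduces *exactly*
  to the empirical pairwise-count AUC, which the tests assert to 1e-12.
  Standard errors use the influence-function (iid) representation with
  the censoring weights treated as fixed; the correction term for the
  estimation of $\hat G$ is omitted. That term is typically small at
  moderate censoring, but the reported CIs are approximate and slightly
  conservative rather than exact. The paired difference of two markers'
  AUC(t) is tested on the same per-subject influence values, which
  respects the within-patient correlation of competing markers. The
  2-year horizon is the default headline time.
* **Cohort homogeneity**: a likelihood-ratio test comparing Cox models
  with and without cohort-origin indicators, used before merging cohorts.

## 6. What the synthetic generator emulates — and what it does not

`simulation_truth()` fixes the whole generative state: per-drug causal
gene modules, disease shift, dose design, potency mapping, clinical
linkage. Every generator is a pure function of (parameters, seed).

* **Expression**: unit-variance log2-scale values. Each drug's causal
  genes (10 of 5,000 by default) form an *equicorrelated co-expression
  module* ($\rho = 0.5$) — the working hypothesis is a coordinated
  resistance program, and pathway co-expression is precisely the structure
  grouped elastic-net selection exists for. This is also a statistical
  necessity at screen scale: with 10 independent equal-weight genes each
  gene's marginal correlation with the outcome is $\approx 1/\sqrt{10}$,
  below the $\sqrt{2\log p / n}$ selection threshold at $p = 5000,
  n = 60$, and no selector can recover the support; the correlated module
  lifts the marginal signal above threshold. The MM-like group adds a
  per-gene offset (sd 0.5) and a 1.3× variance ratio, so harmonisation is
  load-bearing; cohorts add a further 1.4× global scale.
* **Latent resistance**: $r = \sum_g w_g x_g + \varepsilon$ per drug, with
  noise calibrated to a 3:1 effect-to-noise sd ratio. Standardised $r$
  maps linearly to log2 EC50 (spread 1.2 per SD, matching the roughly
  two-fold between-line AUC0 spread such screens report); the true AUC0 is
  the analytic area of the true curve.
* **Plates**: exponential growth at rates suppressed by the true 4PL
  curve; multiplicative log-normal OD noise at CV 5%; untreated rates
  0.02–0.04 h⁻¹ (doubling 17–35 h, the range of aggressive B-cell lines —
  slower lines would leave too little 48 h growth signal relative to the
  measurement noise for the screen design to work at all). With the noise
  switched off, running the analysis modules on the plates returns the
  true AUC0 to quadrature tolerance — the forward and inverse models are
  consistent by construction.
* **Cohorts**: survival exponential with log-hazard
  $\gamma \cdot z + \gamma_{\text{IPI}}(\text{IPI} - \overline{\text{IPI}})$,
  $z$ the standardised mean of per-drug standardised latent resistances,
  $\gamma = \ln 2$ per SD by default; censoring independent uniform with
  the horizon solved numerically to hit the target rate (20%). The
  negative control draws survival from an independent latent factor so a
  correct pipeline must find nothing.

Not emulated: probe-level microarray structure, batch effects beyond
shift/scale, non-exponential growth kinetics, drug–drug interactions
(fusion assumes independence), informative censoring, competing risks,
and cohort-specific gene panels. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to these
real-data complications.

## 7. Problem sizes used by the test suite

The suite exercises the study design at desk scale, chosen as the sizes
the methods are meant for: screens of 12+12 (or 14+12) lines with 18-dose
triplicate plates; signature recovery at 60 training and 40 held-out lines
with 5,000 genes over 20 seeds (5-fold CV over α ∈ {0.1, 0.5, 1}); power
and calibration over 100 seeds with cohorts of 400 (linked) and 500
(negative control). The acceptance script runs the full chain — plates to
survival evaluation — in about a minute on one CPU.

## 8. Known limitations

* LOO-CV over the full 19-point α grid is expensive at microarray scale;
  the coarser grids used in examples trade resolution for time, and the
  full default grids remain available through `elastic_net_config()`.
* The time-dependent ROC variance omits the censoring-estimation term
  (see §5); for publication-grade CIs at heavy censoring a bootstrap is
  advisable.
* The AUC0 scale depends on the chosen curve convention (log2-dose
  integration, percent units); values are comparable within a screen
  analysed consistently, not across conventions.
* Geometric-mean fusion is undefined for non-positive predicted indices;
  linear predictors can produce them for samples far outside the training
  envelope, and the package treats that as an error rather than guessing.
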
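---
title: "Insulin-resistance surrogates in cats: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insulin-resistance surrogates in cats: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felir)
```

## The problem

Obesity causes insulin resistance (IR) in cats and predisposes them to
type-2-like diabetes mellitus. The reference method for quantifying IR —
the euglycemic insulin clamp — is impractical in veterinary medicine, so
clinical work relies on single-sample surrogates. The homeostasis model
assessment,

$$\mathrm{HOMA\text{-}IR} = \frac{\text{glucose (mmol/L)} \times
\text{insulin (mU/L)}}{22.5},$$

is the most widely used. Interpreting it requires three statistical
layers, and this package implements all of them:

1. **Cohort analysis** — screening rules, body-condition (BCS) and
   CT-derived body-fat (BF%) classification, rank-sum group comparisons,
   and ln-linear regression of analytes on BF%.
2. **Population-based reference intervals (RI)** — robust Box-Cox
   estimation with bootstrap confidence limits.
3. **Biological variation** — nested variance components on the ln
   scale, coefficients of variation (CV), the index of individuality
   (II), and reference change values (RCV) for serial monitoring of an
   individual cat.

A fully seeded synthetic-data layer emulates the statistical structure
of a feline obesity cohort so that every stage is testable without
clinical data.

## The biological-variation model

Repeated measurements (cat × weekly occasion × analytical duplicate) are
modelled on the natural-log scale as

$$\ln y_{cor} = \mu + g_c + w_{co} + a_{cor},$$

with independent Gaussian effects for cat (variance $\sigma^2_G$),
occasion within cat ($\sigma^2_I$) and duplicate ($\sigma^2_A$).

**Unbounded REML.** `fit_nested_reml()` maximises the restricted
log-likelihood directly, with the variance components *not* constrained
to be non-negative — the search is limited only by positive definiteness
of the implied marginal covariance. This mirrors the "unbounded"
behaviour of classical mixed-model software and avoids the upward bias
that boundary truncation induces in small designs; a between-cat
component estimated as slightly negative is real evidence of negligible
between-cat variation. Negative point estimates are floored at zero,
with a warning, only when converted to CVs (Cole's equation below is
undefined otherwise). The implementation has two code paths that agree
to numerical precision (this is tested): an $O(1)$-per-evaluation
closed form using the covariance eigenvalues on balanced complete
designs, and a per-cat block-Cholesky form for unbalanced designs such
as a lost duplicate. On balanced designs the optimum coincides with the
nested-ANOVA mean-square estimators, which also serve as the starting
point; the suite verifies agreement to six significant digits against
an independently coded ANOVA oracle, and against `lme4` when all
components are positive.

**CVs, Wald intervals.** Because the analytes are lognormal, ln-scale
SDs convert to natural-scale CVs exactly via Cole's relation
$\mathrm{CV} = \sqrt{e^{\mathrm{SD}^2(\ln x)} - 1}$. Confidence
intervals are Wald intervals on the *variance* scale (estimate
± 1.96 SE from the curvature of the restricted likelihood), with
negative lower endpoints set to zero, and each endpoint then mapped
through Cole's equation. The delta method on the CV scale would be an
alternative; the variance-scale convention was chosen because it is the
one used when variance components are "computed and expressed as CVs"
in the clinical-pathology literature, and it respects the zero floor
naturally. Wald intervals on variance components are asymptotic; a
Monte-Carlo test confirms ~95% coverage for the dominant component in a
40-cat design, but with 7 cats the between-cat interval is wide and its
lower limit is typically zero.

**Index of individuality and RCV.**
$\mathrm{II} = \mathrm{CV}_G / \sqrt{\mathrm{CV}_I^2 + \mathrm{CV}_A^2}$;
values below 0.7 favour population-based RIs, values above 1.7 call for
serial monitoring. The reference change value for ln-normal analytes is

$$\mathrm{RCV}(\%) = 100\,\exp\!\left\{\pm z \sqrt{2\left(
\mathrm{SD}_I^2(\ln x) + \mathrm{SD}_A^2(\ln x)\right)}\right\},$$

with $z = 1.96$ for 95% two-sided probability. Back-transformation
makes the bounds asymmetric — the significant increase exceeds the
significant decrease — and the product of the two percentages is
exactly $100^2$, a property the tests exercise. `rcv_threshold()`
converts the percentages into absolute bounds for a given baseline.

**Outlier screening.** The optional pre-fit screen
(`screen_outliers = TRUE`) applies Tukey fences to the ln-scale
duplicate differences and drops flagged occasions, always reporting what
it removed. It is off by default: which observations to exclude from a
biological-variation study is a judgement call, and the package never
makes it silently.

## Reference intervals

`reference_interval()` chains four steps, each also exposed directly:

1. **Tukey screening** on the original scale: values beyond 1.5 IQR
   from the type-7 quartiles are removed, once, not iteratively.
2. **Box-Cox transformation** with λ chosen by profile likelihood on a
   grid over [−3, 3] with step 0.01 (searched coarse-to-fine, which is
   equivalent for the unimodal profiles involved and much cheaper inside
   the bootstrap). The suite cross-checks λ against `MASS::boxcox`.
3. **Robust limits**: an iterated Tukey-biweight location
   (tuning constant 3.7 MAD units, convergence when the location moves
   < 1e−9, at most 100 iterations) and a biweight-midvariance spread
   (9 MAD units) normalised by a consistency constant computed by
   quadrature so the spread is Fisher-consistent for the Gaussian SD.
   Limits are `location ± t(0.975, n−1) · spread · √(1 + 1/n)`, which
   converges to the parametric ±1.96σ band; at n = 10⁴ the limits agree
   with ±1.96 within ±0.05 (tested). The exact internals of dedicated
   RI software are not published, so exact replication of any particular
   program is explicitly out of scope; the tuning constants above are
   documented and configurable.
4. **Bootstrap 90% CIs** for both limits: nonparametric percentile
   bootstrap of the post-outlier sample, re-running Box-Cox and the
   robust estimator in every resample. A seed is mandatory. The CI is
   flagged inadequate when its width exceeds 0.2× the interval width —
   at n ≈ 60 for a skewed analyte this flag is expected to trip, which
   the tests confirm.

Degenerate inputs (zero MAD, all-equal samples) return a flagged
degenerate interval rather than an error. For non-negative analytes the
lower limit is floored at zero.

**Known limitation.** Tukey screening of a genuinely heavy-tailed
(e.g. strongly lognormal) sample removes part of the real right tail,
pulling the upper limit below the generating 97.5th percentile; the
tests document this on a lognormal fixture. This is inherent to
fence-based screening, not to the estimator.

## Body fat from CT histograms

Masked whole-body CT voxels in the inclusive window [−250, 250] HU form
a bimodal histogram: fat attenuation near −100 HU and lean soft tissue
near +40..60 HU. Bins are centred on HU values (default width 1 HU), so
integer voxel data give integer peak positions. Counts are smoothed
with a centred moving average (default width 5 bins; the source method
for this segmentation does not state whether it smooths, so this is a
documented assumption) and the peaks are the argmax over [−250, −10]
and [+10, +250]. If smoothing flattens a sharp mode into a plateau, the
bin with the highest raw count among the tied bins is taken, then the
bin nearer the window centre. The classification midpoint is the
arithmetic mean of the two peak positions; voxels at or below it are
fat (the boundary voxel counts as fat), strictly above it lean, and

$$\mathrm{BF\%} = 100 \cdot \frac{n_\mathrm{fat}}
{n_\mathrm{fat} + n_\mathrm{lean}}.$$

On phantoms with modes at least 4 SD apart the pipeline recovers the
generating fat fraction within ±0.5 percentage points (tested at CT
scale, 10⁶ voxels). Adiposity classes follow the half-open convention:
lean < 35 ≤ overweight < 45 ≤ obese. `predictive_values()` scores BCS
against the BF% reference standard (NPV for lean scores, PPV for
overweight scores).

## Cohort statistics

- **Wilcoxon rank-sum**: exact enumeration when the smaller group has
  ≤ 12 observations and the pooled sample is tie-free, otherwise the
  normal approximation with midranks, tie-corrected variance and
  continuity correction (the variant used by the base distribution;
  which correction settings the original cohort software used is not
  documented, so the default here is stated explicitly). Descriptives
  use type-7 quartiles.
- **Noether power**: the large-sample relation
  $N = (z_{1-\alpha/2} + z_{power})^2 / (12\,c(1-c)(p'' - 1/2)^2)$ with
  $c = n_1/N$ links sample size to the stochastic superiority
  $p'' = P(X < Y)$. Solving for $p''$ uses this closed form; solving
  for power adds the opposite rejection tail so that power tends to α,
  not zero, as $p'' \to 1/2$. A simulation test confirms the predicted
  80% rejection rate at the 73-vs-77 geometry.
- **Ln-linear regression**: OLS of ln(analyte) on BF%, with residual
  skewness/kurtosis and Shapiro-Wilk diagnostics reported because the
  ln transform is motivated by residual non-normality on the raw scale.
  The slope is interpreted through
  `pct_change_per_delta(beta, 10)` = $100(e^{10\beta} - 1)$, the percent
  change per 10 BF% units. A second regressor (e.g. locomotor signs) is
  available as a pass-through covariate, not a separate model family.

## The synthetic world

The generators state a fixed emulation of the study-like cohort; their
defaults are not tuned to make tests pass.

- **BF%**: truncated normal, parent mean 38.0 and SD 11.9, rejection
  sampled inside [15.3, 61.9]. Truncation shifts the realised moments
  (mean ≈ 38.15, SD ≈ 10.4); tests check the realised moments against
  closed-form truncated-normal targets, not the parent values.
- **Analytes**: $\ln(\text{insulin}) = \ln 5.0 + 0.0225\,(BF - 38) +
  \varepsilon$, residual SD 0.60 (chosen so BF% explains R² ≈ 0.13);
  $\ln(\text{glucose})$ gets the residual slope $0.0262 - 0.0225 =
  0.0037$ and residual SD 0.23. HOMA-IR is always *derived* as
  insulin × glucose / 22.5, never generated with independent noise, so
  its ln-scale slope on BF% is exactly the sum, 0.0262. Giving glucose
  the small positive slope (numerically consistent with the weak,
  non-significant glucose association such cohorts show) is what makes
  the insulin and HOMA-IR slopes simultaneously attainable; forcing the
  glucose slope to zero would make them mutually inconsistent.
- **BCS**: assigned from the true BF% class, then corrupted — a lean
  cat is scored overweight with probability 0.5, an overweight/obese
  cat scored lean with probability 0.025, the rates implied by the
  printed 15/1 and 53/14 misclassification counts. Predictive values
  then follow from these rates and the cohort's lean prevalence.
- **Clinical flags**: deterministically rounded counts of stressed cats
  (9/161), one insulin-interference cat, one hyperglycemic cat with
  raised fructosamine (suspected diabetes), and three
  stress-hyperglycemic cats (glucose 13 mmol/L, fructosamine within its
  interval), so the screening flow 161 → 150 is reproduced exactly.
- **Biological-variation series**: three nested Gaussian effects on the
  ln scale with SDs from inverting Cole's equation; 7 cats × 5
  occasions × 2 duplicates at CVs (52.3, 51.0, 7.4)% around a
  multiplicative centre of 0.78 by default, with an option to drop one
  replicate.
- **CT phantoms**: two Gaussian modes (−100 and +60 HU, SD 20) with an
  *exact* mixing fraction and optional out-of-window contaminants.

What the generators do **not** emulate: breed/age structure in the
analytes, assay drift between runs, within-day sampling-time effects,
disease progression, or the correlation between stress and
hyperglycemia. A green recovery test therefore establishes that the
estimators are correct under the stated lognormal nested model — not
that real feline cohorts satisfy that model.

## Screening configuration

Suspected diabetes requires *both* hyperglycemia above the configured
glucose threshold (default 10 mmol/L) and fructosamine above the
configured cut-off. The fructosamine reference limit is deliberately a
site-configurable input (default 400 µmol/L, a common feline upper
limit) because it is laboratory-dependent; it is not a study-derived
constant. Hyperglycemic cats with normal or unmeasured fructosamine are
retained and listed for follow-up — consistent with stress
hyperglycemia, which is common in cats. Stress itself is an input
boolean judged clinically, never inferred from the data. When several
exclusion reasons apply, a cat is reported once under the first reason
in a fixed order (stressed, underage, pregnant, nonfasted,
diabetes-suspected, insulin-interference) so reports are deterministic.
Every exclusion report embeds the fully resolved configuration, and
`write_run_manifest()` serialises both for audit.

## Numerical choices

- REML optimisation: Nelder-Mead from the ANOVA start, relative
  tolerance 1e−14, with a restart; the best of start and optima is
  taken, so balanced designs return the closed form exactly.
- Non-positive-definite proposals during the search are rejected with a
  large penalty, which is what restricts "unbounded" estimation to the
  valid covariance region.
- The biweight consistency constant is computed once per tuning
  constant by numerical integration and cached.
- All generators are pure functions of (parameters, seed) and restore
  the caller's RNG state.
- Insulin is stored in mU/L only; ng/L is accepted at the boundary and
  converted with the assay factor 0.023.

## Limitations

- With 7 cats the between-cat CV is estimated with 6 degrees of
  freedom; its Wald interval routinely reaches zero and should be read
  as "order of magnitude only".
- The robust RI pipeline assumes the Box-Cox family can normalise the
  data; multimodal reference samples will not be flagged beyond the
  degenerate-spread check.
- BCS misclassification is modelled as independent Bernoulli noise,
  while real scorers err mostly near the class boundary.
- HOMA-IR itself is a surrogate validated in humans; nothing in this
  package addresses its physiological validity in cats.
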
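# felir

Insulin-resistance surrogates, biological variation and body
composition in cats.

Obese cats develop insulin resistance (IR) and are at risk of
type-2-like diabetes mellitus. In practice IR is screened with a single
fasting sample through the homeostasis model assessment,

```
HOMA-IR = glucose (mmol/L) x insulin (mU/L) / 22.5 ,
```

but using that number clinically needs statistical scaffolding:
population-based reference intervals (RI), and — because insulin-related
analytes vary strongly between individuals — biological-variation
indices that tell you whether a population RI is even the right tool.
`felir` implements that full workflow for veterinary clinical
pathologists and researchers:

- **Cohort screening and classification** — validated cohort tables,
  exclusion rules (stress, age, pregnancy, fasting, suspected diabetes
  by glucose + fructosamine, assay interference), body-condition-score
  (BCS) and CT body-fat (BF%) classes, and predictive values of BCS
  against the BF% reference standard.
- **Biological variation** — nested variance components on the ln scale
  by *unbounded* REML (`fit_nested_reml()`), CVs via Cole's equation
  with Wald 95% CIs, the index of individuality
  `II = CV_G / sqrt(CV_I^2 + CV_A^2)`, and asymmetric reference change
  values `RCV(%) = 100 exp{±z sqrt(2 (SD_I² + SD_A²))}` with
  per-individual thresholds (`rcv_threshold()`).
- **Reference intervals** — Tukey outlier screening, Box-Cox
  transformation by profile likelihood, robust biweight limits, and
  bootstrap 90% CIs of both limits (`reference_interval()`).
- **Body composition** — fat/lean segmentation of masked whole-body CT
  Hounsfield-unit histograms by the bimodal-peak midpoint method
  (`body_fat()`).
- **Cohort statistics** — exact/approximate Wilcoxon rank-sum
  comparisons, Noether power for the rank-sum test, and ln-linear
  regression of analytes on BF% with percent-change interpretation.
- **Synthetic data** — seeded generators (`generate_cohort()`,
  `generate_biovar_series()`, `generate_phantom()`) that emulate the
  statistical structure of a feline obesity study, so the whole pipeline
  is testable without clinical data.

See the vignette (`vignettes/feline-insulin-resistance.Rmd`) for the
models, assumptions, tuning constants and design decisions.

## Worked example

```r
library(felir)

# a synthetic enrolment of 161 cats, screened to the analysis cohort
cohort <- generate_cohort(n = 161, seed = 2024)
scr <- apply_exclusions(cohort, analysis_config())
scr$report
#> Cohort exclusion report
#>   retained: 150   excluded: 11
#>             stressed             underage             pregnant
#>                    9                    0                    0
#>            nonfasted   diabetes_suspected insulin_interference
#>                    0                    1                    1
#>   hyperglycemic, fructosamine normal/absent (follow-up): cat022, cat062, cat078
```

Nine stressed cats, one suspected diabetic (hyperglycemia with raised
fructosamine) and one assay-interference cat are removed; three
hyperglycemic cats with normal fructosamine stay in, flagged for
follow-up — the pattern expected from stress hyperglycemia.

```r
series <- generate_biovar_series(seed = 2024)   # 7 cats x 5 weeks x duplicates
biovar_indices(series)
#> Biological variation of HOMA-IR: 7 cats, 5 occasions
#>   CV_G % (95% CI): 29.0 (0.0-51.2)
#>   CV_I % (95% CI): 53.8 (35.6-68.9)
#>   CV_A % (95% CI): 7.6 (5.7-9.1)
#>   II: 0.53
#>   RCV increase: 411%   decrease: 24%
```

With a within-cat CV near 54% a serial increase is significant only
above ~4x baseline, and a decrease below ~0.24x: the asymmetry comes
from back-transforming the ln-scale RCV. Thresholds for a concrete
baseline, here 2 mU/L insulin with the published within-cat CV 48.7%
and analytical CV 6.6%:

```r
rcv_threshold(2, rcv_from_cv(48.7, 6.6))
#>  decrease  increase
#> 0.5495875 7.2781855
```

so only a second result above 7.3 mU/L (or below 0.55) is a significant
change for that cat. A reference interval for HOMA-IR in the lean
cats of the screened cohort:

```r
homa <- with(scr$retained, homa_ir(insulin_mUL, glucose_mmolL))
lean <- classify_bcs(scr$retained$bcs_value, scr$retained$bcs_scale) == "lean"
reference_interval(homa[lean], B = 1000, seed = 7)
#> Reference interval (central 95%, robust/Box-Cox)
#>   0.29 - 1.82  (n = 28, lambda = 0.26)
#>   90% CI lower limit: 0.22 - 0.43, upper limit: 1.41 - 2.2
#>   outliers removed: 2.079406, 2.111243
#>   note: CI width exceeds 20% of the interval width
```

(the width warning is the expected behaviour at n < 40). And body fat
from a CT phantom:

```r
v <- generate_phantom(n_voxels = 1e6, fat_fraction = 0.38, seed = 5)
body_fat(v)
#> Body fat: 38.0% (overweight)
#>   fat peak -101 HU, lean peak 59 HU, midpoint -21 HU
#>   voxels: 380001 fat, 619999 lean
```

## Acceptance script

`scripts/acceptance.R` recomputes, by running the installed package,
the desk-scale quantities that follow from published
biological-variation inputs: the significant-increase thresholds for a
2 mU/L insulin baseline under two analytical CVs, and the detectable
stochastic superiority P(X < Y) of the rank-sum test at 80% power for
group sizes 73 and 77. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and the problem size
`n`) per target.
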
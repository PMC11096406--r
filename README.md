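# skinrate

Does soft tissue tested in uniaxial tension behave differently at
different loading rates? `skinrate` implements a complete, reproducible
pipeline for answering that question from raw force–displacement records,
built for biomechanics groups who characterize skin (and skin-like
tissues) with tensile tests and want the statistics to be as careful as
the mechanics. The package was designed around the analysis of
full-thickness burn human skin tested at 0.3, 2 and 8 mm/s, where the
striking finding is rate *independence* — and it ships a calibrated
synthetic-cohort generator so every stage can be exercised and tested
without access to specimen data.

## What it computes

**Mechanics.** Records `(ΔL, F)` with gauge geometry `(L₀, A₀)` become
nominal stress–strain curves, `σ_N = F/A₀`, `ε_N = ΔL/L₀`. From each curve
the pipeline extracts the ultimate tensile stress and strain (at the
failure peak) and the toughness (trapezoidal area under the curve up to
the peak), and fits the Veronda–Westmann hyperelastic law

```
Ψ(Ī₁, Ī₂) = (μ/γ) (e^{γ(Ī₁−3)} − 1) − μ (Ī₂ − 3)
σ_N = 2μ (1 − λ⁻³) (λ e^{γ(Ī₁−3)} − 1),    λ = 1 + ε_N
```

by bounded Levenberg–Marquardt least squares with an analytic Jacobian,
giving the stiffness scale μ (MPa) and the strain-stiffening exponent γ.

**Statistics.** The five parameters per specimen (UT stress, UT strain,
toughness, μ, γ) are screened with 3×IQR fences and then compared between
rate classes two ways:

* a univariate decision tree at α = 0.01 — Shapiro–Wilk normality on each
  sample, then either F-test + (pooled/Welch) t-test, or
  Kolmogorov–Smirnov + (Wilcoxon rank-sum / Welch t-test) — with Cohen's d
  effect sizes and an exact noncentral-t minimum-sample-size power
  analysis;
* a multivariate multiclass classifier — leave-one-out cross-validated
  multinomial logistic regression — scored by accuracy, the multiclass
  Matthews correlation coefficient, the Fowlkes–Mallows index and the
  adjusted Rand index, plus per-feature contribution fractions.

Near-chance classification together with no univariate rejections is the
signature of rate-independent behavior.

## Worked example

```r
library(skinrate)
cfg <- pipeline_config(out_dir = "demo", seed = 42,
                       generator = cohort_config(n_per_class = c(30, 30, 30)))
res <- run_pipeline(cfg)
```

```
generating synthetic cohort (seed 30179351)
screen kept 77 of 90 samples
skinrate 0.1.0 pipeline summary (seed 42)
samples: 90 tested, 77 kept after 3xIQR screen
median R^2 of hyperelastic fits: 0.9979
univariate rejections at alpha = 0.01: 0 of 15 pairs
LOOCV accuracy = 0.3247, MCC = -0.0207, FMI = 0.3141, ARI = -0.0251
top contributing feature: toughness
```

The generator drew 30 specimens per rate class from the default
(rate-independent) parameter laws; the Veronda–Westmann law fits the
processed curves with median R² ≈ 0.998; none of the 15 parameter/rate
pair comparisons rejects at α = 0.01; and the classifier performs at
chance (accuracy ≈ 1/3, MCC and ARI ≈ 0) — the rate-independent null
behaves as advertised. The report bundle (`features.csv`,
`univariate.csv`, `confusion.csv`, `metrics.json`, `contributions.csv`,
`summary.txt`, plus the resolved `config.yaml`) is written under
`demo/`. A minimum-sample-size query looks like:

```r
min_sample_size(d = 0.4, alpha = 0.05, power = 0.85, ratio = 1, tails = "one")
#> [1] 91
```

A thin command-line wrapper with `generate` / `process` / `screen` /
`univariate` / `classify` / `run-all` subcommands is installed at
`inst/scripts/skinrate-pipeline.R`.

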
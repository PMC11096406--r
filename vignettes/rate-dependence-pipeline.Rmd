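---
title: "Methods: rate-dependence analysis of tensile skin mechanics"
author: "skinrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate-dependence analysis of tensile skin mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinrate)
```

This vignette is the package's own account of the science behind its
pipeline: the constitutive model and its quirks, what the synthetic
cohort generator does and does not emulate, the conventions baked into
the property extraction and the statistics, and the design choices made
where more than one defensible option existed.

## The mechanical model

Uniaxial tensile records — force $F$ (N) against grip displacement
$\Delta L$ (mm), with initial gauge length $L_0$ and cross-section $A_0$
— are converted to *nominal* (engineering) measures,
$\sigma_N = F/A_0$ and $\varepsilon_N = \Delta L / L_0$, with no update
for the deforming cross-section. Skin is modelled as incompressible and
isotropic; under uniaxial stretch $\lambda = 1 + \varepsilon_N$ the
deviatoric invariants are $\bar I_1 = \lambda^2 + 2/\lambda$ and
$\bar I_2 = 2\lambda + 1/\lambda^2$.

The Veronda–Westmann strain energy density,

$$\Psi = \frac{\mu}{\gamma}\left(e^{\gamma(\bar I_1 - 3)} - 1\right)
        - \mu\,(\bar I_2 - 3),$$

was developed for skin and captures the exponential strain stiffening of
collagenous tissue with only two coefficients: a stiffness scale $\mu$
(MPa) and a dimensionless stiffening exponent $\gamma$. Its uniaxial
nominal stress is the exact stretch-derivative of $\Psi$:

$$\sigma_N = 2\mu\,(1 - \lambda^{-3})
             \left(\lambda\, e^{\gamma(\bar I_1 - 3)} - 1\right).$$

Two analytic points matter in practice and are enforced by tests:

* **The $\gamma \to 0$ limit.** The energy's first term approaches
  $\mu(\bar I_1 - 3)$; the package returns this series limit exactly at
  $\gamma = 0$ instead of evaluating an indeterminate ratio, and uses
  `expm1` for small exponents.
* **A quadratic toe.** With the full $-\mu(\bar I_2 - 3)$ term the
  linear parts of the two invariant contributions cancel:
  $\sigma_N = 6\mu\,\varepsilon_N^2 + O(\varepsilon_N^3)$, so the initial
  *tangent* modulus is zero and the quadratic coefficient is $6\mu$. This
  soft toe is physically reasonable for skin, but it means no secant
  slope at small strain estimates $\mu$ well. The fit initializer
  therefore solves $\mu_0$ in closed form from the stress at the
  mid-strain point ($\sigma_N$ is linear in $\mu$) with
  $\gamma_0 = 0.05$.

### Property extraction conventions

* *Failure onset* is the global stress maximum. On a tie (a maximal
  plateau) the **last** index of the plateau is used, so a degenerate
  constant curve keeps its full area; ultimate tensile stress and strain
  are read at that index.
* *Toughness* is the trapezoidal integral of stress over strain from the
  origin to the failure index. Post-peak tails are excluded, which makes
  the property well defined on recordings that continue past rupture.
  At 100 grid points per curve the trapezoid agrees with adaptive
  quadrature of the underlying law to well under 0.5%.
* No smoothing or filtering is applied to the raw signals; an optional
  cleaning step (`clean_record()`) drops points where displacement fails
  to advance and warns.

### Fitting

`fit_hyperelastic()` minimizes unweighted squared nominal-stress
residuals with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
`ftol = ptol = gtol = 1e-12`, 500 iterations) and the analytic Jacobian
$\partial\sigma_N/\partial(\mu, \gamma)$. Bounds are
$\mu \in (10^{-6}, 10^3)$ MPa and $\gamma \in [0, 50]$: negative
$\gamma$ destroys the convexity of the exponential term and never occurs
in the calibrated cohorts. A relative-residual option exists but is off
by default — the reference behaviour is plain least squares on stress.
The curve is truncated at its failure peak before fitting. $R^2$ is
$1 - SS_{res}/SS_{tot}$ on the observed stress. Noiseless synthetic
curves are recovered to $10^{-6}$ relative; under 3% multiplicative
noise the median relative error of both coefficients stays below 5%.
A small plugin seam (`hyperelastic_law()`) lets alternative laws supply
their own stress, energy, bounds and initializer to the same fitter.

## The synthetic cohort generator

The generator exists so that every downstream stage has a realistic,
fully seeded test bed. It emulates a three-rate cohort (0.3, 2, 8 mm/s)
with class sizes 95/92/102 and ASTM D638 Type V gauge geometry
($L_0 = 7.62$ mm, $A_0 = 3.18 \times 2.1 = 6.678$ mm², the mean specimen
thickness being 2.1 mm).

**Parameter laws.** Per specimen, $(\mu, \gamma,
\varepsilon_{rupture})$ are drawn independently from positive,
right-skewed laws calibrated by quartile triplets (median, Q1, Q3):
$\mu$: 0.32 (0.17–0.66) MPa; $\gamma$: 0.07 (0.01–0.12); rupture strain:
1.69 (1.27–2.47). Two calibrations are provided:

* `calibrate_lognormal()` — the log-symmetric lognormal with
  `meanlog = log(median)` and `sdlog = log(Q3/Q1) / (2 z_{0.75})`. It
  preserves the median and the quartile *ratio* but can only match both
  quartiles when the triplet is log-symmetric.
* `calibrate_split_lognormal()` — a two-piece lognormal with separate
  log-scales below and above the median. It reproduces all three
  quartiles exactly for any ordered triplet and collapses to the
  lognormal in the log-symmetric case.

The generator samples from the split law. The choice matters for
$\gamma$, whose triplet is strongly asymmetric (Q1 is 7× below the
median, Q3 only 1.7× above): the log-symmetric law would put its upper
quartile at 0.24 instead of 0.12, doubling the frequency of extreme
strain-stiffening and inflating every emergent stress quantity. With the
split law the empirical quartiles of every generated parameter converge
to the configured triplets (verified at $n = 10^4$).

**Curves.** Each specimen's stress is the Veronda–Westmann response at
its true $(\mu, \gamma)$ on an even strain grid $[0,
\varepsilon_{rupture}]$ (100 points by default; at least 20).
Multiplicative Gaussian noise with coefficient of variation 0.03
(default) is applied — tensile load noise scales with signal — with a
small additive floor ($10^{-4}$ MPa) in the noise scale so near-zero
stresses are not degenerate; the zero-strain point stays exactly zero
and stresses are truncated at zero. Curves convert back to raw units by
$F = \sigma_N A_0$, $\Delta L = \varepsilon_N L_0$.

**Emergent quantities.** Ultimate tensile stress and toughness are *not*
sampled; they emerge from the constitutive response, mirroring their
physical coupling to $(\mu, \gamma, \varepsilon_{rupture})$. One
consequence is worth understanding: because the three inputs are drawn
independently and the stress is convex in the $\gamma$–strain coupling,
the median of the emergent ultimate stress exceeds the stress evaluated
at the median parameters. The acceptance script measures this median at
$n = 10^4$ — about 1.96 MPa versus 1.73 MPa for the
evaluate-at-the-medians figure, a ~13% structural gap. Real cohorts
whose summary quartiles produced the calibration triplets presumably
carry negative correlations among stiffness, stiffening and rupture
strain that the generator's independence assumption cannot represent;
matching marginal quartiles does not pin joint behaviour. The package
keeps the independence assumption (it is the simplest defensible null)
and documents the gap rather than tuning it away.

**Rate effect.** By default the loading-rate class is a pure label —
`rate_effect = 0` encodes the rate-independent null. A scalar
`rate_effect` $r$ applies standardized log-location shifts $(0, r, 2r)$
to the three classes (each in units of that parameter's mean log-scale
spread); a length-3 vector gives per-class shifts directly. Shifts act
on all three parameter laws. Because $\gamma$'s log-spread is large,
shifts beyond roughly 1.5 drive the exponential response towards
overflow; the generator detects non-finite stresses and fails loudly
rather than emitting corrupt cohorts.

**What the generator does not emulate:** anisotropy and Langer-line
orientation, viscoelastic (genuinely rate-dependent) mechanics,
temperature effects, machine compliance, parameter correlations, and
measurement error in displacement. Passing tests therefore demonstrate
the *pipeline's* correctness and calibration under a controlled null,
not the behaviour of real burned skin.

## Univariate statistics

**Outlier screen.** For each of the five parameters, fences are placed
at $Q1 - 3\,\mathrm{IQR}$ and $Q3 + 3\,\mathrm{IQR}$ with
linear-interpolation quantiles (R type 7 — the convention matters, so it
is fixed and documented). A specimen is removed iff any parameter falls
strictly outside its fences; the pass is single-shot and fences default
to the pooled cohort, with a per-rate option (`scope = "by_rate"`) for
designs where a whole class is shifted. On right-skewed,
positive-support data removals occur essentially only above the upper
fence.

**Decision tree.** Each parameter/rate-pair comparison runs at
$\alpha = 0.01$: Shapiro–Wilk on both samples; if both retain
normality, an F-test chooses between the pooled and Welch t-tests;
otherwise the two-sample KS test decides whether the samples share a
continuous shape, routing to the Wilcoxon rank-sum test (same shape) or
the Welch t-test (different shapes). The terminal p-value alone decides;
no multiple-testing correction is applied (decisions are raw per-pair
calls, as is conventional in this workflow). Wilcoxon uses the exact
null for $n \le 25$ without ties, otherwise the normal approximation
with tie and continuity corrections. All five tests are invariant under
a common positive rescaling, so the pair is rescaled by its pooled
maximum before testing — this keeps variance computations finite even
for astronomically heavy-tailed inputs.

*Conservatism of the composed tree.* A gated procedure does not inherit
the size of its terminal test. Under a lognormal null ($n = 95$ vs 92)
the tree rejects in about 0.6% of comparisons at $\alpha = 0.01$
(measured at 10,000 replicates): the null samples on which Wilcoxon
would reject are largely the same ones on which the KS gate fires, and
those are routed to the Welch t-test, which rarely confirms. This is a
property of the prescribed procedure itself, worth knowing when
interpreting "no rejections" — the effective per-comparison size is
below nominal, which only strengthens a null conclusion.

**Effect size and power.** Cohen's d uses the pooled standard
deviation. Minimum sample size inverts the exact noncentral-t power of
the two-sample t-test — noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$ on
$n_1 + n_2 - 2$ degrees of freedom — by doubling-and-bisection, so
`power(n) >= target > power(n-1)` holds by construction. The classical
workflow figure of 91 per group (d = 0.4, $\alpha$ = 0.05, power 0.85,
allocation ratio 1) is reproduced by the **one-tailed** family; the
two-tailed family gives 114. The tails are an explicit argument because
published analyses often omit this detail. The power family is the
t-test, not an ARE-adjusted Wilcoxon.

## Multivariate classification

Leave-one-out cross-validation fits a multinomial (softmax) logistic
model on all-but-one specimen and predicts the held-out one; features
are standardized with the *training fold's* mean and SD so no
information leaks. A small L2 ridge ($10^{-6}$ on standardized
coefficients, `nnet`'s weight decay) guarantees a finite optimum under
separation or duplicated features without materially changing
dense-data fits, and zero starting weights make every fit deterministic.

From the pooled confusion matrix (rows = true class):

* accuracy = trace / total;
* MCC is the multiclass $R_k$ generalization, defined as 0 when a
  denominator factor vanishes;
* FMI and ARI use pair-counting over the two partitions (consistent
  with their clustering origin), so both are functions of the confusion
  matrix alone; degenerate denominators again give 0.

All three are invariant to class relabeling and are cross-checked in the
tests against a brute-force enumeration over all sample pairs.

**Feature contributions.** The "which parameter drives the
classification" question is operationalized — since a classical factor
analysis is not well defined for a classifier — as the normalized mean
absolute standardized coefficient per feature, after converting the
fitted $(K-1)$-reference coefficients to the symmetric sum-to-zero
softmax parameterization. A permutation-importance alternative (mean
drop in in-sample log-likelihood over seeded column permutations) is
available behind `method = "permutation"`; the two agree directionally
on informative-feature benchmarks.

## Pipeline, seeding and outputs

`run_pipeline()` sequences generate (or load) → process → fit → screen
→ univariate → classify and writes a bundle: the resolved `config.yaml`
(16-digit precision so reruns from the file reproduce the run), per-stage
CSVs stamped with package version and seed, `metrics.json`, and a
plain-text summary. One master seed derives per-stage seeds by
stage-name hashing (kept in the 32-bit range), so stages are
independently reproducible; identical config and seed give byte-identical
bundles. Specimen files are plain delimited text with a comment header
(sample id, rate, geometry), readable individually with
`read_tensile_record()`, including headerless two-column CSVs with
geometry supplied as arguments.

## Problem sizes used by the test suite

The suite exercises: quartile convergence and null-median checks at
$10^4$ generated specimens; parameter-recovery Monte Carlo at 200
replicates; the decision tree's null calibration at 2000 replicate pairs
($n = 95$ vs 92); twenty full null cohorts (95/92/102) through fitting
and LOOCV for the classification-under-the-null checks; and a
10,000-specimen cohort for the emergent ultimate-stress median. These
sizes give Monte-Carlo error comfortably below the assertion tolerances
while keeping a full run around two minutes.

## Known limitations

* Nominal measures only; no true-stress conversion, no optical strain.
* The generator's independence of $(\mu, \gamma,
  \varepsilon_{rupture})$ is a modelling choice with measurable
  consequences for emergent medians (discussed above).
* The composed decision tree is conservative under heavy-tailed nulls;
  its effective size is below $\alpha$.
* The five standard tests are delegated to `stats`; the package's
  contribution there is the branch logic, screening, power search and
  reporting, not re-derivations of classical null distributions.
* No equivalence (TOST) testing, Bayesian alternatives, anatomical-site
  stratification, or classifiers beyond regularized multinomial
  logistic regression.
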
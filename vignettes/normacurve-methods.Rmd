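---
title: "Quantifying and normalizing RPPA dilution series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and normalizing RPPA dilution series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normacurve)
```

## The problem

A reverse-phase protein array (RPPA) prints thousands of small lysate
spots on a nitrocellulose slide and probes them all with a single
antibody. Each sample is deposited as a serial dilution (here two-fold
steps), and the goal of quantification is to collapse each dilution
series into one relative expression value. Because a single response
curve is shared by all samples on a slide, the position of a sample's
series along that curve — a horizontal shift on the log-dilution axis,
an EC50-like quantity — is a natural relative expression measure.

Raw intensities also carry variation that has nothing to do with the
protein of interest: non-specific background fluorescence, spot-to-spot
differences in how much total protein was actually deposited, and
smooth spatial trends across the slide. Two companion slides measure
the first two nuisances directly: a negative-control slide processed
without primary antibody (`ctrl`) and a slide stained with a total
protein dye (`sypro`). This package fits quantification and
normalization *simultaneously*: the nuisance terms are part of the
same model that estimates the expression values.

## The base model

For spot $j$ of sample $i$, with $d_j$ the log-scale dilution covariate
(base = the dilution fold, centered on its median, so a 2-fold series
gives consecutive integers with the most concentrated step largest):

$$y_{ij} = f(x_i + d_j) + \varepsilon_{ij}$$

where $f$ is a shared nondecreasing response curve and $x_i$ the
sample's relative log-expression. The fitting algorithm is:

1. **Joint logistic initialization.** A four-parameter logistic
   $\alpha + \beta\,\mathrm{logis}(\gamma (x_i + d_j))$ with shared
   $(\alpha, \beta, \gamma)$ and one shift per sample is fitted by
   alternating nonlinear least squares ($\alpha$ initialized at the
   5th intensity percentile, $\alpha+\beta$ at the 95th, $\gamma = 1$,
   shifts at 0; alternation stops at a relative SSE change below
   $10^{-8}$ or 50 rounds). Orientation is fixed so $\beta \ge 0$.
2. **Curve refit.** Given current shifts, $f$ is re-estimated as a
   monotone nondecreasing quadratic B-spline on $u = x + d$.
3. **Concentration re-estimation.** Given $f$, each series' $x$ is
   re-estimated by bounded one-dimensional least squares.
4. Steps 2–3 are iterated twice (the `n_iter` argument; see below for
   when more passes are warranted).

Estimates are median-centered per array: the model is only identified
up to a translation of $x$ against $d$, so expression values are
relative within a slide.

### Numerical choices

* **Monotone spline.** Quadratic B-spline basis with
  $\min(20, \lfloor n/10 \rfloor)$ quantile knots; monotonicity is
  imposed through nondecreasing spline coefficients, a sufficient
  condition. Writing the coefficients as a free intercept plus
  cumulative nonnegative increments and profiling the intercept out
  turns the constrained least-squares problem into NNLS
  (Lawson–Hanson, via `pracma::lsqnonneg`). Evaluation outside the
  fitted domain clamps to the boundary value — the curve is never
  extrapolated.
* **Concentration search.** The objective
  $\sum_j (y_j - \mathrm{offset}_j - f(x+d_j))^2$ is scanned on a
  200-point grid over the curve domain extended by one dilution step
  on each side, then refined by golden-section search (`optimize`,
  tolerance $10^{-6}$). If a search bound fits as well as the interior
  optimum (a series stuck on a plateau), the bound is returned with a
  `boundary` flag.
* **Flat series.** A series whose dynamic range is below twice the
  robust replicate noise scale (MAD of within-(sample, dilution)
  replicate deviations; when no replicates exist, 0.1% of the global
  dynamic range) is flagged `flat_series` and excluded from fitting
  rather than forced onto the curve.
* **Determinism.** Spots are processed in a canonical order
  internally, so estimates are bit-identical under input-row
  permutations.

## The extended (normalizing) model

The curve-refit step is replaced by a penalized additive model, fitted
with `mgcv` and REML-selected smoothing parameters:

$$y = \beta_0 + s(u) + s(\mathrm{ctrl}) + s(\mathrm{sypro})
      + a_R R + a_C C + b_{\mathrm{series}} + \varepsilon$$

Each term is optional and switched by a `model_spec()`: `sc1` is the
base model, `sc3` adds the linear row/column covariates $R, C$
(within-block indices, centered), `sc4` adds a per-series random
intercept instead (fitted as a ridge-penalized smooth, the standard
smooth-as-random-effect equivalence). The `ctrl` and `sypro`
intensities enter as penalized thin-plate smooths (10 basis functions)
rather than linear terms, since the channel response need not be
linear. Smooths are centered (sum-to-zero over the data), leaving the
intercept with the intensity scale. The penalized $s(u)$ is *not*
constrained to be monotone — that is the price of the additive
machinery — so the monotone fit remains the base quantification route.

During concentration re-estimation, everything except
$\beta_0 + s(u)$ is subtracted from each spot as an offset, so the
series is matched against the *covariate-adjusted* curve: this is what
makes quantification and normalization simultaneous. Under
`replicate_effect = TRUE` one value is estimated per sample by pooling
the squared error over all its series. A degenerate covariate (fewer
than four distinct values, e.g. an all-zero channel) drops its smooth
with a warning, reducing gracefully to the smaller model.

Normalized intensities subtract the fitted channel smooths from the
raw intensities — none, the `ctrl` smooth, the `sypro` smooth, or both
(the corrections are additive, so their order is immaterial).

### How many refinement passes?

The printed algorithm iterates steps 2–3 twice, and `n_iter = 2` is
the default. The initialization, however, knows nothing about the
covariates: when the control channels leak strongly into the antibody
signal, the initial shifts absorb part of that leakage, and the joint
decomposition between $s(u)$ and the channel smooths takes several
passes to converge (each extra pass costs one GAM fit and one round of
grid searches — little next to the initialization). The
amount-correction study below therefore runs `n_iter = 10`; on data
with mild background this makes no difference.

## Validation machinery

* **Cross-validation criterion.** Dilution *series* (not spots) are
  partitioned into 5 folds, 30 random partitions by default. Per
  fold, the model is fitted on the training series; the training
  estimates fix the least-squares offset aligning the known truth
  (defined only up to a constant) to the estimation scale; the
  criterion is the mean squared deviation of held-out intensities
  from the trained model's prediction at the truth-aligned
  concentration. Held-out predictions exclude the series random
  effect, which is undefined for unseen series. Partitioning by series
  keeps every held-out series genuinely out of sample — spots within a
  series are not exchangeable.
* **Regression criterion.** The REML score of the training fits
  (lower is better at fixed data).
* **Correlation criterion.** Pearson correlation of training
  estimates with the truth.
* **Amount-effect test.** `yNorm ~ dilution * amount` with both as
  factors; the amount main effect is tested by a type-II F test
  (amount after dilution). A significant effect on normalized
  intensities means deposited-amount variation survived normalization.
* **Spatial-effect test.** `value ~ group + R + C` with $R, C$ linear
  and one factor level per deposited mixture (sample × dilution step);
  type-II F tests for each spatial covariate. Grouping at the
  deposit level keeps dilution-curve variation out of the residual;
  grouping by sample alone would leave the test badly underpowered.
* **Variance components.** Per-(sample, array) estimates decompose as
  sample fixed effects + array random intercept + residual, by REML
  (`lme4`); the residual variance is the intra-array variability that
  drives the replicate power analysis. A single array leaves the
  inter-array component inestimable (`NA`).
* **Power.** Closed-form noncentral-*t* power of the two-sided
  two-sample pooled-variance *t* test: $\nu = 2n-2$,
  $\lambda = \delta / (\sigma\sqrt{2/n})$,
  $\mathrm{power} = P(T_{\nu,\lambda} < -t_{\nu,1-\alpha/2}) +
  P(T_{\nu,\lambda} > t_{\nu,1-\alpha/2})$; at $\delta = 0$ this
  equals $\alpha$ exactly.
* **Dilution-design study.** The model is refitted keeping only the
  $k$ most concentrated steps; criteria are compared across $k$ with
  the CV criterion restricted to the two most concentrated spots per
  series — the spots all subsets share.

## The simulator

`simulate_rppa_experiment()` emulates a two-block spike-in design:
by default 15 two-fold dilutions starting at 1 mg/ml, 6 technical
replicates, two 40×40 blocks with randomized spot placement (with an
even replicate count the second block repeats the first block's
layout, i.e. replicate superarrays). The generative model is the
extended model read forward:

* total protein per spot = amount multiplier × dilution factor;
* `ctrl` and `sypro` channels are affine in total protein with their
  own multiplicative noise (defaults: ctrl 300 + 1500·t, sypro
  1000 + 20000·t, CV 5%) — both channels therefore discriminate
  starting amounts, and they are mutually correlated through total
  protein, as on real slides;
* the antibody signal is the logistic curve value times a
  multiplicative log-normal factor of stated CV, plus `ctrl_effect` ×
  observed ctrl + `sypro_effect` × observed sypro, plus linear
  row/column gradients, plus an additive noise floor. Planting the
  leakage on the *observed* channel intensities makes the additive
  structure the model assumes exactly true — simulation results
  therefore measure estimation quality, not model misspecification.

Real arrays deviate from this in ways the simulator deliberately does
not model: non-additive channel leakage, pin-tip and evaporation
artifacts, image-segmentation errors, and inter-slide variation
(a single slide is simulated). Passing tests on simulated data show
the algorithms do what they claim under the stated model, not that
the model captures every property of a given laboratory's slides.

Noise realism: reported CVs on such arrays are strongly
intensity-dependent (high CV near background, a few percent for
bright spots). The constant-CV term models the bright-spot regime and
the additive floor produces the rising CV at low intensities; studies
that depend on realistic bright-spot precision use CV 4% with floor
sd 100.

## Study conditions used by the shipped analyses

The acceptance script and test suite rerun the package's headline
analyses at sizes chosen to finish on one CPU in minutes; all
quantities are computed fresh at run time.

* recovery: 20 samples × 5 dilutions × 3 replicates, noise CV 10%;
* covariate benefit: 10 samples × 5 × 2 with planted ctrl/sypro
  leakage, 30 CV repeats;
* amount correction: 5 starting amounts 0.8–1.2 mg/ml × 8 dilutions
  × 3 replicates plus 5 regular samples, 200 simulations;
* spatial removal: gradients of 25/−20 intensity units per
  row/column index on an 8 × 8 × 3 design, 100 simulations;
* calibration: 1000 null simulations per effect test;
* dilution study: shifts evenly spaced in [−1.2, 1.2] so every series
  stays within the curve's dynamic range even at $k = 2$ (with wide
  random shifts, weak series are flagged flat at small $k$ and their
  selective exclusion would bias the comparison).

## Known limitations

* Expression values are relative within one array; no inter-slide
  normalization is attempted.
* The additive-model curve is unconstrained, so a fitted $s(u)$ can
  be locally non-monotone at the dim end of the dynamic range.
* The exact sub-model grid of the four model families is exposed as
  orthogonal switches (`spatial`, `replicate_effect`, `use_ctrl`,
  `use_sypro`) rather than fixed names; `sc2` is deliberately not
  given a canonical meaning and `custom` is preferred when switching
  terms individually.
* Boundary-flagged series (outside the observable concentration
  range) carry the search-bound value; downstream analyses should
  treat them as censored, not as measurements.
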
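---
title: "Methods: mapping vine stem water potential from six-band UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping vine stem water potential from six-band UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinepsi)
```

## The problem

Midday stem water potential (psi, MPa) is the standard field measure of
vine water status: a pressure-chamber reading on individual plants, with
more negative values meaning more stress.  It is accurate but pointwise —
it cannot describe how water status varies across a vineyard, which is
exactly what site-specific irrigation needs.  `vinepsi` implements a
pipeline that estimates psi for every canopy pixel of six-band
(530, 550, 570, 670, 700, 800 nm) UAV imagery, calibrated against
plot-level pressure-chamber readings from a deficit-irrigation trial with
four treatment classes: T0 (no stress, psi > -0.8 MPa), T1 (moderate,
-1.1 to -0.9), T2 (strong, -1.4 to -1.2) and T3 (severe, below -1.4).

The pipeline has five stages, each usable on its own:

1. **Radiometry** — raw digital numbers to reflectance via a white
   reference panel (`calibrate_panel()`, `apply_calibration()`).
2. **Segmentation** — soil vs canopy by a double-normal fit to the NDVI
   histogram and thresholding at the inter-peak occurrence valley
   (`segment_canopy()`).
3. **Spectral indices** — thirteen conventional indices, per pixel
   (`compute_index()`), used as linear baselines.
4. **Perceptron regression** — a one-hidden-layer MLP of psi on per-plot
   mean canopy reflectances, tuned by a restart-based hyperparameter grid
   and a band-ablation study (`train_mlp()`, `grid_search()`,
   `ablation_study()`).
5. **Mapping** — per-pixel prediction, four-class stress classification
   and per-plot aggregation (`predict_map()`, `classify_stress()`,
   `aggregate_plots()`).

No field imagery ships with the package; a seeded synthetic vineyard
generator (`generate_scene()`) provides scenes with the statistical
structure the analysis assumes, so every stage is testable end to end.

## Radiometric normalization

Calibration is single-point empirical-line with gain only: for band $b$,
$\rho_b = \mathrm{DN}_b \cdot s_b$ with
$s_b = \rho_\text{panel} / \overline{\mathrm{DN}}_{\text{panel},b}$.
A gain-only model is the right match for a workflow that images a single
white Spectralon panel and no dark reference; an offset would be
unidentifiable.  Reflectances above 1.2 are flagged and counted but not
clipped — values that high normally indicate a mis-located panel region,
which the user should fix, rather than pixels that should be silently
altered.

## Soil–canopy segmentation

Vineyard NDVI histograms are bimodal: a soil mode at low NDVI and a
canopy mode at high NDVI.  We fit the two-component Gaussian mixture
density $w_1 N(\mu_1,\sigma_1) + w_2 N(\mu_2,\sigma_2)$ to the binned
density (default 100 bins over $[-1, 1]$) by nonlinear least squares
(`minpack.lm::nlsLM`), initialized from a 2-means split of the binned
values.  Fitting the curve rather than reading the raw histogram makes
the threshold robust to bin noise; the observed minimum-frequency bin is
retained as a cross-check (the two agree to about a bin width on
well-separated mixtures).  The threshold is the argmin of the fitted
density on $[\mu_1, \mu_2]$, located by dense grid search (step
$10^{-4}$, ties toward lower NDVI).  Canopy is NDVI *strictly above* the
threshold: the valley bin belongs to neither population, so boundary
pixels are excluded from "pure canopy".

Degenerate (unimodal) input is detected two ways: coincident component
means (within $10^{-3}$) or a vanishing weight (below 0.01), and — since
a least-squares fit of two Gaussians to a unimodal histogram often splits
the mode into two heavily overlapping components instead of collapsing —
the absence of an actual density dip between the fitted means.  Either
raises an error rather than returning a meaningless threshold.

## Spectral indices

`index_catalogue()` carries all thirteen formulas in two dialects.  The
`"printed"` dialect (default) follows the compiled index table of the
source literature *exactly as printed*, which includes two quirks worth
stating plainly:

* RDVI as printed is identical to NDVI.  The canonical renormalized
  difference index divides by $\sqrt{R_{800}+R_{670}}$ instead.
* MSR as printed is $(r - 1)/(r + 1)$ with $r = R_{800}/R_{670}$; the
  canonical modified simple ratio uses $\sqrt{r} + 1$ in the denominator.

The `"canonical"` dialect switches those two formulas to their canonical
forms; everything else is identical in both dialects.  MCARI2's
denominator is read as
$\sqrt{(2R_{800}+1)^2 - 6(R_{800} - 5R_{670}) - 0.5}$, i.e. the $-0.5$
inside the root — the printed rendering is ambiguous and this reading is
documented rather than hidden.  Divisions by zero and negative root
arguments yield nodata, never infinities, so downstream statistics skip
degenerate pixels instead of propagating them.

## The perceptron and its training protocol

The regression core is a single-hidden-layer perceptron: sigmoid hidden
units, linear output, trained by full-batch back-propagation for an
*exact* number of epochs.  Inputs and target are standardized to zero
mean and unit variance before training (essential for gradient descent on
reflectances of order $10^{-1}$ and psi of order $-1$); predictions are
mapped back to MPa.

Hyperparameters are chosen by exhaustive grid search: hidden nodes 2–20,
epochs 100–5000 in steps of 100, each combination trained 20 times from
independent seeded uniform$(-0.5, 0.5)$ initializations.  Restarts guard
against poor local minima; the combination with the lowest *mean* RMSE
across restarts wins (mean, not min, so a combination cannot win on one
lucky draw), with ties broken toward fewer nodes, then fewer epochs —
parsimony.  The full 950-combination grid is supported; the package's
desk-scale default (`grid = "reduced"`) is nodes 2–8, epochs 100–1000,
5 restarts, which the synthetic study conditions comfortably support.
The grid RMSE is computed on the calibration set: the protocol as
described selects by training fit, and over-fitting control comes from
the restart/grid structure and the held-out validation, not from an inner
split.

Every restart seed is a pure function of the configuration seed and the
restart index, and every grid combination's seed is a pure function of
the search seed and the combination (`grid_combo_seed()`).  Two
consequences: the whole search is reproducible bit for bit, and any
single combination can be replayed in isolation — which is how the test
suite verifies the selection against an exhaustive replay.

The learning rate defaults to 0.5.  With standardized data and
mean-gradient updates this is stable for networks of this size, and
measurably necessary: at a rate of 0.01 the network is still far from
convergence after the largest epoch count in the grid (training R²
roughly 0.88 versus 0.99 on a smooth nonlinear target at 1000 epochs).
The rate, activation and batch regime are all config-exposed
(`ann_config()`), since none of them is pinned down by the protocol
itself.

### Band ablation

`ablation_study()` trains seven models: ANN-1 on all six bands, then
ANN-2 through ANN-7 each omitting exactly one wavelength (530, 550, 570,
670, 700, 800 nm in that order).  Each subset gets its own full grid
search on the calibration rows; each selected model is then scored on the
held-out validation rows.  Comparing the seven validation reports ranks
each band's contribution.

## Validation statistics

The split holds out, for every treatment, one randomly chosen repetition
— all of its observations across all flights.  With four treatments of
four repetitions this realizes a 25% validation fraction; the commonly
stated "80/20" is not achievable under a one-repetition-per-treatment
rule with four repetitions, so the rule is implemented as stated and the
realized fraction reported.

`evaluate()` computes, for observed $O$ and predicted $P$:
MAE $= \overline{|P-O|}$; RMSE $= \sqrt{\overline{(P-O)^2}}$;
RE $= 100\cdot\overline{(P-O)/O}$ %; the modified (absolute-value) index
of agreement
$d = 1 - \sum|O-P| \,/\, \sum(|P-\bar O| + |O-\bar O|) \in [0,1]$;
and R² as the squared Pearson correlation of the observed-vs-predicted
scatter.  The RE sign convention follows from $O < 0$: a model that
over-estimates psi (predicts less negative than observed) produces a
negative RE.  RE is undefined at $O = 0$ and such input is rejected.

## Stress classification

The four treatment definitions leave the intervals $(-0.9, -0.8)$ and
$(-1.2, -1.1)$ unassigned.  `classify_stress()` sends gap values to the
nearer boundary and ties (the midpoints $-0.85$, $-1.15$) to the more
stressed class, yielding a monotone rule: T0 above $-0.85$; T1 down to
$-1.15$; T2 down to $-1.4$ inclusive; T3 below.  Per-pixel predictions
are clamped to a plausibility range (default $[-2.5, 0]$ MPa, matching
the span a field map can plausibly show) with clamp counts logged —
perceptrons extrapolate poorly outside their training reflectance range
and silent extrapolation would poison plot means.  Plot classification
uses the plot's mean psi over border-eliminated core pixels.

## The synthetic scene generator

`generate_scene()` emulates the structure the analysis relies on and
nothing more: vertical canopy stripes (2.5 m row spacing, 1.5 m vine
spacing, 6 cm pixels; 12-px stripes giving ~28% cover within the planted
block, ~26% over the whole image with its soil margins) on a soil
background; a completely randomized assignment of four treatments to
4 × 4 plots; one psi draw per plot and flight, uniform in the treatment's
range (psi is measured per plot, so within-plot variation enters only
through noise); and multiplicative Gaussian noise truncated at $\pm 3$
standard deviations (reflectance noise scales with signal, and truncation
keeps reflectance positive), default cv 0.05.

Canopy reflectance responds to stress through per-band scaled-logistic
curves: band $b$ is $\rho_b(\psi) = \rho_b^0 \, (1 + a_b \,
\mathrm{logit}^{-1}((s - m_b)/w_b))$ with $s = -\psi$.  The default
amplitudes make 800 nm fall and 670 nm rise with stress (the classic
canopy signature), and give 550, 570 and 700 nm distinct midpoints and
widths so the six-band-to-psi map saturates at different stress levels in
different bands.  That joint nonlinearity is the point: no single linear
index of the bands is a sufficient statistic for psi, so a nonlinear
learner has something real to gain — without it the ANN-vs-index
comparison would be vacuous.  All curve parameters live in the config
(`stress_response_default()`), not in code, so tests can compute oracles
from them.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: radiative transfer, shadows and view geometry,
registration error between bands, within-plot heterogeneity of water
status, soil moisture variation, and any real vine's spectral response to
psi (which is unknown for this sensor; our curves are a modeling choice,
stated as such).  Passing the recovery tests shows the pipeline's
machinery is correct and self-consistent, not that field R² of any given
magnitude is attainable.

## Numerical choices and degenerate inputs

* Mixture fit: least squares on binned densities, deterministic
  moment-based initialization; an EM fit on raw pixels would be an
  acceptable alternative backend provided it passes the same
  parameter-recovery tests.
* Valley search: fixed $10^{-4}$ grid; ties to lower NDVI.
* Constant regression target: flagged, R² reported as undefined (`NA`)
  rather than 0 or 1.
* Non-finite training loss (learning-rate blow-up) raises an error naming
  the cause rather than returning garbage weights.
* TIFF encoding: 32-bit samples are integer-normalized to $[0,1]$ by
  libtiff, so stacks are stored with a recorded scale factor and a
  validity page (quantization ~$2^{-32}$ of the scale, far below float32
  resolution).

## Problem sizes

The package's own test and example runs use the generator's default trial
(4 treatments × 4 repetitions, 5 flights → 80 plot-flight observations;
624 × 360 px scenes) with the reduced grid, which a laptop core handles
in minutes.  The full 950-combination, 20-restart grid is available
through `grid = "full"` and scales linearly.

## Worked example

```{r example, eval = FALSE}
cfg <- scene_config(seed = 1)            # the default synthetic trial
tab <- build_feature_table(cfg, n_flights = 5)
abl <- ablation_study(tab, seed = 1)     # reduced grid by default
abl

scene <- generate_scene(cfg)
seg <- segment_canopy(scene$stack)
best <- abl$models[[which.min(abl$summary$rmse)]]
smap <- predict_map(best, scene$stack, seg$mask)
aggregate_plots(smap, scene$layout)
```

## Known limitations

* The MLP is plain gradient descent; momentum or second-order methods
  would converge faster but are deliberately outside the protocol.
* Grid selection on calibration RMSE can favour large architectures when
  the calibration set is small; the validation report, not the grid
  record, is the quality claim.
* The segmentation assumes a genuinely bimodal NDVI field; mixed pixels
  at canopy edges are excluded by the strict-inequality threshold but not
  otherwise modeled.
* Border elimination is layout-driven (explicit core rectangles); no
  attempt is made to infer border extent from imagery.
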
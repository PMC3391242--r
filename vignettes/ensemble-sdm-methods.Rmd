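---
title: "Ensemble species distribution modelling on atlas grids: methods and design"
author: "gridsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble species distribution modelling on atlas grids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Atlas data record species presence per map grid cell (here the ~11 x 11 km
scale typical of national topographic-map grids) rather than per sampling
site. For freshwater fish this grain is often dismissed because river
networks are dendritic, yet grid-cell occurrence maps are widely available
where site data are not. `gridsdm` implements a complete ensemble framework
for this setting: explicit predictor selection, four niche-model engines,
repetition-based validation, majority-vote consensus mapping, clustering of
species' environmental responses, and climate-scenario projection with an
explicit account of where the projections are extrapolations.

Because real atlas data of this kind are licensed and not publicly
deposited, the package ships a synthetic-grid module as a first-class,
tested component. Virtual species with *known* logistic niches make every
downstream stage verifiable against ground truth.

## The synthetic grid and what it does (not) emulate

`generatePredictorGrid()` builds each continuous field as a low-order
spatial trend plus Gaussian-smoothed noise. This reproduces the smooth
climate/altitude gradients of a temperate study region without geostatistics
machinery. Altitude is positively skewed and high in the south; annual mean
temperature follows a northing trend minus an altitude effect; precipitation
rises with altitude; cumulative upstream river length is right-skewed;
Strahler order is a discretised monotone transform of cumulative length plus
noise (hence positively correlated with it, as hydromorphologic predictors
are in practice); the ~10-level river-type and 7-level land-use fields are
quantile-binned smooth latent fields, giving spatially coherent categorical
mosaics.

The climate fields are calibrated so their grid means equal a 20th-century
central-European baseline (annual mean temperature 8.4 degC, isothermality
3.1, temperature seasonality 63.7 degC^2, annual precipitation 732.1 mm,
maximum temperature of the warmest month 22.7 degC, precipitation
seasonality 20.7). The bundled `defaultScenarios()` express three
general-circulation-model projections for the 2050s (ECHAM5, HadCM3,
IPSL-CM4 under SRES A1b) as additive shifts against exactly this baseline
(+2.4 to +2.7 degC on annual mean temperature, -15.8 to -18.7 mm on annual
precipitation, etc.), so scenario arithmetic on synthetic grids lands on the
documented future means (e.g. 8.4 + 2.4 = 10.8 degC). Means are matched
exactly; ranges only approximately, because a single affine map cannot pin
both.

Two structural choices deserve emphasis:

* **A designated independent core.** `corePredictors()` names the fields
  built to satisfy the pairwise correlation cap among themselves; the
  remaining climate fields (maximum temperature, wettest/driest-quarter
  temperatures, diurnal range) are deliberately collinear with a core field
  so the correlation filter has realistic work to do. The categorical
  river-type field is tilted by altitude but kept well below the cap
  against it — a niche-defining predictor that the screening stage removed
  would silently change the study design.
* **Smoothness is a knob, not a claim.** Real atlases do not state the
  spatial autocorrelation of their predictors; the smoothing radius is
  exposed as a parameter (scaled to the lattice by default) rather than
  asserted as realistic.

What the generator does *not* emulate: observation error and imperfect
detection, spatial autocorrelation of the *residual* occurrence process
(presences are independent Bernoulli draws given the niche), dispersal
limitation, and the dendritic connectivity of real river networks. Passing
tests therefore demonstrate that the pipeline recovers what it should under
its own model assumptions, not that those assumptions hold for real fish
atlases.

## Virtual species

`defaultNiches()` defines six species spanning the thermal spectrum: two
cold-adapted (one linear, one with a unimodal cold optimum), two
warm-adapted (one with substrate preferences through river-type offsets),
and two climate-neutral species driven by hydromorphology and topography
only. Coefficients are expressed per standard deviation of the supplied
grid's fields (a unit a niche modeller can reason about) and intercepts are
solved by root finding so each species hits a target prevalence of
0.25-0.40 — comfortably above the >50-presence inclusion filter at atlas
scale, and strong enough (per-predictor effects of 1.2-2.2 SD, attainable
AUC ~0.85-0.95) that a well-implemented engine can clear the
validation-ROC projection gate. The exact per-cell occupancy probability is
returned alongside the draws, which is what lets tests compare model
performance against the attainable (Bayes) AUC.

## Predictor selection

Selection proceeds in the order a practitioner would use:

1. **Univariate screen.** `univariateAUC()` is the rank-based (midrank
   tie-corrected) AUC folded as `max(AUC, 1 - AUC)`, so monotonically
   decreasing predictors score symmetrically. Categorical predictors are
   scored by per-level presence frequency.
2. **Correlation capping.** `correlationFilter()` greedily eliminates
   predictors until all retained pairwise associations are below 0.75.
   Mixed types use the standard analogues on a common [0, 1] scale:
   Pearson |r| between numeric pairs, Cramer's V between categorical pairs,
   the correlation ratio (eta) for mixed pairs. Within any violating pair
   the lower-ranked (by mean univariate AUC) predictor is dropped, ties
   broken alphabetically; greedy rather than optimal elimination matches
   the iterative, univariate-supported screening it implements, and the
   output is re-checked against the cap.
3. **PCA representatives.** For a redundant thematic block,
   `pcaRepresentatives()` standardises the columns and returns the
   predictor most correlated with each leading component, with
   explained-variance fractions.
4. **Three-criteria relevance rule.** A predictor is relevant when at least
   two of: mean univariate ROC >= 0.65; mean permutation importance >= 5%;
   selected by the models for at least half the species. "At least half" is
   read conservatively as `n_selected >= ceiling(nSpecies / 2)`. The rule
   is a pure function of the three statistics, exercised in the tests
   against a bundled 15-predictor, 38-species reference summary
   (`atlasScreeningSummary()`).

A caveat the package documents rather than hides: applied to the bundled
reference summary, the rule marks the mean diurnal temperature range as
relevant (it passes the importance and count criteria), although that
predictor is conventionally dropped in favour of isothermality, its
derived cousin. The rule as stated cannot reproduce that exclusion from
the three printed statistics alone; how the criteria interact with the
earlier PCA/correlation stage is left open by the screening procedure the
rule codifies, and the test suite flags (rather than patches) the
discrepancy.

## The four engines

All engines receive the same offered predictor set, record the calibration
range of every predictor they use, and emit per-cell probabilities in
[0, 1] so one thresholding scheme applies to all.

* **GLM** — binomial logit-linear model; bidirectional stepwise AIC from
  the intercept-only start. Complete separation (deviance collapsing to
  zero) triggers a warning and a ridge fallback (glmnet, penalty 1e-4 on
  the standardised scale), flagged in the model blob.
* **GAM** — each continuous predictor enters through a natural cubic spline
  basis with exactly 4 degrees of freedom, knots at calibration quantiles;
  no smoothing-parameter search (the df is fixed by design, so penalised
  smoothing would be a different model). Stepwise AIC operates on whole
  term blocks, the AIC df being the basis columns. Predictors with fewer
  than 8 distinct values are demoted to linear terms with a warning.
* **RF** — bagged classification trees (ranger backend; 500 trees, one
  bootstrap per tree), probability = fraction of trees voting presence,
  obtained from per-tree predictions rather than terminal-node averaging.
  AIC is undefined for bagged trees, so the parsimonious-model search is a
  forward selection on out-of-bag misclassification with a
  one-standard-error stopping rule — the closest tree-ensemble analogue of
  stepwise AIC's intent. Deterministic given the seed.
* **ME** — presence-only maximum entropy: a Gibbs distribution over all
  grid cells whose feature expectations match the presence sample, fitted
  by L1-penalised presence log-likelihood via proximal gradient descent.
  Features are standardised linear + quadratic terms of numeric predictors
  (quadratics give unimodal response capability) and level indicators for
  categorical ones; standardisation makes the output invariant to affine
  rescaling of inputs. The penalty `reg` applies to the total presence
  log-likelihood, so stationarity ties feature-expectation residuals to
  `reg / n_presences`. Cell suitabilities are divided by the maximum
  calibration-background Gibbs weight (and capped at 1 on new data) so that
  thresholds are comparable across engines.

## Validation and thresholding

`makeSplits()` partitions cells 70/30 into calibration/validation,
independently 10 times. Thresholds are estimated on calibration predictions
only — the validation sample would otherwise leak into the reported
validation scores. `chooseThreshold()` scans all unique predicted values
and picks the threshold maximising `min(sensitivity, specificity)`, ties
broken by the smallest |sensitivity - specificity| and then the smallest
threshold; this is the scheme that maximises both rates simultaneously and
typically yields near-equal values. Performance is banded on the
conventional scale (0.5-0.6 fail ... 0.9-1 excellent), intervals
left-closed.

Permutation importance follows the permutation-correlation definition: for
each predictor, the mean Pearson correlation `r` between original
predictions and predictions on data with that predictor permuted; raw
importance `max(0, 1 - r)`, normalised to percentages summing to 100 per
model. Pearson (not Spearman) correlation is used, and normalisation to
percentage shares is chosen so that per-model profiles are comparable —
both are deliberate choices where the underlying convention is loose.
Predictors a model never used leave predictions unchanged (`r = 1`), hence
PI exactly 0.

## Consensus and response clustering

Consensus operates on *binary* member maps (threshold first, vote second):
a cell is presence only if strictly more than 50% of members predict it, so
exact ties on even ensembles fall to absence. The current-condition
ensemble pools engines x repetitions (30 members with three engines); the
joint future ensemble pools engines x repetitions x scenarios (90 members).
The presence-only engine is excluded from consensus by default because its
validation performance varies with occurrence frequency, which undermines
the niche-stability assumption projection rests on; it remains fitted and
evaluated.

Species' responses are summarised as shares of grouped permutation
importance — climate (C), altitude (H), hydromorphology (HY) — and grouped
species by fuzzy c-means (c = 4, fuzzifier m = 2, Euclidean distance on the
share simplex; the conventional defaults). The implementation uses the
standard alternating updates, 20 random restarts keeping the best objective,
convergence when memberships move less than 1e-6, and the limit convention
that an item coinciding with a center takes membership 1. Clustering runs
separately per engine so the response structure can be compared across
engines; cluster labels are arbitrary, so reports relabel clusters by
descending mean altitude share for stable output. Clustering on the 3-share
profiles (rather than full per-predictor importance vectors) matches the
grouped-response table the framework reports; the full-vector alternative
is a one-line change on the profile matrix passed to `fuzzyCMeans()`.

## Projection and uncertainty

Only species whose mean validation ROC over the consensus engines reaches
0.8 ("good") are projected. Each fitted model is applied to each shifted
grid with its stored threshold; loss (gain) is the percentage of currently
occupied cells vacated (newly occupied), both relative to the current
count, so gain can exceed 100. Change tables follow three marginal
averaging schemes: engine rows average over scenarios, scenario rows over
engines, and the "Mean" row compares the joint all-pairs consensus against
the current consensus.

`rangeMismatch()` reports, per predictor used by a species' models, the
percentage of cells whose projected value leaves the calibration range,
and the percentage of cells where at least one predictor does (the union,
hence never smaller than any per-predictor value). The calibration range
per species-predictor is the union across repetitions (min of mins, max of
maxes) — the least conservative choice consistent with reporting one range
per species and predictor; whether the original screening used all cells
or split cells is not determinable, and this choice is the explicit one.
Only continuous/ordinal predictors participate: a categorical predictor
has no range to leave, and a genuinely novel level is a prediction error
rather than a mismatch percentage.

## Numerical and reproducibility choices

* Every stage derives its seed from the master seed through a 31-bit
  polynomial hash of a label path (`deriveSeed(master, "GLM", species,
  repetition)`), so streams never collide and any stage can be re-run in
  isolation bit-identically.
* AUC uses midrank tie correction, making it exactly the normalised
  Mann-Whitney statistic (the tests assert |difference| < 1e-12 against a
  pair-counting oracle).
* Degenerate inputs are handled by contract: single-class truth is an
  error; an all-equal probability vector yields a degenerate threshold
  with a warning; a constant prediction vector makes the importance
  profile undefined (warning, zeros); an all-zero grouped importance
  profile excludes that species from clustering for that engine.
* Default problem sizes: the shipped study conditions are 2,935 cells, six
  virtual species, four engines, ten repetitions, three scenarios.
  Importance profiles are computed on the first repetition's models over a
  1,000-cell subsample with 20 permutations per predictor — permutation
  importance converges quickly in the cell dimension, and profiling every
  repetition would dominate runtime without changing the shares reported.
  Unit tests use 400-600-cell grids.

## Known limitations

* Predictor substitution: when a truth-relevant predictor is correlated
  with a climate field, engines can partially substitute the climate field
  and a nominally climate-neutral species then shows small but non-zero
  projected change. This is a property of correlative SDMs, not a code
  defect; the mismatch report is the tool for judging how far such
  projections extrapolate.
* The additive engines (GLM/GAM) can predict occurrence where one factor
  alone should veto it; no tolerance-limit veto is applied.
* No dispersal constraints, barriers, or species interactions; loss/gain
  figures are potential-habitat arithmetic, not demographic predictions.

## Example

```{r example}
library(gridsdm)
cfg <- pipelineConfig(seed = 1, nCells = 600, reps = 3)
bundle <- runPipeline(cfg)
aggregate(roc_validation ~ engine, bundle$evaluation, mean)
bundle$changeSummaries
writeReportBundle(bundle, "reports")
```
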
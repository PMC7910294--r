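---
title: "Methods: plate normalization, quality statistics and the tiered hit funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate normalization, quality statistics and the tiered hit funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenfunnel)
```

## The problem

Cell-based phenotypic screens of approved-drug libraries look for compounds
that modulate an induced inflammatory response. The motivating assay treats
human brain pericytes with library compounds, stimulates with IL-1β, and
reads out two immunofluorescence channels per well — CCL2 (a chemokine) and
ICAM-1 (an adhesion molecule) — as integrated intensity per Hoechst-counted
cell. `screenfunnel` implements the computational side of that workflow:
per-plate normalization, assay-window statistics, the tiered advancement
rules that turn thousands of wells into a short list of candidate
modulators, four-parameter logistic (4PL) machinery for stimulus
calibration and immunoassay standard curves, and the downstream
quantification arithmetic (bead panels, membrane arrays, ΔCt ratios).
Because no machine-readable plate data accompany the motivating study, a
seeded synthetic-screen generator with known ground truth is a first-class
module: every pipeline stage is tested against planted truth rather than
against archived outputs.

## Plate normalization

Fluorescence screens show multiplicative plate-to-plate variation in both
cell number and absolute intensity. Each plate therefore carries internal
controls, and every well's per-cell intensity is divided by the mean
per-cell intensity of that plate's stimulated-vehicle wells (IL-1β + DMSO),
per channel:

$$a_{w,c} = \frac{I_{w,c}}{\overline{I}^{\,stim}_{c}},\qquad
  r_w = \frac{n_w}{\overline{n}^{\,stim}}$$

The resulting *activity* is 1 for an inert compound, below 1 for
attenuation and above 1 for induction; the *cell ratio* $r_w$ plays the
same role for counts. Division by a plate-level reference removes any
common multiplicative plate factor exactly — this invariance is asserted in
the test suite. Wells with zero cells have no defined per-cell intensity;
they are flagged, given cell ratio 0, and excluded from all statistics
rather than imputed. For the stimulus-independence tier (compounds without
IL-1β) the unstimulated vehicle is the anchor, since no induced reference
exists.

## Assay quality: the screening-window coefficient

Plate quality is summarised by the screening-window coefficient

$$Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}$$

between stimulated-vehicle (positive) and unstimulated-vehicle (negative)
controls, with sample ($n-1$) standard deviations — appropriate for the
small per-plate control counts. $Z' \le 1$ always; it is symmetric in the
two groups and invariant to common shifts and rescalings. The term
"Z-score" is sometimes used loosely for this statistic in the screening
literature; the values it takes (e.g. 0.43 and 0.15 for the two channels
of the motivating screen) are only meaningful for the window coefficient,
not for standardized z-scores, so `zprime()` implements the window
coefficient. Both granularities are exposed: per plate and pooled across a
tier's plates after normalization. Pearson correlation between the two
channels' compound-well activities (`channel_concordance()`) checks that
both readouts track the same underlying modulation.

## The hit funnel

Advancement uses threshold rules, not hypothesis tests, applied per
compound in a fixed order:

1. **Cytotoxicity** — mean cell ratio at or below 0.5 (≥ 50% cell loss)
   excludes the compound before any effect is considered, so cell-loss
   artifacts can never be reported as inhibition.
2. **Effect with acceptable variability** — a channel *qualifies* when its
   mean activity changes by at least 20% in either direction
   (|percent change| ≥ 20, inclusive) with replicate CV below 15%
   (SD as a percent of the mean, strict). Any qualifying channel makes the
   compound a hit; the direction is taken from the larger-magnitude
   qualifying channel, and both channels' values are always reported.
3. **Variability exclusion** — if no channel qualifies cleanly but some
   channel's CV is at or above 15%, the compound is `excluded_variable`
   rather than `not_hit`: it is too noisy to call either way. A clean
   qualifying channel rescues a compound whose other channel is noisy.
   This ordering — hit calls before variability exclusion — is a design
   choice; the alternative (any noisy channel blocks the compound even
   when the other channel is clean) discards interpretable single-channel
   evidence.

The primary tier uses duplicate wells, the secondary tier triplicates; a
compound confirms only if it advanced from the primary tier *and* passes
again. The tertiary tier ranges each confirmed hit over 0.1, 1 and 10 µM
and `dose_select()` picks the dose with maximal absolute change among
doses without disqualifying cell loss (ties: higher cell ratio, then lower
dose). The independence tier re-screens without stimulation, normalised to
the unstimulated vehicle, and flags compounds whose basal effect exceeds
the same 20% threshold — such compounds act on the cells directly rather
than on the stimulus response. Finally `rank_and_diversify()` formalises
the shortlist: hits ranked by maximal |percent change| taken greedily
under a per-therapeutic-class cap, with lexicographic compound-ID
tie-breaks for determinism. The published funnel's last step ("efficacy
as well as diversity in drug type") was a manual judgement; the greedy
rule is this package's declared formalization of it, not a reproduction.

### Numerical boundary handling

Percent changes are compared with a tolerance of $10^{-9}$ percentage
points so that means like 0.80, which are not exactly representable in
binary floating point, sit on the inclusive boundary as intended: mean
activity exactly 0.80 or 1.20 with zero CV is a hit, 0.801/1.199 is not,
and a cell ratio of exactly 0.5 is excluded as cytotoxic.

## Dose–response machinery

The increasing 4PL
$f(x) = b + (t - b)/(1 + (\mathrm{EC}_{50}/x)^{h})$
serves two roles: calibrating the stimulus (the IL-1β concentration
producing half-maximal induction per channel) and as the immunoassay
standard curve. Fitting is nonlinear least squares on log-dose
(`stats::nls`) with data-driven initialization (asymptotes from response
extremes, EC50 from the half-range crossing, Hill slope 1). Two numerical
choices matter:

* The convergence test uses `scaleOffset` so that noiseless
  (zero-residual) data — the round-trip oracle case — converge cleanly
  instead of failing the relative-offset criterion, with `tol` tightened
  to keep parameter recovery at $10^{-6}$ relative error.
* A zero-concentration standard point (the 0 pg/mL point of an 11-point
  bead-array curve) is excluded from the log transform and anchors the
  bottom asymptote through the model function itself.

Inhibition is always represented downstream as activity ratios, never as
descending curves, so $h > 0$ and $t > b$ throughout.
`pick_stimulation_dose()` returns the lowest candidate whose fractional
response $(f(x) - b)/(t - b)$ reaches `min_fraction` (default 0.5,
inclusive) on every channel: a submaximal working point that leaves
headroom to detect both induction and attenuation. The 0.5 default
reproduces the motivating study's choice of 0.05 ng/mL given its EC50s of
0.02 and 0.03 ng/mL; it is exposed as a parameter because the goal, not
the number, is the principle.

## Quantification layer

Bead-array fluorescence is back-calculated through the fitted standard
curve by exact inversion. Readings at or below the curve bottom are
*below detection*: they carry a flag and no numeric value, and are never
substituted with LOD/2 — when a vehicle condition is below detection,
fold changes are not computed and the affected analytes switch to
absolute reporting, mirroring standard panel practice. Readings at or
above the top are censored at the top standard (10,000 pg/mL) with an
`above_range` flag rather than extrapolated, because the inverse curve is
unstable beyond the upper asymptote. Concentrations are normalised per
10,000 cells (`conc × 10⁴ / cells`); the "logged value" used for display
is log10, the conventional scale for pg/mL panels. Membrane arrays are
normalised per blot: duplicate-spot means divided by the mean of the six
reference spots, which makes values exposure-invariant across blots. ΔCt
expression ratios use $2^{-\Delta\Delta C_t}$ against a *named* reference
condition; no default condition is hard-coded because different
experiments anchor at time zero or at untreated. Where a panel spans
several cases, folds are computed per case and then averaged (the
alternative — averaging concentrations before folding — can be had by
pre-aggregating the input).

## The synthetic screen: what it emulates, and what a green test establishes

The generator states a world and the tests measure the pipeline against
it:

* **Layout** — 96-well plates with 80 compound wells (columns 1–10) and
  16 controls (four stimulated-vehicle, four unstimulated-vehicle, two
  TGFβ1 doses, four media-only). Media-only wells carry no cells and no
  signal; they exercise the zero-cell flagging path.
* **Signal model** — per-cell intensity = plate factor × basal level ×
  induction(role, channel) × compound effect × well noise. Intensity
  noise is multiplicative log-normal (unit mean, parameterised by CV)
  because fluorescence is positive and heteroscedastic; cell counts are
  Poisson. The plate factor is shared across channels within a plate,
  reproducing exactly the confound internal normalization removes.
  Defaults: well CV 0.05, plate σ 0.1 (log scale), 2000 cells/well,
  induction fold 5 (so unstimulated vehicle ≈ 0.2 of stimulated), TGFβ1
  inhibition 0.5 at the high dose and half that at the low dose.
* **Truth** — ~10% of compounds are planted modulators with
  |effect − 1| drawn uniformly (default bounds 0.2–0.6), the same effect
  on both channels (the two readouts are co-regulated in the emulated
  biology; channel concordance therefore rises toward 1 as noise
  vanishes); ~5% are cytotoxic with viability in (0.2, 0.5], some of
  which also carry effects so that the exclusion-before-effect rule is
  exercised. Basal effects default to 1 — the stimulus-independence
  check's expected clean outcome.
* **Dose dependence** — at the tertiary tier a compound's effect at dose
  $d$ is attenuated by a Hill factor with a 1 µM midpoint normalised to 1
  at 10 µM, and viability scales as $v^{f(d)}$; a simple, deterministic
  potency model sufficient to test dose selection, not a pharmacological
  claim.
* **Zero-noise determinism** — with both noise terms zero the generator
  replaces Poisson counts by `round(λ × viability)`, making the dataset
  an exact oracle: every normalized activity equals its truth multiplier
  to 1e-12 and the funnel's hit set must equal the truth-derived set
  exactly.

At the default noise, pooled Z′ on normalized activities is ≈ 0.75–0.8;
computed on raw intensities (where the plate factor contributes) it falls
into the 0.1–0.6 band typical of published screens of this kind. The
normalized figure is the honest one for this simulator — normalization
removes the plate factor by construction — and both routes are available.

A green suite establishes that the *rules* are implemented exactly and
that recovery holds under the stated noise; it does not establish that
the simulator reproduces any real screen's plate structure (spatial/edge
effects, channel-specific noise, compound carry-over and
instrument drift are all absent), and no printed result from the
motivating study is recomputable from it.

## Known limitations

* No spatial (row/column/edge) bias modelling or B-score correction — the
  motivating workflow used none, and the simulator plants none.
* The 4PL is symmetric; five-parameter asymmetric curves are out of
  scope.
* Statistical significance testing of per-compound effects is
  deliberately absent: the advancement criteria are threshold rules, and
  standard ANOVA-style analyses belong to general-purpose statistical
  software.
* `rank_and_diversify()` is a formalization of a manual selection step;
  its shortlist should be read as a reproducible proposal, not as the
  only defensible choice.
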
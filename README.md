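# screenfunnel

Analysis pipeline for cell-based phenotypic compound screens read out by
per-cell immunofluorescence — the setting where a library of approved
drugs is tested for modulation of an induced inflammatory response (e.g.
IL-1β-stimulated CCL2 and ICAM-1 expression in human brain pericytes),
and thousands of wells must be triaged to a handful of lead candidates.

The package covers the full computational funnel:

* **Well-table I/O and layout validation** — tidy long-format CSV (one
  row = one well), microplate addressing (A1–H12), role/control checks.
* **Plate normalization** — activities as fractions of each plate's
  stimulated-vehicle mean per-cell intensity, removing multiplicative
  plate effects exactly; cell ratios against control counts.
* **Assay quality** — the screening-window coefficient
  `Z′ = 1 − 3(σₚ + σₙ)/|μₚ − μₙ|` per channel and per plate or pooled,
  TGFβ1 control verdicts, and Pearson concordance between channels.
* **Tiered hit calling** — duplicate primary and triplicate secondary
  screens under the rules: effect ≥ ±20% on either channel (inclusive),
  replicate CV < 15%, cell loss < 50% (cytotoxicity excludes before any
  effect call); dose selection over a 0.1/1/10 µM grid; a
  stimulus-independence check; class-diversified ranking of the final
  shortlist.
* **Dose–response machinery** — four-parameter logistic
  `f(x) = b + (t − b)/(1 + (EC₅₀/x)^h)` fitting on log-dose, exact
  inversion for standard-curve back-calculation, and selection of a
  submaximal stimulation dose leaving headroom to detect induction and
  attenuation.
* **Quantification layer** — bead-panel concentrations from 11-point
  standard curves with below-detection/above-range flags, per-10⁴-cell
  normalization, vehicle fold changes with the below-LOD exception rule,
  six-reference-spot membrane-array normalization, and 2^(−ΔΔCt)
  expression ratios.
* **Synthetic screens with ground truth** — a seeded generator planting
  modulators and cytotoxic compounds under a multiplicative log-normal /
  Poisson noise model, so every stage is testable without external data.

## Worked example

Simulate a 300-compound primary screen (10% planted modulators at 30–60%
effect, 10 cytotoxic compounds) at realistic noise, then run QC and the
primary filter:

```r
library(screenfunnel)

cfg <- sim_config(n_compounds = 300, fraction_modulators = 0.1,
                  effect_bounds = c(0.3, 0.6), fraction_cytotoxic = 10/300,
                  seed = 1)
sim <- simulate_screen(cfg, noise_model(), tier = "primary")
sim$dataset
#> <screen_dataset> tier=primary: 768 wells on 8 plate(s), 300 compound(s)

prim <- run_tier(sim$dataset)
plate_qc(prim$normalized)$screen
#> # A tibble: 1 × 2
#>   zprime_ccl2 zprime_icam1
#>         <dbl>        <dbl>
#> 1       0.786        0.745

head(prim$result[prim$result$verdict != "not_hit",
                 c("compound_id", "percent_change_ccl2", "cell_ratio",
                   "verdict")], 4)
#>   compound_id percent_change_ccl2 cell_ratio verdict
#> 1 CPD0013                   30.5       0.417 excluded_cytotoxic
#> 2 CPD0014                   50.2       1.01  hit_up
#> 3 CPD0020                  -39.7       0.997 hit_down
#> 4 CPD0022                   -8.97      0.461 excluded_cytotoxic
```

CPD0013 shows a +30% apparent induction but loses almost 60% of its
cells, so the cytotoxicity rule excludes it before any hit call; CPD0014
and CPD0020 are genuine bidirectional hits (induction and attenuation).
The pooled Z′ values say the screening window between stimulated and
unstimulated vehicle controls is wide relative to control noise on both
channels. Compare the recovered hit list against the generator's truth
with `hit_ids(prim$result)` and `sim$truth`.

Stimulus calibration picks the working dose from fitted
concentration–response curves:

```r
curves <- list(ccl2 = fourpl(0, 1, 0.02, 1), icam1 = fourpl(0, 1, 0.03, 1))
pick_stimulation_dose(curves, c(0.01, 0.05, 0.5))$dose
#> [1] 0.05
```

With half-maximal concentrations of 0.02 and 0.03, the lowest candidate
giving at least half-maximal response on both channels is 0.05 — a
submaximal working point from which both induction and attenuation are
detectable.

A thin command-line front end over the same functions is installed at
`inst/cli/screenfunnel.R` (subcommands `simulate`, `qc`, `screen`,
`dose`, `blot`, `ddct`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against
the installed package: stimulus calibration from simulated
concentration–response data, a noisy 300-compound primary screen with QC
and truth-recovery statistics, secondary confirmation, dose selection,
the class-diversified shortlist, the stimulus-independence check and the
quantification layer, writing its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
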
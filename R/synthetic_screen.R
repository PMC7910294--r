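# run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# multiplicative log-normal noise with unit mean is parameterised by CV:
# sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2/2
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Simulation configuration for a synthetic screen
#'
#' Describes the compound library and the planted ground truth: how many
#' compounds, what fraction are genuine bidirectional modulators, the bounds
#' of their effect sizes (as |multiplier - 1|), what fraction are cytotoxic,
#' and the dose grid for the concentration-response tier. Defaults emulate a
#' plate-based repurposing screen: a few hundred compounds at 10 uM, ~10%
#' true modulators with 20-60% modulation, ~5% cytotoxic with 50-80% cell
#' loss, and the three-point 0.1/1/10 uM dose grid.
#'
#' @param n_compounds Number of library compounds.
#' @param fraction_modulators Fraction of compounds planted as true
#'   modulators of the stimulated response.
#' @param effect_bounds Bounds on |effect - 1| for planted modulators; the
#'   direction (induction vs attenuation) is drawn at random.
#' @param fraction_cytotoxic Fraction of compounds planted as cytotoxic
#'   (viability drawn in `viability_bounds`).
#' @param viability_bounds Viability multiplier bounds for cytotoxic
#'   compounds; must lie in (0, 0.5] so planted toxins fail the cell
#'   criterion by construction.
#' @param dose_grid Concentrations (uM) for the tertiary tier; strictly
#'   positive and increasing.
#' @param basal_sd Standard deviation of per-compound basal (unstimulated)
#'   log-effects; 0 means every compound is stimulus-dependent
#'   (basal multiplier exactly 1), the outcome the screen design expects.
#' @param seed Integer seed; the whole generator is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 300,
                       fraction_modulators = 0.10,
                       effect_bounds = c(0.2, 0.6),
                       fraction_cytotoxic = 0.05,
                       viability_bounds = c(0.2, 0.5),
                       dose_grid = c(0.1, 1, 10),
                       basal_sd = 0,
                       seed = 1L) {
  stopifnot(n_compounds >= 1,
            fraction_modulators >= 0, fraction_modulators <= 1,
            fraction_cytotoxic >= 0, fraction_cytotoxic <= 1,
            length(effect_bounds) == 2, effect_bounds[1] > 0,
            effect_bounds[2] >= effect_bounds[1],
            length(viability_bounds) == 2, viability_bounds[1] > 0,
            viability_bounds[2] <= 0.5, basal_sd >= 0)
  if (any(dose_grid <= 0) || any(diff(dose_grid) <= 0)) {
    abort("dose_grid must be strictly positive and increasing",
          class = "screenfunnel_config_error")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 fraction_modulators = fraction_modulators,
                 effect_bounds = effect_bounds,
                 fraction_cytotoxic = fraction_cytotoxic,
                 viability_bounds = viability_bounds,
                 dose_grid = dose_grid,
                 basal_sd = basal_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Noise model for the synthetic screen
#'
#' Intensity noise is multiplicative log-normal (fluorescence readouts are
#' positive and heteroscedastic) and cell counts are Poisson. A per-plate
#' log-normal factor shared by both channels reproduces the plate-to-plate
#' variability that internal normalization exists to remove. Induction
#' folds default to 5, so unstimulated vehicle wells sit near 0.2 of the
#' stimulated level — a separation that yields screening-window
#' coefficients in the realistic 0.1-0.6 range at the default noise.
#'
#' When `well_cv` and `plate_sigma` are both zero the generator is fully
#' deterministic: noise factors are 1 and cell counts are
#' `round(cell_lambda * viability)` rather than Poisson draws, so
#' zero-noise datasets are exact oracles.
#'
#' @param plate_sigma SD of the per-plate log-normal factor (log scale).
#' @param well_cv Coefficient of variation of per-well log-normal noise.
#' @param cell_lambda Expected cells per well (Poisson mean).
#' @param induction_fold_ccl2,induction_fold_icam1 Stimulated/basal
#'   intensity ratio for control wells; must exceed 1.
#' @param tgfb_inhibition Fractional inhibition of the induced response in
#'   TGFbeta1 high-dose control wells (the low dose applies half); in
#'   (0, 1).
#' @param basal_intensity Basal per-cell intensity level, arbitrary
#'   fluorescence units.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(plate_sigma = 0.1,
                        well_cv = 0.05,
                        cell_lambda = 2000,
                        induction_fold_ccl2 = 5,
                        induction_fold_icam1 = 5,
                        tgfb_inhibition = 0.5,
                        basal_intensity = 100) {
  stopifnot(plate_sigma >= 0, well_cv >= 0,
            induction_fold_ccl2 > 1, induction_fold_icam1 > 1,
            tgfb_inhibition > 0, tgfb_inhibition < 1, basal_intensity > 0)
  if (cell_lambda <= 0) {
    abort("cell_lambda must be positive", class = "screenfunnel_config_error")
  }
  structure(list(plate_sigma = plate_sigma, well_cv = well_cv,
                 cell_lambda = cell_lambda,
                 induction_fold_ccl2 = induction_fold_ccl2,
                 induction_fold_icam1 = induction_fold_icam1,
                 tgfb_inhibition = tgfb_inhibition,
                 basal_intensity = basal_intensity),
            class = "noise_model")
}

# draw the latent per-compound truth table
draw_truth <- function(config) {
  n <- config$n_compounds
  ids <- sprintf("CPD%04d", seq_len(n))
  n_mod <- round(config$fraction_modulators * n)
  n_tox <- round(config$fraction_cytotoxic * n)
  idx <- sample.int(n, n_mod + n_tox)
  mod_idx <- idx[seq_len(n_mod)]
  tox_idx <- idx[setdiff(seq_len(n_mod + n_tox), seq_len(n_mod))]

  effect <- rep(1, n)
  # modulators: |effect - 1| uniform in bounds, random direction; both
  # channels share the effect (the screen's two readouts are co-regulated)
  if (n_mod > 0) {
    mag <- runif(n_mod, config$effect_bounds[1], config$effect_bounds[2])
    dir <- sample(c(-1, 1), n_mod, replace = TRUE)
    effect[mod_idx] <- pmax(1 + dir * mag, 0.05)
  }
  # cytotoxic compounds may also carry an effect; exclusion must pre-empt it
  if (n_tox > 0) {
    has_eff <- runif(n_tox) < 0.5
    mag <- runif(n_tox, config$effect_bounds[1], config$effect_bounds[2])
    dir <- sample(c(-1, 1), n_tox, replace = TRUE)
    effect[tox_idx][has_eff] <-
      pmax(1 + (dir * mag)[has_eff], 0.05)
  }
  viability <- rep(1, n)
  if (n_tox > 0) {
    viability[tox_idx] <- runif(n_tox, config$viability_bounds[1],
                                config$viability_bounds[2])
  }
  basal <- if (config$basal_sd > 0) exp(rnorm(n, 0, config$basal_sd)) else rep(1, n)
  tibble::tibble(compound_id = ids,
                 effect_ccl2 = effect,
                 effect_icam1 = effect,
                 viability = viability,
                 basal_effect = basal)
}

# 96-well layout: columns 1-10 hold compound wells, 11-12 the controls
plate_layout_controls <- function() {
  tibble::tibble(
    row = c("A", "B", "C", "D", "E", "F", "G", "H",
            "A", "B", "C", "D", "E", "F", "G", "H"),
    col = c(rep(11L, 8), rep(12L, 8)),
    role = c("vehicle_stim", "vehicle_stim", "vehicle_only", "vehicle_only",
             "tgfb_low", "tgfb_high", "media_only", "media_only",
             "vehicle_stim", "vehicle_stim", "vehicle_only", "vehicle_only",
             "tgfb_low", "tgfb_high", "media_only", "media_only"))
}

# dose attenuation of a compound effect relative to its 10 uM value:
# Hill curve with a 1 uM midpoint, normalised so the 10 uM effect is the
# truth multiplier itself
dose_attenuation <- function(dose_um) {
  (dose_um / (dose_um + 1)) / (10 / 11)
}

#' Simulate a tiered phenotypic screen with known ground truth
#'
#' Generates a full plate set for one screen tier. Each 96-well plate holds
#' 80 compound wells (columns 1-10) and 16 control wells (columns 11-12:
#' four stimulated-vehicle, four unstimulated-vehicle, two TGFbeta1 doses,
#' four media-only). A well's per-cell intensity is
#' `plate_factor * basal * induction(role, channel) * effect * noise` and
#' its cell count is Poisson with mean `cell_lambda * viability`
#' (deterministic rounding when all noise is off). The `independence` tier
#' simulates the same paradigm without stimulation: induction is absent and
#' compound wells express the latent basal effect only.
#'
#' @param config A [sim_config()].
#' @param noise A [noise_model()].
#' @param tier `"primary"` (duplicate wells), `"secondary"` (triplicates),
#'   `"tertiary"` (duplicates at each dose of `config$dose_grid`) or
#'   `"independence"` (duplicates, unstimulated).
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `dataset` (a [screen_dataset()]) and `truth`
#'   (tibble: compound_id, effect_ccl2, effect_icam1, viability,
#'   basal_effect).
#' @export
simulate_screen <- function(config = sim_config(), noise = noise_model(),
                            tier = c("primary", "secondary", "tertiary",
                                     "independence"),
                            seed = NULL) {
  tier <- match.arg(tier)
  stopifnot(inherits(config, "sim_config"), inherits(noise, "noise_model"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)

  with_seed(seed, {
    truth <- draw_truth(config)
    replicates <- switch(tier, primary = 2L, secondary = 3L,
                         tertiary = 2L, independence = 2L)
    doses <- if (tier == "tertiary") config$dose_grid else 10
    stimulated <- tier != "independence"

    wells_all <- list()
    plate_counter <- 0L
    for (dose in doses) {
      slots_per_plate <- 80L %/% replicates          # compounds per plate
      n_plates <- ceiling(config$n_compounds / slots_per_plate)
      for (p in seq_len(n_plates)) {
        plate_counter <- plate_counter + 1L
        plate_id <- sprintf("P%03d", plate_counter)
        first <- (p - 1L) * slots_per_plate + 1L
        last <- min(p * slots_per_plate, config$n_compounds)
        ids <- truth$compound_id[first:last]

        slots <- tibble::tibble(
          row = rep(LETTERS[1:8], times = 10),
          col = rep(1:10, each = 8))
        cpd <- rep(ids, each = replicates)
        n_cpd <- length(cpd)
        layout <- slots[seq_len(n_cpd), ]
        layout$role <- "compound"
        layout$compound_id <- cpd
        spare <- slots[setdiff(seq_len(80), seq_len(n_cpd)), ]
        if (nrow(spare) > 0) {
          spare$role <- "media_only"
          spare$compound_id <- ""
          layout <- dplyr::bind_rows(layout, spare)
        }
        ctrl <- plate_layout_controls()
        ctrl$compound_id <- ""
        layout <- dplyr::bind_rows(layout, ctrl)
        layout$plate_id <- plate_id
        layout$concentration_um <-
          ifelse(layout$role == "compound", dose, 0)
        wells_all[[length(wells_all) + 1L]] <- layout
      }
    }
    wells <- dplyr::bind_rows(wells_all)

    ti <- match(wells$compound_id, truth$compound_id)
    att <- dose_attenuation(wells$concentration_um)
    eff_c <- ifelse(is.na(ti), 1, 1 + (truth$effect_ccl2[ti] - 1) * att)
    eff_i <- ifelse(is.na(ti), 1, 1 + (truth$effect_icam1[ti] - 1) * att)
    basal_eff <- ifelse(is.na(ti), 1, truth$basal_effect[ti])
    viab <- ifelse(is.na(ti), 1, truth$viability[ti]^att)

    induction <- function(role, fold) {
      if (!stimulated) return(rep(1, length(role)))
      ifelse(role == "vehicle_only", 1,
      ifelse(role == "tgfb_low", fold * (1 - noise$tgfb_inhibition / 2),
      ifelse(role == "tgfb_high", fold * (1 - noise$tgfb_inhibition),
             fold)))
    }
    cpd_mult_c <- if (stimulated) eff_c else basal_eff
    cpd_mult_i <- if (stimulated) eff_i else basal_eff
    is_cpd <- wells$role == "compound"
    mult_c <- ifelse(is_cpd, cpd_mult_c, 1)
    mult_i <- ifelse(is_cpd, cpd_mult_i, 1)

    zero_noise <- noise$well_cv == 0 && noise$plate_sigma == 0
    plate_factor <- if (zero_noise) {
      setNames(rep(1, plate_counter), sprintf("P%03d", seq_len(plate_counter)))
    } else {
      setNames(exp(rnorm(plate_counter, 0, noise$plate_sigma)),
               sprintf("P%03d", seq_len(plate_counter)))
    }
    pf <- plate_factor[wells$plate_id]
    n <- nrow(wells)
    wells$intensity_ccl2 <- pf * noise$basal_intensity *
      induction(wells$role, noise$induction_fold_ccl2) * mult_c *
      lnorm_noise(n, noise$well_cv)
    wells$intensity_icam1 <- pf * noise$basal_intensity *
      induction(wells$role, noise$induction_fold_icam1) * mult_i *
      lnorm_noise(n, noise$well_cv)

    lam <- noise$cell_lambda * ifelse(is_cpd, viab, 1)
    wells$cell_count <- if (zero_noise) as.integer(round(lam)) else rpois(n, lam)

    # media-only wells carry no cells and no signal
    media <- wells$role == "media_only"
    wells$cell_count[media] <- 0L
    wells$intensity_ccl2[media] <- NA_real_
    wells$intensity_icam1[media] <- NA_real_

    dataset <- screen_dataset(
      wells[, well_table_columns()],
      tier = tier)
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate a dose-response series from a known 4PL curve
#'
#' Draws responses log-normally around the curve value at each dose; zero
#' noise reproduces the curve exactly, making the series a round-trip
#' oracle for [fit_4pl()].
#'
#' @param truth_curve A [fourpl()] curve.
#' @param doses Positive concentrations.
#' @param noise_cv Multiplicative noise CV (0 for exact).
#' @param seed Integer seed.
#' @param replicates Replicate draws per dose.
#' @return Tibble with columns `dose`, `response`.
#' @export
simulate_dose_series <- function(truth_curve, doses, noise_cv = 0, seed = 1L,
                                 replicates = 1L) {
  stopifnot(inherits(truth_curve, "fourpl"))
  if (length(doses) == 0) abort("dose list must be nonempty")
  if (any(doses <= 0)) abort("doses must be positive")
  with_seed(seed, {
    d <- rep(doses, each = replicates)
    tibble::tibble(
      dose = d,
      response = predict(truth_curve, d) * lnorm_noise(length(d), noise_cv))
  })
}

#' Simulate a multiplex bead-array panel with standards
#'
#' Emits, per analyte, the 11-point standard series on the 0-10,000 pg/mL
#' grid (0 plus ten two-fold dilutions from the 10,000 pg/mL top standard)
#' passed through that analyte's standard curve, plus sample fluorescence
#' generated from the true concentrations. The truth table, including the
#' per-cell-normalised value (pg/mL per 10,000 cells), is returned for
#' recovery tests.
#'
#' @param true_conc Named numeric vector: true concentration (pg/mL) per
#'   analyte; nonnegative.
#' @param curves Named list of [fourpl()] standard curves covering every
#'   analyte in `true_conc`.
#' @param cells Cell count used for per-cell normalisation.
#' @param noise_cv Multiplicative noise CV on sample fluorescence.
#' @param seed Integer seed.
#' @return List with `standards` (analyte, conc_pgml, signal), `samples`
#'   (analyte, signal, cells) and `truth` (analyte, true_conc, cells,
#'   per_cell_true).
#' @export
simulate_cba_panel <- function(true_conc, curves, cells = 10000,
                               noise_cv = 0, seed = 1L) {
  if (any(true_conc < 0)) abort("true concentrations must be >= 0")
  stopifnot(all(names(true_conc) %in% names(curves)), cells > 0)
  for (cv in curves) {
    stopifnot(inherits(cv, "fourpl"))
  }
  std_grid <- c(0, 10000 / 2^(9:0))
  with_seed(seed, {
    standards <- dplyr::bind_rows(lapply(names(true_conc), function(a) {
      tibble::tibble(analyte = a, conc_pgml = std_grid,
                     signal = predict(curves[[a]], std_grid))
    }))
    samples <- dplyr::bind_rows(lapply(names(true_conc), function(a) {
      tibble::tibble(
        analyte = a,
        signal = predict(curves[[a]], true_conc[[a]]) *
          lnorm_noise(1, noise_cv),
        cells = cells)
    }))
    truth <- tibble::tibble(
      analyte = names(true_conc),
      true_conc = as.numeric(true_conc),
      cells = cells,
      per_cell_true = as.numeric(true_conc) * 1e4 / cells)
    list(standards = standards, samples = samples, truth = truth)
  })
}

#' Simulate an antibody membrane array (spot blot)
#'
#' Builds a blot with duplicate spots per analyte and exactly six reference
#' spots. Analyte intensities are `reference_value * effect * noise`, so
#' normalised values recover the effects; multiplying the whole blot by any
#' positive constant leaves the normalised output unchanged (exposure
#' invariance).
#'
#' @param n_analytes Number of analytes (>= 1).
#' @param reference_value Intensity of the reference spots; > 0.
#' @param effects Numeric vector of length `n_analytes` (recycled if length
#'   1): true normalised value per analyte.
#' @param duplicate Emit two spots per analyte (default) or one.
#' @param noise_cv Multiplicative noise CV per spot.
#' @param seed Integer seed.
#' @return Tibble with columns `row`, `col`, `label`, `intensity`;
#'   reference spots carry the label `"reference"`.
#' @export
simulate_blot <- function(n_analytes, reference_value = 100, effects = 1,
                          duplicate = TRUE, noise_cv = 0, seed = 1L) {
  if (n_analytes < 1) abort("n_analytes must be >= 1")
  if (reference_value <= 0) {
    abort("reference_value must be positive",
          class = "screenfunnel_config_error")
  }
  effects <- rep_len(effects, n_analytes)
  labels <- sprintf("A%03d", seq_len(n_analytes))
  n_spots_per <- if (duplicate) 2L else 1L
  with_seed(seed, {
    spot_lab <- c(rep(labels, each = n_spots_per), rep("reference", 6))
    spot_val <- c(rep(reference_value * effects, each = n_spots_per),
                  rep(reference_value, 6))
    n <- length(spot_lab)
    spot_val <- spot_val * lnorm_noise(n, noise_cv)
    ncol_grid <- 10L
    tibble::tibble(
      row = (seq_len(n) - 1L) %/% ncol_grid + 1L,
      col = (seq_len(n) - 1L) %% ncol_grid + 1L,
      label = spot_lab,
      intensity = spot_val)
  })
}

#' Simulate therapeutic-class annotations for a compound library
#'
#' Assigns each compound a therapeutic class drawn from the kinds of
#' categories an FDA-approved repurposing library spans, for exercising
#' class-diversified ranking.
#'
#' @param compound_ids Character vector of compound IDs.
#' @param classes Candidate class labels.
#' @param seed Integer seed.
#' @return Tibble `compound_id`, `therapeutic_class`.
#' @export
simulate_annotations <- function(compound_ids,
                                 classes = c("anti-bacterial", "anti-asthmatic",
                                             "anti-helminthic", "cardiotonic",
                                             "bronchodilator", "anti-septic",
                                             "anti-neoplastic", "anti-amoebic",
                                             "anti-inflammatory"),
                                 seed = 1L) {
  with_seed(seed, tibble::tibble(
    compound_id = compound_ids,
    therapeutic_class = sample(classes, length(compound_ids),
                               replace = TRUE)))
}
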
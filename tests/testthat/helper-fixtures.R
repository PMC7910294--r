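# fixtures are built in code: a minimal valid plate and normalized-well
# tables with prescribed activities, for exercising the tier rules directly

# one 96-format plate with hand-set control intensities and optional
# compound wells (per-cell intensities and counts)
make_plate <- function(plate_id = "P1",
                       stim_ccl2 = c(190, 210), stim_icam1 = c(190, 210),
                       veh_ccl2 = c(40, 40), veh_icam1 = c(40, 40),
                       stim_count = 2000, veh_count = 2000,
                       compounds = NULL, tgfb = TRUE) {
  n_s <- length(stim_ccl2)
  n_v <- length(veh_ccl2)
  rows <- tibble::tibble(
    plate_id = plate_id,
    row = LETTERS[seq_len(n_s + n_v)],
    col = 12L,
    role = c(rep("vehicle_stim", n_s), rep("vehicle_only", n_v)),
    compound_id = "",
    concentration_um = 0,
    cell_count = c(rep(stim_count, n_s), rep(veh_count, n_v)),
    intensity_ccl2 = c(stim_ccl2, veh_ccl2),
    intensity_icam1 = c(stim_icam1, veh_icam1))
  if (tgfb) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      plate_id = plate_id, row = c("A", "B"), col = 11L,
      role = c("tgfb_low", "tgfb_high"), compound_id = "",
      concentration_um = 0, cell_count = 2000,
      intensity_ccl2 = c(150, 100), intensity_icam1 = c(150, 100)))
  }
  if (!is.null(compounds)) {
    n <- nrow(compounds)
    cpd <- tibble::tibble(
      plate_id = plate_id,
      row = rep(LETTERS[1:8], length.out = n),
      col = rep(1:10, each = 8, length.out = n),
      role = "compound",
      compound_id = compounds$compound_id,
      concentration_um = 10,
      cell_count = compounds$cell_count,
      intensity_ccl2 = compounds$intensity_ccl2,
      intensity_icam1 = compounds$intensity_icam1)
    rows <- dplyr::bind_rows(rows, cpd)
  }
  rows
}

# normalized compound wells with prescribed per-replicate activities
make_normalized <- function(compound_id, activity_ccl2,
                            activity_icam1 = activity_ccl2,
                            cell_ratio = 1, concentration_um = 10,
                            plate_id = "P1") {
  n <- length(activity_ccl2)
  tibble::tibble(
    plate_id = plate_id,
    row = rep(LETTERS[1:8], length.out = n),
    col = seq_len(n),
    role = "compound",
    compound_id = compound_id,
    concentration_um = concentration_um,
    cell_count = round(2000 * cell_ratio),
    activity_ccl2 = activity_ccl2,
    activity_icam1 = activity_icam1,
    cell_ratio = rep_len(cell_ratio, n))
}

# summaries table from one or more make_normalized() blocks
make_summaries <- function(...) {
  summarize_compounds(dplyr::bind_rows(...))
}

# truth-derived primary hit set: the oracle for funnel recovery tests
truth_hit_set <- function(truth, effect_min = 0.2, viability_min = 0.5) {
  sort(truth$compound_id[
    (abs(truth$effect_ccl2 - 1) >= effect_min |
       abs(truth$effect_icam1 - 1) >= effect_min) &
      truth$viability > viability_min])
}
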
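#' Fit per-analyte standard curves
#'
#' Fits a [fourpl()] standard curve per analyte from an 11-point standard
#' table (0-10,000 pg/mL grid); the 0 pg/mL point anchors the bottom
#' asymptote.
#'
#' @param standards Tibble with columns `analyte`, `conc_pgml`, `signal`.
#' @return Named list of `fourpl` curves.
#' @export
fit_standard_curves <- function(standards) {
  stopifnot(all(c("analyte", "conc_pgml", "signal") %in% names(standards)))
  parts <- split(standards, standards$analyte)
  lapply(parts, function(tab) fit_4pl(tab$conc_pgml, tab$signal)$curve)
}

#' Back-calculate analyte concentrations from fluorescence
#'
#' Converts raw fluorescence to concentration through each analyte's
#' standard curve. Readings at or below the curve bottom are flagged
#' `below_lod` and carry no numeric value; readings at or above the top
#' are flagged `above_range` and censored at the top standard
#' (10,000 pg/mL) rather than extrapolated, because the inverse curve is
#' unstable beyond the upper asymptote.
#'
#' @param raw Tibble with columns `analyte`, `signal` and optionally
#'   `condition` and `cells` (carried through).
#' @param curves Named list of [fourpl()] curves covering every analyte.
#' @param top_standard Censoring value for above-range readings (pg/mL).
#' @return Tibble: input columns plus `concentration` and `detection`
#'   (`ok`, `below_lod`, `above_range`).
#' @export
quantify_panel <- function(raw, curves, top_standard = 10000) {
  stopifnot(all(c("analyte", "signal") %in% names(raw)))
  missing <- setdiff(unique(raw$analyte), names(curves))
  if (length(missing) > 0) {
    abort(paste0("no standard curve for analyte(s): ",
                 paste(missing, collapse = ", ")),
          class = "screenfunnel_missing_curve")
  }
  out <- raw
  out$concentration <- NA_real_
  out$detection <- NA_character_
  for (a in unique(raw$analyte)) {
    idx <- which(raw$analyte == a)
    inv <- inverse_4pl(curves[[a]], raw$signal[idx], flag = TRUE)
    conc <- inv$concentration
    conc[inv$detection == "above_range"] <- top_standard
    out$concentration[idx] <- conc
    out$detection[idx] <- inv$detection
  }
  out
}

#' Normalise concentrations to cell number
#'
#' Expresses a secreted concentration per 10,000 cells:
#' `per_cell_conc = concentration * 1e4 / cells`. Below-detection and
#' above-range measurements pass through unchanged with their flag — a
#' censored value must never be silently rescaled into a numeric result.
#'
#' @param measurements Tibble from [quantify_panel()] with a `cells`
#'   column (or supply `cells`).
#' @param cells Optional cell count overriding the column.
#' @param log10_transform Also report `log10_per_cell` for `ok` rows
#'   (the conventional display scale for pg/mL panels).
#' @return Input with `per_cell_conc` (pg/mL per 10^4 cells) and
#'   optionally `log10_per_cell`.
#' @export
normalize_per_cell <- function(measurements, cells = NULL,
                               log10_transform = FALSE) {
  m <- measurements
  if (!is.null(cells)) m$cells <- cells
  if (!"cells" %in% names(m)) abort("no cell counts supplied")
  if (any(is.na(m$cells) | m$cells <= 0)) {
    abort("cell counts must be positive", class = "screenfunnel_cell_error")
  }
  ok <- m$detection == "ok"
  m$per_cell_conc <- NA_real_
  m$per_cell_conc[ok] <- m$concentration[ok] * 1e4 / m$cells[ok]
  if (log10_transform) {
    m$log10_per_cell <- NA_real_
    pos <- ok & m$per_cell_conc > 0
    m$log10_per_cell[pos] <- log10(m$per_cell_conc[pos])
  }
  m
}

#' Fold change versus the vehicle condition
#'
#' Divides each condition's value by the vehicle condition's value, per
#' analyte. When the vehicle itself is below detection no fold is
#' computable; those analytes switch to absolute reporting (`mode =
#' "absolute"`, fold `NA`), mirroring how panels report analytes such as
#' G-CSF, GM-CSF and RANTES that are undetectable under vehicle.
#'
#' @param measurements Tibble with `analyte`, `condition`, `detection` and
#'   a value column.
#' @param vehicle_label The vehicle condition's label.
#' @param value_col Which column to fold (default `per_cell_conc`, falling
#'   back to `concentration`).
#' @return Tibble: `analyte`, `condition`, `value`, `fold`, `mode`
#'   (`fold` or `absolute`).
#' @export
fold_vs_vehicle <- function(measurements, vehicle_label = "vehicle",
                            value_col = NULL) {
  m <- measurements
  if (is.null(value_col)) {
    value_col <- if ("per_cell_conc" %in% names(m)) "per_cell_conc"
                 else "concentration"
  }
  if (!vehicle_label %in% m$condition) {
    abort(paste0("vehicle condition '", vehicle_label, "' absent"),
          class = "screenfunnel_missing_vehicle")
  }
  rows <- lapply(split(m, m$analyte), function(tab) {
    veh <- tab[tab$condition == vehicle_label, ]
    if (nrow(veh) == 0) {
      abort(paste0("vehicle condition absent for analyte ", tab$analyte[1]),
            class = "screenfunnel_missing_vehicle")
    }
    veh_ok <- veh$detection[1] == "ok" && is.finite(veh[[value_col]][1]) &&
      veh[[value_col]][1] > 0
    tibble::tibble(
      analyte = tab$analyte,
      condition = tab$condition,
      value = tab[[value_col]],
      fold = if (veh_ok) tab[[value_col]] / veh[[value_col]][1]
             else NA_real_,
      mode = if (veh_ok) "fold" else "absolute")
  })
  dplyr::bind_rows(rows)
}

#' Normalise a membrane array to its reference spots
#'
#' Averages each analyte's duplicate spots and divides by the mean of the
#' blot's six reference spots, making values comparable across blots and
#' invariant to overall exposure: scaling every spot by the same positive
#' constant leaves the output unchanged.
#'
#' @param blot Tibble with columns `label` and `intensity`; reference
#'   spots carry the label `"reference"` (exactly six required).
#' @return Tibble: `analyte`, `normalized` (duplicate mean over reference
#'   mean), `n_spots`.
#' @export
normalize_blot <- function(blot) {
  stopifnot(all(c("label", "intensity") %in% names(blot)))
  refs <- blot$intensity[blot$label == "reference"]
  if (length(refs) != 6) {
    abort(sprintf("expected exactly 6 reference spots, found %d",
                  length(refs)),
          class = "screenfunnel_layout_error")
  }
  ref_mean <- mean(refs)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    abort("reference spot mean is not positive: degenerate blot",
          class = "screenfunnel_degenerate_blot")
  }
  spots <- blot[blot$label != "reference", ]
  if (any(spots$intensity < 0)) abort("spot intensities must be >= 0")
  spots |>
    dplyr::group_by(analyte = .data$label) |>
    dplyr::summarise(normalized = mean(.data$intensity) / ref_mean,
                     n_spots = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$analyte)
}

#' Delta-Ct expression ratios
#'
#' Quantifies qPCR expression relative to a reference condition with the
#' delta-Ct method: per gene, `delta_ct = ct_target - ct_gapdh` and
#' `fold = 2^-(delta_ct_condition - delta_ct_reference)`, so the reference
#' condition has fold exactly 1 and each cycle of difference doubles or
#' halves the ratio.
#'
#' @param records Tibble with columns `gene`, `condition`, `ct_target`,
#'   `ct_gapdh`.
#' @param reference_condition Name of the reference condition (e.g. time
#'   zero or untreated); every gene must include it.
#' @return Input with `delta_ct` and `fold_vs_reference` columns.
#' @export
delta_ct_fold <- function(records, reference_condition) {
  stopifnot(all(c("gene", "condition", "ct_target", "ct_gapdh") %in%
                  names(records)))
  if (any(!is.finite(records$ct_gapdh))) {
    abort("missing GAPDH Ct in one or more records",
          class = "screenfunnel_missing_reference")
  }
  if (any(!is.finite(records$ct_target))) {
    abort("missing target Ct in one or more records",
          class = "screenfunnel_missing_reference")
  }
  out <- tibble::as_tibble(records)
  out$delta_ct <- out$ct_target - out$ct_gapdh
  rows <- lapply(split(out, out$gene), function(tab) {
    ref <- tab[tab$condition == reference_condition, ]
    if (nrow(ref) == 0) {
      abort(paste0("gene ", tab$gene[1], " lacks reference condition '",
                   reference_condition, "'"),
            class = "screenfunnel_missing_reference")
    }
    tab$fold_vs_reference <- 2^(-(tab$delta_ct - mean(ref$delta_ct)))
    tab
  })
  dplyr::bind_rows(rows)
}
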
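#' Normalise one plate to its stimulated-vehicle controls
#'
#' Converts raw per-cell intensities into dimensionless activities by
#' dividing by the mean per-cell intensity of the plate's stimulated
#' vehicle wells (IL-1beta + DMSO), per channel, and cell counts into a
#' cell ratio against the mean stimulated-vehicle count. This internal
#' normalization removes any multiplicative plate factor exactly, which is
#' what makes plates comparable in a multi-plate screen. For an
#' unstimulated (independence) tier, pass `ref_role = "vehicle_only"`.
#'
#' Wells with zero cells get `NA` activities and cell ratio 0; they are
#' excluded from all plate statistics, never imputed.
#'
#' @param wells Well tibble for a single plate (canonical columns).
#' @param ref_role Role used as the normalization anchor; default
#'   `"vehicle_stim"`.
#' @return Tibble of normalised wells: identity columns plus
#'   `activity_ccl2`, `activity_icam1`, `cell_ratio`.
#' @export
normalize_plate <- function(wells, ref_role = "vehicle_stim") {
  wells <- tibble::as_tibble(wells)
  if (length(unique(wells$plate_id)) != 1) {
    abort("normalize_plate expects wells from exactly one plate")
  }
  ref <- wells[wells$role == ref_role & wells$cell_count > 0, ]
  if (nrow(ref) < 2) {
    abort(paste0("plate ", wells$plate_id[1], " has fewer than 2 usable ",
                 ref_role, " wells"),
          class = "screenfunnel_normalization_error")
  }
  mu_c <- mean(ref$intensity_ccl2)
  mu_i <- mean(ref$intensity_icam1)
  mu_n <- mean(ref$cell_count)
  if (!is.finite(mu_c) || !is.finite(mu_i) || mu_c <= 0 || mu_i <= 0) {
    abort(paste0("plate ", wells$plate_id[1],
                 ": reference wells have degenerate mean intensity"),
          class = "screenfunnel_degenerate_control_error")
  }
  out <- wells
  out$activity_ccl2 <- out$intensity_ccl2 / mu_c
  out$activity_icam1 <- out$intensity_icam1 / mu_i
  out$cell_ratio <- out$cell_count / mu_n
  zero <- out$cell_count == 0
  out$activity_ccl2[zero] <- NA_real_
  out$activity_icam1[zero] <- NA_real_
  out$cell_ratio[zero] <- 0
  out
}

#' Normalise every plate of a screen dataset
#'
#' Applies [normalize_plate()] plate by plate. The independence tier is
#' automatically anchored on unstimulated vehicle wells, since no
#' stimulated reference exists there.
#'
#' @param dataset A [screen_dataset()].
#' @param ref_role Override the normalization anchor role; by default
#'   `"vehicle_stim"`, or `"vehicle_only"` when `dataset$tier` is
#'   `"independence"`.
#' @return Tibble of normalised wells across all plates.
#' @export
normalize_screen <- function(dataset, ref_role = NULL) {
  stopifnot(inherits(dataset, "screen_dataset"))
  if (is.null(ref_role)) {
    ref_role <- if (dataset$tier == "independence") "vehicle_only"
                else "vehicle_stim"
  }
  parts <- split(dataset$wells, dataset$wells$plate_id)
  dplyr::bind_rows(lapply(parts, normalize_plate, ref_role = ref_role))
}

#' Screening-window coefficient (Z-prime)
#'
#' The assay-quality statistic
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' between a positive and a negative control group, using sample (n-1)
#' standard deviations. Z' is at most 1, symmetric in the two groups, and
#' invariant to shifting both groups by a constant or scaling both by a
#' common factor. Values above 0.5 indicate an excellent assay window;
#' screens remain workable down to roughly 0.
#'
#' @param positive,negative Numeric vectors of control readouts (>= 2
#'   values each, distinct means).
#' @return The Z' coefficient (scalar).
#' @export
zprime <- function(positive, negative) {
  positive <- positive[is.finite(positive)]
  negative <- negative[is.finite(negative)]
  if (length(positive) < 2 || length(negative) < 2) {
    abort("each control group needs >= 2 values",
          class = "screenfunnel_insufficient_replicates")
  }
  mu_p <- mean(positive); mu_n <- mean(negative)
  if (mu_p == mu_n) {
    abort("control means are equal: screening window undefined",
          class = "screenfunnel_undefined_window")
  }
  1 - 3 * (sd(positive) + sd(negative)) / abs(mu_p - mu_n)
}

#' Per-plate and screen-level quality statistics
#'
#' Computes, per plate, the Z' window per channel (stimulated vehicle vs
#' unstimulated vehicle, on normalised activities), the control separation
#' (stimulated mean over unstimulated mean), and the TGFbeta1 inhibition
#' verdict; plus pooled screen-level Z' per channel across all plates.
#'
#' @param normalized Tibble of normalised wells ([normalize_screen()]).
#' @param min_inhibition Minimum TGFbeta1 inhibition for the control check.
#' @param min_zprime Z' threshold entering the per-plate `pass` flag;
#'   default 0 (any positive window).
#' @return A list: `plates` (per-plate tibble with `zprime_ccl2`,
#'   `zprime_icam1`, `separation_ccl2`, `separation_icam1`, TGFbeta
#'   verdicts, `pass`) and `screen` (pooled Z' per channel).
#' @export
plate_qc <- function(normalized, min_inhibition = 0.2, min_zprime = 0) {
  parts <- split(normalized, normalized$plate_id)
  rows <- lapply(parts, function(p) {
    pos_c <- p$activity_ccl2[p$role == "vehicle_stim"]
    neg_c <- p$activity_ccl2[p$role == "vehicle_only"]
    pos_i <- p$activity_icam1[p$role == "vehicle_stim"]
    neg_i <- p$activity_icam1[p$role == "vehicle_only"]
    ctl <- suppressWarnings(control_check(p, min_inhibition = min_inhibition))
    get_inh <- function(r) {
      v <- ctl$inhibition[!is.na(ctl$role) & ctl$role == r]
      if (length(v)) v[1] else NA_real_
    }
    z_c <- tryCatch(zprime(pos_c, neg_c), error = function(e) NA_real_)
    z_i <- tryCatch(zprime(pos_i, neg_i), error = function(e) NA_real_)
    tibble::tibble(
      plate_id = p$plate_id[1],
      zprime_ccl2 = z_c,
      zprime_icam1 = z_i,
      separation_ccl2 = mean(pos_c, na.rm = TRUE) / mean(neg_c, na.rm = TRUE),
      separation_icam1 = mean(pos_i, na.rm = TRUE) / mean(neg_i, na.rm = TRUE),
      tgfb_low_inhibition = get_inh("tgfb_low"),
      tgfb_high_inhibition = get_inh("tgfb_high"),
      tgfb_verdict = ctl$verdict[1],
      pass = !is.na(z_c) & !is.na(z_i) &
        pmax(z_c, z_i) >= min_zprime & ctl$verdict[1] != "fail")
  })
  plates <- dplyr::bind_rows(rows)

  pooled <- function(ch) {
    pos <- normalized[[ch]][normalized$role == "vehicle_stim"]
    neg <- normalized[[ch]][normalized$role == "vehicle_only"]
    tryCatch(zprime(pos, neg), error = function(e) NA_real_)
  }
  list(plates = plates,
       screen = tibble::tibble(
         zprime_ccl2 = pooled("activity_ccl2"),
         zprime_icam1 = pooled("activity_icam1")))
}

#' Pearson concordance between the two readout channels
#'
#' Product-moment correlation between the normalised CCL2 and ICAM-1
#' activities of compound wells across all plates, with the two-sided
#' p-value. A strong positive correlation indicates both channels report
#' the same underlying modulation, so either is a valid screen readout.
#'
#' @param activity_ccl2,activity_icam1 Paired numeric vectors (n >= 3,
#'   each with nonzero variance).
#' @return A list with `r` and `p_value`.
#' @export
channel_concordance <- function(activity_ccl2, activity_icam1) {
  keep <- is.finite(activity_ccl2) & is.finite(activity_icam1)
  x <- activity_ccl2[keep]; y <- activity_icam1[keep]
  if (length(x) < 3) abort("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in a channel: correlation undefined",
          class = "screenfunnel_degenerate_input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' TGFbeta1 control verdict for one plate
#'
#' The screen carries TGFbeta1 (a known inhibitor of the induced response)
#' on every plate as a pharmacological sanity control. Observed inhibition
#' is `1 - mean activity` of the TGFbeta wells per dose; the plate passes
#' if inhibition reaches `min_inhibition` on the designated channel at the
#' high dose. Plates without TGFbeta wells are reported as
#' `"not_evaluated"` with a warning, not failed.
#'
#' @param plate Normalised wells of a single plate.
#' @param min_inhibition Minimum fractional inhibition; default 0.2.
#' @param channel Channel to evaluate (`"activity_ccl2"` or
#'   `"activity_icam1"`).
#' @return Tibble with one row per TGFbeta role present (`role`,
#'   `inhibition`, `verdict`), or a single `"not_evaluated"` row.
#' @export
control_check <- function(plate, min_inhibition = 0.2,
                          channel = "activity_ccl2") {
  tg <- plate[plate$role %in% c("tgfb_low", "tgfb_high"), ]
  if (nrow(tg) == 0) {
    warn("no TGFbeta control wells on plate: control check skipped")
    return(tibble::tibble(role = NA_character_, inhibition = NA_real_,
                          verdict = "not_evaluated"))
  }
  by_role <- tg |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(
      inhibition = 1 - mean(.data[[channel]], na.rm = TRUE),
      .groups = "drop")
  # the high dose is decisive; fall back to low if high is absent
  decisive <- if ("tgfb_high" %in% by_role$role) "tgfb_high" else "tgfb_low"
  pass <- by_role$inhibition[by_role$role == decisive] >= min_inhibition
  by_role$verdict <- if (isTRUE(pass)) "pass" else "fail"
  by_role[, c("role", "inhibition", "verdict")]
}
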
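# boundary tolerance: the +/-20% effect rule is inclusive, and means such
# as 0.80 must sit exactly on the boundary despite binary floating point
EFFECT_EPS <- 1e-9

#' Default funnel thresholds
#'
#' Effect threshold is inclusive (>= 20% change over stimulated vehicle on
#' either channel); replicate variability and cell-loss thresholds are
#' strict (CV < 15%, cell loss < 50%, i.e. cell ratio > 0.5).
#'
#' @param effect_pct Minimum absolute percent change to call a hit.
#' @param cv_pct Maximum replicate CV (percent) for a qualifying channel.
#' @param max_cell_loss_pct Maximum tolerated cell loss (percent); a
#'   compound at or beyond it is excluded as cytotoxic.
#' @return Named list of thresholds.
#' @export
funnel_thresholds <- function(effect_pct = 20, cv_pct = 15,
                              max_cell_loss_pct = 50) {
  stopifnot(effect_pct > 0, cv_pct > 0,
            max_cell_loss_pct > 0, max_cell_loss_pct < 100)
  list(effect_pct = effect_pct, cv_pct = cv_pct,
       max_cell_loss_pct = max_cell_loss_pct)
}

#' Per-compound replicate summaries for one tier
#'
#' Collapses normalised compound wells to one row per compound (and per
#' concentration, if several doses are present): mean activity and percent
#' change per channel, replicate CV (sample SD as percent of the mean),
#' mean cell ratio and replicate count. Wells with zero cells contribute a
#' cell ratio of 0 but are excluded from the intensity statistics.
#'
#' @param normalized Normalised wells ([normalize_screen()]).
#' @return Tibble with one row per compound (x concentration), sorted by
#'   `compound_id`.
#' @export
summarize_compounds <- function(normalized) {
  cpd <- normalized[normalized$role == "compound", ]
  if (nrow(cpd) == 0) abort("no compound wells to summarise")
  cpd |>
    dplyr::group_by(.data$compound_id, .data$concentration_um) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_ccl2 = mean(.data$activity_ccl2, na.rm = TRUE),
      mean_icam1 = mean(.data$activity_icam1, na.rm = TRUE),
      cv_ccl2 = 100 * sd(.data$activity_ccl2, na.rm = TRUE) /
        mean(.data$activity_ccl2, na.rm = TRUE),
      cv_icam1 = 100 * sd(.data$activity_icam1, na.rm = TRUE) /
        mean(.data$activity_icam1, na.rm = TRUE),
      cell_ratio = mean(.data$cell_ratio),
      .groups = "drop") |>
    dplyr::mutate(
      percent_change_ccl2 = (.data$mean_ccl2 - 1) * 100,
      percent_change_icam1 = (.data$mean_icam1 - 1) * 100) |>
    dplyr::arrange(.data$compound_id, .data$concentration_um)
}

# the shared tier rule, evaluated in a fixed order per compound:
# (1) cytotoxicity, (2) variability on otherwise-qualifying channels,
# (3) effect call with direction from the larger-magnitude channel
apply_tier_rule <- function(summaries, thresholds) {
  th <- thresholds
  min_ratio <- 1 - th$max_cell_loss_pct / 100

  eval_row <- function(row) {
    pct <- c(ccl2 = row$percent_change_ccl2, icam1 = row$percent_change_icam1)
    cv <- c(ccl2 = row$cv_ccl2, icam1 = row$cv_icam1)
    cv[is.na(cv)] <- 0   # zero-spread replicates have CV 0, not NA

    if (row$cell_ratio <= min_ratio + EFFECT_EPS) {
      return(list(verdict = "excluded_cytotoxic",
                  reason = sprintf("cell ratio %.3f <= %.2f",
                                   row$cell_ratio, min_ratio)))
    }
    effect_ok <- abs(pct) >= th$effect_pct - EFFECT_EPS
    cv_ok <- cv < th$cv_pct
    qualifying <- effect_ok & cv_ok
    if (any(qualifying)) {
      ch <- names(pct)[qualifying][which.max(abs(pct[qualifying]))]
      dir <- if (pct[ch] > 0) "hit_up" else "hit_down"
      return(list(verdict = dir,
                  reason = sprintf("%s %+.1f%% (CV %.1f%%)",
                                   ch, pct[ch], cv[ch])))
    }
    # no clean channel qualifies: a channel too variable to call blocks
    # the compound rather than letting it pass silently as not_hit
    if (any(!cv_ok)) {
      ch <- names(pct)[!cv_ok][which.max(cv[!cv_ok])]
      return(list(verdict = "excluded_variable",
                  reason = sprintf("%s CV %.1f%% >= %.0f%%",
                                   ch, cv[ch], th$cv_pct)))
    }
    list(verdict = "not_hit",
         reason = sprintf("max |change| %.1f%% < %.0f%%",
                          max(abs(pct)), th$effect_pct))
  }

  verdicts <- character(nrow(summaries))
  reasons <- character(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    v <- eval_row(summaries[i, ])
    verdicts[i] <- v$verdict
    reasons[i] <- v$reason
  }
  summaries$verdict <- verdicts
  summaries$reason <- reasons
  summaries
}

#' Primary-tier hit filter
#'
#' Applies the advancement criteria of the duplicate-well primary screen:
#' a compound advances if either channel changes by at least
#' `effect_pct` (default +/-20%) over the stimulated vehicle with
#' replicate CV below `cv_pct` (default 15%), unless cell loss reaches
#' `max_cell_loss_pct` (default 50%), in which case it is excluded as
#' cytotoxic regardless of effect — cell-loss artifacts must never be
#' reported as inhibition, so the cytotoxicity rule is evaluated first.
#'
#' @param summaries Per-compound summaries ([summarize_compounds()]), two
#'   or more replicates each.
#' @param thresholds See [funnel_thresholds()].
#' @return `summaries` with `verdict` (`hit_up`, `hit_down`, `not_hit`,
#'   `excluded_cytotoxic`, `excluded_variable`) and `reason` columns.
#' @export
primary_filter <- function(summaries, thresholds = funnel_thresholds()) {
  single <- summaries$compound_id[summaries$n_replicates < 2]
  if (length(single) > 0) {
    abort(paste0("compound(s) with a single replicate: ",
                 paste(single, collapse = ", ")),
          class = "screenfunnel_insufficient_replicates")
  }
  apply_tier_rule(summaries, thresholds)
}

#' Secondary-tier (confirmation) filter
#'
#' Re-applies the tier rule to triplicate summaries. A compound confirms
#' only if it advanced from the primary tier AND passes here; compounds
#' outside `primary_hits` are returned with verdict `"not_evaluated"`.
#'
#' @param summaries Triplicate per-compound summaries.
#' @param thresholds See [funnel_thresholds()].
#' @param primary_hits Character vector of compound IDs that advanced from
#'   the primary tier; `NULL` evaluates all compounds.
#' @return Summaries with `verdict` and `reason`.
#' @export
secondary_filter <- function(summaries, thresholds = funnel_thresholds(),
                             primary_hits = NULL) {
  few <- summaries$compound_id[summaries$n_replicates < 3]
  if (length(few) > 0) {
    abort(paste0("compound(s) with fewer than 3 replicates: ",
                 paste(few, collapse = ", ")),
          class = "screenfunnel_insufficient_replicates")
  }
  out <- apply_tier_rule(summaries, thresholds)
  if (!is.null(primary_hits)) {
    skip <- !out$compound_id %in% primary_hits
    out$verdict[skip] <- "not_evaluated"
    out$reason[skip] <- "not a primary hit"
  }
  out
}

#' Select the follow-up concentration per compound
#'
#' From tertiary-tier summaries over a dose grid, chooses per compound the
#' dose producing the maximal absolute change on either channel among the
#' doses without disqualifying cell loss; ties break toward higher cell
#' ratio, then lower dose. If no dose passes the cell criterion the
#' compound is excluded as cytotoxic; if the best surviving dose is
#' sub-threshold the verdict is `not_hit` at that dose.
#'
#' @param tertiary Per-compound, per-dose summaries
#'   ([summarize_compounds()] of a tertiary-tier screen).
#' @param thresholds See [funnel_thresholds()].
#' @return Tibble with one row per compound: `compound_id`, `chosen_dose`,
#'   channel percent changes and cell ratio at that dose, `verdict` and
#'   `rationale`.
#' @export
dose_select <- function(tertiary, thresholds = funnel_thresholds()) {
  if (nrow(tertiary) == 0) abort("empty dose set")
  min_ratio <- 1 - thresholds$max_cell_loss_pct / 100

  per_cpd <- split(tertiary, tertiary$compound_id)
  rows <- lapply(per_cpd, function(tab) {
    if (nrow(tab) < 2) {
      abort(paste0("compound ", tab$compound_id[1],
                   " has fewer than 2 dose summaries"))
    }
    tab$max_abs <- pmax(abs(tab$percent_change_ccl2),
                        abs(tab$percent_change_icam1))
    ok <- tab$cell_ratio > min_ratio + EFFECT_EPS
    if (!any(ok)) {
      best <- tab[order(-tab$cell_ratio, tab$concentration_um), ][1, ]
      return(tibble::tibble(
        compound_id = best$compound_id,
        chosen_dose = NA_real_,
        percent_change_ccl2 = best$percent_change_ccl2,
        percent_change_icam1 = best$percent_change_icam1,
        cell_ratio = best$cell_ratio,
        verdict = "excluded_cytotoxic",
        rationale = "no dose passes the cell-loss criterion"))
    }
    cand <- tab[ok, ]
    cand <- cand[order(-cand$max_abs, -cand$cell_ratio,
                       cand$concentration_um), ]
    best <- cand[1, ]
    verdict <- if (best$max_abs >= thresholds$effect_pct - EFFECT_EPS) {
      if (abs(best$percent_change_ccl2) >= abs(best$percent_change_icam1)) {
        if (best$percent_change_ccl2 > 0) "hit_up" else "hit_down"
      } else {
        if (best$percent_change_icam1 > 0) "hit_up" else "hit_down"
      }
    } else {
      "not_hit"
    }
    tibble::tibble(
      compound_id = best$compound_id,
      chosen_dose = best$concentration_um,
      percent_change_ccl2 = best$percent_change_ccl2,
      percent_change_icam1 = best$percent_change_icam1,
      cell_ratio = best$cell_ratio,
      verdict = verdict,
      rationale = sprintf(
        "maximal |change| %.1f%% at %g uM with cell ratio %.2f",
        best$max_abs, best$concentration_um, best$cell_ratio))
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$compound_id)
}

#' Flag stimulus-independent compound effects
#'
#' Compounds are re-screened without stimulation, normalised to the
#' unstimulated vehicle; any compound whose basal activity changes by at
#' least `threshold_pct` on either channel is flagged as confounded (its
#' apparent modulation does not require the inflammatory stimulus). A
#' clean screen — the outcome the funnel expects — returns zero flags.
#'
#' @param summaries Per-compound summaries from an independence-tier
#'   screen (normalised to `vehicle_only`).
#' @param threshold_pct Flagging threshold on |percent change|.
#' @return Tibble: `compound_id`, channel percent changes, `flag`
#'   (`none`, `basal_up`, `basal_down`).
#' @export
independence_check <- function(summaries, threshold_pct = 20) {
  pct_c <- summaries$percent_change_ccl2
  pct_i <- summaries$percent_change_icam1
  big <- pmax(abs(pct_c), abs(pct_i)) >= threshold_pct - EFFECT_EPS
  lead <- ifelse(abs(pct_c) >= abs(pct_i), pct_c, pct_i)
  tibble::tibble(
    compound_id = summaries$compound_id,
    percent_change_ccl2 = pct_c,
    percent_change_icam1 = pct_i,
    flag = ifelse(!big, "none", ifelse(lead > 0, "basal_up", "basal_down")))
}

#' Rank confirmed hits and diversify by therapeutic class
#'
#' Formalises the final shortlist step: confirmed hits are ranked by their
#' maximal absolute channel change and taken greedily under a per-class
#' cap, so the shortlist combines efficacy with diversity in drug type.
#' Deterministic: ties break on compound ID lexicographically; compounds
#' without an annotation fall into class `"unknown"`.
#'
#' @param confirmed Tier summaries of confirmed hits (verdict `hit_up` or
#'   `hit_down`).
#' @param annotations Tibble `compound_id`, `therapeutic_class`, or `NULL`.
#' @param k Target shortlist size (> 0).
#' @param max_per_class Maximum compounds per therapeutic class.
#' @return Tibble of at most `k` rows: `compound_id`,
#'   `therapeutic_class`, `score` (max |percent change|), `rank`; the
#'   attribute `shortfall` records how many short of `k` the input was.
#' @export
rank_and_diversify <- function(confirmed, annotations = NULL, k = 10,
                               max_per_class = 2) {
  if (k <= 0) abort("k must be positive")
  stopifnot(max_per_class >= 1)
  hits <- confirmed[confirmed$verdict %in% c("hit_up", "hit_down"), ]
  if (nrow(hits) == 0) {
    out <- tibble::tibble(compound_id = character(0),
                          therapeutic_class = character(0),
                          score = numeric(0), rank = integer(0))
    attr(out, "shortfall") <- k
    return(out)
  }
  hits$score <- pmax(abs(hits$percent_change_ccl2),
                     abs(hits$percent_change_icam1))
  cls <- rep("unknown", nrow(hits))
  if (!is.null(annotations)) {
    m <- match(hits$compound_id, annotations$compound_id)
    cls[!is.na(m)] <- annotations$therapeutic_class[m[!is.na(m)]]
  }
  hits$therapeutic_class <- cls
  hits <- hits[order(-hits$score, hits$compound_id), ]

  taken <- integer(0)
  class_used <- c()
  for (i in seq_len(nrow(hits))) {
    if (length(taken) >= k) break
    cl <- hits$therapeutic_class[i]
    used <- if (cl %in% names(class_used)) class_used[[cl]] else 0L
    if (used < max_per_class) {
      taken <- c(taken, i)
      class_used[cl] <- used + 1L
    }
  }
  out <- hits[taken, c("compound_id", "therapeutic_class", "score")]
  out$rank <- seq_len(nrow(out))
  attr(out, "shortfall") <- max(0L, k - nrow(out))
  out
}

#' Run a full screen tier end to end
#'
#' Convenience wrapper: normalises a dataset, summarises compounds and
#' applies the tier's filter. For the tertiary tier the result is the
#' per-compound dose decision table.
#'
#' @param dataset A [screen_dataset()].
#' @param thresholds See [funnel_thresholds()].
#' @param primary_hits Passed to [secondary_filter()] for secondary tiers.
#' @return A list with `normalized`, `summaries` and `result` (the tier's
#'   verdict table).
#' @export
run_tier <- function(dataset, thresholds = funnel_thresholds(),
                     primary_hits = NULL) {
  normalized <- normalize_screen(dataset)
  summaries <- summarize_compounds(normalized)
  result <- switch(
    dataset$tier,
    primary = primary_filter(summaries, thresholds),
    secondary = secondary_filter(summaries, thresholds, primary_hits),
    tertiary = dose_select(summaries, thresholds),
    independence = independence_check(summaries, thresholds$effect_pct))
  list(normalized = normalized, summaries = summaries, result = result)
}

#' Hit compound IDs from a verdict table
#' @param result A tibble with `compound_id` and `verdict` columns.
#' @return Character vector of compounds with verdict `hit_up`/`hit_down`.
#' @export
hit_ids <- function(result) {
  sort(result$compound_id[result$verdict %in% c("hit_up", "hit_down")])
}
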
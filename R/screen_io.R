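#' @importFrom rlang .data abort warn
#' @importFrom stats sd setNames rnorm rpois runif median
#' @importFrom utils read.csv write.csv
NULL

#' Well roles recognised on a screening plate
#'
#' The six well roles used throughout the pipeline: test-compound wells,
#' the stimulated vehicle (IL-1beta + DMSO) that anchors plate
#' normalization, the unstimulated vehicle (0.01% BSA + DMSO), the two
#' TGFbeta1 inhibition controls (1 and 10 ng/mL) and media-only wells.
#' Media-only wells are carried in files but excluded from all statistics.
#'
#' @return Character vector of valid role labels.
#' @export
well_roles <- function() {
  c("compound", "vehicle_stim", "vehicle_only", "tgfb_low", "tgfb_high",
    "media_only")
}

#' Canonical well-table columns
#' @return Character vector of the canonical long-format column names.
#' @export
well_table_columns <- function() {
  c("plate_id", "row", "col", "role", "compound_id", "concentration_um",
    "cell_count", "intensity_ccl2", "intensity_icam1")
}

#' Construct a validated screen dataset
#'
#' Bundles a long-format well table with optional compound annotations and a
#' screen-tier label, and enforces the structural invariants every
#' downstream stage relies on: microplate addressing (rows A-H, columns
#' 1-12), role/compound consistency, uniqueness of (plate, row, col), and
#' control coverage (at least two stimulated-vehicle and two
#' unstimulated-vehicle wells per plate). Wells with zero cells have their
#' per-cell intensities set to `NA` and are flagged, since a per-cell
#' readout is meaningless without cells.
#'
#' @param wells Data frame with the columns of [well_table_columns()].
#' @param annotations Optional data frame with columns `compound_id`,
#'   `therapeutic_class`.
#' @param tier One of `"primary"`, `"secondary"`, `"tertiary"`,
#'   `"independence"`.
#' @return An object of class `screen_dataset`: a list with elements
#'   `wells` (tibble), `annotations` (tibble or `NULL`) and `tier`.
#' @export
screen_dataset <- function(wells, annotations = NULL,
                           tier = c("primary", "secondary", "tertiary",
                                    "independence")) {
  tier <- match.arg(tier)
  wells <- tibble::as_tibble(wells)

  missing_cols <- setdiff(well_table_columns(), names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("well table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "screenfunnel_schema_error")
  }

  wells$plate_id <- as.character(wells$plate_id)
  wells$row <- toupper(as.character(wells$row))
  wells$col <- as.integer(wells$col)
  wells$role <- as.character(wells$role)
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[is.na(wells$compound_id)] <- ""
  wells$concentration_um <- as.numeric(wells$concentration_um)
  wells$concentration_um[is.na(wells$concentration_um)] <- 0
  wells$cell_count <- as.integer(wells$cell_count)
  wells$intensity_ccl2 <- as.numeric(wells$intensity_ccl2)
  wells$intensity_icam1 <- as.numeric(wells$intensity_icam1)

  bad_row <- !wells$row %in% LETTERS[1:8]
  bad_col <- is.na(wells$col) | wells$col < 1 | wells$col > 12
  bad_role <- !wells$role %in% well_roles()
  if (any(bad_row | bad_col | bad_role)) {
    abort(paste0("invalid well address or role at row(s): ",
                 paste(utils::head(which(bad_row | bad_col | bad_role), 10),
                       collapse = ", ")),
          class = "screenfunnel_schema_error")
  }

  key <- paste(wells$plate_id, wells$row, wells$col, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0("duplicate well address(es): ",
                 paste(unique(dup), collapse = ", ")),
          class = "screenfunnel_integrity_error")
  }

  is_cpd <- wells$role == "compound"
  if (any(is_cpd & wells$compound_id == "")) {
    abort("compound wells must carry a nonempty compound_id",
          class = "screenfunnel_integrity_error")
  }
  if (any(!is_cpd & wells$compound_id != "")) {
    abort("non-compound wells must have an empty compound_id",
          class = "screenfunnel_integrity_error")
  }
  if (any(!is_cpd & wells$concentration_um > 0)) {
    abort("concentration_um > 0 is only valid for compound wells",
          class = "screenfunnel_integrity_error")
  }
  if (any(is.na(wells$cell_count) | wells$cell_count < 0)) {
    abort("cell_count must be a nonnegative integer",
          class = "screenfunnel_integrity_error")
  }

  # per-cell intensity is undefined at zero cells; flag, never impute
  zero_cells <- wells$cell_count == 0
  has_int <- !is.na(wells$intensity_ccl2) | !is.na(wells$intensity_icam1)
  wells$flag_zero_cells <- zero_cells
  wells$intensity_ccl2[zero_cells] <- NA_real_
  wells$intensity_icam1[zero_cells] <- NA_real_
  missing_int <- !zero_cells & wells$role != "media_only" &
    (is.na(wells$intensity_ccl2) | is.na(wells$intensity_icam1))
  if (any(missing_int)) {
    abort(paste0("missing intensity with nonzero cell count at: ",
                 paste(key[missing_int], collapse = ", ")),
          class = "screenfunnel_integrity_error")
  }
  neg_int <- !zero_cells &
    ((!is.na(wells$intensity_ccl2) & wells$intensity_ccl2 < 0) |
     (!is.na(wells$intensity_icam1) & wells$intensity_icam1 < 0))
  if (any(neg_int)) {
    abort("intensities must be nonnegative",
          class = "screenfunnel_integrity_error")
  }

  ctrl <- table(wells$plate_id[wells$role == "vehicle_stim"])
  ctrl_neg <- table(wells$plate_id[wells$role == "vehicle_only"])
  plates <- unique(wells$plate_id)
  lacking <- plates[!(plates %in% names(ctrl) & ctrl[plates] >= 2) |
                    !(plates %in% names(ctrl_neg) & ctrl_neg[plates] >= 2)]
  if (length(lacking) > 0) {
    abort(paste0("plate(s) lacking >=2 vehicle_stim and >=2 vehicle_only ",
                 "control wells: ", paste(lacking, collapse = ", ")),
          class = "screenfunnel_control_coverage_error")
  }

  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    if (!all(c("compound_id", "therapeutic_class") %in% names(annotations))) {
      abort("annotations need columns compound_id and therapeutic_class",
            class = "screenfunnel_schema_error")
    }
    if (anyDuplicated(annotations$compound_id)) {
      abort("annotation compound_id values must be unique",
            class = "screenfunnel_integrity_error")
    }
  }

  structure(list(wells = wells, annotations = annotations, tier = tier),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> tier=%s: %d wells on %d plate(s), %d compound(s)\n",
              x$tier, nrow(x$wells), length(unique(x$wells$plate_id)),
              length(unique(x$wells$compound_id[x$wells$role == "compound"]))))
  invisible(x)
}

#' Read a long-format well table
#'
#' Reads a tidy CSV (one row = one well) into a validated
#' [screen_dataset()]. Column names can be remapped via `schema` when the
#' file uses instrument-specific headers.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @param annotations_path Optional path to a compound annotation CSV with
#'   columns `compound_id,therapeutic_class`.
#' @inheritParams screen_dataset
#' @return A `screen_dataset`.
#' @export
read_well_table <- function(path, schema = NULL, annotations_path = NULL,
                            tier = "primary") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        abort(paste0("schema maps '", canonical, "' to missing column '",
                     src, "'"),
              class = "screenfunnel_schema_error")
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  ann <- if (!is.null(annotations_path)) {
    read.csv(annotations_path, stringsAsFactors = FALSE)
  }
  screen_dataset(df, annotations = ann, tier = tier)
}

#' Write a screen dataset back to CSV
#'
#' Inverse of [read_well_table()]; writing then reading reproduces every
#' field to full precision.
#'
#' @param dataset A `screen_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "screen_dataset"))
  out <- dataset$wells[, well_table_columns()]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Report-only layout validation
#'
#' Summarises per-plate control coverage, per-compound replicate counts and
#' wells excluded as media-only. Never mutates the dataset; primary-tier
#' compounds present in fewer than two wells are flagged (the screen design
#' calls for duplicates at the primary tier and triplicates at the
#' secondary tier).
#'
#' @param dataset A `screen_dataset`.
#' @return A list with tibbles `plates` (control counts per plate),
#'   `replicates` (well count per compound, with an `expected` column and
#'   `warning` flag) and `excluded` (media-only wells).
#' @export
validate_layout <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  w <- dataset$wells

  plates <- w |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_vehicle_stim = sum(.data$role == "vehicle_stim"),
      n_vehicle_only = sum(.data$role == "vehicle_only"),
      n_tgfb_low = sum(.data$role == "tgfb_low"),
      n_tgfb_high = sum(.data$role == "tgfb_high"),
      n_media_only = sum(.data$role == "media_only"),
      n_compound = sum(.data$role == "compound"),
      .groups = "drop") |>
    dplyr::mutate(controls_complete = .data$n_vehicle_stim >= 2 &
                    .data$n_vehicle_only >= 2 &
                    .data$n_tgfb_low >= 1 & .data$n_tgfb_high >= 1)

  expected <- switch(dataset$tier, primary = 2L, secondary = 3L, 2L)
  replicates <- w |>
    dplyr::filter(.data$role == "compound") |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_wells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(expected = expected,
                  warning = .data$n_wells < expected)

  excluded <- w |>
    dplyr::filter(.data$role == "media_only") |>
    dplyr::select("plate_id", "row", "col")

  list(plates = plates, replicates = replicates, excluded = excluded)
}

#' Write the tiered funnel report
#'
#' Writes one CSV per tier (compound, channel effects, replicate CV, cell
#' ratio, verdict and reason) and a plain-text summary with per-tier
#' screened and advancing counts — the funnel shape, e.g.
#' `1280 -> 82 -> 44 -> 10` in a full repurposing screen.
#'
#' @param results Named list of tier summary tibbles as returned by
#'   [primary_filter()] and friends; names are tier labels and order is the
#'   funnel order.
#' @param path Output prefix; files are written as `<path>_<tier>.csv` and
#'   `<path>_summary.txt`.
#' @param n_screened Number of compounds entering the first tier; defaults
#'   to the row count of the first element.
#' @return Invisibly, a character vector of the files written.
#' @export
write_funnel_report <- function(results, path, n_screened = NULL) {
  if (length(results) == 0) abort("results must contain at least one tier")
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("results must be a named list of tier summaries")
  }
  if (is.null(n_screened)) n_screened <- nrow(results[[1]])

  files <- character(0)
  counts <- integer(0)
  for (tier in names(results)) {
    tab <- results[[tier]]
    f <- paste0(path, "_", tier, ".csv")
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    counts[tier] <- if ("verdict" %in% names(tab)) {
      sum(tab$verdict %in% c("hit_up", "hit_down"))
    } else {
      nrow(tab)
    }
  }
  summary_file <- paste0(path, "_summary.txt")
  lines <- c("funnel summary",
             sprintf("screened: %d", n_screened),
             sprintf("%s hits: %d", names(counts), counts),
             paste("shape:", paste(c(n_screened, counts), collapse = " -> ")))
  writeLines(lines, summary_file)
  invisible(c(files, summary_file))
}
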
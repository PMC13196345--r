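#' Ratiometric well readout (F590/F520)
#'
#' The JC-10 dye reports mitochondrial membrane potential as the ratio of
#' red J-aggregate emission (590 nm) to green monomer emission (520 nm);
#' a higher ratio indicates a more polarized membrane.
#'
#' @param f590 Numeric vector, red-channel intensity (arbitrary units, >= 0).
#' @param f520 Numeric vector, green-channel intensity (arbitrary units, > 0).
#' @return Numeric vector of dimensionless F590/F520 ratios.
#' @examples
#' well_ratio(0.6, 0.3) # 2
#' @export
well_ratio <- function(f590, f520) {
  if (any(!is.finite(f520)) || any(f520 <= 0)) {
    abort("invalid measurement: f520 must be finite and > 0",
          class = "mmpscreen_invalid_measurement")
  }
  if (any(!is.finite(f590)) || any(f590 < 0)) {
    abort("invalid measurement: f590 must be finite and >= 0",
          class = "mmpscreen_invalid_measurement")
  }
  f590 / f520
}

well_roles <- c("wt_control", "mt_control", "fccp_control", "treatment")

parse_well <- function(well) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (!all(ok)) {
    abort(paste0("malformed well address(es): ",
                 paste(unique(well[!ok]), collapse = ", ")),
          class = "mmpscreen_parse_error")
  }
  tibble(
    well = well,
    row = substr(well, 1, 1),
    col = as.integer(substr(well, 2, nchar(well)))
  )
}

well_name <- function(row, col) paste0(row, col)

#' Construct a screen dataset from a table of well measurements
#'
#' @param wells Tibble with columns `plate_id`, `well`, `role`,
#'   `treatment_id`, `f590`, `f520` (and optionally `ratio`, cross-checked
#'   at 1e-6 relative tolerance when supplied).
#' @param screen_type `"drug"` or `"sirna"`; controls the expected plate
#'   control layout (3 WT / 3 MT / 2 FCCP wells for drug plates, 4 WT /
#'   4 MT / no FCCP for siRNA plates).
#' @param validate Check layout invariants (default `TRUE`).
#' @return An object of class `screen_dataset`: a list with elements
#'   `screen_type` and `wells` (one row per well, with `row`, `col` and
#'   `ratio` filled in).
#' @export
screen_dataset <- function(wells, screen_type = c("drug", "sirna"),
                           validate = TRUE) {
  screen_type <- match.arg(screen_type)
  req <- c("plate_id", "well", "role", "treatment_id", "f590", "f520")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "mmpscreen_parse_error")
  }
  wells <- as_tibble(wells)
  pw <- parse_well(wells$well)
  wells$well <- pw$well
  wells$row <- pw$row
  wells$col <- pw$col
  wells$role <- as.character(wells$role)
  wells$treatment_id <- as.character(wells$treatment_id)
  computed <- well_ratio(wells$f590, wells$f520)
  if ("ratio" %in% names(wells) && any(!is.na(wells$ratio))) {
    given <- wells$ratio
    rel <- abs(given - computed) / pmax(abs(computed), .Machine$double.eps)
    bad <- which(!is.na(given) & rel > 1e-6)
    if (length(bad) > 0) {
      abort(paste0("ratio column disagrees with f590/f520 at wells: ",
                   paste(head(wells$well[bad], 5), collapse = ", ")),
            class = "mmpscreen_validation_error")
    }
  }
  wells$ratio <- computed
  wells <- relocate(wells, "plate_id", "well", "row", "col", "role",
                    "treatment_id", "f590", "f520", "ratio")
  ds <- structure(list(screen_type = screen_type, wells = wells),
                  class = "screen_dataset")
  if (validate) validate_screen(ds)
  ds
}

#' @export
print.screen_dataset <- function(x, ...) {
  w <- x$wells
  cat(sprintf("<screen_dataset: %s screen, %d plates, %d wells, %d treatments>\n",
              x$screen_type, length(unique(w$plate_id)), nrow(w),
              length(unique(w$treatment_id[w$role == "treatment"]))))
  invisible(x)
}

#' Validate screen layout invariants
#'
#' Checks well-address uniqueness per plate, role values, control-well
#' counts per plate for the screen type, treatment-id presence, and plate
#' size. Violations raise a validation error naming the offending wells.
#'
#' @param ds A [screen_dataset()].
#' @return `ds`, invisibly.
#' @export
validate_screen <- function(ds) {
  w <- ds$wells
  bad_role <- setdiff(unique(w$role), well_roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
          class = "mmpscreen_validation_error")
  }
  dup <- w |> count(.data$plate_id, .data$well) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (plate, well) entries: ",
                 paste(head(paste(dup$plate_id, dup$well), 5), collapse = ", ")),
          class = "mmpscreen_validation_error")
  }
  is_tr <- w$role == "treatment"
  has_id <- !is.na(w$treatment_id) & w$treatment_id != ""
  if (any(is_tr & !has_id)) {
    abort("treatment wells without treatment_id",
          class = "mmpscreen_validation_error")
  }
  if (any(!is_tr & has_id)) {
    abort("control wells must not carry a treatment_id",
          class = "mmpscreen_validation_error")
  }
  counts <- w |>
    group_by(.data$plate_id) |>
    summarise(
      n_wt = sum(.data$role == "wt_control"),
      n_mt = sum(.data$role == "mt_control"),
      n_fccp = sum(.data$role == "fccp_control"),
      n_treatment = sum(.data$role == "treatment"),
      n_total = n(), .groups = "drop"
    )
  expect <- if (ds$screen_type == "drug") {
    list(wt = 3L, mt = 3L, fccp = 2L, max_tr = 88L)
  } else {
    list(wt = 4L, mt = 4L, fccp = 0L, max_tr = 80L)
  }
  bad <- counts |> filter(.data$n_wt != expect$wt | .data$n_mt != expect$mt |
                          .data$n_fccp != expect$fccp |
                          .data$n_treatment > expect$max_tr |
                          .data$n_total > 96L)
  if (nrow(bad) > 0) {
    abort(paste0("plate layout violation on plate(s): ",
                 paste(bad$plate_id, collapse = ", ")),
          class = "mmpscreen_validation_error")
  }
  invisible(ds)
}

#' Read a plate-format screen CSV
#'
#' Expects header columns `plate_id, well, role, treatment_id, f590, f520`
#' and optionally `ratio` (cross-checked against f590/f520 when present).
#'
#' @param path Path to the CSV file.
#' @inheritParams screen_dataset
#' @return A [screen_dataset()].
#' @export
read_screen_csv <- function(path, screen_type = c("drug", "sirna")) {
  screen_type <- match.arg(screen_type)
  wells <- tryCatch(
    # numeric fields are read as text and converted via base R's
    # correctly-rounded parser, so full-precision round trips are exact
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("cannot parse ", path, ": ",
                                     conditionMessage(e)),
                              class = "mmpscreen_parse_error")
  )
  if (nrow(wells) == 0) {
    abort(paste0("empty screen file: ", path),
          class = "mmpscreen_parse_error")
  }
  prob <- readr::problems(wells)
  if (nrow(prob) > 0) {
    abort(paste0("malformed rows in ", path, " at line(s): ",
                 paste(head(prob$row, 5), collapse = ", ")),
          class = "mmpscreen_parse_error")
  }
  for (col in intersect(c("f590", "f520", "ratio"), names(wells))) {
    parsed <- as.numeric(wells[[col]])
    bad <- which(is.na(parsed) & !is.na(wells[[col]]) &
                   toupper(wells[[col]]) != "NA")
    if (length(bad) > 0) {
      abort(paste0("malformed numeric field ", col, " in ", path,
                   " at row(s): ", paste(head(bad, 5), collapse = ", ")),
            class = "mmpscreen_parse_error")
    }
    wells[[col]] <- parsed
  }
  screen_dataset(wells, screen_type)
}

#' Write a screen dataset to CSV
#'
#' Numeric fields are written with shortest round-trip precision, so
#' `read_screen_csv(write_screen_csv(ds, f))` reproduces all values exactly.
#'
#' @param ds A [screen_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(ds, path) {
  out <- ds$wells |>
    select("plate_id", "well", "role", "treatment_id",
           "f590", "f520", "ratio") |>
    mutate(across(c("f590", "f520", "ratio"), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Normalize one plate against its wild-type control wells
#'
#' Each well's F590/F520 ratio is divided by the arithmetic mean ratio of
#' the wild-type control wells on the same plate, so that the per-plate
#' mean of normalized WT wells is exactly 1. Intra-plate normalization
#' removes plate-to-plate scale differences.
#'
#' @param plate Tibble of wells from a single plate (as in
#'   `screen_dataset$wells`), with columns `role` and `ratio`.
#' @return The input tibble with a `normalized_ratio` column added.
#' @export
normalize_plate <- function(plate) {
  wt <- plate$ratio[plate$role == "wt_control"]
  if (length(wt) < 1) {
    abort("no wt_control wells on plate: missing normalization reference",
          class = "mmpscreen_missing_reference")
  }
  plate$normalized_ratio <- plate$ratio / mean(wt)
  plate
}

#' Normalize every plate of a screen
#'
#' @param ds A [screen_dataset()].
#' @return Tibble of all wells with a `normalized_ratio` column
#'   (plate-wise WT-referenced).
#' @export
normalize_screen <- function(ds) {
  ds$wells |>
    group_by(.data$plate_id) |>
    group_modify(~ normalize_plate(.x)) |>
    ungroup() |>
    relocate("plate_id")
}

#' Aggregate duplicate-well replicates per treatment
#'
#' Replicate normalized ratios for each treatment (one per duplicate plate)
#' are averaged; reproducibility is summarized as the coefficient of
#' variation, 100 * sample SD / mean. Treatments present on a single plate
#' are retained but flagged (`flagged = TRUE`, CV reported as 0), never
#' dropped.
#'
#' @param normalized Tibble from [normalize_screen()].
#' @return Tibble with one row per treatment: `treatment_id`, `n_rep`,
#'   `replicates` (list column), `aggregate`, `cv_percent`, `flagged`.
#' @export
aggregate_replicates <- function(normalized) {
  tr <- normalized |> filter(.data$role == "treatment")
  if (nrow(tr) == 0) {
    abort("no treatment wells to aggregate", class = "mmpscreen_validation_error")
  }
  tr |>
    group_by(.data$treatment_id) |>
    summarise(
      n_rep = n(),
      replicates = list(.data$normalized_ratio),
      aggregate = mean(.data$normalized_ratio),
      cv_percent = if (n() > 1) {
        100 * sd(.data$normalized_ratio) / mean(.data$normalized_ratio)
      } else 0,
      .groups = "drop"
    ) |>
    mutate(flagged = .data$n_rep < 2)
}

#' Write per-treatment normalized values to CSV
#'
#' @param aggregated Tibble from [aggregate_replicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_csv <- function(aggregated, path) {
  n_max <- max(aggregated$n_rep)
  reps <- purrr::map(aggregated$replicates,
                     ~ c(.x, rep(NA_real_, n_max - length(.x))))
  rep_tbl <- do.call(rbind, reps)
  colnames(rep_tbl) <- paste0("rep", seq_len(n_max))
  out <- bind_cols(
    aggregated |> select("treatment_id", "n_rep"),
    as_tibble(rep_tbl),
    aggregated |> select("aggregate", "cv_percent", "flagged")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
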
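#' Z'-factor assay quality statistic
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|, computed with
#' sample standard deviations. Z' = 1 is an ideal assay window; values
#' at or below 0 indicate overlapping control distributions. Z' is
#' invariant under a common positive rescaling of both groups, so it can
#' be computed on raw or plate-normalized ratios interchangeably.
#'
#' @param pos_values Numeric vector of positive-control readouts
#'   (here: untreated wild-type wells).
#' @param neg_values Numeric vector of negative-control readouts
#'   (here: untreated mutant wells).
#' @return Z'-factor (dimensionless, <= 1).
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    abort("z_prime needs >= 2 values per control group",
          class = "mmpscreen_insufficient_replicates")
  }
  window <- abs(mean(pos_values) - mean(neg_values))
  if (window == 0) {
    abort("control group means are equal: assay window undefined",
          class = "mmpscreen_undefined_window")
  }
  1 - 3 * (sd(pos_values) + sd(neg_values)) / window
}

#' Coefficient of variation of replicate wells
#'
#' 100 * sample SD / mean, the standard duplicate-well reproducibility
#' statistic. Scale-invariant.
#'
#' @param values Numeric vector (>= 2 replicate readouts, positive mean).
#' @return CV in percent.
#' @export
duplicate_cv <- function(values) {
  if (length(values) < 2) {
    abort("duplicate_cv needs >= 2 values",
          class = "mmpscreen_insufficient_replicates")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    abort("duplicate_cv needs a positive mean",
          class = "mmpscreen_invalid_input")
  }
  100 * sd(values) / m
}

#' Screen-level quality control report
#'
#' Computes the per-plate Z'-factor from normalized WT vs. untreated MT
#' control wells, the duplicate CV of every multi-replicate treatment, and
#' the screen-level CV summary with the acceptability flag (`all_pass_cv15`:
#' every treatment CV below 15%). Plates with missing or degenerate
#' controls are reported as QC failures (`status` column), not raised as
#' errors, and no plate is discarded on low Z'.
#'
#' @param ds A [screen_dataset()].
#' @param normalized Tibble from [normalize_screen()] on the same screen.
#' @return An object of class `screen_qc_report`: list with `plates`
#'   (per-plate Z' and control statistics), `cvs` (per-treatment CV),
#'   `cv_mean`, `cv_median`, `frac_cv_lt_10`, `frac_cv_lt_15`,
#'   `all_pass_cv15`.
#' @export
qc_screen <- function(ds, normalized) {
  plates <- normalized |>
    group_by(.data$plate_id) |>
    group_modify(function(p, key) {
      pos <- p$normalized_ratio[p$role == "wt_control"]
      neg <- p$normalized_ratio[p$role == "mt_control"]
      zp <- tryCatch(z_prime(pos, neg), error = function(e) NA_real_)
      tibble(
        z_prime = zp,
        mu_pos = mean(pos), sigma_pos = sd(pos),
        mu_neg = mean(neg), sigma_neg = sd(neg),
        n_pos = length(pos), n_neg = length(neg),
        status = if (is.na(zp)) "qc_failure" else "ok"
      )
    }) |>
    ungroup()

  agg <- aggregate_replicates(normalized)
  cvs <- agg |>
    filter(.data$n_rep >= 2) |>
    select("treatment_id", "cv_percent")
  cv <- cvs$cv_percent
  structure(list(
    plates = plates,
    cvs = cvs,
    cv_mean = if (length(cv)) mean(cv) else NA_real_,
    cv_median = if (length(cv)) median(cv) else NA_real_,
    frac_cv_lt_10 = if (length(cv)) mean(cv < 10) else NA_real_,
    frac_cv_lt_15 = if (length(cv)) mean(cv < 15) else NA_real_,
    all_pass_cv15 = length(cv) > 0 && all(cv < 15)
  ), class = "screen_qc_report")
}

#' @export
print.screen_qc_report <- function(x, ...) {
  cat(sprintf("<screen_qc_report: %d plates, Z' in [%.3f, %.3f]>\n",
              nrow(x$plates), min(x$plates$z_prime, na.rm = TRUE),
              max(x$plates$z_prime, na.rm = TRUE)))
  cat(sprintf("  duplicate CV: mean %.2f%%, median %.2f%%, %.1f%% < 10%%, all < 15%%: %s\n",
              x$cv_mean, x$cv_median, 100 * x$frac_cv_lt_10,
              x$all_pass_cv15))
  invisible(x)
}

#' Write a QC report as JSON (and optionally the per-treatment CVs as CSV)
#'
#' @param qc A `screen_qc_report` from [qc_screen()].
#' @param json_path Output JSON path.
#' @param cv_csv_path Optional CSV path for per-treatment CVs.
#' @return `json_path`, invisibly.
#' @export
write_qc_json <- function(qc, json_path, cv_csv_path = NULL) {
  payload <- list(
    plates = qc$plates,
    cv_summary = list(
      cv_mean = qc$cv_mean, cv_median = qc$cv_median,
      frac_cv_lt_10 = qc$frac_cv_lt_10, frac_cv_lt_15 = qc$frac_cv_lt_15,
      all_pass_cv15 = qc$all_pass_cv15
    )
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cv_csv_path)) readr::write_csv(qc$cvs, cv_csv_path, progress = FALSE)
  invisible(json_path)
}
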
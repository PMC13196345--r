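#' Fluorescence trace container
#'
#' One region of interest's fluorescence time series, sampled at a fixed
#' frame interval (1 frame every 2 s by default, the frame-scanning rate
#' used for Fluo-4 astrocyte recordings).
#'
#' @param cell_id Identifier.
#' @param values Numeric vector of fluorescence values (a.u., > 0,
#'   length >= 10).
#' @param dt Sampling interval in seconds (default 2).
#' @return Object of class `fluorescence_trace` with fields `cell_id`,
#'   `dt`, `values`, `duration` (= dt * (n - 1) seconds).
#' @export
fluorescence_trace <- function(cell_id, values, dt = 2) {
  values <- as.numeric(values)
  if (length(values) < 10) {
    abort("trace must have >= 10 frames", class = "mmpscreen_invalid_trace")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("trace values must be finite and > 0",
          class = "mmpscreen_invalid_trace")
  }
  if (!is.finite(dt) || dt <= 0) {
    abort("dt must be > 0", class = "mmpscreen_invalid_trace")
  }
  structure(list(cell_id = as.character(cell_id), dt = dt, values = values,
                 duration = dt * (length(values) - 1)),
            class = "fluorescence_trace")
}

#' Baseline fluorescence F0
#'
#' F0 is the 10th percentile of the trace, a conventional baseline rule
#' that ignores sparse transient frames.
#'
#' @param trace A [fluorescence_trace()].
#' @return Scalar F0 (> 0).
#' @export
baseline_f0 <- function(trace) {
  f0 <- unname(quantile(trace$values, 0.10, type = 7))
  if (!is.finite(f0) || f0 <= 0) {
    abort("non-positive baseline F0", class = "mmpscreen_invalid_trace")
  }
  f0
}

#' Detect spontaneous calcium transients in a trace
#'
#' The trace is normalized to F/F0 (F0 from [baseline_f0()]). The noise
#' scale and baseline center are estimated iteratively: the scale is
#' seeded from the median absolute first difference (transients rise and
#' decay over several frames, so frame-to-frame differences are dominated
#' by noise), then baseline frames are found by sigma-clipping
#' (discarding frames above center + 2.5 sigma) and center/scale are
#' re-estimated from the clipped frames until stable. This stays
#' calibrated even when transients occupy a large fraction of the
#' recording. An event is a run of at least `min_duration_frames`
#' consecutive frames exceeding `center + k_sigma * sigma_noise`; runs
#' separated by less than `min_separation_s` are merged, and a merged run
#' containing several transients in quick succession (the fluorescence
#' never returning to baseline between them) is split at significant
#' valleys: a drop and subsequent rise of more than `k_sigma * sigma`
#' with peaks at least `min_separation_s` apart starts a new event. The
#' event amplitude is the peak F/F0. Detection is invariant to rescaling
#' the trace by a positive constant.
#'
#' @param trace A [fluorescence_trace()].
#' @param k_sigma Threshold multiplier (default 3).
#' @param min_separation_s Merge events closer than this many seconds
#'   (default 4, i.e. 2 frames at the default sampling).
#' @param min_duration_frames Minimum frames above threshold for an event
#'   (default 2; suppresses single-frame noise excursions).
#' @return Tibble of events: `onset_index`, `peak_index`, `amplitude`
#'   (peak F/F0), `threshold` (the F/F0 detection level used).
#' @export
detect_events <- function(trace, k_sigma = 3, min_separation_s = 4,
                          min_duration_frames = 2) {
  f0 <- baseline_f0(trace)
  f <- trace$values / f0
  sigma <- 1.4826 * median(abs(diff(f))) / sqrt(2)
  if (sigma == 0) sigma <- sd(f) # degenerate flat trace
  ctr <- median(f)
  if (sigma > 0) {
    for (i in 1:6) { # sigma-clip down to baseline frames
      keep <- f <= ctr + 2.5 * sigma
      if (sum(keep) < 5) break
      ctr_new <- median(f[keep])
      sigma_new <- sd(f[keep])
      if (!is.finite(sigma_new) || sigma_new == 0) break
      done <- abs(ctr_new - ctr) < 1e-12 && abs(sigma_new - sigma) < 1e-12
      ctr <- ctr_new
      sigma <- sigma_new
      if (done) break
    }
  }
  if (!is.finite(sigma) || sigma == 0) {
    return(empty_events(ctr))
  }
  thr <- ctr + k_sigma * sigma
  above <- f > thr
  if (!any(above)) return(empty_events(thr))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ev <- tibble(start = starts[runs$values], end = ends[runs$values]) |>
    filter(.data$end - .data$start + 1 >= min_duration_frames)
  if (nrow(ev) == 0) return(empty_events(thr))
  # merge events separated by less than min_separation_s
  gap_frames <- max(1, ceiling(min_separation_s / trace$dt))
  merged <- ev[1, ]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - merged$end[nrow(merged)] - 1 < gap_frames) {
        merged$end[nrow(merged)] <- ev$end[i]
      } else {
        merged <- bind_rows(merged, ev[i, ])
      }
    }
  }
  purrr::map_dfr(seq_len(nrow(merged)), function(i) {
    seg <- merged$start[i]:merged$end[i]
    purrr::map_dfr(split_run(f[seg], k_sigma * sigma, gap_frames),
                   function(ev) {
                     sub <- seg[ev[1]:ev[2]]
                     peak <- sub[which.max(f[sub])]
                     tibble(onset_index = seg[ev[1]], peak_index = peak,
                            amplitude = f[peak], threshold = thr)
                   })
  })
}

# hysteresis splitting of one supra-threshold run into events: a new
# event starts when the trace has dropped more than `prom` below the
# running peak and then risen more than `prom` above the running valley,
# with peaks at least `min_gap` frames apart
split_run <- function(v, prom, min_gap) {
  events <- list()
  start <- 1L
  peak_v <- v[1]; peak_i <- 1L
  valley_v <- Inf; valley_i <- 1L
  descending <- FALSE
  for (k in seq_along(v)) {
    if (!descending) {
      if (v[k] > peak_v) { peak_v <- v[k]; peak_i <- k }
      if (peak_v - v[k] > prom) {
        descending <- TRUE
        valley_v <- v[k]; valley_i <- k
      }
    } else {
      if (v[k] < valley_v) { valley_v <- v[k]; valley_i <- k }
      if (v[k] - valley_v > prom && (k - peak_i) >= min_gap) {
        events[[length(events) + 1L]] <- c(start, valley_i)
        start <- valley_i + 1L
        peak_v <- v[k]; peak_i <- k
        descending <- FALSE
      }
    }
  }
  events[[length(events) + 1L]] <- c(start, length(v))
  events
}

empty_events <- function(thr) {
  tibble(onset_index = integer(), peak_index = integer(),
         amplitude = numeric(), threshold = numeric())
}

#' Per-cell summary of detected transients
#'
#' @param trace A [fluorescence_trace()].
#' @param events Tibble from [detect_events()] on the same trace.
#' @param min_events Minimum number of events for the cell to be called
#'   oscillating (default 2).
#' @return Tibble row: `cell_id`, `n_events`, `mean_amplitude` (NA when no
#'   events), `frequency` (events per minute of recording), `oscillating`.
#' @export
summarize_trace <- function(trace, events, min_events = 2) {
  n_ev <- nrow(events)
  tibble(
    cell_id = trace$cell_id,
    n_events = n_ev,
    mean_amplitude = if (n_ev >= 1) mean(events$amplitude) else NA_real_,
    frequency = n_ev / (trace$duration / 60),
    oscillating = n_ev >= min_events
  )
}

#' Group-level calcium activity summary
#'
#' The percentage of oscillating cells is computed over all cells;
#' amplitude and frequency statistics (mean +/- SEM, SEM = SD / sqrt(n))
#' are computed over oscillating cells only, matching how spontaneous
#' activity is conventionally reported.
#'
#' @param summaries Tibble of rows from [summarize_trace()].
#' @param label Group label.
#' @return List of class `group_summary`: `label`, `n_cells`,
#'   `n_oscillating`, `pct_oscillating`, `amplitude_mean`, `amplitude_sem`,
#'   `frequency_mean`, `frequency_sem` (amplitude/frequency are `NA` when
#'   no cell oscillates).
#' @export
summarize_group <- function(summaries, label = "group") {
  if (nrow(summaries) < 1) {
    abort("no cells to summarize", class = "mmpscreen_invalid_input")
  }
  osc <- summaries |> filter(.data$oscillating)
  n_osc <- nrow(osc)
  sem <- function(x) sd(x) / sqrt(length(x))
  structure(list(
    label = label,
    n_cells = nrow(summaries),
    n_oscillating = n_osc,
    pct_oscillating = 100 * n_osc / nrow(summaries),
    amplitude_mean = if (n_osc) mean(osc$mean_amplitude) else NA_real_,
    amplitude_sem = if (n_osc > 1) sem(osc$mean_amplitude) else NA_real_,
    frequency_mean = if (n_osc) mean(osc$frequency) else NA_real_,
    frequency_sem = if (n_osc > 1) sem(osc$frequency) else NA_real_
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary %s: %d cells, %.1f%% oscillating, amplitude %.2f +/- %.2f, frequency %.2f +/- %.2f /min>\n",
    x$label, x$n_cells, x$pct_oscillating,
    x$amplitude_mean, x$amplitude_sem, x$frequency_mean, x$frequency_sem))
  invisible(x)
}

#' Run detection and summaries over a set of traces
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param label Group label for the summary.
#' @param ... Passed to [detect_events()].
#' @param min_events Oscillating-cell criterion (default 2).
#' @return List with `per_cell` (tibble) and `group` (`group_summary`).
#' @export
analyze_traces <- function(traces, label = "group", min_events = 2, ...) {
  per_cell <- purrr::map_dfr(traces, function(tr) {
    summarize_trace(tr, detect_events(tr, ...), min_events = min_events)
  })
  list(per_cell = per_cell, group = summarize_group(per_cell, label))
}

#' Read ROI traces from long-format CSV
#'
#' Expects columns `cell_id`, `frame`, `fluorescence`.
#'
#' @param path CSV path.
#' @param dt Sampling interval in seconds (default 2).
#' @return List of [fluorescence_trace()] objects, one per cell.
#' @export
read_traces_csv <- function(path, dt = 2) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  req <- c("cell_id", "frame", "fluorescence")
  if (!all(req %in% names(d))) {
    abort("traces CSV needs columns cell_id, frame, fluorescence",
          class = "mmpscreen_parse_error")
  }
  d$frame <- as.integer(d$frame)
  d$fluorescence <- as.numeric(d$fluorescence) # base parser: exact round trip
  d |>
    arrange(.data$cell_id, .data$frame) |>
    group_by(.data$cell_id) |>
    group_map(~ fluorescence_trace(.y$cell_id, .x$fluorescence, dt = dt))
}

#' Write ROI traces to long-format CSV
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  d <- purrr::map_dfr(traces, function(tr) {
    tibble(cell_id = tr$cell_id, frame = seq_along(tr$values),
           fluorescence = sprintf("%.17g", tr$values))
  })
  readr::write_csv(d, path, progress = FALSE)
  invisible(path)
}
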
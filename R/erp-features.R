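#' Measurement windows of the three ERP components
#'
#' Returns the window constants a component is measured with. All windows
#' are closed intervals in ms relative to the component's lock event:
#'
#' * `cnv` — onset-locked; baseline `[-200, 0]`; climbing-rate regression
#'   window `[250, 650]`; peak = most negative sample in `[0, 1600]`;
#'   mean window `[250, 250 + duration]` (extends past the stimulus offset
#'   for every duration below 1600 ms by construction of the printed rule).
#' * `offset_p2` — offset-locked; baseline `[-50, 50]` around the offset;
#'   peak = most positive sample in `[0, 500]`; mean window `[140, 300]`.
#' * `lpct` — cue-locked (question mark = offset + response gap); baseline
#'   `[-50, 50]` around the cue; peak = most positive sample in `[0, 500]`;
#'   mean window `[300, 500]` relative to the stimulus *offset* (the mean
#'   and the baseline deliberately use different locks).
#'
#' Peak amplitudes are always the mean over the 10 ms surrounding the peak
#' (5 ms either side).
#'
#' @param component `"cnv"`, `"offset_p2"` or `"lpct"`.
#' @return A list with `component`, `lock`, `baseline_window`,
#'   `search_window`, `mean_window`, `mean_lock`, `polarity`,
#'   `peak_halfwidth_ms`.
#' @export
component_spec <- function(component = c("cnv", "offset_p2", "lpct")) {
  component <- match.arg(component)
  switch(component,
    cnv = list(component = "cnv", lock = "onset",
               baseline_window = c(-200, 0), search_window = c(0, 1600),
               rate_window = c(250, 650), mean_window = NULL,
               mean_lock = "onset", polarity = "negative",
               peak_halfwidth_ms = 5),
    offset_p2 = list(component = "offset_p2", lock = "offset",
                     baseline_window = c(-50, 50), search_window = c(0, 500),
                     mean_window = c(140, 300), mean_lock = "offset",
                     polarity = "positive", peak_halfwidth_ms = 5),
    lpct = list(component = "lpct", lock = "cue",
                baseline_window = c(-50, 50), search_window = c(0, 500),
                mean_window = c(300, 500), mean_lock = "offset",
                polarity = "positive", peak_halfwidth_ms = 5)
  )
}

# per-trial lock times (ms relative to stimulus onset) for an epoch_set
lock_times <- function(epochs, lock) {
  switch(lock,
    onset = rep(0, nrow(epochs$info)),
    offset = epochs$info$duration_ms,
    cue = epochs$info$cue_latency_ms,
    abort(paste0("Unknown lock event '", lock, "'."))
  )
}

#' Baseline-correct an epoch set
#'
#' Subtracts, from every trial, its mean amplitude over a window relative
#' to a lock event (stimulus onset, stimulus offset, or response cue).
#' Offset- and cue-relative windows are resolved per trial from the trial
#' metadata, since offsets differ across trials.
#'
#' @param epochs An [epoch_set()].
#' @param lock `"onset"`, `"offset"` or `"cue"`.
#' @param window Closed window `c(from, to)` in ms relative to the lock.
#' @return The baseline-corrected [epoch_set()] (baseline recorded).
#' @export
baseline_correct <- function(epochs, lock = "onset", window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  locks <- lock_times(epochs, lock)
  times <- epochs$times
  for (i in seq_len(nrow(epochs$data))) {
    idx <- which(times >= locks[i] + window[1] & times <= locks[i] + window[2])
    if (length(idx) == 0 || locks[i] + window[1] < times[1] ||
        locks[i] + window[2] > times[length(times)]) {
      abort(paste0("Baseline window [", window[1], ", ", window[2],
                   "] ms relative to ", lock, " falls outside the epoch grid",
                   " for trial ", i, "."))
    }
    epochs$data[i, ] <- epochs$data[i, ] - mean(epochs$data[i, idx])
  }
  epochs$baseline <- list(lock = lock, window = window)
  epochs
}

#' Average epochs within participant x context x duration cells
#'
#' Pointwise arithmetic mean of all trials in each cell. Metadata of the
#' returned set records the number of trials per cell (`n_trials`);
#' ground-truth columns, if present, are averaged within the cell.
#'
#' @param epochs An [epoch_set()].
#' @param by Grouping columns (must exist in the metadata).
#' @return An [epoch_set()] with one row per cell.
#' @export
condition_average <- function(epochs,
                              by = c("participant", "context", "duration_ms")) {
  stopifnot(inherits(epochs, "epoch_set"))
  info <- epochs$info
  if (!all(by %in% names(info))) {
    abort(paste("Grouping columns missing from metadata:",
                paste(setdiff(by, names(info)), collapse = ", ")))
  }
  key <- do.call(paste, c(info[by], sep = "\r"))
  groups <- split(seq_len(nrow(info)), key)
  if (any(lengths(groups) == 0)) abort("Empty condition cell.")

  keep_num <- intersect(c("cue_latency_ms", "response_gap_ms",
                          "true_slope_uv_s", "true_plateau_uv"), names(info))
  cells <- info |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(keep_num), mean),
      n_trials = dplyr::n(), .groups = "drop"
    )
  if ("experiment" %in% names(info)) {
    cells <- dplyr::left_join(
      cells, dplyr::distinct(info, dplyr::across(dplyr::all_of(c(by, "experiment")))),
      by = by)
  }
  cell_key <- do.call(paste, c(cells[by], sep = "\r"))
  avg <- matrix(0, nrow(cells), ncol(epochs$data))
  for (j in seq_len(nrow(cells))) {
    rows <- groups[[cell_key[j]]]
    avg[j, ] <- colMeans(epochs$data[rows, , drop = FALSE])
  }
  epoch_set(avg, epochs$times, cells, lock = epochs$lock,
            baseline = epochs$baseline)
}

# resolve (wave, times) from either a template tibble or a pair of vectors
wave_times <- function(wave, times) {
  if (is.data.frame(wave)) {
    list(v = wave$amplitude_uv, t = wave$time_ms)
  } else {
    if (is.null(times)) abort("Supply `times` when `wave` is a bare vector.")
    list(v = as.numeric(wave), t = as.numeric(times))
  }
}

window_idx <- function(t, window, what = "Window") {
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    abort(paste0(what, " [", window[1], ", ", window[2],
                 "] ms is not covered by the waveform grid [",
                 t[1], ", ", t[length(t)], "] ms."))
  }
  which(t >= window[1] & t <= window[2])
}

#' CNV climbing rate of an averaged waveform
#'
#' Ordinary least-squares slope of amplitude against time over the early
#' CNV build-up window (default 250-650 ms after stimulus onset, i.e.
#' after the onset P2), expressed in uV/s.
#'
#' @param wave A waveform: either a tibble with `time_ms` and
#'   `amplitude_uv` (as returned by [erp_template()]) or a numeric vector
#'   with `times` supplied.
#' @param times Sample times (ms) when `wave` is a bare vector.
#' @param window Closed regression window, ms after onset.
#' @return Slope in uV/s.
#' @export
cnv_climbing_rate <- function(wave, times = NULL, window = c(250, 650)) {
  wt <- wave_times(wave, times)
  idx <- window_idx(wt$t, window, "Climbing-rate window")
  fit <- lm(amp ~ t_s, data = data.frame(amp = wt$v[idx], t_s = wt$t[idx] / 1000))
  unname(coef(fit)[["t_s"]])
}

#' Peak latency and amplitude of an averaged waveform
#'
#' Finds the extremum of the stated polarity inside a closed search
#' window; ties resolve to the earliest sample. The peak amplitude is the
#' mean over the 10 ms surrounding the peak (5 ms either side), clipped to
#' the grid (and flagged) if the peak sits within 5 ms of the epoch edge.
#' An extremum landing exactly on a window edge is returned but flagged.
#'
#' @inheritParams cnv_climbing_rate
#' @param polarity `"negative"` (minimum) or `"positive"` (maximum).
#' @param search_window Closed search window, ms (same time base as the
#'   waveform).
#' @param halfwidth_ms Half-width of the amplitude averaging window.
#' @return One-row tibble: `peak_latency_ms`, `peak_amplitude_uv`,
#'   `at_edge`, `clipped`.
#' @export
peak_measure <- function(wave, times = NULL,
                         polarity = c("negative", "positive"),
                         search_window, halfwidth_ms = 5) {
  polarity <- match.arg(polarity)
  wt <- wave_times(wave, times)
  idx <- window_idx(wt$t, search_window, "Peak search window")
  v <- wt$v[idx]
  pos <- if (polarity == "negative") which.min(v) else which.max(v)
  peak_t <- wt$t[idx[pos]]
  amp_win <- c(peak_t - halfwidth_ms, peak_t + halfwidth_ms)
  clipped <- amp_win[1] < wt$t[1] || amp_win[2] > wt$t[length(wt$t)]
  aidx <- which(wt$t >= amp_win[1] & wt$t <= amp_win[2])
  tibble::tibble(
    peak_latency_ms = peak_t,
    peak_amplitude_uv = mean(wt$v[aidx]),
    at_edge = pos == 1L || pos == length(idx),
    clipped = clipped
  )
}

#' Mean amplitude over a closed window
#'
#' @inheritParams cnv_climbing_rate
#' @param window Closed window, ms (same time base as the waveform).
#' @return Mean amplitude in uV.
#' @export
windowed_mean_amplitude <- function(wave, times = NULL, window) {
  wt <- wave_times(wave, times)
  idx <- window_idx(wt$t, window, "Mean-amplitude window")
  mean(wt$v[idx])
}

#' Latency at which the waveform turns from negative to positive
#'
#' Scans the onset-locked average for the first sample pair with
#' `value(t[i]) < 0 <= value(t[i+1])` and `t[i] >= after_ms`, then refines
#' the crossing by linear interpolation between the two samples. Returns
#' `NA` (a value, not an error) if the waveform never crosses before the
#' grid ends.
#'
#' @inheritParams cnv_climbing_rate
#' @param after_ms Earliest time (ms after onset) a crossing counts.
#' @return Crossing latency in ms, or `NA_real_`.
#' @export
crossing_latency <- function(wave, times = NULL, after_ms = 650) {
  wt <- wave_times(wave, times)
  n <- length(wt$v)
  ok <- which(wt$t[-n] >= after_ms & wt$v[-n] < 0 & wt$v[-1] >= 0)
  if (length(ok) == 0) return(NA_real_)
  i <- ok[1]
  v0 <- wt$v[i]; v1 <- wt$v[i + 1]
  wt$t[i] + (0 - v0) / (v1 - v0) * (wt$t[i + 1] - wt$t[i])
}

#' Extract the full ERP feature table from an epoch set
#'
#' Runs the complete measurement chain: for each component, baseline
#' correction at its own lock ([component_spec()]), averaging within
#' participant x context x duration cells, and the component's measures.
#' Returns one row per cell with units as suffixed in the column names.
#'
#' Latencies of offset-P2 and LPCt are reported relative to their lock
#' events (stimulus offset and response cue); CNV measures and the
#' crossing latency are onset-relative.
#'
#' @param epochs An [epoch_set()] of single trials (or of averages if
#'   every cell holds one "trial").
#' @param components Which components to measure.
#' @param include_crossing Also compute the post-650-ms negative-to-positive
#'   crossing latency of the CNV average.
#' @param single_trial If `TRUE`, measures are computed per trial rather
#'   than on condition averages (exploratory; the standard chain averages
#'   first).
#' @return An `erp_features` tibble: `participant`, `context`,
#'   `duration_ms`, `n_trials`, then per-component measure columns.
#' @export
extract_erp_features <- function(epochs,
                                 components = c("cnv", "offset_p2", "lpct"),
                                 include_crossing = TRUE,
                                 single_trial = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  components <- match.arg(components, several.ok = TRUE)
  by <- c("participant", "context", "duration_ms")
  if (single_trial) by <- c(by, "trial_id")

  out <- NULL
  for (comp in components) {
    spec <- component_spec(comp)
    bl <- baseline_correct(epochs, spec$lock, spec$baseline_window)
    avg <- condition_average(bl, by = by)
    cells <- avg$info
    rows <- purrr::map_dfr(seq_len(nrow(cells)), function(j) {
      measure_component(avg$data[j, ], avg$times, cells[j, ], spec,
                        include_crossing = include_crossing && comp == "cnv")
    })
    block <- dplyr::bind_cols(cells[by], cells["n_trials"], rows)
    out <- if (is.null(out)) block else
      dplyr::left_join(out, dplyr::select(block, -"n_trials"), by = by)
  }
  truth <- intersect(c("true_slope_uv_s", "true_plateau_uv"),
                     names(epochs$info))
  if (length(truth) > 0) {
    truth_tbl <- epochs$info |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(truth), mean),
                       .groups = "drop")
    out <- dplyr::left_join(out, truth_tbl, by = by)
  }
  class(out) <- c("erp_features", class(out))
  out
}

# measures of one component on one averaged cell waveform
measure_component <- function(wave, times, cell, spec, include_crossing) {
  lock_t <- switch(spec$lock, onset = 0, offset = cell$duration_ms,
                   cue = cell$cue_latency_ms)
  prefix <- switch(spec$component, cnv = "cnv", offset_p2 = "p2", lpct = "lpct")

  pk <- peak_measure(wave, times, polarity = spec$polarity,
                     search_window = lock_t + spec$search_window,
                     halfwidth_ms = spec$peak_halfwidth_ms)
  res <- tibble::tibble(
    "{prefix}_peak_latency_ms" := pk$peak_latency_ms - lock_t,
    "{prefix}_peak_amplitude_uv" := pk$peak_amplitude_uv,
    "{prefix}_peak_flag" := pk$at_edge | pk$clipped
  )
  if (spec$component == "cnv") {
    mean_win <- c(250, 250 + cell$duration_ms)
    res <- dplyr::bind_cols(
      tibble::tibble(
        cnv_rate_uv_s = cnv_climbing_rate(wave, times, spec$rate_window),
        cnv_mean_amplitude_uv = windowed_mean_amplitude(wave, times, mean_win)
      ),
      res
    )
    if (include_crossing) {
      res$crossing_latency_ms <- crossing_latency(wave, times, after_ms = 650)
    }
  } else {
    mean_lock_t <- switch(spec$mean_lock, onset = 0, offset = cell$duration_ms,
                          cue = cell$cue_latency_ms)
    res[[paste0(prefix, "_mean_amplitude_uv")]] <-
      windowed_mean_amplitude(wave, times, mean_lock_t + spec$mean_window)
  }
  res
}

#' Plot condition-averaged ERP waveforms
#'
#' Averages the epoch set within context x duration cells (collapsing
#' participants) and draws the grand-average waveforms per duration,
#' faceted by context.
#'
#' @param epochs An [epoch_set()], ideally baseline-corrected.
#' @param max_time_ms Right edge of the plotted time axis.
#' @return A ggplot object.
#' @export
plot_erp <- function(epochs, max_time_ms = 2400) {
  avg <- condition_average(epochs, by = c("context", "duration_ms"))
  df <- as_tibble(avg) |> dplyr::filter(.data$time_ms <= max_time_ms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv,
                                   color = factor(.data$duration_ms))) +
    ggplot2::geom_hline(yintercept = 0, alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~context) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Amplitude (uV, negative up)",
                  color = "Duration (ms)") +
    ggplot2::theme_minimal()
}

#' Write / read an ERP feature table as columnar text
#'
#' @param features An `erp_features` tibble.
#' @param path File path (tab-separated; units are part of column names).
#' @export
write_erp_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_erp_features
#' @export
read_erp_features <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("erp_features", class(out))
  out
}
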
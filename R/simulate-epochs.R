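#' Epoch container for a single virtual channel
#'
#' An `epoch_set` holds a trials-by-samples waveform matrix on one shared
#' time grid (ms relative to stimulus onset), plus one metadata row per
#' trial. It is the unit of exchange between the simulator and the ERP
#' measurement functions.
#'
#' @param data Numeric matrix, trials in rows, samples in columns (uV).
#' @param times Numeric vector of sample times (ms, uniform step).
#' @param info Tibble with one row per trial; must contain `participant`,
#'   `context`, `duration_ms`, `cue_latency_ms`.
#' @param lock Event the grid is locked to (always `"onset"` for simulated
#'   epochs; offset- and cue-relative windows are resolved per trial from
#'   the metadata).
#' @param baseline `NULL`, or a record of the baseline correction applied.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, info, lock = "onset", baseline = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != length(times)) {
    abort("ncol(data) must equal length(times).")
  }
  if (nrow(data) != nrow(info)) {
    abort("info must have one row per trial (row of data).")
  }
  need <- c("context", "duration_ms", "cue_latency_ms")
  if (!all(need %in% names(info))) {
    abort(paste("info must contain columns:", paste(need, collapse = ", ")))
  }
  structure(
    list(data = data, times = as.numeric(times),
         info = tibble::as_tibble(info), lock = lock, baseline = baseline),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$data), " trials x ", ncol(x$data), " samples (",
      x$times[1], " to ", x$times[length(x$times)], " ms, step ",
      x$times[2] - x$times[1], " ms)\n", sep = "")
  bl <- if (is.null(x$baseline)) "none" else
    paste0(x$baseline$lock, " [", x$baseline$window[1], ", ",
           x$baseline$window[2], "] ms")
  cat("  baseline: ", bl, "\n", sep = "")
  print(dplyr::count(x$info, .data$context, name = "trials"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.epoch_set <- function(x, ...) x$info

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.epoch_set <- function(x, ...) {
  n <- nrow(x$data)
  nt <- length(x$times)
  dplyr::bind_cols(
    x$info[rep(seq_len(n), each = nt), ],
    tibble::tibble(time_ms = rep(x$times, n),
                   amplitude_uv = as.vector(t(x$data)))
  )
}

# seeded band-limited noise matrix: white (flat) and/or 1/f^chi spectra,
# brick-wall low-passed, scaled so each sample has the target sd.
# `sd_uv` and `exponent` may be vectors of component pairs; independent
# components add in quadrature per frequency and are synthesized in one pass.
noise_matrix <- function(n_trials, n_samples, fs, sd_uv, exponent = 0,
                         lowpass_hz = Inf) {
  keep <- sd_uv > 0
  sd_uv <- sd_uv[keep]
  exponent <- rep_len(exponent, length(keep))[keep]
  if (length(sd_uv) == 0 || n_trials == 0) {
    return(matrix(0, n_trials, n_samples))
  }
  # frequency grid of a 2-3-5-smooth padded window, so the noise is not
  # periodic over the (shorter) epoch
  n_fft <- stats::nextn(n_samples)
  freq <- (1:(n_fft %/% 2)) * fs / n_fft
  active <- freq <= lowpass_hz
  if (sum(active) <= 400) {
    # band-limited case: random-phase harmonic synthesis; per-sample
    # variance is sum of squared component amplitudes (stationary)
    f <- freq[active]
    amp2 <- rep(0, length(f))
    for (j in seq_along(sd_uv)) {
      a <- if (exponent[j] > 0) f^(-exponent[j] / 2) else rep(1, length(f))
      amp2 <- amp2 + a^2 * sd_uv[j]^2 / sum(a^2)
    }
    amp <- sqrt(amp2)
    t_idx <- 0:(n_samples - 1)
    arg <- 2 * pi * outer(f, t_idx) / fs                 # m x n_samples
    basis <- rbind(cos(arg), sin(arg))                   # 2m x n_samples
    coef <- sweep(matrix(rnorm(n_trials * 2 * length(f)), nrow = n_trials),
                  2, rep(amp, 2), "*")
    coef %*% basis
  } else {
    # broadband case: spectral shaping by FFT filtering of white noise
    k <- 0:(n_fft - 1)
    fr <- pmin(k, n_fft - k) * fs / n_fft
    h2 <- rep(0, n_fft)
    for (j in seq_along(sd_uv)) {
      hj <- ifelse(fr > 0 & fr <= lowpass_hz,
                   ifelse(rep(exponent[j], n_fft) > 0, fr^(-exponent[j] / 2), 1),
                   0)
      h2 <- h2 + hj^2 * sd_uv[j]^2 / mean(hj^2)
    }
    h <- sqrt(h2)
    white <- matrix(rnorm(n_trials * n_fft), nrow = n_fft)
    spec <- mvfft(white) * h
    out <- t(Re(mvfft(spec, inverse = TRUE)) / n_fft)
    out[, seq_len(n_samples), drop = FALSE]
  }
}

#' Simulate an epoch set for a trial schedule
#'
#' Generates one epoch per schedule row and participant: the noiseless
#' [erp_template()] for the trial's duration and context (with
#' per-participant CNV slope and plateau offsets, drawn once per
#' participant and shared across contexts), plus band-limited white noise
#' and optional 1/f^chi noise. Output is bit-reproducible given
#' `(schedule, params, n_participants, seed)`.
#'
#' @param schedule Schedule tibble (one or more contexts row-bound); must
#'   carry `duration_ms`, `context` and `response_gap_ms`.
#' @param params An [erp_params()] object.
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return An [epoch_set()] with per-trial ground truth (`true_slope_uv_s`,
#'   `true_plateau_uv`) in its metadata.
#' @examples
#' sched <- enumerate_trials(bisection_design("exp1", "PS"), seed = 1)[1:8, ]
#' ep <- simulate_epochs(sched, erp_params(), n_participants = 1, seed = 2)
#' dim(ep$data)
#' @export
simulate_epochs <- function(schedule, params, n_participants, seed) {
  stopifnot(inherits(params, "erp_params"))
  need <- c("duration_ms", "context", "response_gap_ms")
  if (!all(need %in% names(schedule))) {
    abort("schedule must contain duration_ms, context and response_gap_ms.")
  }
  times <- epoch_times(params)
  n_per <- nrow(schedule)

  withr::with_seed(as.integer(seed), {
    subj <- tibble::tibble(
      participant = seq_len(n_participants),
      slope_offset = rnorm(n_participants, 0, params$slope_sd),
      plateau_offset = rnorm(n_participants, 0, params$plateau_sd)
    )
    info <- tidyr::crossing(subj, schedule) |>
      dplyr::arrange(.data$participant, .data$trial) |>
      dplyr::mutate(
        true_slope_uv_s = pmin(-1, ctx_vec(params$cnv_slope, .data$context) +
                                 .data$slope_offset),
        true_plateau_uv = pmin(-1, ctx_vec(params$plateau_uv, .data$context) +
                                 .data$plateau_offset),
        cue_latency_ms = .data$duration_ms + .data$response_gap_ms
      ) |>
      dplyr::select(-"slope_offset", -"plateau_offset")

    data <- matrix(0, nrow(info), length(times))
    cells <- dplyr::distinct(info, .data$context, .data$duration_ms,
                             .data$response_gap_ms, .data$true_slope_uv_s,
                             .data$true_plateau_uv)
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      tpl <- erp_template_vec(times, cell$duration_ms, cell$context, params,
                              cell$response_gap_ms,
                              slope_uv_s = cell$true_slope_uv_s,
                              plateau_uv = cell$true_plateau_uv)
      rows <- which(info$context == cell$context &
                      info$duration_ms == cell$duration_ms &
                      info$response_gap_ms == cell$response_gap_ms &
                      info$true_slope_uv_s == cell$true_slope_uv_s &
                      info$true_plateau_uv == cell$true_plateau_uv)
      data[rows, ] <- matrix(tpl, length(rows), length(times), byrow = TRUE)
    }
    if (params$noise_sd_uv > 0 || params$pink_sd_uv > 0) {
      data <- data + noise_matrix(
        nrow(info), length(times), params$sampling_rate_hz,
        sd_uv = c(params$noise_sd_uv, params$pink_sd_uv),
        exponent = c(0, params$pink_exponent),
        lowpass_hz = params$noise_lowpass_hz
      )
    }
  })

  info$trial_id <- seq_len(nrow(info))
  epoch_set(data, times, info, lock = "onset")
}

# vectorized context-parameter lookup
ctx_vec <- function(value, contexts) {
  if (is.null(names(value))) return(rep(unname(value[1]), length(contexts)))
  out <- unname(value[contexts])
  out[is.na(out)] <- unname(value[1])
  out
}

#' Write / read an epoch set as text plus JSON sidecar
#'
#' The waveform matrix goes to `<prefix>.tsv` (one row per trial, no
#' header) and the grid, lock, baseline record and trial metadata to
#' `<prefix>.json`.
#'
#' @param epochs An [epoch_set()].
#' @param prefix Path prefix (without extension).
#' @return `write_epoch_set()` returns `prefix` invisibly;
#'   `read_epoch_set()` returns an [epoch_set()].
#' @export
write_epoch_set <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(epochs$data),
                                     .name_repair = "minimal"),
                   paste0(prefix, ".tsv"), col_names = FALSE)
  sidecar <- list(
    times = list(start_ms = epochs$times[1],
                 step_ms = epochs$times[2] - epochs$times[1],
                 n = length(epochs$times)),
    lock = epochs$lock,
    baseline = epochs$baseline,
    info = epochs$info
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(readr::read_tsv(paste0(prefix, ".tsv"),
                                    col_names = FALSE, show_col_types = FALSE))
  dimnames(data) <- NULL
  times <- side$times$start_ms + side$times$step_ms * (0:(side$times$n - 1))
  baseline <- side$baseline
  if (!is.null(baseline)) baseline$window <- as.numeric(baseline$window)
  epoch_set(data, times, tibble::as_tibble(side$info),
            lock = side$lock, baseline = baseline)
}

#' Import epochs from a BrainVision-style ASCII export
#'
#' Convenience reader for epoch waveforms exported as plain text from
#' BrainVision-style tooling: an optional block of non-numeric header
#' lines followed by a numeric matrix, either one trial per row
#' (`orientation = "rows"`) or one trial per column
#' (`orientation = "columns"`, i.e. samples down the file). The caller
#' supplies the grid and per-trial metadata, which such exports do not
#' carry in machine-readable form.
#'
#' @param path Path to the exported text file.
#' @param info Tibble of per-trial metadata (see [epoch_set()]).
#' @param start_ms Time of the first sample, ms relative to stimulus onset.
#' @param sampling_rate_hz Sampling rate of the export, Hz.
#' @param orientation `"rows"` or `"columns"` (trials per row / per column).
#' @param sep Field separator (default: any whitespace).
#' @return An [epoch_set()].
#' @export
read_brainvision_epochs <- function(path, info, start_ms, sampling_rate_hz,
                                    orientation = c("rows", "columns"),
                                    sep = "") {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  is_num <- grepl("^\\s*[-+0-9]", lines)
  first <- which(is_num)[1]
  if (is.na(first)) abort("No numeric data found in file.")
  mat <- as.matrix(utils::read.table(text = lines[first:length(lines)],
                                     sep = sep, dec = "."))
  dimnames(mat) <- NULL
  if (orientation == "columns") mat <- t(mat)
  times <- start_ms + (0:(ncol(mat) - 1)) * 1000 / sampling_rate_hz
  epoch_set(mat, times, info, lock = "onset")
}
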
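#' Simulate bisection responses from a logistic observer
#'
#' Draws Bernoulli "long"/"short" judgments for every trial of a schedule
#' and every simulated participant. The schedule may span several contexts
#' (bind the per-context schedules with [dplyr::bind_rows()]): participant
#' threshold offsets and slopes are drawn once per participant and shared
#' across their contexts, so within-participant context effects are driven
#' solely by the ensemble-mean pull `context_weight`.
#'
#' The ensemble mean of each context is computed from the schedule's own
#' duration tallies (identical to [ensemble_mean()] of the generating
#' design, since `enumerate_trials()` preserves counts exactly).
#'
#' Per-participant thresholds are clamped to stay 50 ms inside the anchors.
#'
#' @param schedule Schedule tibble from [enumerate_trials()] (one or more
#'   contexts row-bound).
#' @param params A [behavior_params()] object.
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed; output is a pure function of inputs and seed.
#' @param anchors Short/long anchor pair (ms) used for threshold clamping.
#' @return A tibble of bisection trials: `participant`, `context`,
#'   `experiment`, `trial`, `duration_ms`, `response` ("short"/"long"),
#'   plus the per-trial ground truth `true_threshold_ms`, `true_slope_ms`.
#' @examples
#' sched <- enumerate_trials(bisection_design("exp1", "PS"), seed = 1)
#' trials <- simulate_responses(sched, behavior_params(), n_participants = 2, seed = 7)
#' dplyr::count(trials, response)
#' @export
simulate_responses <- function(schedule, params, n_participants, seed,
                               anchors = c(400, 1600)) {
  stopifnot(inherits(params, "behavior_params"))
  if (params$slope_ms <= 0) abort("Logistic slope must be positive.")
  need <- c("trial", "duration_ms", "context")
  if (!all(need %in% names(schedule))) {
    abort("schedule must contain columns trial, duration_ms, context.")
  }

  ens <- schedule |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(ensemble_ms = mean(.data$duration_ms), .groups = "drop")

  withr::with_seed(as.integer(seed), {
    subj <- tibble::tibble(
      participant = seq_len(n_participants),
      threshold_offset_ms = rnorm(n_participants, 0, params$threshold_sd_ms),
      true_slope_ms = pmax(20, rnorm(n_participants, params$slope_ms,
                                     params$slope_sd_ms))
    )
    out <- tidyr::crossing(subj, schedule) |>
      dplyr::left_join(ens, by = "context") |>
      dplyr::mutate(
        true_threshold_ms = pmin(
          anchors[2] - 50,
          pmax(anchors[1] + 50,
               (1 - params$context_weight) * params$base_threshold_ms +
                 params$context_weight * .data$ensemble_ms +
                 .data$threshold_offset_ms)
        ),
        p_long = params$lapse / 2 + (1 - params$lapse) *
          stats::plogis((.data$duration_ms - .data$true_threshold_ms) /
                          .data$true_slope_ms),
        response = ifelse(runif(dplyr::n()) < .data$p_long, "long", "short")
      )
  })

  cols <- c("participant", "context", "trial", "duration_ms", "response",
            "true_threshold_ms", "true_slope_ms")
  if ("experiment" %in% names(out)) cols <- c(cols[1:2], "experiment", cols[-(1:2)])
  dplyr::select(out, dplyr::all_of(cols)) |>
    dplyr::arrange(.data$participant, .data$context, .data$trial)
}

#' Probability of a "long" response under the generator's observer model
#'
#' @param duration_ms Probe duration(s), ms.
#' @param threshold_ms Logistic threshold alpha, ms.
#' @param slope_ms Logistic scale beta, ms (> 0).
#' @param lapse Lapse rate lambda, split between asymptotes.
#' @return Probability vector.
#' @export
p_long <- function(duration_ms, threshold_ms, slope_ms, lapse = 0) {
  if (slope_ms <= 0) abort("slope_ms must be positive.")
  lapse / 2 + (1 - lapse) * stats::plogis((duration_ms - threshold_ms) / slope_ms)
}

#' Write / read bisection trial tables as columnar text
#'
#' @param trials Trials tibble (one row per trial).
#' @param path File path (tab-separated text).
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
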
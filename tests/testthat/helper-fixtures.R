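# shared fixtures: all built in code, scaled for fast tests

# schedule with one trial per duration for the given arm
unit_schedule <- function(experiment, context) {
  d <- bisection_design(experiment, context)
  tibble::tibble(
    trial = seq_along(d$durations_ms),
    block = 1L,
    duration_ms = d$durations_ms,
    context = context,
    experiment = experiment,
    response_gap_ms = d$response_gap_ms
  )
}

params_with <- function(defaults, overrides) {
  defaults[names(overrides)] <- overrides
  do.call(erp_params, defaults)
}

# erp params with all phasic components silenced: pure CNV, no noise
cnv_only_params <- function(...) {
  params_with(list(n1_amp_uv = 0, p2_amp_uv = 0,
                   offp2_amp0_uv = 0, offp2_amp_gain = 0,
                   lpct_amp0_uv = 0, lpct_amp_gain = 0,
                   noise_sd_uv = 0, pink_sd_uv = 0,
                   slope_sd = 0, plateau_sd = 0), list(...))
}

# noiseless, heterogeneity-free defaults (all components present)
quiet_params <- function(...) {
  params_with(list(noise_sd_uv = 0, pink_sd_uv = 0,
                   slope_sd = 0, plateau_sd = 0), list(...))
}

# trial table with exact per-duration "long" counts (noiseless proportions)
trials_from_counts <- function(durations, n_per, k_long,
                               participant = 1, context = "PS") {
  purrr::map2_dfr(durations, k_long, function(d, k) {
    tibble::tibble(
      participant = participant, context = context, duration_ms = d,
      response = c(rep("long", k), rep("short", n_per - k))
    )
  })
}

# build a psychometric_fit object directly from known parameters
fit_from_params <- function(alpha, beta, lapse = 0) {
  structure(
    list(alpha_ms = alpha, beta_ms = beta, lapse = lapse, lapse_free = FALSE,
         nll = 0, converged = TRUE, n_trials = 0,
         proportions = tibble::tibble(duration_ms = numeric(),
                                      n = integer(), k = integer(),
                                      p_long = numeric())),
    class = "psychometric_fit"
  )
}
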
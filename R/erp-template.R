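#' Noiseless single-trial ERP template
#'
#' Evaluates the generator's deterministic frontocentral waveform for one
#' probe duration in one context, on the standard epoch grid (time relative
#' to stimulus onset). See [erp_params()] for the pieces: onset N1/P2
#' complex, climbing CNV with plateau clipping and post-plateau relaxation
#' (held through the response gap and resolving linearly once the cue
#' arrives), duration-dependent offset P2, and a cue-locked LPCt with a
#' hinge (leveling) in its duration dependence. The template is identically
#' zero at `t <= 0`.
#'
#' @param duration_ms Probe duration, ms (within the 400-1600 anchor range).
#' @param context Context label used to resolve context-dependent
#'   parameters (`"PS"`, `"NS"`, `"DF"`, `"AF"`, or any label present in the
#'   parameter vectors).
#' @param params An [erp_params()] object.
#' @param response_gap_ms Blank between stimulus offset and response cue
#'   (0 for Experiment 1, 300 for Experiment 2).
#' @param slope_uv_s,plateau_uv Optional per-participant overrides of the
#'   context's CNV slope (uV/s) and plateau (uV).
#' @return A tibble with columns `time_ms` and `amplitude_uv`.
#' @examples
#' tpl <- erp_template(800, "PS", erp_params(), response_gap_ms = 0)
#' range(tpl$time_ms)
#' @export
erp_template <- function(duration_ms, context, params, response_gap_ms = 0,
                         slope_uv_s = NULL, plateau_uv = NULL) {
  times <- epoch_times(params)
  tibble::tibble(
    time_ms = times,
    amplitude_uv = erp_template_vec(times, duration_ms, context, params,
                                    response_gap_ms, slope_uv_s, plateau_uv)
  )
}

# time grid implied by erp_params
epoch_times <- function(params) {
  step <- 1000 / params$sampling_rate_hz
  seq(params$epoch_start_ms, params$epoch_end_ms, by = step)
}

# fast vector version used by the simulator; returns amplitudes (uV)
erp_template_vec <- function(times, duration_ms, context, params,
                             response_gap_ms = 0,
                             slope_uv_s = NULL, plateau_uv = NULL) {
  if (duration_ms < 400 || duration_ms > 1600) {
    abort("duration_ms must lie within the 400-1600 ms anchor range.")
  }
  slope <- slope_uv_s %||% ctx_param(params$cnv_slope, context)
  plateau <- plateau_uv %||% ctx_param(params$plateau_uv, context)
  if (slope >= 0) abort("CNV slope must be negative.")
  if (plateau >= 0) abort("CNV plateau must be negative.")

  gauss <- function(amp, mu, sdv) amp * exp(-((times - mu)^2) / (2 * sdv^2))

  onset <- params$cnv_onset_ms
  offset <- duration_ms
  cue <- offset + response_gap_ms
  m <- slope / 1000      # uV per ms
  r <- params$cnv_rebound / 1000
  t_plateau <- onset + plateau / m   # plateau/m > 0

  # CNV: ramp, (optional) plateau + relaxation, resolution ramp to zero
  cnv <- numeric(length(times))
  ramp_idx <- times >= onset & times <= pmin(t_plateau, offset)
  cnv[ramp_idx] <- m * (times[ramp_idx] - onset)
  if (t_plateau < offset) {
    rel_idx <- times > t_plateau & times <= offset
    cnv[rel_idx] <- pmin(0, plateau + r * (times[rel_idx] - t_plateau))
  }
  v_off <- if (offset <= onset) 0
           else if (offset <= t_plateau) m * (offset - onset)
           else pmin(0, plateau + r * (offset - t_plateau))
  # the negativity holds through the response gap and dissipates only once
  # the cue arrives (in the no-gap design the cue IS the offset)
  hold_idx <- times > offset & times <= cue
  cnv[hold_idx] <- v_off
  res_idx <- times > cue & times <= cue + params$resolution_ms
  cnv[res_idx] <- v_off * (1 - (times[res_idx] - cue) / params$resolution_ms)

  dur_s <- (duration_ms - 400) / 1000
  offp2_amp <- params$offp2_amp0_uv + params$offp2_amp_gain * dur_s
  offp2_lat <- params$offp2_lat0_ms + params$offp2_lat_gain * dur_s
  level <- ctx_param(params$lpct_level_ms, context)
  lpct_amp <- params$lpct_amp0_uv +
    params$lpct_amp_gain * max(0, level - duration_ms) / 1000
  lpct_lat <- max(80, params$lpct_lat0_ms + params$lpct_lat_gain * dur_s)

  wave <- gauss(params$n1_amp_uv, params$n1_lat_ms, params$n1_sd_ms) +
    gauss(params$p2_amp_uv, params$p2_lat_ms, params$p2_sd_ms) +
    cnv +
    gauss(offp2_amp, offset + offp2_lat, params$offp2_sd_ms) +
    gauss(lpct_amp, cue + lpct_lat, params$lpct_sd_ms)

  wave * (times > 0)
}
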
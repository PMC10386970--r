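#' Ground-truth parameters of the behavioral generator
#'
#' Parameterizes the synthetic observer. Each participant `p` judging in
#' context `c` uses a logistic psychometric function whose threshold is
#' pulled toward the context's ensemble mean:
#'
#'   alpha\[p, c\] = (1 - w) * base_threshold + w * ensemble_mean(c) + offset\[p\]
#'
#'   P(long | D) = lapse / 2 + (1 - lapse) * plogis((D - alpha) / slope)
#'
#' with `offset[p] ~ N(0, threshold_sd)` shared across the participant's
#' contexts, and a per-participant slope `~ N(slope, slope_sd)` truncated
#' below at 20 ms. `w = 0` ignores the context entirely; `w = 1` puts the
#' threshold at the ensemble mean. The default `base_threshold` is the
#' geometric mean of the 400/1600 ms anchors (800 ms), the classical
#' bisection point.
#'
#' @param context_weight Pull of the threshold toward the ensemble mean,
#'   in `[0, 1]`.
#' @param base_threshold_ms Context-free threshold (ms).
#' @param slope_ms Logistic scale parameter beta (ms); larger = shallower.
#' @param lapse Lapse rate lambda in `[0, 0.1]`, split evenly between the
#'   two asymptotes.
#' @param threshold_sd_ms Between-participant SD of the threshold offset (ms).
#' @param slope_sd_ms Between-participant SD of the slope (ms).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(context_weight = 0.5,
                            base_threshold_ms = sqrt(400 * 1600),
                            slope_ms = 100,
                            lapse = 0,
                            threshold_sd_ms = 60,
                            slope_sd_ms = 15) {
  if (slope_ms <= 0) abort("slope_ms (logistic scale) must be positive.")
  if (lapse < 0 || lapse > 0.1) abort("lapse must lie in [0, 0.1].")
  if (context_weight < 0 || context_weight > 1) {
    abort("context_weight must lie in [0, 1].")
  }
  structure(
    list(
      context_weight = context_weight,
      base_threshold_ms = base_threshold_ms,
      slope_ms = slope_ms,
      lapse = lapse,
      threshold_sd_ms = threshold_sd_ms,
      slope_sd_ms = slope_sd_ms
    ),
    class = "behavior_params"
  )
}

#' Ground-truth parameters of the EEG epoch generator
#'
#' Describes the noiseless per-trial waveform of a single frontocentral
#' virtual channel (standing for the mean of FCz, FC1, FC2, C1, C2, Cz) and
#' the noise added to it. The template is a sum of:
#'
#' * an onset complex: a negative N1 Gaussian and a positive P2 Gaussian;
#' * the CNV: zero until `cnv_onset_ms`, then a linear ramp at
#'   `cnv_slope` (uV/s, negative, per context) clipped at `plateau_uv`
#'   (per context); after the plateau is reached the negativity relaxes
#'   back at `cnv_rebound` (uV/s, small positive drift) until stimulus
#'   offset, holds through the response gap, and returns linearly to zero
#'   over `resolution_ms` once the cue appears (so the negativity persists
#'   ~300 ms longer when a gap separates offset and cue);
#' * an offset P2 Gaussian ~200 ms after offset whose amplitude grows and
#'   latency shrinks with duration;
#' * a cue-locked LPCt Gaussian whose amplitude and latency fall with
#'   duration until a leveling point (per context; by default near the
#'   context's programmed bisection threshold), after which they plateau.
#'
#' Noise is band-limited white Gaussian noise (brick-wall low-pass at
#' `noise_lowpass_hz`, emulating the 0.1-30 Hz analysis bandwidth applied
#' to real recordings) plus optional 1/f^chi "pink" noise, both seeded.
#'
#' Context-dependent fields (`cnv_slope`, `plateau_uv`, `lpct_level_ms`)
#' are named vectors over context labels; scalar values recycle to all
#' contexts.
#'
#' @param cnv_slope CNV climbing rate(s), uV/s, negative. Defaults follow
#'   the short-context-steeper ordering (PS -23, NS -20, DF -19, AF -17).
#' @param cnv_onset_ms Ramp onset, ms after stimulus onset.
#' @param plateau_uv CNV plateau level(s), uV, negative. Defaults keep the
#'   early ramp unclipped through the 250-650 ms regression window.
#' @param cnv_rebound Post-plateau relaxation rate, uV/s (>= 0).
#' @param resolution_ms Post-cue linear return-to-baseline time, ms.
#' @param n1_amp_uv,n1_lat_ms,n1_sd_ms Onset N1 Gaussian (amplitude negative).
#' @param p2_amp_uv,p2_lat_ms,p2_sd_ms Onset P2 Gaussian (amplitude positive).
#' @param offp2_amp0_uv Offset-P2 amplitude at the 400-ms duration, uV.
#' @param offp2_amp_gain Offset-P2 amplitude gain, uV per second of duration.
#' @param offp2_lat0_ms Offset-P2 latency (post-offset) at 400 ms duration.
#' @param offp2_lat_gain Offset-P2 latency gain, ms per second of duration
#'   (negative: later offsets peak earlier).
#' @param offp2_sd_ms Offset-P2 Gaussian width, ms.
#' @param lpct_amp0_uv LPCt amplitude floor (long durations), uV.
#' @param lpct_amp_gain LPCt amplitude gain below the leveling point, uV per
#'   second of (leveling point - duration); positive: shorter = larger.
#' @param lpct_level_ms Leveling (hinge) point(s), ms; default near the
#'   programmed behavioral threshold of each context.
#' @param lpct_lat0_ms LPCt latency (post-cue) at the 400-ms duration, ms.
#' @param lpct_lat_gain LPCt latency gain, ms per second of duration
#'   (negative).
#' @param lpct_sd_ms LPCt Gaussian width, ms.
#' @param noise_sd_uv Per-sample SD of the band-limited white noise, uV.
#' @param pink_sd_uv Per-sample SD of the 1/f^chi noise component, uV.
#' @param pink_exponent Spectral exponent chi >= 0 of the pink component.
#' @param noise_lowpass_hz Brick-wall low-pass cutoff for the white
#'   component, Hz.
#' @param slope_sd Between-participant SD of the CNV slope, uV/s.
#' @param plateau_sd Between-participant SD of the plateau level, uV.
#' @param sampling_rate_hz Sampling rate of the epoch grid, Hz.
#' @param epoch_start_ms,epoch_end_ms Epoch grid limits relative to
#'   stimulus onset, ms.
#' @return A list of class `erp_params`.
#' @export
erp_params <- function(cnv_slope = c(PS = -23, NS = -20, DF = -19, AF = -17),
                       cnv_onset_ms = 250,
                       plateau_uv = c(PS = -10.5, NS = -9.5, DF = -9, AF = -8.5),
                       cnv_rebound = 3,
                       resolution_ms = 250,
                       n1_amp_uv = -3, n1_lat_ms = 100, n1_sd_ms = 20,
                       p2_amp_uv = 4, p2_lat_ms = 180, p2_sd_ms = 25,
                       offp2_amp0_uv = 5.5, offp2_amp_gain = 2.9,
                       offp2_lat0_ms = 260, offp2_lat_gain = -78,
                       offp2_sd_ms = 45,
                       lpct_amp0_uv = 2.5, lpct_amp_gain = 8,
                       lpct_level_ms = c(PS = 844, NS = 956, DF = 800, AF = 1000),
                       lpct_lat0_ms = 330, lpct_lat_gain = -77,
                       lpct_sd_ms = 55,
                       noise_sd_uv = 5, pink_sd_uv = 2, pink_exponent = 1,
                       noise_lowpass_hz = 30,
                       slope_sd = 2.5, plateau_sd = 1,
                       sampling_rate_hz = 1000,
                       epoch_start_ms = -300, epoch_end_ms = 2800) {
  if (any(cnv_slope >= 0)) abort("cnv_slope must be negative (uV/s).")
  if (any(plateau_uv >= 0)) abort("plateau_uv must be negative (uV).")
  if (noise_sd_uv < 0 || pink_sd_uv < 0) abort("noise SDs must be >= 0.")
  if (pink_exponent < 0) abort("pink_exponent must be >= 0.")
  if (sampling_rate_hz <= 0) abort("sampling_rate_hz must be positive.")
  if (cnv_rebound < 0) abort("cnv_rebound must be >= 0.")
  structure(
    list(
      cnv_slope = cnv_slope, cnv_onset_ms = cnv_onset_ms,
      plateau_uv = plateau_uv, cnv_rebound = cnv_rebound,
      resolution_ms = resolution_ms,
      n1_amp_uv = n1_amp_uv, n1_lat_ms = n1_lat_ms, n1_sd_ms = n1_sd_ms,
      p2_amp_uv = p2_amp_uv, p2_lat_ms = p2_lat_ms, p2_sd_ms = p2_sd_ms,
      offp2_amp0_uv = offp2_amp0_uv, offp2_amp_gain = offp2_amp_gain,
      offp2_lat0_ms = offp2_lat0_ms, offp2_lat_gain = offp2_lat_gain,
      offp2_sd_ms = offp2_sd_ms,
      lpct_amp0_uv = lpct_amp0_uv, lpct_amp_gain = lpct_amp_gain,
      lpct_level_ms = lpct_level_ms,
      lpct_lat0_ms = lpct_lat0_ms, lpct_lat_gain = lpct_lat_gain,
      lpct_sd_ms = lpct_sd_ms,
      noise_sd_uv = noise_sd_uv, pink_sd_uv = pink_sd_uv,
      pink_exponent = pink_exponent, noise_lowpass_hz = noise_lowpass_hz,
      slope_sd = slope_sd, plateau_sd = plateau_sd,
      sampling_rate_hz = sampling_rate_hz,
      epoch_start_ms = epoch_start_ms, epoch_end_ms = epoch_end_ms
    ),
    class = "erp_params"
  )
}

# resolve a possibly context-named parameter for one context label
ctx_param <- function(value, context) {
  if (is.null(names(value))) return(unname(value[1]))
  if (context %in% names(value)) return(unname(value[[context]]))
  unname(value[1])
}
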
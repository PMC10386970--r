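make_epochs <- function(data, durations, context = "PS", gap = 0,
                        times = seq(-300, 2800)) {
  info <- tibble::tibble(
    participant = 1, context = context, duration_ms = durations,
    response_gap_ms = gap, cue_latency_ms = durations + gap,
    trial_id = seq_along(durations)
  )
  epoch_set(data, times, info)
}

test_that("baseline correction removes the per-trial window mean", {
  times <- seq(-300, 2800)
  # constant trials become all-zero
  ep <- make_epochs(matrix(5, 3, length(times)), rep(800, 3))
  bl <- baseline_correct(ep, "onset", c(-200, 0))
  expect_equal(bl$data, matrix(0, 3, length(times)))
  expect_equal(bl$baseline, list(lock = "onset", window = c(-200, 0)))

  # linear trial: offset-locked baseline of a 400-ms trial uses [350, 450]
  # ms after onset, whose mean is the value at 400 ms
  ramp <- matrix(times, 1, length(times), byrow = TRUE)
  ep2 <- make_epochs(ramp, 400)
  bl2 <- baseline_correct(ep2, "offset", c(-50, 50))
  expect_equal(bl2$data[1, times == 400], 0)
  expect_equal(bl2$data[1, times == 500], 100)

  # cue lock honors the response gap
  ep3 <- make_epochs(ramp, 400, gap = 300)
  bl3 <- baseline_correct(ep3, "cue", c(-50, 50))
  expect_equal(bl3$data[1, times == 700], 0)

  # mean over the baseline window is zero afterwards
  noisy <- make_epochs(matrix(rnorm(2 * length(times)), 2), c(800, 1008))
  bln <- baseline_correct(noisy, "onset", c(-200, 0))
  expect_equal(rowMeans(bln$data[, times >= -200 & times <= 0]), c(0, 0),
               tolerance = 1e-12)

  # windows that leave the grid name the offending trial
  short <- make_epochs(matrix(0, 1, 100), 800, times = seq(0, 99))
  expect_error(baseline_correct(short, "onset", c(-200, 0)), "trial 1")
})

test_that("condition averages are pointwise means with cell bookkeeping", {
  times <- seq(-300, 2800)
  v <- sin(times / 200)
  ep <- make_epochs(rbind(v, v, -v, -v + 2), c(800, 800, 800, 1008))
  avg <- condition_average(ep)
  expect_equal(nrow(avg$data), 2)
  cell800 <- avg$data[avg$info$duration_ms == 800, ]
  expect_equal(cell800, (v + v - v) / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(avg$info$n_trials[avg$info$duration_ms == 800], 3L)
  # identical trials average to themselves; +v/-v averages to 0
  ep2 <- make_epochs(rbind(v, v), c(800, 800))
  expect_equal(condition_average(ep2)$data[1, ], v, ignore_attr = TRUE)
  ep3 <- make_epochs(rbind(v, -v), c(800, 800))
  expect_equal(max(abs(condition_average(ep3)$data)), 0)
})

test_that("climbing rate is the OLS slope in uV/s over [250, 650]", {
  times <- seq(-300, 2800)
  # exact ramp: -20 uV/s
  ramp <- -20 * pmax(0, times) / 1000
  expect_equal(cnv_climbing_rate(ramp, times), -20, tolerance = 1e-12)
  expect_equal(cnv_climbing_rate(rep(0, length(times)), times), 0)

  # normal-equations oracle on a seeded irregular waveform
  ols_oracle <- function(v, t, w) {
    idx <- t >= w[1] & t <= w[2]
    X <- cbind(1, t[idx] / 1000)
    solve(t(X) %*% X, t(X) %*% v[idx])[2]
  }
  for (seed in 1:5) {
    v <- withr::with_seed(seed, cumsum(rnorm(length(times), 0, 0.2)))
    expect_equal(cnv_climbing_rate(v, times), ols_oracle(v, times, c(250, 650)),
                 tolerance = 1e-9)
  }
  expect_error(cnv_climbing_rate(ramp, times, window = c(250, 5000)),
               "not covered")
})

test_that("peak measures find the stated extremum with 10-ms averaging", {
  times <- seq(-300, 2800)
  g <- -6 * exp(-((times - 800)^2) / (2 * 50^2))
  pk <- peak_measure(g, times, "negative", c(0, 1600))
  expect_equal(pk$peak_latency_ms, 800)
  # 10-ms window mean is strictly smaller in magnitude than the raw extremum
  expect_lt(abs(pk$peak_amplitude_uv), 6)
  expect_gt(abs(pk$peak_amplitude_uv), 5.9)
  expect_false(pk$at_edge)

  # plateau ties resolve to the earliest sample
  flat <- ifelse(times >= 600 & times <= 900, -4, 0)
  expect_equal(peak_measure(flat, times, "negative", c(0, 1600))$peak_latency_ms,
               600)

  # an extremum on the window edge is flagged
  rampdown <- -pmax(0, times) / 1000
  expect_true(peak_measure(rampdown, times, "negative", c(0, 1600))$at_edge)

  # brute-force scan oracle on 100 seeded waveforms: exact agreement
  scan_peak <- function(v, t, w, negative) {
    idx <- which(t >= w[1] & t <= w[2])
    vv <- if (negative) v[idx] else -v[idx]
    i <- idx[which(vv == min(vv))[1]]
    aidx <- which(t >= t[i] - 5 & t <= t[i] + 5)
    c(t[i], mean(v[aidx]))
  }
  for (seed in 1:100) {
    v <- withr::with_seed(seed, as.vector(
      timebisect:::noise_matrix(1, length(times), 1000, 3, 1, 30)))
    neg <- seed %% 2 == 0
    pk <- peak_measure(v, times, if (neg) "negative" else "positive",
                       c(0, 1600))
    oracle <- scan_peak(v, times, c(0, 1600), neg)
    expect_identical(pk$peak_latency_ms, oracle[1])
    expect_identical(pk$peak_amplitude_uv, oracle[2])
  }
})

test_that("windowed means follow the closed-interval rule", {
  times <- seq(-300, 2800)
  expect_equal(windowed_mean_amplitude(rep(-2, length(times)), times,
                                       c(140, 300)), -2)
  # linear ramp a*t averages to a*(w0+w1)/2 on a symmetric grid
  a <- 0.004
  expect_equal(windowed_mean_amplitude(a * times, times, c(250, 650)),
               a * (250 + 650) / 2, tolerance = 1e-12)
  expect_error(windowed_mean_amplitude(a * times, times, c(2500, 3000)),
               "not covered")
})

test_that("crossing latency interpolates the first post-650 sign change", {
  times <- seq(-300, 2800)
  line <- (times - 1210) / 1000
  expect_equal(crossing_latency(line, times), 1210, tolerance = 1)
  expect_true(is.na(crossing_latency(rep(-1, length(times)), times)))
  # a waveform already positive by 650 ms has no countable crossing
  early <- (times - 300) / 1000
  expect_true(is.na(crossing_latency(early, times)))
  # but one crossing just after the cutoff is caught
  late <- (times - 651) / 1000
  expect_equal(crossing_latency(late, times), 651, tolerance = 1e-9)

  # oversampled brute-force oracle within 1 ms on seeded smooth waveforms
  scan_crossing <- function(v, t) {
    tt <- seq(650, max(t), by = 0.1)
    vv <- stats::approx(t, v, tt)$y
    i <- which(vv[-length(vv)] < 0 & vv[-1] >= 0)[1]
    if (is.na(i)) NA_real_ else tt[i]
  }
  hits <- 0
  for (seed in 1:100) {
    v <- withr::with_seed(seed, as.vector(
      timebisect:::noise_matrix(1, length(times), 1000, 2, 1, 20))) -
      pmax(0, 1 - times / 1500)
    got <- crossing_latency(v, times)
    oracle <- scan_crossing(v, times)
    if (is.na(oracle)) {
      expect_true(is.na(got))
    } else {
      hits <- hits + 1
      expect_equal(got, oracle, tolerance = 1)
    }
  }
  expect_gt(hits, 50)  # the construction produces real crossings
})

test_that("the feature table has one row per cell with programmed values", {
  sched <- dplyr::bind_rows(unit_schedule("exp1", "PS"),
                            unit_schedule("exp1", "NS"))
  p <- quiet_params()
  ep <- simulate_epochs(sched, p, n_participants = 19, seed = 2)
  ft <- extract_erp_features(ep)
  expect_equal(nrow(ft), 19 * 2 * 7)
  expect_equal(nrow(dplyr::distinct(ft, participant, context, duration_ms)),
               nrow(ft))

  # noiseless templates: climbing rate equals the programmed slope wherever
  # the regression window precedes the offset and the plateau
  clean <- dplyr::filter(ft, duration_ms >= 700)
  expect_equal(clean$cnv_rate_uv_s, clean$true_slope_uv_s, tolerance = 0.05)
  with_zeroed <- extract_erp_features(
    simulate_epochs(unit_schedule("exp1", "PS"), cnv_only_params(),
                    n_participants = 1, seed = 3))
  clean0 <- dplyr::filter(with_zeroed, duration_ms >= 800)
  expect_equal(clean0$cnv_rate_uv_s, clean0$true_slope_uv_s, tolerance = 1e-9)

  # CNV mean window of a 400-ms trial is [250, 650]
  tpl400 <- simulate_epochs(unit_schedule("exp1", "PS")[1, ], p, 1, seed = 4)
  bl <- baseline_correct(tpl400, "onset", c(-200, 0))
  manual <- windowed_mean_amplitude(bl$data[1, ], bl$times, c(250, 650))
  ft400 <- dplyr::filter(extract_erp_features(tpl400),
                         context == "PS", duration_ms == 400)
  expect_equal(ft400$cnv_mean_amplitude_uv, manual, tolerance = 1e-12)
})

test_that("feature extraction is invariant to trial order and DC offsets", {
  sched <- dplyr::bind_rows(unit_schedule("exp1", "PS")[rep(1:7, 3), ]) |>
    dplyr::mutate(trial = dplyr::row_number())
  ep <- simulate_epochs(sched, erp_params(noise_sd_uv = 2, pink_sd_uv = 0,
                                          slope_sd = 0, plateau_sd = 0),
                        n_participants = 1, seed = 6)
  ft <- extract_erp_features(ep)

  perm <- withr::with_seed(1, sample(nrow(ep$data)))
  ep_shuffled <- epoch_set(ep$data[perm, ], ep$times, ep$info[perm, ])
  ft_shuffled <- extract_erp_features(ep_shuffled)
  expect_equal(as.data.frame(ft), as.data.frame(ft_shuffled), tolerance = 1e-12)

  ep_dc <- epoch_set(ep$data + 7.5, ep$times, ep$info)
  ft_dc <- extract_erp_features(ep_dc)
  expect_equal(as.data.frame(ft), as.data.frame(ft_dc), tolerance = 1e-9)
})

test_that("single-trial extraction keeps one row per trial", {
  sched <- unit_schedule("exp2", "DF")[1:4, ]
  ep <- simulate_epochs(sched, quiet_params(), 1, seed = 7)
  ft <- extract_erp_features(ep, single_trial = TRUE)
  expect_equal(nrow(ft), 4)
  expect_true("trial_id" %in% names(ft))
})

test_that("feature tables round-trip through columnar text", {
  sched <- unit_schedule("exp1", "PS")[1:3, ]
  ft <- extract_erp_features(simulate_epochs(sched, quiet_params(), 1, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_erp_features(ft, path)
  back <- read_erp_features(path)
  expect_equal(back$cnv_rate_uv_s, ft$cnv_rate_uv_s, tolerance = 1e-9)
  expect_s3_class(back, "erp_features")
})
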
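test_that("paired t matches hand computation and the textbook formula", {
  # differences [1, 2, 3]: mean 2, sd 1, t = 2 * sqrt(3), df = 2
  y <- c(10, 20, 30)
  res <- paired_t(y + c(1, 2, 3), y)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 2)
  expect_true(res$ci_low < 2 && 2 < res$ci_high)

  # textbook-formula oracle on 50 seeded datasets, agreement to 1e-10
  for (seed in 1:50) {
    xy <- withr::with_seed(seed, list(x = rnorm(12, 1), y = rnorm(12)))
    res <- paired_t(xy$x, xy$y)
    d <- xy$x - xy$y
    t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
    p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
    ci_oracle <- mean(d) + c(-1, 1) * qt(0.975, length(d) - 1) *
      sd(d) / sqrt(length(d))
    expect_equal(res$t, t_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_equal(c(res$ci_low, res$ci_high), ci_oracle, tolerance = 1e-10)
  }
})

test_that("paired t is antisymmetric and rejects degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.8, 3.9, 1.7, 4.0)
  expect_identical(paired_t(x, y)$t, -paired_t(y, x)$t)
  # zero-mean differences with positive variance: t = 0, p = 1
  res0 <- paired_t(c(1, 2, 3), c(2, 1, 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x[1:2], y[1:2]), "at least 3")
  expect_error(paired_t(x, y[1:3]), "equal length")
})

test_that("JZS Bayes factor favors the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bayes_factor(0, 20), 1)
  bfs <- vapply(c(0, 1, 2, 3, 4, 6), function(t) jzs_bayes_factor(t, 19),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  # scale sensitivity: wider prior penalizes small effects more
  expect_gt(jzs_bayes_factor(1, 20, scale = sqrt(2) / 2),
            jzs_bayes_factor(1, 20, scale = 1.4))
})

test_that("JZS quadrature agrees with an independent dense-grid oracle", {
  # trapezoid integration on a log-spaced g grid, separate code path
  jzs_oracle <- function(t, n, r) {
    nu <- n - 1
    g <- exp(seq(log(1e-8), log(1e8), length.out = 40000))
    s <- 1 + n * g * r^2
    num <- s^(-0.5) * (1 + t^2 / (s * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
    den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    sum(diff(g) * (num[-1] + num[-length(num)]) / 2) / den
  }
  for (case in list(c(2.63, 19), c(0.5, 10), c(4.2, 17), c(-2.97, 17))) {
    expect_equal(jzs_bayes_factor(case[1], case[2]),
                 jzs_oracle(case[1], case[2], sqrt(2) / 2),
                 tolerance = 0.01)
  }
})

test_that("Pearson correlation matches closed forms and handles edge cases", {
  x <- c(1, 2, 4, 7, 9)
  res <- pearson_corr(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_equal(res$bf10, Inf)

  # orthogonal contrast: exactly zero correlation
  res0 <- pearson_corr(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(res0$r, 0)
  expect_equal(res0$p, 1)
  expect_lt(res0$bf10, 1)

  # textbook formulas on a seeded bivariate sample
  xy <- withr::with_seed(42, {
    xs <- rnorm(17); list(x = xs, y = 0.5 * xs + rnorm(17, 0, sqrt(0.75)))
  })
  res <- pearson_corr(xy$x, xy$y)
  r_oracle <- sum((xy$x - mean(xy$x)) * (xy$y - mean(xy$y))) /
    sqrt(sum((xy$x - mean(xy$x))^2) * sum((xy$y - mean(xy$y))^2))
  t_oracle <- r_oracle * sqrt(15 / (1 - r_oracle^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, 15)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 15), tolerance = 1e-12)

  expect_error(pearson_corr(x, rep(1, 5)), "Zero variance")
  expect_error(pearson_corr(x[1:2], x[1:2]), "at least 3")
})

test_that("correlation Bayes factor integrates the exact r density", {
  # midpoint-rule oracle with its own 2F1 evaluation
  bf_oracle <- function(r, n) {
    rho <- seq(-0.9999, 0.9999, length.out = 20001)
    f21 <- function(z) {
      total <- term <- 1
      for (k in 0:500) {
        term <- term * (0.5 + k)^2 / ((n - 0.5 + k) * (k + 1)) * z
        total <- total + term
        if (abs(term) < 1e-15 * abs(total)) break
      }
      total
    }
    lik <- vapply(rho, function(p) {
      exp((n - 1) / 2 * log(1 - p^2) - (n - 1.5) * log(1 - p * r)) *
        f21((1 + p * r) / 2)
    }, numeric(1))
    mean(lik) / f21(0.5)
  }
  for (case in list(c(0.32, 17), c(-0.5, 12), c(0.05, 30))) {
    expect_equal(timebisect:::correlation_bf(case[1], case[2]),
                 bf_oracle(case[1], case[2]), tolerance = 0.01)
  }
})

# synthetic feature-like table with programmed fixed effects
lmm_data <- function(n_sub, b_context = 0, b_dur = 0, sd_int = 1,
                     sd_res = 1.5, seed = 1) {
  durations <- bisection_design("exp1", "PS")$durations_ms
  withr::with_seed(seed, {
    tidyr::crossing(participant = 1:n_sub, context = c("PS", "NS"),
                    duration_ms = durations) |>
      dplyr::mutate(
        intercept = rnorm(n_sub)[participant] * sd_int,
        y = intercept + b_context * (context == "NS") +
          b_dur * duration_ms / 1000 + rnorm(dplyr::n(), 0, sd_res)
      )
  })
}

test_that("the mixed model recovers programmed fixed effects", {
  # 20 seeded datasets with a -1.5 uV/s duration slope and no context effect
  est <- p_ctx <- numeric(20)
  for (s in 1:20) {
    d <- lmm_data(19, b_dur = -1.5, seed = s)
    m <- fit_lmm(d, "y")
    est[s] <- m$coefficients$estimate[m$coefficients$term == "duration_s"]
    p_ctx[s] <- timebisect:::context_p_value(m)
  }
  expect_lt(abs(mean(est) + 1.5), 0.3)
  expect_true(all(abs(est + 1.5) < 1))
  expect_gte(mean(p_ctx > 0.05), 0.9)
})

test_that("mixed-model estimates scale linearly and degrade gracefully", {
  d <- lmm_data(8, b_context = 1, b_dur = -2, seed = 3)
  m1 <- fit_lmm(d, "y")
  d2 <- dplyr::mutate(d, y = 2 * y)
  m2 <- fit_lmm(d2, "y")
  expect_equal(m2$coefficients$estimate, 2 * m1$coefficients$estimate,
               tolerance = 1e-6)

  # constant response: all slopes zero, singular random intercept flagged
  d0 <- dplyr::mutate(d, y = 3)
  m0 <- suppressMessages(suppressWarnings(fit_lmm(d0, "y")))
  expect_true(m0$singular)
  expect_equal(max(abs(m0$coefficients$estimate[-1])), 0, tolerance = 1e-8)

  expect_error(fit_lmm(dplyr::filter(d, context == "PS"), "y"), "2 contexts")
  expect_error(fit_lmm(dplyr::filter(d, participant <= 3), "y"),
               "5 participants")
})

test_that("Kenward-Roger and Satterthwaite dfs are both available and close", {
  d <- lmm_data(10, b_dur = -1, seed = 9)
  kr <- fit_lmm(d, "y", df_method = "kenward-roger")
  sat <- fit_lmm(d, "y", df_method = "satterthwaite")
  expect_equal(kr$df_method, "kenward-roger")
  expect_equal(sat$df_method, "satterthwaite")
  expect_equal(kr$coefficients$estimate, sat$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(kr$coefficients$p_value, sat$coefficients$p_value,
               tolerance = 0.05)
  gl <- glance(kr)
  expect_equal(gl$n_participants, 10)
  expect_false(gl$singular)
})
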
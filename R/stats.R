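#' Paired t-test with JZS Bayes factor
#'
#' Classical two-sided paired t-test on `x - y` (via [stats::t.test()]),
#' augmented with the default Jeffreys-Zellner-Siow Bayes factor
#' ([jzs_bayes_factor()]) for the same contrast.
#'
#' @param x,y Paired numeric vectors of equal length, n >= 3.
#' @param bf_scale Cauchy prior scale for the Bayes factor.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `ci_low`,
#'   `ci_high`, `bf10`, `n`.
#' @examples
#' paired_t(c(1, 2, 3, 5), c(0, 1, 1, 2))
#' @export
paired_t <- function(x, y, bf_scale = sqrt(2) / 2) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x - y) == 0) {
    abort("Differences have zero variance; the paired t statistic is undefined.")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    mean_diff = unname(tt$estimate),
    ci_low = tt$conf.int[1],
    ci_high = tt$conf.int[2],
    bf10 = jzs_bayes_factor(unname(tt$statistic), n, scale = bf_scale),
    n = n
  )
}

#' One-sample JZS Bayes factor from a t statistic
#'
#' Default-prior Bayes factor BF10 for a one-sample (or paired) design:
#' Cauchy prior with scale `r` on the standardized effect, equivalently a
#' normal effect prior with an inverse-gamma(1/2, 1/2) mixing variance.
#' Computed by adaptive quadrature of the Zellner-Siow mixture integral
#'
#'   BF10 = Integral_0^Inf (1 + N g r^2)^(-1/2)
#'          (1 + t^2 / ((1 + N g r^2) nu))^(-(nu+1)/2) pi(g) dg
#'          / (1 + t^2/nu)^(-(nu+1)/2),
#'
#' with `nu = n - 1` and `pi(g)` the inverse-gamma(1/2, 1/2) density. The
#' prior scale is a modeling choice (default `sqrt(2)/2`); published BF
#' values depend on the scale used.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of pairs), n >= 2.
#' @param scale Cauchy prior scale r > 0.
#' @param rel_tol Quadrature relative tolerance.
#' @return BF10 (evidence for a nonzero effect over the point null).
#' @export
jzs_bayes_factor <- function(t, n, scale = sqrt(2) / 2, rel_tol = 1e-8) {
  if (n < 2) abort("n must be at least 2.")
  if (scale <= 0) abort("Prior scale must be positive.")
  nu <- n - 1
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    s <- 1 + n * g * scale^2
    log_num <- -0.5 * log(s) - (nu + 1) / 2 * log1p(t^2 / (s * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
    exp(log_num - log_den)
  }
  q <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = rel_tol, abs.tol = 0,
              subdivisions = 500L),
    error = function(e) e
  )
  if (inherits(q, "error")) {
    abort(paste("JZS quadrature failed to converge:", conditionMessage(q)))
  }
  if (q$value <= 0 || q$abs.error > 100 * rel_tol * q$value) {
    abort(paste0("JZS quadrature did not reach the requested tolerance ",
                 "(estimate ", signif(q$value, 6), ", abs.error ",
                 signif(q$abs.error, 3), ")."))
  }
  q$value
}

# Gaussian hypergeometric 2F1(a, b; c; z) by series, |z| < 1
hyp2f1 <- function(a, b, c, z, tol = 1e-13, max_iter = 100000L) {
  term <- 1
  total <- 1
  for (k in 0:(max_iter - 1)) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  abort("2F1 series did not converge.")
}

#' Pearson correlation with exact-density Bayes factor
#'
#' Sample Pearson correlation with the classical t-based two-sided test
#' (`df = n - 2`, via [stats::cor.test()]) and a Bayes factor computed by
#' integrating the exact sampling density of r over a uniform prior on the
#' population correlation (stretched beta with kappa = 1), using a series
#' evaluation of the Gaussian hypergeometric function.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 (complete pairs used).
#' @return One-row tibble: `r`, `df`, `t`, `p`, `bf10`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in x or y; correlation undefined.")
  }
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  tibble::tibble(
    r = r,
    df = unname(ct$parameter),
    t = unname(ct$statistic),
    p = ct$p.value,
    bf10 = if (abs(r) > 1 - 1e-12) Inf else correlation_bf(r, n),
    n = n
  )
}

# BF10 for a correlation: uniform prior on rho, exact r density
# (rho-free factors cancel in the likelihood ratio)
correlation_bf <- function(r, n) {
  loglik <- function(rho) {
    (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
      log(hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2))
  }
  log_l0 <- loglik(0)
  f <- function(rho) {
    vapply(rho, function(p) exp(loglik(p) - log_l0), numeric(1)) * 0.5
  }
  integrate(f, -1, 1, rel.tol = 1e-8)$value
}

#' Random-intercept linear mixed model for ERP features
#'
#' Fits `response ~ context * duration_s + (1 | participant)` by REML,
#' with the duration predictor rescaled to seconds so slope estimates read
#' in uV (or ms) per second of duration. p-values use small-sample
#' denominator degrees of freedom: Kenward-Roger by default, or
#' Satterthwaite. Confidence intervals are Wald intervals on the
#' approximated df.
#'
#' @param data Feature table with columns `participant`, `context`,
#'   `duration_ms`, and the response.
#' @param response Response column, as a string (e.g.
#'   `"cnv_mean_amplitude_uv"`).
#' @param df_method `"kenward-roger"` or `"satterthwaite"`.
#' @return An object of class `lmm_result`; see [tidy.lmm_result()].
#' @export
fit_lmm <- function(data, response,
                    df_method = c("kenward-roger", "satterthwaite")) {
  df_method <- match.arg(df_method)
  need <- c("participant", "context", "duration_ms", response)
  if (!all(need %in% names(data))) {
    abort(paste("data must contain columns:", paste(need, collapse = ", ")))
  }
  if (dplyr::n_distinct(data$context) < 2) abort("Need at least 2 contexts.")
  if (dplyr::n_distinct(data$duration_ms) < 3) abort("Need at least 3 durations.")
  if (dplyr::n_distinct(data$participant) < 5) abort("Need at least 5 participants.")

  d <- data |>
    dplyr::mutate(
      .response = .data[[response]],
      duration_s = .data$duration_ms / 1000,
      context = factor(.data$context),
      participant = factor(.data$participant)
    ) |>
    dplyr::filter(is.finite(.data$.response))

  model <- lmerTest::lmer(.response ~ context * duration_s + (1 | participant),
                          data = d, REML = TRUE)
  ddf <- if (df_method == "kenward-roger") "Kenward-Roger" else "Satterthwaite"
  coefs <- summary(model, ddf = ddf)$coefficients
  tidy_coefs <- tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    std_error = coefs[, "Std. Error"],
    df = coefs[, "df"],
    statistic = coefs[, "t value"],
    p_value = coefs[, "Pr(>|t|)"]
  ) |>
    dplyr::mutate(
      ci_low = .data$estimate - qt(0.975, .data$df) * .data$std_error,
      ci_high = .data$estimate + qt(0.975, .data$df) * .data$std_error
    )
  vc <- as.data.frame(lme4::VarCorr(model))
  singular <- lme4::isSingular(model)
  if (singular) {
    warn("Random-intercept fit is singular (participant variance ~ 0).")
  }
  structure(
    list(
      model = model,
      coefficients = tidy_coefs,
      response = response,
      df_method = df_method,
      singular = singular,
      random_intercept_var = vc$vcov[vc$grp == "participant"],
      residual_var = vc$vcov[vc$grp == "Residual"],
      n_obs = nrow(d),
      n_participants = dplyr::n_distinct(d$participant)
    ),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> ", x$response, " ~ context * duration_s + (1 | participant)\n",
      "  df method: ", x$df_method,
      if (x$singular) "   [singular fit]", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a fitted mixed model
#'
#' @param x An [fit_lmm()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per fixed effect with estimate, SE,
#'   approximated df, t, p and Wald CI. `glance()`: one-row fit summary
#'   with variance components and diagnostics.
#' @exportS3Method generics::tidy
tidy.lmm_result <- function(x, ...) x$coefficients

#' @rdname tidy.lmm_result
#' @exportS3Method generics::glance
glance.lmm_result <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_participants = x$n_participants,
    random_intercept_var = x$random_intercept_var,
    residual_var = x$residual_var,
    df_method = x$df_method, singular = x$singular,
    reml_criterion = lme4::REMLcrit(x$model)
  )
}

# p-value of the context main effect (used by calibration checks)
context_p_value <- function(lmm) {
  stopifnot(inherits(lmm, "lmm_result"))
  tc <- lmm$coefficients
  row <- grepl("^context", tc$term) & !grepl(":", tc$term)
  tc$p_value[row][1]
}
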
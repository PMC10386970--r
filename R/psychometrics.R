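#' Fit a logistic psychometric function by maximum likelihood
#'
#' Fits `P(long | D) = lambda/2 + (1 - lambda) * plogis((D - alpha) / beta)`
#' to the trials of one participant in one context, maximizing the
#' Bernoulli likelihood over threshold `alpha` and scale `beta` (and,
#' optionally, the lapse rate `lambda`). By default `lambda` is fixed at 0,
#' the conventional two-parameter bisection fit; `lapse = "free"` estimates
#' it under the bound `lambda <= 0.06`.
#'
#' Optimization is derivative-free Nelder-Mead from four deterministic
#' starting points spanning the duration range; ties are broken by lowest
#' negative log-likelihood, then smallest `beta`, so fits are reproducible.
#'
#' @param trials Tibble with columns `duration_ms` and `response`
#'   (`"short"`/`"long"`, or 0/1, or logical), for a single
#'   participant-context cell. At least two distinct durations and both
#'   response categories are required.
#' @param lapse `0` (fixed, default), a fixed numeric value in `[0, 0.1]`,
#'   or `"free"`.
#' @return An object of class `psychometric_fit` with elements `alpha_ms`,
#'   `beta_ms`, `lapse`, `lapse_free`, `nll`, `converged`, `n_trials` and
#'   `proportions` (observed per-duration proportions of "long").
#' @examples
#' sched <- enumerate_trials(bisection_design("exp1", "PS"), seed = 1)
#' trials <- simulate_responses(sched, behavior_params(), 1, seed = 3)
#' fit <- fit_psychometric(trials)
#' pse_jnd(fit)
#' @export
fit_psychometric <- function(trials, lapse = 0) {
  if (!all(c("duration_ms", "response") %in% names(trials))) {
    abort("trials must contain columns duration_ms and response.")
  }
  long <- response_as_long(trials$response)
  agg <- tibble::tibble(duration_ms = trials$duration_ms, long = long) |>
    dplyr::group_by(.data$duration_ms) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$long), .groups = "drop") |>
    dplyr::arrange(.data$duration_ms)
  if (nrow(agg) < 2) {
    abort("Need at least two distinct durations to fit a psychometric function.")
  }
  if (sum(agg$k) == 0 || sum(agg$k) == sum(agg$n)) {
    abort(paste0(
      "Non-identifiable psychometric data: all responses are '",
      if (sum(agg$k) == 0) "short" else "long",
      "'. Threshold and slope cannot be estimated."
    ))
  }

  lapse_free <- identical(lapse, "free")
  lapse_fixed <- if (lapse_free) 0 else as.numeric(lapse)
  if (!lapse_free && (lapse_fixed < 0 || lapse_fixed > 0.1)) {
    abort("Fixed lapse must lie in [0, 0.1].")
  }
  lapse_max <- 0.06

  d <- agg$duration_ms
  rng <- range(d)
  span <- max(diff(rng), 1)

  nll_fun <- function(par) {
    alpha <- par[1]
    beta <- exp(par[2])
    lam <- if (lapse_free) lapse_max * stats::plogis(par[3]) else lapse_fixed
    p <- lam / 2 + (1 - lam) * stats::plogis((d - alpha) / beta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }

  starts <- lapply(c(0.2, 0.4, 0.6, 0.8), function(q) {
    st <- c(rng[1] + q * span, log(span / 6))
    if (lapse_free) st <- c(st, stats::qlogis(0.02 / lapse_max))
    st
  })
  fits <- lapply(starts, function(st) {
    stats::optim(st, nll_fun, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  })
  nlls <- vapply(fits, function(f) f$value, numeric(1))
  betas <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- order(round(nlls, 9), betas)[1]
  fit <- fits[[best]]

  structure(
    list(
      alpha_ms = fit$par[1],
      beta_ms = max(exp(fit$par[2]), 1e-6),  # guard against step-limit fits
      lapse = if (lapse_free) lapse_max * stats::plogis(fit$par[3]) else lapse_fixed,
      lapse_free = lapse_free,
      nll = fit$value,
      converged = fit$convergence == 0 && is.finite(fit$value),
      n_trials = sum(agg$n),
      proportions = dplyr::mutate(agg, p_long = .data$k / .data$n)
    ),
    class = "psychometric_fit"
  )
}

response_as_long <- function(response) {
  if (is.character(response) || is.factor(response)) {
    response <- as.character(response)
    bad <- !response %in% c("short", "long")
    if (any(bad)) abort("response must be 'short' or 'long'.")
    response == "long"
  } else {
    as.logical(response)
  }
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> alpha = ", round(x$alpha_ms, 1), " ms, beta = ",
      round(x$beta_ms, 1), " ms, lapse = ", signif(x$lapse, 3),
      if (x$lapse_free) " (free)" else " (fixed)",
      ", NLL = ", round(x$nll, 2),
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_psychometric one-row tibble of fitted parameters.
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.psychometric_fit <- function(x, ...) {
  pj <- pse_jnd(x)
  tibble::tibble(
    alpha_ms = x$alpha_ms, beta_ms = x$beta_ms, lapse = x$lapse,
    pse_ms = pj[["pse_ms"]], jnd_ms = pj[["jnd_ms"]]
  )
}

#' @describeIn fit_psychometric one-row fit summary (NLL, n, convergence).
#' @exportS3Method generics::glance
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, n_trials = x$n_trials, converged = x$converged,
                 lapse_free = x$lapse_free)
}

#' Duration at which the fitted curve reaches a response probability
#'
#' Solves `P(long | D) = p` on the fitted psychometric curve by
#' root-finding (bisection via [stats::uniroot()] to 1e-6 ms), so lapse-rate
#' fits need no special casing. For the lapse-free logistic the closed
#' forms are `alpha` at `p = 0.5` and `alpha + beta * log(3)` at `p = 0.75`.
#'
#' @param fit A [fit_psychometric()] result.
#' @param p Target probability (strictly between the fitted asymptotes).
#' @return Duration in ms.
#' @export
psy_threshold <- function(fit, p) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) abort("Cannot evaluate thresholds of a non-converged fit.")
  lo_asym <- fit$lapse / 2
  hi_asym <- 1 - fit$lapse / 2
  if (p <= lo_asym || p >= hi_asym) {
    abort(paste0("Probability ", p, " is not attainable: the fitted curve is ",
                 "bounded to (", lo_asym, ", ", hi_asym, ") by the lapse rate."))
  }
  f <- function(dur) {
    fit$lapse / 2 + (1 - fit$lapse) *
      stats::plogis((dur - fit$alpha_ms) / fit$beta_ms) - p
  }
  half_width <- max(
    fit$beta_ms * (abs(stats::qlogis((p - lo_asym) / (1 - fit$lapse))) + 40),
    1e-3
  )
  uniroot(f, lower = fit$alpha_ms - half_width,
          upper = fit$alpha_ms + half_width, tol = 1e-6)$root
}

#' PSE and JND of a fitted psychometric function
#'
#' The point of subjective equality (PSE) is the duration at which the
#' fitted curve reaches 50% "long" responses; the just noticeable
#' difference (JND) is the difference between the 75% and 50% thresholds.
#' Both are computed on the fitted curve by root-finding
#' ([psy_threshold()]).
#'
#' @param fit A converged [fit_psychometric()] result.
#' @return Named numeric vector `c(pse_ms = , jnd_ms = )`.
#' @export
pse_jnd <- function(fit) {
  pse <- psy_threshold(fit, 0.5)
  jnd <- psy_threshold(fit, 0.75) - pse
  c(pse_ms = pse, jnd_ms = jnd)
}

#' Fit psychometric functions per participant and context
#'
#' Maps [fit_psychometric()] over every participant-context cell of a
#' long-format trial table, returning one tidy row per cell. Cells whose
#' fit fails (e.g. all responses in one category) are flagged rather than
#' dropped.
#'
#' @param trials Trial tibble with `participant`, `context`,
#'   `duration_ms`, `response`.
#' @param lapse Passed to [fit_psychometric()].
#' @return Tibble with columns `participant`, `context`, `alpha_ms`,
#'   `beta_ms`, `lapse`, `pse_ms`, `jnd_ms`, `nll`, `converged`, `note`.
#' @export
fit_bisection <- function(trials, lapse = 0) {
  trials |>
    dplyr::group_by(.data$participant, .data$context) |>
    dplyr::group_modify(function(cell, key) {
      res <- tryCatch(fit_psychometric(cell, lapse = lapse),
                      error = function(e) e)
      if (inherits(res, "error")) {
        tibble::tibble(alpha_ms = NA_real_, beta_ms = NA_real_,
                       lapse = NA_real_, pse_ms = NA_real_, jnd_ms = NA_real_,
                       nll = NA_real_, converged = FALSE,
                       note = conditionMessage(res))
      } else {
        dplyr::bind_cols(tidy(res),
                         tibble::tibble(nll = res$nll,
                                        converged = res$converged,
                                        note = NA_character_))
      }
    }) |>
    dplyr::ungroup()
}

#' Plot a fitted psychometric function
#'
#' Observed per-duration proportions of "long" responses with the fitted
#' logistic curve.
#'
#' @param object A [fit_psychometric()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psychometric_fit <- function(object, ...) {
  rng <- range(object$proportions$duration_ms)
  grid <- tibble::tibble(duration_ms = seq(rng[1], rng[2], length.out = 200))
  grid$p_long <- p_long(grid$duration_ms, object$alpha_ms, object$beta_ms,
                        object$lapse)
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$duration_ms, y = .data$p_long)) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$alpha_ms, linetype = "dashed",
                        alpha = 0.4) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "Probe duration (ms)", y = "P('long')",
                  title = sprintf("PSE %.0f ms, JND %.0f ms",
                                  pse_jnd(object)[["pse_ms"]],
                                  pse_jnd(object)[["jnd_ms"]])) +
    ggplot2::theme_minimal()
}
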
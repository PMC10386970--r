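#' Configuration of a full synthetic experiment run
#'
#' Bundles everything that determines a pipeline run; a run is a pure
#' function of its config (including the seed). The config round-trips
#' losslessly through a flat, commented key/value text file
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param experiment `"exp1"` (spacing contexts PS/NS) or `"exp2"`
#'   (frequency contexts DF/AF).
#' @param n_participants Simulated sample size (19 and 17 were the
#'   analyzed samples of the two experiments).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param behavior A [behavior_params()] object (or overrides list).
#' @param erp An [erp_params()] object (or overrides list).
#' @param lapse Lapse handling for psychometric fits (see
#'   [fit_psychometric()]).
#' @param single_trial Extract ERP features per trial instead of per
#'   condition average.
#' @param bf_scale JZS prior scale for Bayes factors.
#' @param df_method Mixed-model denominator-df method (see [fit_lmm()]).
#' @param rep_scale Multiplier on the design's repetition counts, for
#'   desk-scale runs (1 = the printed counts; 0.25 quarters every count,
#'   minimum one presentation per duration).
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = "exp1", n_participants = 19, seed = 1,
                       out_dir = NULL,
                       behavior = behavior_params(), erp = erp_params(),
                       lapse = 0, single_trial = FALSE,
                       bf_scale = sqrt(2) / 2,
                       df_method = "kenward-roger", rep_scale = 1) {
  if (is.list(behavior) && !inherits(behavior, "behavior_params")) {
    behavior <- do.call(behavior_params, behavior)
  }
  if (is.list(erp) && !inherits(erp, "erp_params")) {
    erp <- do.call(erp_params, erp)
  }
  if (!experiment %in% c("exp1", "exp2")) {
    abort("experiment must be 'exp1' or 'exp2'.")
  }
  structure(
    list(experiment = experiment, n_participants = n_participants,
         seed = as.integer(seed), out_dir = out_dir,
         behavior = behavior, erp = erp, lapse = lapse,
         single_trial = single_trial, bf_scale = bf_scale,
         df_method = df_method, rep_scale = rep_scale),
    class = "run_config"
  )
}

# contexts of each experiment, short context first
experiment_contexts <- function(experiment) {
  switch(experiment, exp1 = c("PS", "NS"), exp2 = c("DF", "AF"))
}

#' Write / read a run config as flat key/value text
#'
#' Scalars are written as `key: value`; named parameter vectors as
#' comma-separated `name=value` pairs; nested parameter blocks are
#' flattened with a `behavior.` / `erp.` prefix.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.null(v)) return("NULL")
    if (!is.null(names(v))) {
      return(paste(names(v), format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = "=", collapse = ","))
    }
    if (is.numeric(v)) return(paste(format(v, digits = 17, trim = TRUE,
                                           scientific = FALSE), collapse = ","))
    paste(as.character(v), collapse = ",")
  }
  lines <- c("# timebisect run configuration")
  for (nm in names(config)) {
    v <- config[[nm]]
    if (inherits(v, c("behavior_params", "erp_params"))) {
      for (sub in names(v)) {
        lines <- c(lines, paste0(nm, ".", sub, ": ", fmt(v[[sub]])))
      }
    } else {
      lines <- c(lines, paste0(nm, ": ", fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parse_val <- function(s) {
    s <- trimws(s)
    if (identical(s, "NULL")) return(NULL)
    if (grepl("=", s, fixed = TRUE)) {
      parts <- strsplit(strsplit(s, ",")[[1]], "=", fixed = TRUE)
      return(setNames(as.numeric(vapply(parts, `[`, "", 2)),
                      vapply(parts, `[`, "", 1)))
    }
    items <- trimws(strsplit(s, ",")[[1]])
    if (all(items %in% c("TRUE", "FALSE"))) return(as.logical(items))
    num <- suppressWarnings(as.numeric(items))
    if (!anyNA(num)) return(num)
    items
  }
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- lapply(kv, function(x) parse_val(x[2]))
  names(vals) <- keys

  top <- vals[!grepl(".", keys, fixed = TRUE)]
  beh <- vals[grepl("^behavior\\.", keys)]
  names(beh) <- sub("^behavior\\.", "", names(beh))
  erp <- vals[grepl("^erp\\.", keys)]
  names(erp) <- sub("^erp\\.", "", names(erp))
  args <- top
  args$behavior <- do.call(behavior_params, beh)
  args$erp <- do.call(erp_params, erp)
  do.call(run_config, args)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes design expansion, behavioral and EEG simulation, psychometric
#' fitting, ERP feature extraction and group statistics for one
#' experiment, end to end. With an output directory set, writes the trial
#' table, psychometric fit table, ERP feature table, the
#' condition-averaged epoch container (onset-baselined), the statistics
#' table, a formatted summary table and a run log; re-running the same
#' config reproduces every output bit for bit.
#'
#' With a single participant, group tests are skipped with an explicit
#' notice; all per-participant tables are still produced.
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle` with elements `config`,
#'   `designs`, `schedules`, `trials`, `psychometric_fits`, `features`,
#'   `avg_epochs`, `statistics`, `table1`, `log`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  contexts <- experiment_contexts(config$experiment)
  seed <- config$seed
  log_lines <- c(
    paste0("timebisect ", as.character(utils::packageVersion("timebisect")),
           " | R ", R.version$major, ".", R.version$minor),
    paste0("stage=config experiment=", config$experiment,
           " n_participants=", config$n_participants, " seed=", seed)
  )

  designs <- lapply(contexts, function(ctx) {
    d <- bisection_design(config$experiment, ctx)
    if (config$rep_scale != 1) {
      d$repetitions <- pmax(1L, as.integer(round(d$repetitions * config$rep_scale)))
    }
    d
  })
  names(designs) <- contexts

  schedules <- purrr::imap(designs, function(d, ctx) {
    enumerate_trials(d, seed = seed + match(ctx, contexts))
  })
  schedule_all <- dplyr::bind_rows(schedules)
  log_lines <- c(log_lines, paste0("stage=designs trials_per_context=",
                                   paste(vapply(schedules, nrow, 1L),
                                         collapse = "/")))

  trials <- simulate_responses(schedule_all, config$behavior,
                               config$n_participants, seed = seed + 11)
  fits <- fit_bisection(trials, lapse = config$lapse)
  log_lines <- c(log_lines,
                 paste0("stage=behavior trials=", nrow(trials),
                        " fits=", nrow(fits),
                        " converged=", sum(fits$converged)))

  features <- NULL
  avg_sets <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    ep <- simulate_epochs(schedule_all, config$erp, n_participants = 1,
                          seed = seed + 100 + p)
    ep$info$participant <- p
    feats_p <- extract_erp_features(ep, single_trial = config$single_trial)
    features <- dplyr::bind_rows(features, feats_p)
    bl <- baseline_correct(ep, "onset", c(-200, 0))
    avg_sets[[p]] <- condition_average(bl)
  }
  avg_epochs <- epoch_set(
    do.call(rbind, lapply(avg_sets, function(a) a$data)),
    avg_sets[[1]]$times,
    dplyr::bind_rows(lapply(avg_sets, function(a) a$info)),
    lock = "onset", baseline = list(lock = "onset", window = c(-200, 0))
  )
  log_lines <- c(log_lines, paste0("stage=erp feature_rows=", nrow(features)))

  stats_out <- group_statistics(config, contexts, fits, features)
  log_lines <- c(log_lines, paste0("stage=stats tests=", nrow(stats_out$tests),
                                   if (!is.null(stats_out$notice))
                                     paste0(" notice='", stats_out$notice, "'")))

  table1 <- make_table1_data(fits, features, contexts)

  report <- structure(
    list(config = config, designs = designs, schedules = schedules,
         trials = trials, psychometric_fits = fits, features = features,
         avg_epochs = avg_epochs, statistics = stats_out$tests,
         lmm_fits = stats_out$lmms, notice = stats_out$notice,
         table1 = table1, log = log_lines),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# paired contrasts, mixed models and correlation for one run;
# short context is always the first element of `contexts`
group_statistics <- function(config, contexts, fits, features) {
  short <- contexts[1]; long <- contexts[2]
  notice <- NULL
  tests <- NULL
  lmms <- list()

  if (config$n_participants < 3) {
    notice <- paste0("Group tests skipped: need >= 3 participants, have ",
                     config$n_participants, ".")
    return(list(tests = tibble::tibble(), lmms = lmms, notice = notice))
  }

  wide <- fits |>
    dplyr::filter(.data$converged) |>
    dplyr::select("participant", "context", "pse_ms", "jnd_ms") |>
    tidyr::pivot_wider(names_from = "context",
                       values_from = c("pse_ms", "jnd_ms"))
  add_t <- function(label, x, y) {
    res <- tryCatch(
      dplyr::mutate(paired_t(x, y, bf_scale = config$bf_scale),
                    note = NA_character_),
      error = function(e) {
        tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                       mean_diff = mean(x - y), ci_low = NA_real_,
                       ci_high = NA_real_, bf10 = NA_real_,
                       n = length(x), note = conditionMessage(e))
      }
    )
    dplyr::bind_cols(tibble::tibble(measure = label,
                                    contrast = paste(short, "-", long)), res)
  }
  tests <- dplyr::bind_rows(
    add_t("pse_ms", wide[[paste0("pse_ms_", short)]],
          wide[[paste0("pse_ms_", long)]]),
    add_t("jnd_ms", wide[[paste0("jnd_ms_", short)]],
          wide[[paste0("jnd_ms_", long)]])
  )

  rate_wide <- features |>
    dplyr::group_by(.data$participant, .data$context) |>
    dplyr::summarise(rate = mean(.data$cnv_rate_uv_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "context", values_from = "rate")
  tests <- dplyr::bind_rows(
    tests,
    add_t("cnv_rate_uv_s", rate_wide[[short]], rate_wide[[long]])
  )

  lmm_responses <- c("cnv_mean_amplitude_uv",
                     if (config$experiment == "exp1") "p2_peak_latency_ms",
                     if (config$experiment == "exp2")
                       c("lpct_peak_latency_ms", "lpct_mean_amplitude_uv"))
  if (config$n_participants >= 5) {
    for (resp in lmm_responses) {
      lmms[[resp]] <- fit_lmm(features, resp, df_method = config$df_method)
    }
  } else {
    notice <- paste0("Mixed models skipped: need >= 5 participants, have ",
                     config$n_participants, ".")
  }

  if (config$experiment == "exp2") {
    cnv_diff <- features |>
      dplyr::group_by(.data$participant, .data$context) |>
      dplyr::summarise(m = mean(.data$cnv_mean_amplitude_uv), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "context", values_from = "m") |>
      dplyr::mutate(diff = .data[[long]] - .data[[short]])
    pse_diff <- wide |>
      dplyr::mutate(diff = .data[[paste0("pse_ms_", long)]] -
                      .data[[paste0("pse_ms_", short)]])
    keep <- complete.cases(cnv_diff$diff, pse_diff$diff)
    if (sum(keep) >= 3) {
      cor_res <- pearson_corr(cnv_diff$diff[keep], pse_diff$diff[keep])
      tests <- dplyr::bind_rows(
        tests,
        dplyr::bind_cols(
          tibble::tibble(measure = "cnv_mean_vs_pse_diff",
                         contrast = paste(long, "-", short)),
          dplyr::rename(cor_res, mean_diff = "r"))
      )
    }
  }
  list(tests = tests, lmms = lmms, notice = notice)
}

# per-context mean +/- SEM summary underlying the formatted table
make_table1_data <- function(fits, features, contexts) {
  sem <- function(x) sd(x) / sqrt(length(x))
  per_participant <- features |>
    dplyr::group_by(.data$participant, .data$context) |>
    dplyr::summarise(
      climbing_rate_uv_s = mean(.data$cnv_rate_uv_s),
      peak_latency_ms = mean(.data$cnv_peak_latency_ms),
      peak_amplitude_uv = mean(.data$cnv_peak_amplitude_uv),
      mean_amplitude_uv = mean(.data$cnv_mean_amplitude_uv),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(fits, "participant", "context", "pse_ms", "jnd_ms"),
      by = c("participant", "context")
    )
  per_participant |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      dplyr::across(
        c("climbing_rate_uv_s", "peak_latency_ms", "peak_amplitude_uv",
          "mean_amplitude_uv", "pse_ms", "jnd_ms"),
        list(mean = ~mean(.x, na.rm = TRUE),
             sem = ~sem(.x[is.finite(.x)]))
      ),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$context, contexts))
}

#' Formatted per-context summary table of a run
#'
#' Lays out, per context, the across-participant mean and standard error
#' of the CNV climbing rate, peak latency, peak amplitude and mean
#' amplitude together with the behavioral PSE and JND — the standard
#' summary layout for this paradigm. Cells that could not be computed are
#' reported as `NA`, never imputed.
#'
#' @param report A [run_experiment()] result (or its `table1` element).
#' @return Character vector of formatted lines (also printed invisibly by
#'   [run_experiment()] into `table1.txt`).
#' @export
make_table1 <- function(report) {
  data <- if (inherits(report, "report_bundle")) report$table1 else report
  cols <- c("climbing_rate_uv_s", "peak_latency_ms", "peak_amplitude_uv",
            "mean_amplitude_uv", "pse_ms", "jnd_ms")
  labels <- c("Climbing rate (uV/s)", "Peak latency (ms)",
              "Peak amplitude (uV)", "Mean amplitude (uV)",
              "PSE (ms)", "JND (ms)")
  header <- sprintf("%-22s %s", "Measure",
                    paste(sprintf("%-20s", data$context), collapse = " "))
  rows <- vapply(seq_along(cols), function(i) {
    vals <- sprintf("%8.2f +/- %-7.2f",
                    data[[paste0(cols[i], "_mean")]],
                    data[[paste0(cols[i], "_sem")]])
    sprintf("%-22s %s", labels[i], paste(sprintf("%-20s", vals), collapse = " "))
  }, character(1))
  c(header, strrep("-", nchar(header)), rows,
    sprintf("%-22s %s", "n participants",
            paste(sprintf("%-20d", data$n), collapse = " ")))
}

# write every artifact of a report bundle to a directory
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(out_dir, ...)
  write_trials(report$trials, f("trials.tsv"))
  for (ctx in names(report$schedules)) {
    write_schedule(report$schedules[[ctx]], f(paste0("schedule_", ctx, ".tsv")))
    write_design(report$designs[[ctx]], f(paste0("design_", ctx, ".txt")))
  }
  readr::write_tsv(report$psychometric_fits, f("psychometric_fits.tsv"))
  write_erp_features(report$features, f("erp_features.tsv"))
  write_epoch_set(report$avg_epochs, f("epochs_avg"))
  if (nrow(report$statistics) > 0) {
    readr::write_tsv(report$statistics, f("statistics.tsv"))
  }
  lmm_rows <- purrr::imap_dfr(report$lmm_fits, function(m, resp) {
    dplyr::bind_cols(tibble::tibble(response = resp), tidy(m))
  })
  if (nrow(lmm_rows) > 0) readr::write_tsv(lmm_rows, f("lmm_coefficients.tsv"))
  writeLines(make_table1(report), f("table1.txt"))
  log <- report$log
  if (!is.null(report$notice)) log <- c(log, paste0("notice=", report$notice))
  writeLines(log, f("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", x$config$experiment, ", ",
      x$config$n_participants, " participants, seed ", x$config$seed, "\n\n",
      sep = "")
  cat(make_table1(x), sep = "\n")
  if (!is.null(x$notice)) cat("\n", x$notice, "\n", sep = "")
  invisible(x)
}
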
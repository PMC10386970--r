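#' Experimental designs of the two bisection experiments
#'
#' `bisection_design()` returns the printed design of one experiment/context
#' arm of the study: the duration set, the per-duration presentation counts,
#' the anchors, and the trial-timing constants. Four arms exist:
#'
#' * `exp1` / `PS`: positively skewed (log-spaced) durations, 48 repetitions
#'   each — the "short" spacing context.
#' * `exp1` / `NS`: negatively skewed (mirrored) durations, 48 repetitions
#'   each — the "long" spacing context.
#' * `exp2` / `AF`: equally spaced durations sampled with ascending
#'   frequency (12 ... 84) — the "long" frequency context.
#' * `exp2` / `DF`: the same durations with descending frequency (84 ... 12)
#'   — the "short" frequency context.
#'
#' Both experiments anchor the task at 400 ms (short) and 1600 ms (long) and
#' run 336 trials per session (six blocks of 56). Experiment 2 inserts a
#' 300-ms blank between stimulus offset and the response cue; in Experiment 1
#' the cue follows the offset immediately.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param context Context label: `"PS"` or `"NS"` for `exp1`; `"AF"` or
#'   `"DF"` for `exp2`.
#' @return An object of class `bisection_design`: a list with elements
#'   `experiment`, `context`, `durations_ms`, `repetitions`,
#'   `short_anchor_ms`, `long_anchor_ms`, `fixation_ms`, `response_gap_ms`,
#'   `iti_ms`, `n_blocks`, `block_size`.
#' @examples
#' d <- bisection_design("exp1", "PS")
#' ensemble_mean(d)
#' @export
bisection_design <- function(experiment, context) {
  experiment <- as.character(experiment)[1]
  context <- as.character(context)[1]
  arms <- list(
    exp1.PS = list(durations = c(400, 504, 636, 800, 1008, 1270, 1600),
                   repetitions = rep(48L, 7), gap = 0),
    exp1.NS = list(durations = c(400, 730, 992, 1200, 1366, 1496, 1600),
                   repetitions = rep(48L, 7), gap = 0),
    exp2.AF = list(durations = seq(400, 1600, by = 200),
                   repetitions = c(12L, 24L, 36L, 48L, 60L, 72L, 84L), gap = 300),
    exp2.DF = list(durations = seq(400, 1600, by = 200),
                   repetitions = rev(c(12L, 24L, 36L, 48L, 60L, 72L, 84L)), gap = 300)
  )
  key <- paste(experiment, context, sep = ".")
  if (!key %in% names(arms)) {
    abort(paste0(
      "Unknown design arm: experiment = '", experiment, "', context = '",
      context, "'. Valid arms: exp1/PS, exp1/NS, exp2/AF, exp2/DF."
    ))
  }
  arm <- arms[[key]]
  new_bisection_design(
    experiment = experiment, context = context,
    durations_ms = arm$durations, repetitions = arm$repetitions,
    response_gap_ms = arm$gap
  )
}

new_bisection_design <- function(experiment, context, durations_ms, repetitions,
                                 short_anchor_ms = 400, long_anchor_ms = 1600,
                                 fixation_ms = 500, response_gap_ms = 0,
                                 iti_ms = 1000, n_blocks = 6L, block_size = 56L) {
  stopifnot(length(durations_ms) == length(repetitions))
  if (is.unsorted(durations_ms, strictly = TRUE)) {
    abort("Durations must be strictly increasing.")
  }
  if (durations_ms[1] != short_anchor_ms ||
      durations_ms[length(durations_ms)] != long_anchor_ms) {
    abort("Duration set must start at the short anchor and end at the long anchor.")
  }
  if (any(repetitions <= 0)) abort("All repetition counts must be positive.")
  if (!response_gap_ms %in% c(0, 300)) {
    abort("response_gap_ms must be 0 (exp1) or 300 (exp2).")
  }
  structure(
    list(
      experiment = experiment, context = context,
      durations_ms = as.numeric(durations_ms),
      repetitions = as.integer(repetitions),
      short_anchor_ms = short_anchor_ms, long_anchor_ms = long_anchor_ms,
      fixation_ms = fixation_ms, response_gap_ms = response_gap_ms,
      iti_ms = iti_ms, n_blocks = as.integer(n_blocks),
      block_size = as.integer(block_size)
    ),
    class = "bisection_design"
  )
}

#' @export
print.bisection_design <- function(x, ...) {
  cat("<bisection_design> ", x$experiment, "/", x$context,
      "  (", sum(x$repetitions), " trials, gap ", x$response_gap_ms, " ms)\n",
      sep = "")
  cat("  durations (ms): ", paste(x$durations_ms, collapse = ", "), "\n", sep = "")
  cat("  repetitions:    ", paste(x$repetitions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn bisection_design one row per duration with its repetition count.
#' @param x A `bisection_design`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bisection_design <- function(x, ...) {
  tibble::tibble(
    experiment = x$experiment, context = x$context,
    duration_ms = x$durations_ms, repetitions = x$repetitions
  )
}

#' Frequency-weighted ensemble mean of a design
#'
#' The mean of the session's duration distribution, weighting each duration
#' by its presentation count: `sum(d * r) / sum(r)`. This is the quantity the
#' bisection threshold is drawn toward under ensemble-context modulation; in
#' Experiment 1 the NS ensemble mean exceeds the PS one by 223.71 ms (223 ms
#' when truncated to whole milliseconds, as conventionally reported).
#'
#' @param design A [bisection_design()].
#' @return Ensemble mean in ms.
#' @export
ensemble_mean <- function(design) {
  stopifnot(inherits(design, "bisection_design"))
  sum(design$durations_ms * design$repetitions) / sum(design$repetitions)
}

#' Expand a design into a randomized trial schedule
#'
#' Randomly permutes the multiset of durations implied by the design's
#' repetition counts and partitions the session into consecutive blocks.
#' Shuffling is an unconstrained random permutation; per-duration tallies
#' always equal the design's repetition counts exactly.
#'
#' @param design A [bisection_design()].
#' @param seed Integer seed; the schedule is a pure function of
#'   `(design, seed)`.
#' @return A tibble with columns `trial`, `block`, `duration_ms`,
#'   `context`, `experiment`, `response_gap_ms`.
#' @examples
#' sched <- enumerate_trials(bisection_design("exp1", "PS"), seed = 1)
#' nrow(sched) # 336
#' @export
enumerate_trials <- function(design, seed) {
  stopifnot(inherits(design, "bisection_design"))
  durations <- rep(design$durations_ms, times = design$repetitions)
  shuffled <- withr::with_seed(as.integer(seed), sample(durations))
  n <- length(shuffled)
  tibble::tibble(
    trial = seq_len(n),
    block = ((seq_len(n) - 1L) %/% design$block_size) + 1L,
    duration_ms = shuffled,
    context = design$context,
    experiment = design$experiment,
    response_gap_ms = design$response_gap_ms
  )
}

#' Read and write designs as flat key/value text
#'
#' A `bisection_design` round-trips through a human-editable `key: value`
#' text file; vectors are comma-separated.
#'
#' @param design A [bisection_design()].
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a `bisection_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bisection_design"))
  fields <- design
  lines <- vapply(names(fields), function(nm) {
    paste0(nm, ": ", paste(fields[[nm]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- lapply(kv, function(x) trimws(paste(x[-1], collapse = ":")))
  names(vals) <- keys
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  new_bisection_design(
    experiment = vals[["experiment"]], context = vals[["context"]],
    durations_ms = num("durations_ms"), repetitions = num("repetitions"),
    short_anchor_ms = num("short_anchor_ms"), long_anchor_ms = num("long_anchor_ms"),
    fixation_ms = num("fixation_ms"), response_gap_ms = num("response_gap_ms"),
    iti_ms = num("iti_ms"), n_blocks = num("n_blocks"), block_size = num("block_size")
  )
}

#' Write a trial schedule as columnar text
#'
#' @param schedule A schedule tibble from [enumerate_trials()].
#' @param path File path (tab-separated text).
#' @export
write_schedule <- function(schedule, path) {
  readr::write_tsv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
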
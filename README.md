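# timebisect

Simulation and analysis tools for **temporal-bisection psychophysics with
concurrent EEG**, built for studying how *ensemble context* — the spacing
and sampling frequency of an interval set — biases perceived duration and
its electrophysiological signatures.

## The problem

In a bisection task, listeners judge whether a probe interval is closer to
a short (400 ms) or long (1600 ms) anchor. The transition point between
"short" and "long" answers — the point of subjective equality (PSE) — is
not fixed by the anchors: it migrates toward the mean of the session's
duration distribution. Two session designs probe this:

* **spacing contexts** — positively skewed (PS) vs negatively skewed (NS)
  duration sets sharing both anchors, ensemble means 223.71 ms apart;
* **frequency contexts** — one equally spaced set sampled with descending
  (DF) vs ascending (AF) frequencies (ensemble means 800 vs 1200 ms), with
  a 300-ms blank before the response cue.

On the EEG side, three frontocentral components track the interval and the
decision: the contingent negative variation (CNV), a slow negativity whose
early build-up rate (the OLS slope over 250–650 ms post-onset, in µV/s) is
context-sensitive; the offset P2; and the late positive component of
timing (LPCt) after the response cue.

The package implements the full chain as tidyverse-style, tibble-first
functions:

| stage | functions |
|---|---|
| designs | `bisection_design()`, `ensemble_mean()`, `enumerate_trials()` |
| synthetic data | `behavior_params()`, `erp_params()`, `simulate_responses()`, `erp_template()`, `simulate_epochs()` |
| psychometrics | `fit_psychometric()`, `fit_bisection()`, `pse_jnd()`, `psy_threshold()` |
| ERP features | `baseline_correct()`, `condition_average()`, `cnv_climbing_rate()`, `peak_measure()`, `windowed_mean_amplitude()`, `crossing_latency()`, `extract_erp_features()` |
| statistics | `paired_t()`, `jzs_bayes_factor()`, `pearson_corr()`, `fit_lmm()` |
| pipeline | `run_config()`, `run_experiment()`, `make_table1()` |

The behavioral model is a lapse-augmented logistic whose threshold is
pulled toward the context's ensemble mean,

    P(long | D) = λ/2 + (1−λ) / (1 + exp(−(D − α)/β)),
    α(p, c) = (1−w)·α₀ + w·Ē(c) + u(p),

fitted by maximum likelihood; PSE and JND (75%−50% thresholds) come from
root-finding on the fitted curve. The EEG generator produces single-trial
epochs (template + seeded band-limited white and 1/f noise) with known
ground truth, so every measurement stage is verified by parameter
recovery. Group inference uses paired t-tests with JZS Bayes factors and
random-intercept linear mixed models with Kenward–Roger p-values.

## Worked example

Simulate the spacing experiment at its printed size (19 participants, 336
trials per context), fit psychometric functions per participant and
context, and test the context effect:

```r
library(timebisect)
library(dplyr)

ps <- bisection_design("exp1", "PS")
ns <- bisection_design("exp1", "NS")
ensemble_mean(ns) - ensemble_mean(ps)
#> [1] 223.7143

sched  <- bind_rows(enumerate_trials(ps, seed = 1),
                    enumerate_trials(ns, seed = 2))
trials <- simulate_responses(sched, behavior_params(),
                             n_participants = 19, seed = 7)
fits <- fit_bisection(trials)

fits |> group_by(context) |> summarise(pse = mean(pse_ms), jnd = mean(jnd_ms))
#> # A tibble: 2 × 3
#>   context   pse   jnd
#>   <chr>   <dbl> <dbl>
#> 1 NS       972.  113.
#> 2 PS       867.  112.

wide <- fits |> select(participant, context, pse_ms) |>
  tidyr::pivot_wider(names_from = context, values_from = pse_ms)
paired_t(wide$PS, wide$NS)
#> # A tibble: 1 × 8
#>       t    df        p mean_diff ci_low ci_high         bf10     n
#>   <dbl> <dbl>    <dbl>     <dbl>  <dbl>   <dbl>        <dbl> <int>
#> 1 -18.9    18 2.50e-13     -104.  -116.   -92.8 24664951573.    19
```

The PSE sits ~105 ms lower in the short (PS) than the long (NS) context —
the generator was programmed with a pull of w = 0.5 toward ensemble means
223.71 ms apart, so the recovered shift is right where it should be, while
the JND is context-invariant by construction. `run_experiment(run_config())`
runs the same chain end to end including EEG simulation, ERP feature
extraction (`extract_erp_features()`) and mixed models, and
`make_table1(report)` prints the per-context mean ± SEM summary table.
`autoplot()` on a psychometric fit and `plot_erp()` on an epoch set give
the standard diagnostic figures. A thin command-line wrapper with verbs
`run-all`, `simulate`, `fit-behavior`, `extract-erp`, `stats` and
`dump-defaults` ships in `inst/scripts/timebisect`.

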
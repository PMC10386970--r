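---
title: "Models and methods behind timebisect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind timebisect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timebisect)
```

## The scientific setting

In an auditory temporal-bisection task an observer hears a probe interval
and judges whether it was closer to a memorized short anchor (400 ms) or
long anchor (1600 ms). Although the anchors never change, the *ensemble
context* of the session — how the probe durations are spaced, or how often
each is presented — biases the judgment: the bisection threshold migrates
toward the mean of the session's duration distribution. timebisect packages
the complete analysis chain for a two-experiment study of this effect with
concurrent EEG:

* **Experiment 1 (spacing).** Two sessions share anchors but differ in
  spacing: a positively skewed set (PS, log-spaced: 400, 504, 636, 800,
  1008, 1270, 1600 ms) and its mirrored, negatively skewed counterpart
  (NS: 400, 730, 992, 1200, 1366, 1496, 1600 ms), every duration presented
  48 times (336 trials, six blocks of 56). The NS ensemble mean exceeds the
  PS mean by 223.71 ms.
* **Experiment 2 (frequency).** One equally spaced set (400–1600 ms in
  200-ms steps) sampled with ascending frequencies (AF: 12, 24, ..., 84)
  or the mirror-descending frequencies (DF), and a 300-ms blank between
  stimulus offset and the response cue. Ensemble means: DF 800 ms, AF
  1200 ms.

On the EEG side the analysis concerns a frontocentral channel (the mean of
FCz, FC1, FC2, C1, C2, Cz) and three components: the contingent negative
variation (CNV) climbing during the probe, the offset P2 shortly after the
probe ends, and the late positive component of timing (LPCt) after the
response cue.

Because the study's group-level numbers come from real recordings, the
package is organized around *parameter recovery on synthetic data*: a
generator with known ground truth emulates the behavioral and
electrophysiological structure, and every measurement stage is validated by
recovering what was programmed.

## Behavioral model

Responses are Bernoulli draws from a lapse-augmented logistic psychometric
function,

$$P(\text{"long"} \mid D) \;=\; \frac{\lambda}{2} + (1-\lambda)\,
  \bigl[1 + e^{-(D - \alpha_{p,c})/\beta_p}\bigr]^{-1},$$

whose threshold is pulled toward the context's ensemble mean
$\bar{E}_c$:

$$\alpha_{p,c} = (1-w)\,\alpha_0 + w\,\bar{E}_c + u_p,
  \qquad u_p \sim N(0, \sigma_\alpha^2).$$

Defaults (chosen once, as plausible values for trained adult observers in
this paradigm): pull $w = 0.5$; context-free threshold $\alpha_0 = 800$ ms
(the geometric mean of the anchors, the classical bisection point); scale
$\beta = 100$ ms with between-participant SD 15 ms (floored at 20 ms);
lapse $\lambda = 0$; between-participant threshold SD 60 ms. The
participant offset $u_p$ is drawn once and shared across that participant's
contexts, so within-participant context effects are produced solely by the
ensemble pull. Thresholds are clamped 50 ms inside the anchors so every
simulated observer is identifiable in principle. With these defaults the
programmed PS−NS threshold difference is $0.5 \times 223.71 \approx 112$
ms, comfortably detectable at 48 trials per duration — which is what makes
the sign-recovery property a meaningful end-to-end check rather than a coin
flip.

**Fitting.** `fit_psychometric()` maximizes the Bernoulli likelihood over
$(\alpha, \log\beta)$ (and optionally a lapse bounded at 0.06) with
Nelder–Mead from four deterministic starts spanning the duration range;
ties are broken by lowest NLL, then smallest $\beta$, so refits are
bit-reproducible. $\lambda$ is fixed at 0 by default — the two-parameter
fit conventional for bisection data — with the free-lapse variant behind a
flag, since published fits of this design do not report a lapse term.
PSE (50% point) and JND (75% − 50% point) are obtained by root-finding on
the fitted curve rather than by the closed forms $\alpha$ and
$\beta\ln 3$, so the lapse variant needs no special casing; the closed
forms survive as test oracles. Cells with all-identical responses are
flagged non-identifiable and never extrapolated.

## EEG generator

Each simulated trial is a deterministic template plus seeded noise on a
fixed grid (−300 to 2800 ms around stimulus onset at 1000 Hz, covering the
longest trial: 1600 ms probe + 300 ms gap + the LPCt window). The template
sums:

1. an onset complex — negative N1 (−3 µV at 100 ms, SD 20 ms) and positive
   P2 (+4 µV at 180 ms, SD 25 ms) Gaussians;
2. the CNV — zero until 250 ms, then a linear ramp at the context's
   climbing rate (defaults −23/−20 µV/s for PS/NS and −19/−17 µV/s for
   DF/AF, mirroring the short-context-steeper ordering), clipped at a
   plateau (−10.5/−9.5/−9/−8.5 µV); after the plateau the negativity
   relaxes at +3 µV/s, giving the template a well-defined peak rather than
   a flat shelf (a flat plateau would make the programmed peak latency
   unrecoverable: the argmin of a flat segment plus noise is uniform over
   the segment, whereas published grand averages peak at 600–900 ms and
   then dissipate);
3. resolution — the negativity holds its offset value through the response
   gap and returns linearly to baseline over 250 ms once the cue arrives.
   In the no-gap design this is exactly a post-offset linear return; with
   the 300-ms gap it reproduces the observation that the same probe
   duration sustains its negativity ~300 ms longer when the cue is
   delayed, which is what shifts crossing latencies between the two
   experiments;
4. an offset P2 Gaussian (SD 45 ms) whose amplitude grows (+2.9 µV/s) and
   latency shrinks (−78 ms/s) with probe duration;
5. a cue-locked LPCt Gaussian (SD 55 ms) whose amplitude follows a hinge:
   $a_0 + a_1 \max(0, L_c - D)/1000$ with $a_0 = 2.5$ µV, $a_1 = 8$ µV/s
   and leveling point $L_c$ defaulting to the context's programmed
   behavioral threshold — shorter probes yield larger, later LPCt, flat
   beyond the hinge; latency falls at −77 ms/s.

The plateau defaults are deliberately deep enough that, for every context,
the ramp is still unclipped at 650 ms — otherwise the climbing-rate window
below would measure a mixture of ramp and plateau and could not return the
programmed slope. This puts the template's peak amplitudes near −10 µV,
somewhat deeper than typical group means from real recordings; ground-truth
recoverability was given priority over cosmetic matching of real-data
means, which synthetic data cannot legitimately reproduce anyway.

Between-participant heterogeneity adds a shared offset to each
participant's CNV slope (SD 2.5 µV/s) and plateau (SD 1 µV), drawn once and
applied in both contexts.

**Noise.** Trials receive band-limited Gaussian noise: a white component
(per-sample SD 5 µV) plus a 1/f pink component (SD 2 µV, exponent 1), both
brick-wall low-passed at 30 Hz. The band limit emulates the 0.1–30 Hz
analysis bandwidth applied to real recordings before ERP measurement — the
generator produces epochs as they would look *after* preprocessing, which
is also why artifact simulation, re-referencing and ICA are out of scope.
Synthesis is spectral: component amplitudes are combined in quadrature on
the frequency grid of a padded window and realized with seeded
random-phase harmonics, so every epoch set is bit-reproducible from
`(params, seed)`. What the generator does **not** emulate: multi-channel
topography and volume conduction, artifacts, non-stationary noise,
trial-order effects, or drift–diffusion dynamics behind the decision.
Passing recovery tests therefore demonstrate that the *measurement chain*
is correct and unbiased under the stated noise model — not that real EEG
satisfies that model.

## ERP measurement rules

All measures operate on participant × context × duration condition
averages (a single-trial mode exists behind a flag for power exploration).
Windows are closed intervals on the 1-ms grid:

| component | lock | baseline | peak search | mean window |
|---|---|---|---|---|
| CNV | onset | [−200, 0] | most negative in [0, 1600] | [250, 250 + D] |
| offset P2 | offset | offset ± 50 | most positive in [0, 500] | [140, 300] |
| LPCt | cue | cue ± 50 | most positive in [0, 500] | [300, 500] *after offset* |

plus the CNV climbing rate — the OLS slope of amplitude on time over
[250, 650] ms in µV/s — and the crossing latency — the first
negative-to-positive zero crossing after 650 ms, refined by linear
interpolation between the bracketing samples (the least surprising choice
at a 1-ms resolution; a 10-kHz resampled scan agrees within 1 ms). Peak
amplitudes are the mean of the 10 ms around the peak; ties resolve to the
earliest sample (deterministic, and conservative for latency effects);
extrema on a window edge and averaging windows clipped by the epoch edge
are flagged, not silently accepted. The CNV mean window [250, 250 + D] is
applied literally even though it extends past the stimulus offset — that is
how the rule is defined — and the LPCt mean window is offset-locked while
its baseline is cue-locked, preserving that mixed convention exactly.

Two deliberate consequences of these printed rules show up in synthetic
data and are worth knowing about. First, for short probes (400–636 ms) the
climbing-rate window [250, 650] overlaps the offset, the resolution ramp
and the offset P2, so the per-cell "slope" there is a mixture — recovery
checks therefore evaluate cells whose offset clears the window
(D ≥ 700 ms). Second, 400-ms templates are already net-positive by 650 ms
(the offset P2 dominates), so their crossing latency is correctly *missing*
— a value, not an error.

## Group statistics

`paired_t()` and `pearson_corr()` are classical two-sided tests (via
`stats::t.test`/`stats::cor.test`) augmented with Bayes factors. The
one-sample JZS Bayes factor integrates the Zellner–Siow mixture by adaptive
quadrature (tolerance 1e−8, non-convergence is an error, never a silent
truncation); the Cauchy prior scale defaults to √2/2 and is a knob, since
published BF values depend on an unstated prior. The correlation BF
integrates the exact sampling density of r under a uniform prior on ρ,
with a series evaluation of the Gaussian hypergeometric function.

`fit_lmm()` fits `response ~ context * duration_s + (1 | participant)` by
REML, duration rescaled to seconds so coefficients read in µV (or ms) per
second. Small-sample p-values use Kenward–Roger denominator degrees of
freedom by default (Satterthwaite available); the method used is recorded
in the result. Calibration is checked by simulation: under a pure
random-intercept null the context test's type-I error at nominal 0.05 stays
below 0.075 over 400 seeded datasets, and a programmed −1.5 µV/s duration
slope is recovered within ±0.3.

## Pipeline and reproducibility

`run_experiment()` chains design expansion → response and epoch simulation
→ psychometric fits → feature extraction → group tests, writing columnar
text tables, a key/value config and a run log (package version, seed,
per-stage row counts — no timestamps, so reruns are bit-identical). Epochs
are simulated and measured one participant at a time; the epoch container
written to disk holds the onset-baselined condition averages, since a full
single-trial container for a printed-size experiment would be hundreds of
megabytes of text with no analytic role — single-trial sets remain
writable via `write_epoch_set()` for small runs. With one participant,
group tests are skipped with an explicit notice; with fewer than five,
mixed models are skipped likewise.

Block boundaries in Experiment 2 are not specified by the design source,
so sessions are partitioned into six blocks of 56 for symmetry with
Experiment 1 — bookkeeping that no statistic consumes. Only global
per-duration counts are enforced within a session (no within-block
balancing is assumed), and shuffling is an unconstrained permutation.
Session order is a participant attribute with no effect on any
computation.

## Problem sizes used by the checks

The verification suite runs at the study's own scale where that is cheap
(19 participants × 336 trials per context for behavioral recovery; 48
trials per cell for ERP recovery) and at desk scale elsewhere: 200
simulated participant pairs for the threshold-ordering property, 40 seeded
runs for climbing-rate recovery, 400 null and 100 effect simulations for
mixed-model calibration (200 and 60 in the acceptance script). These sizes
were fixed when the checks were designed, as sizes at which the programmed
effects are decisively detectable.

## Known limitations

* The CNV peak latency of long-duration cells is intrinsically noisy: the
  template's extremum sits in a shallow valley (ramp in, gentle relaxation
  out), so at realistic noise the extracted latency scatters widely — as it
  does in real data, where group SEs of 30–70 ms are typical. Latency
  recovery is therefore validated on the sharp offset-P2 and LPCt peaks
  and on CNV cells whose offset truncates the ramp.
* The lapse-free default fit slightly underestimates the JND when the true
  observer lapses; the free-lapse flag exists for that case.
* The generator's functional forms (Gaussian components, linear ramps, a
  hinge for the LPCt) are modeling choices for testability, not claims
  about cortical dynamics; in particular the linear resolution ramp is a
  stand-in for an unmodeled return-to-baseline process.
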
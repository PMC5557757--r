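---
title: "Methods: simulating and analysing a four-task tactile sensitivity study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a four-task tactile sensitivity study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactsens)
```

## The problem this package addresses

Tactile atypicality in autism spectrum disorder (ASD) can arise in the
perceptual domain (detection and discrimination thresholds) or in the
autonomic domain (sympathetic responses to stimulation that the person may
not even report as unpleasant). Separating the two requires a protocol that
measures, in the same participants, (i) event-related skin conductance
responses (SCR) and subjective ratings to suprathreshold electrical stimuli,
(ii) two-point discrimination and light-touch detection thresholds by
adaptive staircases at several body sites, and (iii) sensitivity to small
force differences by the method of constant stimuli. `tactsens` implements
that full measurement-and-analysis chain as reusable, tested code, together
with a synthetic-cohort generator so that every stage can be validated
without access to participant data.

## The synthetic cohort

`cohort_spec()` / `generate_cohort()` draw a cohort of ASD and TD
participants (defaults 23 and 19) around one latent standard-normal
*autonomic reactivity* trait per participant. The generator is
linear-Gaussian throughout:

* **Questionnaires.** Each SRS-2 (sub)score and AASP quadrant score is
  `mean + sd * (loading * trait + sqrt(1 - loading^2) * noise)`, truncated at
  instrument floors and ceilings. The loading (default 0.7) is on the
  correlation scale, so the trait-score correlation equals the loading by
  construction; the AASP Sensation Seeking quadrant loads negatively, as
  lower seeking accompanies higher reactivity. No published generative model
  exists for these instruments; the linear-Gaussian form is the simplest one
  that produces the dependence structure the correlation analyses assume.
* **SCR amplitudes.** Participant-level mean amplitudes per intensity are
  calibrated to the published group cell statistics (ASD weak 1.025 uS, SD
  0.559; TD weak 0.489, SD 0.336; ASD strong 2.165, SD 1.040; TD strong
  1.332, SD 0.581). Each cell's variance is split into a trait share (0.2),
  a share common to both intensities (0.3) and an intensity-specific
  remainder, which fixes the within-participant weak-strong correlation at
  0.5. That correlation is not reported anywhere we could calibrate to, so
  it is an exposed parameter rather than an assertion; 0.5 is a typical
  test-retest-like value for electrodermal amplitudes. Because the published
  cell SDs describe observed three-trial means, the participant-level
  variance is reduced by `trial_amp_sd^2 / 3` so the simulated observed
  means reproduce the printed SDs. About 10% of participants are
  electrodermal non-responders (amplitudes scaled to near zero), the
  conventional population rate, which is what makes the inclusion rule
  consequential.
* **Psychophysical observers.** Every participant carries logistic-observer
  parameters per task and site: thresholds drawn from moment-matched
  lognormals around the published site-by-group means (keeping them positive
  and right-skewed), spread set to 30% of the threshold (Weber-like
  scaling), 2IFC guess rate 0.5, and a small lapse rate (0.02) in the
  staircase simulations. The comparison-task observer has a PSE centred on
  the 1.4 g standard and a lognormal scale parameter `b` (mean 2 per gram),
  chosen so that the 0.4-6 g comparison range spans the psychometric
  function the way published example curves do.

All randomness flows from a single integer seed through
`substream_seed()`, a multiplicative integer mix that gives every
participant-by-task stage its own reproducible substream; identical spec and
seed give bit-identical output, and any stage can be regenerated in
isolation.

## Skin conductance traces and the event-related SCR

A trace is tonic level + linear drift + one Bateman (bi-exponential) kernel
per stimulation event + white noise, sampled at 20 Hz (ample for locating a
multi-second SCR peak while keeping files small). The kernel uses rise and
decay constants 0.75 s and 4 s and is normalised to unit peak, so an
injected amplitude A produces a phasic excursion whose maximum is exactly A
— which is what makes the extraction stage exactly checkable. The kernel
onset delay is *computed from the target peak latency*: the analytic peak of
the kernel sits `tau_r tau_d log(tau_d/tau_r)/(tau_d - tau_r)` = 1.545 s
after kernel onset, so the delay is set to place the average peak 4.593 s
after the stimulus offset, the latency the analyses are calibrated against.
(Fixing the delay near 1.5 s, a value sometimes quoted for SCR onset
latency, would put the peak near 2 s post offset; since the binding
constraint here is the peak latency, the delay is derived, not asserted.) A
per-event Gaussian jitter on the delay (SD 1.5 s) spreads latencies across
trials.

The event-related SCR statistic is deliberately literal: the *pre-stimulus
value* is the conductance at the last sample strictly before onset (a point
value, not a pre-window average); the *peak* is the global maximum over the
half-open window (offset, offset + 10 s]; the *delta* is peak minus
pre-stimulus value. Windows overlapping the next event are not truncated.
A trial counts as showing an event-related SCR when its delta reaches
0.05 uS, the conventional electrodermal minimum response; the source
analyses state no criterion, so it is an exposed parameter and results are
reported alongside the value used. Whether the published mean peak latency
was computed per trial or per participant mean is equally unstated, so the
pipeline reports both. Negative deltas are retained in trial records but
can never satisfy the response criterion. A participant enters the SCR
analyses only with at least one responding trial at each intensity.

## The adaptive staircases

Both threshold tasks use the transformed up-down (2-down/1-up) rule: one
level harder after two consecutive correct responses, one level easier
after every error, clamped at the ladder ends. The two-point ladder is
2-20 mm by 1, 20-40 by 2, 40-90 by 5 (the 0-mm single needle exists only as
the catch presentation); the detection ladder is the standard von Frey set
0.008-6.0 g. A reversal is recorded when the direction of an actual level
change flips, and its value is the level at which the change occurred — the
conventional peak/valley reading. Runs end at ten reversals (threshold =
mean of the last five reversal values) or at ten consecutive correct
responses at the minimum level (`passed_minimum`). Start level defaults to
the ladder maximum (clearly suprathreshold, mirroring clinical practice);
the consecutive-correct counter clears on every level change
(`reset_on_change`, exposed because the original bookkeeping is not
verifiable from the text — under the 2-down/1-up rule the two settings
coincide, which is itself asserted by a test).

The rule converges where `P(correct)^2 = 1/2`, i.e. at the 70.7%-correct
level (`level_p707()`). `convergence_study()` shows the estimator recovering
that level to within one ladder step when the observer's spread is
comparable to the local step size — the regime the task designs put their
participants in. When the spread is several times the step, ten reversals
terminate before the descent from the suprathreshold start equilibrates and
estimates stay biased toward the start level; that is a property of short
transformed up-down runs, not of this implementation (running the same
observers to 40 reversals removes it), and the harness makes it visible
rather than hiding it.

Participants who pass the smallest two-point range enter the site ANOVA at
the minimum ladder level (2 mm), with the substitution logged in the
exclusion ledger — how such runs entered the original analysis is unstated,
and recording them at the floor is the least-assumptive choice that keeps
the design complete for the repeated-measures model.

## The constant-stimuli comparison task

The 1.4 g standard is compared against 0.4, 0.6, 1.0, 2.0, 4.0 and 6.0 g,
eight trials per comparison per block over four blocks: 192 trials. The
response tables are fitted with a two-parameter cumulative logistic
`F(x) = 1/(1 + exp(-(a + b x)))` by penalised maximum likelihood — the
published fitting equation carries no free parameters, and location/scale is
the minimal family consistent with fitting it to data. Guess and lapse rates
are optional *fixed* constants defaulting to 0 (the settings used with the
original toolbox are unstated, so ours are declared rather than inferred). A
weak ridge on `b` (weight 0.01) stabilises near-separable tables, which six
forces at 32 trials can produce; tables whose fractions are all 0 or 1 are
flagged `converged = FALSE` and excluded from group inference. Forces enter
in raw grams (the published curves are plotted on raw force). The PSE is
`-a/b`; the sensitivity metric is the slope of the curve at 50% "stronger"
responses, exactly `b/4` for the logistic; group comparison uses the
per-participant slope as the unit of analysis.

## The statistical battery

* `pooled_t_test()` — equal-variance Student t from summary statistics (the
  printed dfs of 37 and 40 match pooled, not Welch, dfs), Cohen's d on the
  pooled SD.
* `mixed_anova()` — 2 x K split-plot decomposition via `aov()` with an
  `Error(participant)` stratum: between effect against subjects-within-
  groups, within and interaction against their own residual; partial eta
  squared uses each effect's own error term; no sphericity correction
  (uncorrected dfs are what the reference statistics report), noted in the
  result metadata.
* `bonferroni_pairwise()` — paired t per level pair, p times the number of
  pairs, capped at 1.
* `mann_whitney()` — midrank U with the normal approximation and explicit
  `z`; the tie correction is on and the continuity correction off by
  default, which best reproduces published z values; both are exposed, and
  the pipeline reports the no-tie-correction variant alongside, since
  whether the published values included it is not stated.
* `pearson_test()` / `pearson_p_from_r()` — product-moment r with the
  t-transform p on n - 2 df.
* `bh_fdr()` — the rank-form Benjamini-Hochberg procedure with critical
  values `q = Q i / m` and the *strict* largest-`p < q` rule, implemented
  verbatim rather than via the common `p <= q` variant (they differ only at
  exact equality); ties share the decision of the highest-ranked tied
  member. The SCR-questionnaire batteries run with m = 14 (seven SRS-2
  scores x two intensities) and m = 8 (four AASP quadrants x two
  intensities).

## The pipeline and its bookkeeping

`run_pipeline()` chains simulate, extract, estimate and test, writes every
intermediate as headered CSV (traces as `time_s, conductance_uS`), the
statistics as nested JSON, an exclusion ledger and a plain-text report, and
is byte-identical under a fixed config and seed. Attrition that is a cohort
fact rather than a rule — scheduling conflicts, refusal of stimulation,
experimental error — enters as config-supplied annotations (the defaults
emulate the reference cohort's counts); the computed exclusions are
`no_scr_peak` from the inclusion rule and the `passed_minimum` notes.

## Validation scales and what they show

The test suite exercises: exact rule-table and by-hand oracles (staircase
trajectories, split-plot sums of squares, slice-and-mean thresholds,
counting and truth-table oracles); closed-form recoveries (unit-kernel
amplitude identity, logistic self-consistency at effectively infinite n,
`b/4` against a finite difference); and Monte-Carlo properties at moderate
sizes chosen to keep the default run near ten seconds — 2,000 staircase
runs for the convergence study, 1,000 traces for the extraction scan, 60
simulated participants per condition for slope recovery, 100 replicates of
400-participant cohorts for the power of the group comparison. The power
harness works at the amplitude level (latent participant means plus
trial-mean noise, non-responders dropped as the inclusion rule would):
statistically equivalent to full trace synthesis followed by extraction,
whose fidelity the scan oracle establishes separately, and an order of
magnitude faster.

What passing these tests shows is that the *procedures* are implemented
faithfully and that the generator has the dependence structure the analyses
assume. It does not show that real electrodermal data meet those
assumptions: the generator has no respiration- or movement-linked
artifacts, no habituation across the six trials, no tonic drift coupling to
arousal, Gaussian questionnaire noise, and logistic observers with
stationary thresholds. Group comparisons on simulated cohorts reproduce the
reference cell means by construction, so they validate the machinery, never
the science of any particular dataset.

## Known limitations

* No tonic/phasic decomposition or deconvolution; overlapping SCR windows
  are used as-is (and logged), matching the literal statistic.
* The exact Mann-Whitney distribution is not computed (normal approximation
  only), so very small groups should not rely on the reported p.
* Psychometric fits have no per-participant uncertainty (no bootstrap CIs);
  inference happens at the group level on the slope.
* The staircase estimator's finite-run bias for wide-spread observers is
  documented and measurable with `convergence_study()` but not corrected.
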
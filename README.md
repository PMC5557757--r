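# tactsens

Simulation and analysis of a four-task tactile sensitivity protocol that
separates *autonomic* from *perceptual* tactile hypersensitivity — the kind
of study design used to ask whether adults with autism spectrum disorder
(ASD) respond differently to touch in their sympathetic nervous system, in
their conscious reports, or in their discrimination thresholds.

The package implements, as tested R code:

* **Event-related skin conductance responses (SCR).** For each 1-s
  electrical stimulus, the statistic is the peak conductance within the 10-s
  window after stimulus offset minus the conductance immediately before
  onset; participants enter the analysis only with at least one responding
  trial (delta >= 0.05 uS) per intensity.
* **Transformed up-down (2-down/1-up) staircases** for two-point
  discrimination (2-90 mm needle separations) and von Frey touch detection
  (0.008-6 g), terminating at ten reversals (threshold = mean of the last
  five reversal levels) or ten consecutive correct responses at the minimum
  level. The rule converges at the 70.7%-correct point,
  `P(correct) = sqrt(1/2)`.
* **A constant-stimuli touch comparison task** (1.4 g standard vs six
  comparison forces, 192 trials) fitted with a two-parameter cumulative
  logistic `F(x) = 1 / (1 + exp(-(a + b x)))`; the sensitivity index is the
  slope at the 50% point, `b/4`, and the PSE is `-a/b`.
* **The statistical battery**: pooled-SD two-sample t with Cohen's *d*,
  2 x K mixed-design ANOVA with partial eta squared, Bonferroni pairwise
  post-hocs, Mann-Whitney U with explicit normal-approximation *z*, Pearson
  correlation with the t-transform p, and the rank-form Benjamini-Hochberg
  procedure (`q = Q i / m`, strict `p < q` step-up rule).
* **A seeded synthetic-cohort generator** that emulates the study
  population: a latent autonomic-reactivity trait links phasic SCR
  amplitudes to questionnaire subscores (SRS-2, AASP), SCR traces are built
  from unit-peak Bateman kernels on realistic tonic levels, and every
  psychophysical task is answered by per-participant logistic observers.

## Worked example

Run the whole pipeline on a synthetic cohort of 23 ASD and 19 TD
participants and look at the headline statistics:

```r
library(tactsens)
cfg <- run_config(cohort_spec(seed = 42), quiet = TRUE)
out <- run_pipeline(cfg)
```

The report for this seed prints:

```
Electrical stimulation task: 20 ASD + 18 TD included
Event-related SCR ANOVA:
  group          F(1, 36) = 49.089, p = 3.22e-08, partial eta^2 = 0.577
  intensity      F(1, 36) = 99.599, p = 6.555e-12, partial eta^2 = 0.735
  interaction    F(1, 36) = 12.055, p = 0.001361, partial eta^2 = 0.251
Mean SCR peak latency: 4.649 s (per trial)
Sensation threshold: t(37) = 0.241, p = 0.811, d = 0.08
Two-point discrimination ANOVA:
  group          F(1, 39) = 1.294, p = 0.2623, partial eta^2 = 0.032
  site           F(2, 78) = 109.162, p = 2.471e-23, partial eta^2 = 0.737
Touch comparison slope: t(40) = -1.477, p = 0.147, d = 0.46
```

Read: the simulated ASD group shows the larger event-related SCR (the
generator builds that effect in), peak latencies average near 4.6 s, and
the perceptual tasks show the expected strong body-site effect with no
group difference. Individual pieces work standalone:

```r
res <- run_staircase(observer_spec(threshold = 10, spread = 1.5),
                     ladder_2pdt(), seed = 1)
res
#> Staircase run: 92 trials, 10 reversals, ten_reversals (threshold 8.8)

pooled_t_test(8.262, 1.563, 20, 8.375, 1.505, 19)
#> Pooled two-sample t: t(37) = 0.230, p = 0.820, Cohen's d = 0.07
```

A command-line wrapper lives at `inst/cli/tactile-pipeline.R`
(`simulate` / `analyze` / `report` / `all`, with `--seed`, `--out`,
`--config`, `--log-level`).

## Package layout

| Area | Functions |
|---|---|
| Synthetic data | `cohort_spec()`, `generate_cohort()`, `simulate_sc_trace()`, `observer_spec()`, `simulate_ratings()` |
| SCR events | `extract_event_scr()`, `participant_inclusion()`, `summarize_scr()` |
| Staircases | `ladder_2pdt()`, `ladder_tdt()`, `run_staircase()`, `convergence_study()` |
| Psychometric | `constant_stimuli_design()`, `tabulate_responses()`, `fit_logistic()`, `slope_at_pse()` |
| Statistics | `pooled_t_test()`, `mixed_anova()`, `mann_whitney()`, `pearson_test()`, `bh_fdr()` |
| Pipeline | `run_config()`, `run_pipeline()`, `apply_exclusions()`, `scr_group_power()` |

The methods vignette
(`vignettes/tactile-sensitivity-pipeline.Rmd`) documents the generative
model, every tunable parameter with units and defaults, the numerical
choices, and what the synthetic validation does and does not establish
about real data.
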
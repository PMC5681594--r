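# wakecue

Simulation and analysis of **awake targeted memory reactivation (TMR)**
experiments with object–location associations.

In this paradigm, participants learn the screen locations of 18 objects to
a criterion, place every object once immediately after learning, then
perform a deliberately monotonous lexical-decision cover task during which
8 of the objects are flashed for 50 ms (cued); 8 matched objects are never
re-exposed (uncued) and 2 poorly learned ones are flagged out of the
comparison. A day later every object is placed twice more, and an explicit
cue-discrimination test asks which objects were flashed. The scientific
questions are whether brief awake re-exposure stabilises spatial memories,
whether the benefit is larger when cues arrive during less vigilant
moments of the cover task, whether it is larger for weaker learners and
weaker associations, and whether it survives when explicitly recognised
cues are excluded.

The raw data for this design are not publicly deposited, so wakecue pairs
every analysis with a generative simulator of the full experiment and
validates the machinery by parameter recovery and brute-force oracles.

## What is inside

* **Spatial memory mixture model** — placements are modelled as
  `p · N₂(anchor, σ²I) + (1 − p) · 1/(1280·1024)`: an isotropic 2D
  Gaussian of precision σ (px) around the studied *or* remembered
  (immediate-test) location, mixed with uniform guessing over the screen.
  `fit_mixture()` maximises the likelihood under box constraints
  (p ∈ [0,1], σ ∈ [1,800] px), `classify_trials()` labels single trials
  as memory success when the Gaussian density beats the guessing density,
  and `compare_anchor_precision()` contrasts studied- vs remembered-anchor
  precision per participant.
* **Balanced cue assignment** — `assign_cues()` flags associations with
  immediate error > mean + 2 SD, then searches all 6,435 unordered 8-vs-8
  splits of the remaining 16 for the one that equates mean immediate error
  between cued and uncued sets.
* **Vigilance and cueing benefits** — `normalize_rts()` turns arrow-task
  RTs in the ITIs before each re-exposure into item-level vigilance
  covariates; `cueing_benefit()` computes each cued association's benefit
  (participant's mean uncued stability error minus its own).
* **Robust statistics** — `irls_regression()` (bisquare IRLS, c = 4.685),
  `ols_with_exclusion()` (z-score outlier removal), and
  `permutation_test_slope()` (response permutation of the IRLS slope with
  a two-sided add-one p-value).
* **Group inference** — `rm_anova()` (fully within-subject designs with
  partial η²), `paired_t()`/`unpaired_t()` with Cohen's d,
  `learning_factor()` (PC1 of immediate error and training rounds),
  `split_half_by_initial_memory()`, and `discrimination_chi2()` (per
  participant 2×2 χ² on high-confident "cued" ratings; discriminators at
  p < 0.1).
* **Generative simulator** — `simulate_experiment()` produces the whole
  dataset (placements, training rounds, the 96-trial LDT with 24 balanced
  cue events and arrow RTs, discrimination ratings) from one seed, with a
  participant-ability latent and an ITI-level vigilance latent coupling
  into the cueing benefit. `run_full_analysis()` chains everything into a
  report; `write_experiment()`/`read_experiment()` use plain CSV schemas.

Everything is data-frame-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` displays.

## Worked example

```r
library(wakecue)

exp <- simulate_experiment(sim_config(n_participants = 100, seed = 11))
exp
#> <wakecue_experiment> 100 participants x 18 objects (seed 11)
#>   tables: trials (1800 rows), ldt (9600 rows), ratings (1800 rows)

rep <- run_full_analysis(exp, n_perm = 2000, seed = 1)
rep
#> <wakecue_report>
#>   100 participants; fraction closer to remembered = 75.1%
#>   cueing main effect: F(1,99) = 41.51, p = 4.27e-09
#>   vigilance-benefit slope: beta = 0.15, p = 0.0178 (perm p = 0.0415)
```

Reading the numbers: 75.1% of delayed placements land closer to where the
participant put the object on day 1 than to where it was studied — the
delayed memory tracks the *remembered* location, which is why stability
(delayed vs immediate distance) is the primary outcome. The cueing main
effect says cued associations moved less from their immediate placements
than uncued ones, and the positive vigilance slope says associations cued
after slower (less vigilant) arrow-task responses benefited more; the
permutation p-value is the seed-reproducible nonparametric check of that
slope. Drilling in:

```r
s <- rep$summary
s$anchoring$precision[c("sigma_studied_cm", "sigma_remembered_cm")]
#> $sigma_studied_cm    [1] 1.93
#> $sigma_remembered_cm [1] 1.21
s$stability$cued_vs_uncued[c("t", "df", "p", "cohens_d")]
#> t = 6.44, df = 99, p = 4.6e-09, d = 0.64
c(s$stability$success_rate_cued_pct, s$stability$success_rate_uncued_pct)
#> [1] 96.1 92.0
```

Mixture precision is markedly better for remembered than studied anchors
(1.21 vs 1.93 cm), and the group-level mixture classification gives cued
associations a higher memory-success rate — the two signatures the
simulator is calibrated to produce and the analysis stack must recover.

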
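---
title: "Models and methods behind wakecue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wakecue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wakecue)
```

wakecue simulates and analyses awake targeted-memory-reactivation (TMR)
experiments with object–location associations: participants learn 18
object locations on a 1280 × 1024 px grid to a criterion, place each
object once immediately after learning, are briefly re-exposed to 8 of the
objects during a lexical-decision cover task, and place all objects again
twice a day later. This vignette explains the generative model, the
statistical machinery, and the numerical and design choices, in that
order.

## The spatial memory mixture model

A placement is modelled as a two-component mixture. With probability $p$
(memory success) the placement is an isotropic bivariate Gaussian around
its *anchor* with standard deviation $\sigma$ px (memory precision); with
probability $1-p$ it is uniform over the screen, with density
$g = 1/(1280 \times 1024) \approx 7.63\times10^{-7}$ per px² (the
guessing rate). The per-trial likelihood is

$$L_t = p\,\phi_2(\mathbf{x}_t;\,\mathbf{a}_t,\,\sigma^2 I) + (1-p)\,g ,$$

and `fit_mixture()` minimises $-\sum_t \log L_t$ with `L-BFGS-B` under the
box constraints $p \in [0,1]$, $\sigma \in [1, 800]$ px. Two anchors are
of interest for delayed placements: the *studied* location from training
and the *remembered* location (the immediate-test placement). Fitting
both and comparing the two $\sigma$s per participant asks which reference
the delayed memory actually tracks.

Numerical choices:

* Per-trial likelihoods are floored at `1e-300` before the log, so the
  boundary $p = 1$ cannot underflow to $-\infty$ in the far tail.
* The optimiser restarts from a fixed rotation through
  $p \in \{0.5, 0.9, 0.99\} \times \sigma \in \{30, 80, 200\}$ px (5
  starts by default) and keeps the best converged solution. The surface is
  smooth in two dimensions; the test suite verifies on every run that the
  optimum undercuts a 101 × 101 grid over the whole box.
* Trial-level classification ("success" vs "guess") compares the **raw**
  component densities $\phi_2 > g$, not the mixture-weighted posteriors —
  equivalently, success within the radial cutoff
  $r^\* = \sigma\sqrt{-2\ln(2\pi\sigma^2 g)}$. A `weighted = TRUE` flag
  switches to the posterior comparison. The unweighted rule makes the
  cutoff independent of $\hat p$, which also means a *smaller* fitted
  $\sigma$ implies a *stricter* cutoff; see the note on the generator's
  success-rate structure below.
* Because only 8 trials per condition exist per participant,
  cued/uncued fits are pooled across participants
  (`group_fit_by_condition()`), each trial keeping its own anchor;
  per-participant fits are used only for the studied-vs-remembered
  precision comparison, where all 36 delayed trials are available.

## The synthetic experiment generator

`simulate_experiment()` draws every measurement the pipeline consumes.
Per participant $i$, an ability latent $\lambda_i \sim N(0,1)$ (higher =
worse) scales immediate placement noise
($\sigma_i = 55\,e^{0.25\lambda_i}$ px) and the training-rounds count
($2 + \mathrm{Pois}(0.55\,e^{0.35\lambda_i})$ per association, matching
reported training ranges for this paradigm (2–6 rounds, per-association
mean near 2.55)).
Studied locations are uniform with a 125 px edge margin (object sprites
span 250 px) and a 100 px minimum separation — the real sampling scheme
is unreported, so both are exposed parameters without any fidelity claim.

Cue assignment **runs the package's own procedure** on the simulated
immediate errors: associations more than 2 SD above the mean error are
flagged (topped up at random to 2), and the remaining 16 are split 8 vs 8
by exhaustive search over all 6,435 unordered partitions, minimising the
cued–uncued difference in mean immediate error. Which side is labelled
"cued" is a seeded coin flip, since the means are matched.

Delayed round-1 placements are Gaussian around the **immediate**
placement (the anchoring structure: memory drifts from what was expressed,
not from what was studied), with SD 45 px for uncued associations and

$$\sigma_{\text{cued},ij} = \max\!\big(5,\; 45 - (10 + 4\lambda_i +
15\,\bar v_{ij})\big)$$

for cued ones, where $\bar v_{ij}$ is the mean of the ITI-level vigilance
latent over the three ITIs preceding that object's re-exposures. Worse
learners and less vigilant (slower) states therefore yield larger
benefits, the two couplings the analyses must recover. Round 2 adds
35 px of drift to round 1. Each delayed placement is a uniform guess with
probability 0.05 (uncued) or 0.025 (cued): in this paradigm cueing shows
up both as higher precision *and* as a higher probability of memory
success, and without the guessing-rate component the classification
cutoff effect noted above would invert the success-rate ordering.

The cover task is generated structurally exactly: 96 trials in three
thirds of 32; ITI durations 10/12/14/16 s, eight of each per third, with
$\mathrm{duration}/2$ arrows at 2 s each; 24 cue trials (one per cued
object per third, two per ITI duration per third, half before words and
half before pseudo-words). Arrow RTs are participant baseline
(450 ± 60 ms) plus 40 ms per vigilance-latent unit plus 60 ms arrow
noise; lexical RTs add a 32 ms inflation after re-exposures (a reported
trend-level magnitude). Cue-discrimination ratings follow an equal-variance
signal-detection model with per-participant $d' \sim N(1, 0.8)$ and
criteria at $d'/2 \pm 0.8$; by default $d'$ is independent of the
benefit, with a coupling knob for sensitivity analyses.

Determinism: one master seed; per-participant substream seeds are drawn
once from it, so datasets are bit-reproducible and participants can be
generated independently.

Calibration was set once against magnitudes reported for this paradigm — immediate error
near 77 px / 2.0 cm, remembered-anchor precision near 1.1 cm vs 1.77 cm
studied, cued/uncued immediate match at 1.81 cm each, success rates near
93–95%, a positive mean stability benefit of roughly 0.2–0.6 cm — and
not revisited. What the generator does **not** emulate: the raw
item-level RT–benefit correlation comes out near 0.05–0.08 rather than
reported item-level robust-regression correlations near $r = 0.25$, because uniform-guess trials
fatten the benefit tails; lexical content, learning-block feedback and
any participant exclusions are not modelled. Passing tests therefore
show that the machinery recovers the structure this generator encodes,
not that real data would show these effect sizes.

## Cue assignment, errors and derived measures

`spatial_errors()` expands a trial table into all Euclidean distances the
analyses use; stability error is the delayed-vs-immediate distance and
the across-round distance compares the two delayed placements.
`fraction_closer_to_remembered()` counts strict inequalities (exact
ties, a measure-zero event under the model, count as not-closer).
High-error flagging uses the one-sided rule error > mean + 2 SD with the
$n-1$ SD. Unit conversion uses 38.697 px/cm, reconstructed from the
reported dual-unit pair 264.3 px ≡ 6.83 cm (the alternative pair 77.3 px ≡ 2.00 cm
gives 38.65 — consistent to rounding); the true monitor geometry is
unreported.

The per-association cueing benefit is the participant's mean uncued
stability error minus the association's own stability error (positive =
cueing helped), averaged over the two delayed rounds by default.
Pre-cue vigilance is the mean arrow RT over the three ITIs preceding an
object's re-exposures, minus the participant's mean over no-cue ITIs
(`"noncued_itis"`), or over all ITIs (`"all_itis"`). The two references
differ by a per-participant constant, so within-participant statistics
are mode-invariant exactly; pooled statistics agree only approximately,
because the constant varies across participants.

## Robust regression and permutation inference

`irls_regression()` implements bisquare iteratively reweighted least
squares: standardised residuals $u = r / (c\,s\,\sqrt{1-h})$ with
$c = 4.685$, robust scale $s = \mathrm{median}(|r|)/0.6745$ and fixed OLS
leverages $h$; weights $(1-u^2)^2$ inside $|u|<1$, zero outside;
iteration until coefficients move less than $10^{-8}$. Standard errors
and $t$ come from the final weighted fit with $n-2$ df (a sandwich
estimator is deliberately out of scope), and the reported $r$ is the
plain Pearson correlation of the raw data. A perfect fit ($s \to 0$)
short-circuits with unit weights. `ols_with_exclusion()` is the
complementary check: drop points with $|z| > k$ SD in either variable
(default $k = 3$, the conventional choice for this check; the
alternative $k = 2$ variant is one argument away) and fit OLS.

`permutation_test_slope()` permutes the response, recomputes the IRLS
slope, and reports the two-sided add-one p-value
$(1 + \#\{|b^\*| \ge |b|\})/(1 + n_{\text{perm}})$, which can never be
zero. The construction (what is permuted, the statistic, sidedness,
add-one) is this package's own choice; reference analyses of this
paradigm do not document their permutation construction. A caveat the package surfaces deliberately: the
item-level analysis pools associations across participants, and
benefits within a participant share that participant's uncued-mean
reference. Under the generator's null coupling this dependence makes the
pooled permutation test mildly anti-conservative with the IRLS statistic
(measured type-I error around 0.06–0.08 at $\alpha = 0.05$ over 500
simulated datasets, versus ~0.055 for the OLS statistic, and nominal
behaviour on iid data). Item-level conclusions from this design should
therefore lean on effect sizes and the per-participant analyses rather
than the pooled p-value alone; a mixed-effects treatment is out of scope.

## Group inference

`rm_anova()` performs the classical fully-within-subject decomposition on
cell means via `aov()` error strata (each effect tested against its
effect × subject interaction), with
$\eta_p^2 = F\,\mathrm{df}_1/(F\,\mathrm{df}_1 + \mathrm{df}_2)$.
Designs must be complete; effects whose error stratum is numerically zero
(constant data) are returned flagged rather than with spurious $F$s. No
sphericity correction is applied by default — every factor except the
four-level rating factor has two levels — but Greenhouse–Geisser is
available. Cohen's d is mean-difference / SD-of-differences for paired
contrasts (consistent with reported $t \approx d\sqrt{n}$ pairs in this paradigm) and
pooled-SD for unpaired. The learning factor z-scores mean immediate
error and mean training rounds and takes PC1, sign-aligned so higher =
worse learning. The cue-discrimination classifier builds each
participant's 2 × 2 table of cue status against "high-confident cued" vs
anything else, computes the uncorrected Pearson chi-squared
(closed form; zero-margin tables give 0), and labels discriminators at
$p < 0.1$; expected counts are always below 5 at this design size, which
is logged once per call rather than escalated to an exact test, the
convention this paradigm's analyses use.

No multiple-comparison correction is applied anywhere, replicating the paradigm's standard
analysis strategy; with ~20 tests per full run this is a known
limitation of the design, not of the implementation.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` size their simulations so that
Monte-Carlo error is small relative to the asserted effect: parameter
recovery uses 20 replicates of $n = 2000$ mixture draws; structural
properties use 150–250 simulated participants; permutation calibration
uses 500 datasets of 24 participants × 200 permutations. All randomness
flows from explicit seeds, and `run_full_analysis()` emits a manifest
(config snapshot, seeds, package version) from which a run can be
reproduced exactly.
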
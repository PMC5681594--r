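test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- sim_config(n_participants = 3, seed = 915)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$ldt, e2$ldt)
  expect_identical(e1$ratings, e2$ratings)
  # a different seed gives different data
  e3 <- simulate_experiment(cfg, seed = 916)
  expect_false(identical(e1$trials, e3$trials))
})

test_that("every session satisfies the LDT structural invariants", {
  exp <- sim_default_small()
  for (pid in unique(exp$ldt$participant_id)) {
    s <- exp$ldt[exp$ldt$participant_id == pid, ]
    expect_equal(nrow(s), 96)
    cued <- s$cue_object_id[!is.na(s$cue_object_id)]
    expect_length(cued, 24)
    expect_true(all(table(cued) == 3))
    # cue events balanced over the four ITI durations and lexical classes
    expect_true(all(table(s$iti_duration_s[!is.na(s$cue_object_id)]) == 6))
    expect_equal(sum(s$is_word[!is.na(s$cue_object_id)]), 12)
    expect_equal(sum(s$is_word), 48)
    # one re-exposure of each object per third of the session
    third <- ceiling(s$trial_index / 32)
    for (k in 1:3) {
      expect_setequal(s$cue_object_id[third == k & !is.na(s$cue_object_id)],
                      unique(cued))
    }
    # the arrow count fills the ITI at 2 s per arrow
    expect_equal(lengths(s$arrow_rts_ms) * 2, s$iti_duration_s)
    expect_true(all(unlist(s$arrow_rts_ms) > 0))
  }
  # trial-side counts
  counts <- dplyr::count(exp$trials, participant_id, cue_status)
  expect_true(all(counts$n[counts$cue_status == "cued"] == 8))
  expect_true(all(counts$n[counts$cue_status == "uncued"] == 8))
  expect_true(all(counts$n[counts$cue_status == "flagged"] == 2))
  expect_true(all(exp$trials$n_training_rounds >= 2))
})

test_that("zero round-2 drift and zero guessing reproduce round 1 exactly", {
  cfg <- sim_config(n_participants = 2, sigma_round2 = 0,
                    guess_prob_immediate = 0, guess_prob_delayed = 0,
                    seed = 5)
  exp <- simulate_experiment(cfg)
  expect_identical(exp$trials$delayed2_x, exp$trials$delayed1_x)
  expect_identical(exp$trials$delayed2_y, exp$trials$delayed1_y)
})

test_that("default experiment placements stay on the grid", {
  exp <- sim_default_small()
  g <- exp$config$grid
  for (col in c("studied", "immediate", "delayed1", "delayed2")) {
    expect_true(all(exp$trials[[paste0(col, "_x")]] >= 0 &
                      exp$trials[[paste0(col, "_x")]] <= g$width_px))
    expect_true(all(exp$trials[[paste0(col, "_y")]] >= 0 &
                      exp$trials[[paste0(col, "_y")]] <= g$height_px))
  }
})

test_that("mixture samples behave at the degenerate corners", {
  # p = 1, sigma = 1: placements essentially on their anchors
  tight <- simulate_mixture_sample(1, 1, n = 100, seed = 1)
  d <- euclidean_error(tight$x, tight$y, tight$anchor_x, tight$anchor_y)
  expect_true(all(d < 5))

  # p = 0: placements uniform; 4x4 chi-squared goodness of fit not rejected
  unif <- simulate_mixture_sample(0, 45, n = 10000, seed = 2)
  bins <- table(cut(unif$x, seq(0, 1280, length.out = 5)),
                cut(unif$y, seq(0, 1024, length.out = 5)))
  gof <- stats::chisq.test(as.vector(bins), p = rep(1 / 16, 16))
  expect_gt(gof$p.value, 0.01)

  expect_error(simulate_mixture_sample(1.4, 45, 10), "domain error")
  expect_error(simulate_mixture_sample(0.5, 900, 10), "domain error")
  expect_error(simulate_mixture_sample(0.5, 0.5, 10), "domain error")
})

test_that("mixture sample mean radial error matches the analytic mixture mean", {
  p <- 0.93; s <- 45; n <- 2000
  samp <- simulate_mixture_sample(p, s, n = n, seed = 606)
  d <- euclidean_error(samp$x, samp$y, samp$anchor_x, samp$anchor_y)

  # analytic: p * sigma * sqrt(pi/2) + (1 - p) * E[dist of two uniform
  # points]; the latter by numeric integration over the triangular
  # densities of |dx| and |dy|
  a <- 1280; b <- 1024
  nx <- 400
  dx <- seq(0, a, length.out = nx + 1)[-1] - a / (2 * nx)
  dy <- seq(0, b, length.out = nx + 1)[-1] - b / (2 * nx)
  fx <- 2 * (a - dx) / a^2 * (a / nx)
  fy <- 2 * (b - dy) / b^2 * (b / nx)
  e_unif <- sum(outer(fx, fy) * sqrt(outer(dx^2, dy^2, "+")))
  analytic <- p * s * sqrt(pi / 2) + (1 - p) * e_unif

  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - analytic), 3 * se)
})

test_that("delayed placements anchor on remembered, not studied, locations", {
  exp <- sim_default_big()
  e <- spatial_errors(exp$trials)
  expect_lt(mean(c(e$delayed1_remembered_px, e$delayed2_remembered_px)),
            mean(c(e$delayed1_studied_px, e$delayed2_studied_px)))
  expect_gt(fraction_closer_to_remembered(exp$trials), 0.5)
})

test_that("invalid configurations raise configuration errors", {
  expect_error(sim_config(n_cued = 9), "configuration error")
  expect_error(sim_config(guess_prob_delayed = 1.5), "configuration error")
  expect_error(sim_config(sigma_delay_uncued = -3), "configuration error")
  expect_error(sim_config(n_participants = 0), "configuration error")
})

test_that("training rounds grow with the ability latent", {
  exp <- sim_default_big()
  per <- dplyr::summarise(
    dplyr::group_by(exp$trials, participant_id),
    rounds = mean(n_training_rounds), .groups = "drop")
  per <- dplyr::inner_join(per, exp$truth, by = "participant_id")
  expect_gt(stats::cor(per$rounds, per$ability), 0)
  # worse ability also means larger immediate errors
  e <- spatial_errors(exp$trials)
  imm <- tapply(e$immediate_error_px, e$participant_id, mean)
  per$imm <- imm[per$participant_id]
  expect_gt(stats::cor(per$imm, per$ability), 0)
})
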
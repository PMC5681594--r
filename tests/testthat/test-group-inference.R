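# manual within-subject sums-of-squares decomposition for a 2x2 design,
# used as an independent oracle for rm_anova()
manual_anova_2x2 <- function(d) {
  # d: subj, a, b, y (one row per cell)
  gm <- mean(d$y)
  subj_m <- tapply(d$y, d$subj, mean)
  a_m <- tapply(d$y, d$a, mean)
  b_m <- tapply(d$y, d$b, mean)
  ab_m <- tapply(d$y, list(d$a, d$b), mean)
  sa_m <- tapply(d$y, list(d$subj, d$a), mean)
  sb_m <- tapply(d$y, list(d$subj, d$b), mean)
  n_s <- length(subj_m)
  ss_a <- 2 * n_s * sum((a_m - gm)^2)
  ss_b <- 2 * n_s * sum((b_m - gm)^2)
  ss_ab <- n_s * sum((ab_m - outer(a_m - gm, b_m - gm, "+") - gm)^2)
  ss_sa <- 2 * sum((sa_m - outer(subj_m - gm, a_m - gm, "+") - gm)^2)
  ss_sb <- 2 * sum((sb_m - outer(subj_m - gm, b_m - gm, "+") - gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_subj <- 4 * sum((subj_m - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_subj - ss_sa - ss_sb
  list(
    F_a = (ss_a / 1) / (ss_sa / (n_s - 1)),
    F_b = (ss_b / 1) / (ss_sb / (n_s - 1)),
    F_ab = (ss_ab / 1) / (ss_sab / (n_s - 1))
  )
}

test_that("rm_anova matches a hand-computed 2x2 decomposition", {
  withr::with_seed(21, {
    d <- tidyr::expand_grid(subj = sprintf("s%02d", 1:12),
                            a = c("a1", "a2"), b = c("b1", "b2"))
    d$y <- stats::rnorm(nrow(d)) +
      rep(stats::rnorm(12), each = 4) + # subject offsets
      0.8 * (d$a == "a2") + 0.3 * (d$a == "a2") * (d$b == "b2")
  })
  res <- rm_anova(d, "y", "subj", c("a", "b"))
  oracle <- manual_anova_2x2(d)
  expect_equal(res$F[res$effect == "a"], oracle$F_a, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "b"], oracle$F_b, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "a:b"], oracle$F_ab, tolerance = 1e-9)
  expect_equal(res$df_den, rep(11, 3))
})

test_that("two-level within effects satisfy F = t^2 and the partial eta identity", {
  withr::with_seed(55, {
    for (i in 1:5) {
      n <- 10 + i
      a <- stats::rnorm(n, mean = 0.4)
      b <- stats::rnorm(n)
      d <- tibble::tibble(
        subj = rep(sprintf("s%02d", 1:n), 2),
        cond = rep(c("x", "y"), each = n),
        val = c(a, b))
      res <- rm_anova(d, "val", "subj", "cond")
      tt <- paired_t(a, b)
      expect_equal(res$F, tt$t^2, tolerance = 1e-9)
      expect_equal(res$p, tt$p, tolerance = 1e-9)
      expect_equal(res$partial_eta_sq,
                   res$F * res$df_num / (res$F * res$df_num + res$df_den),
                   tolerance = 1e-12)
    }
  })
})

test_that("rm_anova rejects incomplete designs and flags degenerate data", {
  d <- tidyr::expand_grid(subj = sprintf("s%d", 1:6), a = c("x", "y"))
  d$y <- stats::rnorm(12)
  expect_error(rm_anova(d[-1, ], "y", "subj", "a"), "incomplete")
  expect_error(rm_anova(d, "y", "subj", "missing_col"), "missing")

  d$y <- 5
  res <- rm_anova(d, "y", "subj", "a")
  expect_true(res$degenerate)
})

test_that("t-tests match closed forms and the reference implementation", {
  expect_equal(paired_t(rep(3, 10), rep(3, 10))$t, 0)
  expect_equal(paired_t(rep(3, 10), rep(3, 10))$cohens_d, 0)

  # a difference vector with mean 1 and SD 1 at n = 25: t = 5, d = 1
  withr::with_seed(8, z <- as.numeric(scale(stats::rnorm(25))))
  diffs <- 1 + z
  res <- paired_t(diffs)
  expect_equal(res$t, 5, tolerance = 1e-12)
  expect_equal(res$cohens_d, 1, tolerance = 1e-12)
  expect_equal(res$t, res$cohens_d * sqrt(25), tolerance = 1e-12)

  withr::with_seed(9, {
    a <- stats::rnorm(14, 1); b <- stats::rnorm(14)
    ref <- stats::t.test(a, b, paired = TRUE)
    mine <- paired_t(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

    a2 <- stats::rnorm(11, 0.5); b2 <- stats::rnorm(17)
    ref2 <- stats::t.test(a2, b2, var.equal = TRUE)
    mine2 <- unpaired_t(a2, b2)
    expect_equal(mine2$t, unname(ref2$statistic), tolerance = 1e-12)
    expect_equal(mine2$p, ref2$p.value, tolerance = 1e-12)
    expect_identical(mine2$df, 26L)
  })
})

test_that("the learning factor spans the rank-1 and isotropic corner cases", {
  d_corr <- tibble::tibble(id = 1:10, err = as.numeric(1:10),
                           rnd = 2 + 3 * as.numeric(1:10))
  lf <- learning_factor(d_corr, err, rnd)
  expect_equal(abs(unname(lf$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(lf$variance_explained, 1, tolerance = 1e-9)
  expect_gt(stats::cor(lf$scores$learning_score, d_corr$err), 0.999)

  # exactly orthogonal z-scored inputs split the variance evenly
  withr::with_seed(6, {
    e1 <- as.numeric(scale(stats::rnorm(20)))
    e2 <- as.numeric(scale(stats::resid(stats::lm(stats::rnorm(20) ~ e1))))
  })
  lf0 <- learning_factor(tibble::tibble(id = 1:20, err = e1, rnd = e2),
                         err, rnd)
  expect_equal(lf0$variance_explained, 0.5, tolerance = 1e-9)

  # sign alignment: higher score always means higher immediate error
  d_neg <- tibble::tibble(id = 1:10, err = as.numeric(10:1),
                          rnd = as.numeric(10:1) + stats::rnorm(10, 0, 0.1))
  lf_neg <- learning_factor(d_neg, err, rnd)
  expect_gt(stats::cor(lf_neg$scores$learning_score, d_neg$err), 0)
})

test_that("split-half strata are exhaustive, disjoint and tie-stable", {
  tr <- sim_default_small()$trials
  split <- split_half_by_initial_memory(tr)
  counts <- dplyr::count(split, participant_id, cue_status, initial_memory)
  expect_true(all(counts$n == 4))
  agg <- dplyr::summarise(
    dplyr::group_by(split, participant_id, cue_status, initial_memory),
    m = mean(immediate_error_px), .groups = "drop")
  w <- tidyr::pivot_wider(agg, names_from = initial_memory, values_from = m)
  expect_true(all(w$low <= w$high))

  # all-equal errors: assignment falls back to object-id order
  tied <- make_stability_trials(rep(10, 4), rep(20, 4))
  tied$immediate_x <- 500 # all immediate errors identical
  tied$immediate_y <- 500
  s_tied <- split_half_by_initial_memory(tied)
  cued_low <- s_tied$object_id[s_tied$cue_status == "cued" &
                                 s_tied$initial_memory == "low"]
  expect_identical(sort(cued_low), c("o01", "o02"))
})

test_that("discrimination chi-squared matches the closed form and labels", {
  mk <- function(a, b, c, d) {
    tibble::tibble(
      participant_id = "p1",
      object_id = sprintf("o%02d", 1:16),
      cue_status = rep(c("cued", "uncued"), each = 8),
      rating = c(rep("HC_cued", a), rep("LC_uncued", b),
                 rep("HC_cued", c), rep("LC_uncued", d)))
  }
  # perfect discrimination: chi^2 = N(ad-bc)^2/(r1 r2 c1 c2) = 16
  perfect <- suppressMessages(discrimination_chi2(mk(8, 0, 0, 8)))
  expect_equal(perfect$chi_sq, 16)
  expect_lt(perfect$p, 0.001)
  expect_identical(perfect$label, "discriminator")
  expect_equal(perfect$hc_hit_rate, 1)
  expect_equal(perfect$hc_fa_rate, 0)

  # identical rating distributions: no signal
  none <- suppressMessages(discrimination_chi2(mk(4, 4, 4, 4)))
  expect_equal(none$chi_sq, 0)
  expect_identical(none$label, "non_discriminator")

  # zero margin (no high-confident-cued responses at all)
  zero_margin <- suppressMessages(discrimination_chi2(mk(0, 8, 0, 8)))
  expect_equal(zero_margin$chi_sq, 0)
  expect_identical(zero_margin$label, "non_discriminator")

  # random tables agree with the uncorrected Pearson test
  withr::with_seed(19, {
    for (i in 1:5) {
      a <- sample(1:7, 1); c <- sample(1:7, 1)
      tab <- mk(a, 8 - a, c, 8 - c)
      ref <- suppressWarnings(stats::chisq.test(
        matrix(c(a, 8 - a, c, 8 - c), 2, byrow = TRUE), correct = FALSE))
      mine <- suppressMessages(discrimination_chi2(tab))
      expect_equal(mine$chi_sq, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("rating distributions sum to one and subset contrasts drop participants", {
  exp <- sim_default_small()
  dist <- rating_distribution(exp$ratings)
  sums <- dplyr::summarise(
    dplyr::group_by(dist, participant_id, cue_status),
    s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_equal(nrow(dist), 10 * 2 * 4)

  contrast <- labeled_subset_contrast(exp$trials, "rated_uncued_only")
  expect_lte(contrast$n_retained, 10)
  expect_identical(contrast$test$n, contrast$n_retained)

  # participants lacking a cell in the subset are dropped
  tr <- make_stability_trials(c(30, 40), c(60, 70))
  tr$rating <- c("HC_cued", "HC_cued", "LC_uncued", "HC_uncued")
  tr2 <- dplyr::mutate(tr, participant_id = "p2",
                       rating = c("LC_uncued", "HC_uncued",
                                  "LC_uncued", "HC_uncued"))
  tr3 <- dplyr::mutate(tr2, participant_id = "p3")
  both <- dplyr::bind_rows(tr, tr2, tr3)
  res <- labeled_subset_contrast(both, "rated_uncued_only")
  expect_identical(res$n_retained, 2L) # p1 has no rated-uncued cued trials
  expect_setequal(res$per_participant$participant_id, c("p2", "p3"))
  expect_equal(res$per_participant$uncued - res$per_participant$cued,
               rep(65 - 35, 2))
})
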
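# End-to-end orchestration: run every analysis stage in the order the
# experimental questions are asked, and collect a reproducible report.

.t_summary <- function(tt) {
  list(t = tt$t, df = tt$df, p = tt$p, cohens_d = tt$cohens_d,
       mean_diff = tt$mean_diff, n = tt$n)
}

.anova_summary <- function(an) {
  lapply(seq_len(nrow(an)), function(i) list(
    effect = an$effect[i], F = an$F[i], df_num = an$df_num[i],
    df_den = an$df_den[i], p = an$p[i],
    partial_eta_sq = an$partial_eta_sq[i]))
}

.robust_summary <- function(fit) {
  list(beta = fit$beta, se_beta = fit$se_beta, r = fit$r, t = fit$t_stat,
       df = fit$df, p = fit$p_value, n = fit$n)
}

#' Run the complete analysis pipeline
#'
#' Composes every analysis stage on one experiment, in order: spatial
#' errors; the studied-vs-remembered anchoring analyses (ANOVA, trialwise
#' fraction closer, per-participant mixture precision); cued-vs-uncued
#' stability contrasts and group-level mixture success rates; the
#' vigilance-benefit robust regression with its permutation test and the
#' post-cue RT analyses; the learning-factor and split-half analyses; and
#' the cue-discrimination analyses. The result is deterministic given the
#' input data and `seed`.
#'
#' @param experiment A `wakecue_experiment` (from [simulate_experiment()] or
#'   [read_experiment()]).
#' @param grid A [grid_spec()]; defaults to the experiment's own grid when
#'   available.
#' @param n_perm Permutations for the slope permutation tests.
#' @param seed Seed for the permutation streams.
#' @return A list of class `wakecue_report`: `summary` (nested list of
#'   headline statistics, JSON-ready), `errors` (long error table),
#'   `item_level` (per-cued-association RT/benefit table), `anchoring`,
#'   `stability`, `mixture`, `vigilance`, `learning`, `discrimination`
#'   (stage objects) and `manifest`.
#' @export
run_full_analysis <- function(experiment, grid = NULL, n_perm = 2000L,
                              seed = 1L) {
  stopifnot(inherits(experiment, "wakecue_experiment"))
  trials <- experiment$trials
  ldt <- experiment$ldt
  validate_experiment_tables(trials, ldt, experiment$ratings)
  if (is.null(grid)) {
    grid <- if (inherits(experiment$config, "wakecue_config")) {
      experiment$config$grid
    } else {
      grid_spec()
    }
  }

  errors <- spatial_errors(trials, grid)
  comp <- errors[errors$cue_status %in% c("cued", "uncued"), , drop = FALSE]

  # -- anchoring: studied vs remembered -------------------------------
  long <- error_table(trials, grid)
  anchor_anova <- rm_anova(long, "error_px", "participant_id",
                           c("anchor_mode", "round"))
  frac_closer <- fraction_closer_to_remembered(trials, grid)
  precision <- compare_anchor_precision(trials, grid)

  # -- cueing and stability -------------------------------------------
  stab_long <- long[long$anchor_mode == "remembered" &
                      long$cue_status %in% c("cued", "uncued"), ]
  cueing_anova <- rm_anova(stab_long, "error_px", "participant_id",
                           c("cue_status", "round"))
  per_stab <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(stab_long, participant_id, cue_status),
                     error_px = mean(error_px), .groups = "drop"),
    names_from = cue_status, values_from = error_px)
  stability_t <- paired_t(per_stab$uncued, per_stab$cued)
  across_means <- dplyr::summarise(
    dplyr::group_by(comp, participant_id, cue_status),
    across_px = mean(across_round_px), .groups = "drop")
  across_wide <- tidyr::pivot_wider(across_means, names_from = cue_status,
                                    values_from = across_px)
  across_t <- paired_t(across_wide$uncued, across_wide$cued)
  imm_match <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(comp, participant_id, cue_status),
                     imm_px = mean(immediate_error_px), .groups = "drop"),
    names_from = cue_status, values_from = imm_px)

  # -- mixture success rates ------------------------------------------
  succ <- participant_success_rates(trials, "remembered", grid)
  success_anova <- rm_anova(succ, "success_rate", "participant_id",
                            c("cue_status", "round"))
  succ_means <- tapply(succ$success_rate, succ$cue_status, mean)

  # -- vigilance -------------------------------------------------------
  items <- item_level_table(trials, ldt, grid = grid)
  pre_fit <- irls_regression(items, pre_cue_rt, benefit_px)
  pre_perm <- permutation_test_slope(items, pre_cue_rt, benefit_px,
                                     n_perm = n_perm, seed = seed)
  pre_excl <- ols_with_exclusion(items, pre_cue_rt, benefit_px, k_sd = 3)
  post_fit <- irls_regression(items, post_cue_rt, benefit_px)
  rt_contrast <- post_cue_rt_contrast(ldt)

  # -- learning --------------------------------------------------------
  per_learn <- dplyr::summarise(
    dplyr::group_by(errors, participant_id),
    mean_immediate_error_px = mean(immediate_error_px),
    mean_rounds = mean(n_training_rounds), .groups = "drop")
  benefit_per_part <- tibble::tibble(
    participant_id = per_stab$participant_id,
    benefit_px = per_stab$uncued - per_stab$cued)
  lf <- learning_factor(per_learn, mean_immediate_error_px, mean_rounds)
  learn_df <- dplyr::inner_join(lf$scores, benefit_per_part,
                                by = "participant_id")
  learn_df$benefit_cm <- px_to_cm(learn_df$benefit_px, grid)
  learning_fit <- irls_regression(learn_df, learning_score, benefit_cm)
  split <- split_half_by_initial_memory(trials, grid)
  split_long <- tidyr::pivot_longer(
    split, cols = c("delayed1_remembered_px", "delayed2_remembered_px"),
    names_to = "round", values_to = "error_px")
  split_anova <- rm_anova(split_long, "error_px", "participant_id",
                          c("initial_memory", "cue_status", "round"))
  split_t <- lapply(c(low = "low", high = "high"), function(s) {
    w <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(split_long[split_long$initial_memory == s, ],
                        participant_id, cue_status),
        error_px = mean(error_px), .groups = "drop"),
      names_from = cue_status, values_from = error_px)
    paired_t(w$uncued, w$cued)
  })

  # -- cue discrimination ---------------------------------------------
  rate_dist <- rating_distribution(experiment$ratings)
  rating_anova <- rm_anova(rate_dist, "proportion", "participant_id",
                           c("cue_status", "rating"))
  disc <- discrimination_chi2(experiment$ratings)
  disc_groups <- dplyr::inner_join(disc, benefit_per_part,
                                   by = "participant_id")
  nd <- disc_groups$benefit_px[disc_groups$label == "non_discriminator"]
  dd <- disc_groups$benefit_px[disc_groups$label == "discriminator"]
  disc_t <- if (length(nd) >= 2 && length(dd) >= 2) {
    unpaired_t(nd, dd)
  } else {
    .na_ttest(length(nd) + length(dd), paired = FALSE)
  }
  lab_uncued <- labeled_subset_contrast(trials, "rated_uncued_only", grid)
  lab_cued <- labeled_subset_contrast(trials, "rated_cued_only", grid)

  summary <- list(
    design = list(
      n_participants = length(unique(trials$participant_id)),
      n_objects = length(unique(trials$object_id)),
      guessing_density_per_px2 = guessing_density(grid)),
    anchoring = list(
      anova = .anova_summary(anchor_anova),
      fraction_closer_to_remembered_pct = 100 * frac_closer,
      precision = list(
        sigma_studied_cm = mean(precision$per_participant$sigma_studied_cm),
        sigma_remembered_cm = mean(precision$per_participant$sigma_remembered_cm),
        test = .t_summary(precision$test))),
    stability = list(
      immediate_match = list(
        cued_cm = px_to_cm(mean(imm_match$cued), grid),
        uncued_cm = px_to_cm(mean(imm_match$uncued), grid)),
      cueing_anova = .anova_summary(cueing_anova),
      cued_vs_uncued = .t_summary(stability_t),
      across_round = .t_summary(across_t),
      success_anova = .anova_summary(success_anova),
      success_rate_cued_pct = 100 * unname(succ_means["cued"]),
      success_rate_uncued_pct = 100 * unname(succ_means["uncued"])),
    vigilance = list(
      pre_cue = .robust_summary(pre_fit),
      pre_cue_permutation_p = pre_perm$p_value,
      pre_cue_excluding_outliers = c(.robust_summary(pre_excl),
                                     n_dropped = pre_excl$n_dropped),
      post_cue = .robust_summary(post_fit),
      post_cue_rt_contrast = .t_summary(rt_contrast$test)),
    learning = list(
      factor_variance_explained = lf$variance_explained,
      factor_input_r = lf$r_inputs,
      factor_vs_benefit = .robust_summary(learning_fit),
      split_half_anova = .anova_summary(split_anova),
      cueing_low_error = .t_summary(split_t$low),
      cueing_high_error = .t_summary(split_t$high)),
    discrimination = list(
      rating_anova = .anova_summary(rating_anova),
      n_discriminators = sum(disc$label == "discriminator"),
      n_non_discriminators = sum(disc$label == "non_discriminator"),
      benefit_non_vs_discriminators = .t_summary(disc_t),
      rated_uncued_only = c(.t_summary(lab_uncued$test),
                            n_retained = lab_uncued$n_retained),
      rated_cued_only = c(.t_summary(lab_cued$test),
                          n_retained = lab_cued$n_retained)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("wakecue")),
    analysis_seed = as.integer(seed),
    n_perm = as.integer(n_perm),
    data_seed = experiment$seed,
    config = if (inherits(experiment$config, "wakecue_config")) {
      cfg <- experiment$config; cfg$grid <- unclass(cfg$grid); unclass(cfg)
    } else {
      experiment$config
    })

  structure(
    list(summary = summary, errors = long, item_level = items,
         anchoring = list(anova = anchor_anova, precision = precision,
                          fraction_closer = frac_closer),
         stability = list(anova = cueing_anova, t = stability_t,
                          across_t = across_t, success = succ),
         vigilance = list(pre_fit = pre_fit, perm = pre_perm,
                          excl = pre_excl, post_fit = post_fit,
                          rt_contrast = rt_contrast),
         learning = list(factor = lf, fit = learning_fit,
                         split_anova = split_anova, split_t = split_t),
         discrimination = list(ratings = rate_dist, anova = rating_anova,
                               chi2 = disc, group_t = disc_t,
                               rated_uncued = lab_uncued,
                               rated_cued = lab_cued),
         manifest = manifest),
    class = "wakecue_report")
}

#' @export
print.wakecue_report <- function(x, ...) {
  s <- x$summary
  cat("<wakecue_report>\n")
  cat(sprintf("  %d participants; fraction closer to remembered = %.1f%%\n",
              s$design$n_participants,
              s$anchoring$fraction_closer_to_remembered_pct))
  cat(sprintf("  cueing main effect: F(%d,%d) = %.2f, p = %.3g\n",
              s$stability$cueing_anova[[1]]$df_num,
              s$stability$cueing_anova[[1]]$df_den,
              s$stability$cueing_anova[[1]]$F,
              s$stability$cueing_anova[[1]]$p))
  cat(sprintf("  vigilance-benefit slope: beta = %.2f, p = %.3g (perm p = %.3g)\n",
              s$vigilance$pre_cue$beta, s$vigilance$pre_cue$p,
              s$vigilance$pre_cue_permutation_p))
  invisible(x)
}
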
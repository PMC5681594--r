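# Group-level inference: repeated-measures ANOVA, paired/unpaired contrasts
# with effect sizes, the PCA learning factor, the item-level split-half
# strata, and the per-participant cue-discrimination classifier.

#' Repeated-measures ANOVA on a fully within-subject design
#'
#' Standard univariate within-subject decomposition on cell means: each
#' effect is tested against its own effect-by-subject interaction mean
#' square. The design must be complete (every participant contributes every
#' cell); replicate rows within a cell are averaged first. Partial eta
#' squared is `F * df_num / (F * df_num + df_den)`. No sphericity correction
#' is applied by default; all factors in the designs this package targets
#' have two levels except the four-level rating factor, for which
#' `gg_correction = TRUE` applies Greenhouse-Geisser adjusted degrees of
#' freedom.
#'
#' @param data A data frame in long format.
#' @param dv Name of the numeric response column (string).
#' @param subject Name of the participant identifier column (string).
#' @param within Character vector of within-subject factor column names.
#' @param gg_correction Apply Greenhouse-Geisser correction to p-values
#'   (default `FALSE`).
#' @return A tibble of class `wakecue_anova` with one row per effect:
#'   `effect`, `df_num`, `df_den`, `F`, `p`, `partial_eta_sq`, `degenerate`.
#' @examples
#' d <- tidyr::expand_grid(id = factor(1:6), a = c("x", "y"))
#' d$y <- stats::rnorm(nrow(d))
#' rm_anova(d, "y", "id", "a")
#' @export
rm_anova <- function(data, dv, subject, within, gg_correction = FALSE) {
  stopifnot(is.character(dv), is.character(subject), is.character(within),
            length(within) >= 1)
  cols <- c(dv, subject, within)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- tibble::as_tibble(data[, cols])
  names(d) <- c(".dv", ".subj", paste0(".w", seq_along(within)))
  d$.subj <- factor(d$.subj)
  wnames <- paste0(".w", seq_along(within))
  for (wn in wnames) d[[wn]] <- factor(d[[wn]])

  # collapse replicates to cell means; a complete design is required
  d <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(c(".subj", wnames)))),
    .dv = mean(.dv), .groups = "drop")
  n_cells <- prod(vapply(d[wnames], nlevels, integer(1)))
  counts <- table(d$.subj)
  if (any(counts != n_cells) || nrow(d) != nlevels(d$.subj) * n_cells) {
    stop("incomplete within-subject design: every participant must ",
         "contribute every factor cell")
  }

  rhs <- paste(wnames, collapse = "*")
  form <- stats::as.formula(
    paste0(".dv ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  # sums of squares this far below the response scale are numerical dust
  ss_floor <- 1e-12 * max(sum(d$.dv^2), .Machine$double.xmin)

  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms_here <- rownames(tab)
    for (i in seq_along(terms_here)) {
      term <- trimws(terms_here[i])
      if (term == "Residuals") next
      ss_eff <- tab[i, "Sum Sq"]
      res_row <- which(trimws(terms_here) == "Residuals")
      ss_err <- tab[res_row, "Sum Sq"]
      df1 <- tab[i, "Df"]
      df2 <- tab[res_row, "Df"]
      Fv <- (ss_eff / df1) / (ss_err / df2)
      degenerate <- !is.finite(Fv) || ss_err <= ss_floor
      pretty <- term
      for (k in seq_along(within)) {
        pretty <- gsub(paste0(".w", k), within[k], pretty, fixed = TRUE)
      }
      if (degenerate) {
        Fv <- NA_real_
        pes <- NA_real_
        p <- NA_real_
      } else {
        pes <- ss_eff / (ss_eff + ss_err)
        eps <- if (gg_correction && df1 > 1) .gg_epsilon(d, term, wnames) else 1
        p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = pretty, df_num = df1, df_den = df2,
        F = Fv, p = p, partial_eta_sq = pes, degenerate = degenerate)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wakecue_anova", class(out))
  out
}

# Greenhouse-Geisser epsilon for one within effect, from the covariance of
# the subject-by-cell matrix of that effect's marginal cell means
.gg_epsilon <- function(d, term, wnames) {
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  cell <- interaction(d[facs], drop = TRUE)
  m <- tapply(d$.dv, list(d$.subj, cell), mean)
  S <- stats::cov(m)
  k <- ncol(S)
  # Box/Greenhouse-Geisser epsilon from the double-centred covariance
  D <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
  max(min(eps, 1), 1 / (k - 1))
}

#' Paired and unpaired t-tests with Cohen's d
#'
#' `paired_t()` tests the mean of `a - b` against zero; its Cohen's d is the
#' mean difference over the SD of the differences. `unpaired_t()` is the
#' classic pooled-variance two-sample test with pooled-SD Cohen's d.
#'
#' @param a,b Numeric vectors (equal length for `paired_t`).
#' @return A one-row tibble of class `wakecue_ttest`: `t`, `df`, `p`,
#'   `cohens_d`, `mean_diff`, `paired`, `n` (for unpaired, `n` is `c(n1 +
#'   n2)` and `df = n1 + n2 - 2`).
#' @examples
#' paired_t(rnorm(10, 1), rnorm(10))
#' @export
paired_t <- function(a, b = NULL) {
  diffs <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  stopifnot(n >= 2)
  sd_d <- stats::sd(diffs)
  if (sd_d == 0) {
    t <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    d <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) == 0) 1 else 0
  } else {
    t <- mean(diffs) / (sd_d / sqrt(n))
    d <- mean(diffs) / sd_d
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  out <- tibble::tibble(t = t, df = n - 1L, p = p, cohens_d = d,
                        mean_diff = mean(diffs), paired = TRUE, n = n)
  class(out) <- c("wakecue_ttest", class(out))
  out
}

# placeholder result when a contrast has too few observations to test
.na_ttest <- function(n, paired) {
  out <- tibble::tibble(t = NA_real_, df = NA_integer_, p = NA_real_,
                        cohens_d = NA_real_, mean_diff = NA_real_,
                        paired = paired, n = as.integer(n))
  class(out) <- c("wakecue_ttest", class(out))
  out
}

#' @rdname paired_t
#' @export
unpaired_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  df <- n1 + n2 - 2L
  out <- tibble::tibble(
    t = t, df = df, p = 2 * stats::pt(-abs(t), df),
    cohens_d = if (sp2 == 0) 0 else (mean(a) - mean(b)) / sqrt(sp2),
    mean_diff = mean(a) - mean(b), paired = FALSE, n = n1 + n2)
  class(out) <- c("wakecue_ttest", class(out))
  out
}

#' Learning/initial-memory factor from PCA
#'
#' Z-scores two participant-level learning measures (mean immediate-test
#' error and mean training rounds to criterion) and extracts their first
#' principal component as a single learning factor. The score is
#' sign-aligned so that higher scores mean worse learning (positive
#' correlation with immediate error).
#'
#' @param data A data frame with one row per participant.
#' @param error,rounds Unquoted columns holding mean immediate error and
#'   mean training rounds.
#' @return A list of class `wakecue_learning_factor`: `scores` (the input
#'   tibble plus a `learning_score` column), `loadings` (named length-2
#'   vector), `variance_explained` and the input correlation `r_inputs`.
#' @export
learning_factor <- function(data, error, rounds) {
  ev <- rlang::eval_tidy(rlang::enquo(error), data)
  rv <- rlang::eval_tidy(rlang::enquo(rounds), data)
  stopifnot(length(ev) >= 3, all(is.finite(ev)), all(is.finite(rv)))
  z <- cbind(error = as.numeric(scale(ev)), rounds = as.numeric(scale(rv)))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  if (stats::cor(score, ev) < 0) {
    score <- -score
    loadings <- -loadings
  }
  out <- tibble::as_tibble(data)
  out$learning_score <- score
  structure(
    list(scores = out, loadings = loadings,
         variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
         r_inputs = stats::cor(ev, rv)),
    class = "wakecue_learning_factor"
  )
}

#' @export
print.wakecue_learning_factor <- function(x, ...) {
  cat(sprintf(
    "<wakecue_learning_factor> PC1 explains %.1f%% (input r = %.2f); loadings: error %.3f, rounds %.3f\n",
    100 * x$variance_explained, x$r_inputs, x$loadings[1], x$loadings[2]))
  invisible(x)
}

#' Split associations by initial memory within participant and condition
#'
#' Within each participant-by-cueing-condition set of associations, the half
#' with the lowest immediate-test errors forms the "low" (well-learned)
#' stratum and the half with the highest errors the "high" stratum. Ties are
#' broken by stable object-id order, so strata are always exhaustive and
#' disjoint.
#'
#' @param trials Trial table including `cue_status` (flagged associations
#'   are dropped).
#' @param grid A [grid_spec()].
#' @return The cued/uncued rows of [spatial_errors()] output plus an
#'   `initial_memory` column with values `"low"`/`"high"`.
#' @export
split_half_by_initial_memory <- function(trials, grid = grid_spec()) {
  e <- spatial_errors(trials, grid)
  e <- e[e$cue_status %in% c("cued", "uncued"), , drop = FALSE]
  e <- dplyr::group_by(e, participant_id, cue_status)
  e <- dplyr::mutate(
    e,
    .pos = order(order(immediate_error_px, object_id)),
    initial_memory = ifelse(.pos <= dplyr::n() / 2, "low", "high"))
  dplyr::select(dplyr::ungroup(e), -".pos")
}

#' Per-participant cue-discrimination chi-squared classifier
#'
#' For each participant, builds the 2x2 table of cue status (cued/uncued)
#' against whether the object was rated "high-confident cued" versus any
#' other response, and computes the Pearson chi-squared statistic (closed
#' form `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, no continuity correction;
#' a zero margin gives 0 by convention). Participants with `p < 0.1` (df =
#' 1, upper tail) are labelled discriminators. Expected cell counts below 5
#' are reported via a message rather than switching to an exact test.
#'
#' @param ratings A data frame with columns `participant_id`, `object_id`,
#'   `cue_status` (`"cued"`/`"uncued"`; other values are dropped) and
#'   `rating` (one of `"HC_cued"`, `"LC_cued"`, `"LC_uncued"`,
#'   `"HC_uncued"`).
#' @return A tibble with one row per participant: `chi_sq`, `p`, `label`
#'   (`"discriminator"`/`"non_discriminator"`), `hc_hit_rate` (proportion of
#'   cued objects rated HC_cued) and `hc_fa_rate` (same for uncued).
#' @export
discrimination_chi2 <- function(ratings) {
  stopifnot(all(c("participant_id", "cue_status", "rating") %in% names(ratings)))
  r <- ratings[ratings$cue_status %in% c("cued", "uncued"), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(r), participant_id),
    a = sum(cue_status == "cued" & rating == "HC_cued"),
    b = sum(cue_status == "cued" & rating != "HC_cued"),
    c = sum(cue_status == "uncued" & rating == "HC_cued"),
    d = sum(cue_status == "uncued" & rating != "HC_cued"),
    .groups = "drop")
  N <- out$a + out$b + out$c + out$d
  denom <- (out$a + out$b) * (out$c + out$d) * (out$a + out$c) * (out$b + out$d)
  chi <- ifelse(denom == 0, 0, N * (out$a * out$d - out$b * out$c)^2 / denom)
  exp_min <- pmin((out$a + out$b) * (out$a + out$c),
                  (out$a + out$b) * (out$b + out$d),
                  (out$c + out$d) * (out$a + out$c),
                  (out$c + out$d) * (out$b + out$d)) / N
  if (any(exp_min < 5)) {
    message(sum(exp_min < 5),
            " participant(s) have expected 2x2 counts below 5; ",
            "chi-squared p-values are approximate")
  }
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  tibble::tibble(
    participant_id = out$participant_id,
    chi_sq = chi, p = p,
    label = ifelse(p < 0.1, "discriminator", "non_discriminator"),
    hc_hit_rate = out$a / (out$a + out$b),
    hc_fa_rate = out$c / (out$c + out$d))
}

#' Rating distribution by cueing condition
#'
#' Per-participant proportions of each of the four discrimination responses
#' within cued and uncued objects; proportions sum to 1 within each
#' participant-condition cell.
#'
#' @inheritParams discrimination_chi2
#' @return A tibble: `participant_id`, `cue_status`, `rating`, `proportion`.
#' @export
rating_distribution <- function(ratings) {
  r <- ratings[ratings$cue_status %in% c("cued", "uncued"), , drop = FALSE]
  r$rating <- factor(r$rating,
                     levels = c("HC_cued", "LC_cued", "LC_uncued", "HC_uncued"))
  counts <- dplyr::count(tibble::as_tibble(r),
                         participant_id, cue_status, rating, .drop = FALSE)
  counts <- dplyr::group_by(counts, participant_id, cue_status)
  out <- dplyr::mutate(counts, proportion = n / sum(n))
  dplyr::select(dplyr::ungroup(out), -"n")
}

#' Cued vs uncued stability restricted to a rating-defined subset
#'
#' Recomputes the paired cued-vs-uncued memory-stability contrast after
#' excluding associations based on how the object was rated in the
#' cue-discrimination test: `"rated_uncued_only"` keeps associations whose
#' object was labelled *not seen* (rating `LC_uncued` or `HC_uncued`),
#' `"rated_cued_only"` keeps those labelled *seen*. Participants without at
#' least one cued and one uncued association in the subset are dropped.
#'
#' @param trials Trial table including `cue_status` and `rating`.
#' @param subset `"rated_uncued_only"` or `"rated_cued_only"`.
#' @param grid A [grid_spec()].
#' @return A list: `test` (paired [paired_t()] of uncued minus cued
#'   stability), `per_participant` tibble and `n_retained`.
#' @export
labeled_subset_contrast <- function(trials,
                                    subset = c("rated_uncued_only",
                                               "rated_cued_only"),
                                    grid = grid_spec()) {
  subset <- match.arg(subset)
  stopifnot("rating" %in% names(trials))
  keep_ratings <- if (subset == "rated_uncued_only") {
    c("LC_uncued", "HC_uncued")
  } else {
    c("HC_cued", "LC_cued")
  }
  e <- spatial_errors(trials, grid)
  e <- e[e$cue_status %in% c("cued", "uncued") & e$rating %in% keep_ratings, ,
         drop = FALSE]
  e$stability_px <- (e$delayed1_remembered_px + e$delayed2_remembered_px) / 2
  per <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(e, participant_id, cue_status),
                     stability_px = mean(stability_px), .groups = "drop"),
    names_from = cue_status, values_from = stability_px)
  if (!all(c("cued", "uncued") %in% names(per))) {
    return(list(test = .na_ttest(0L, paired = TRUE),
                per_participant = per[0, ], n_retained = 0L))
  }
  per <- per[stats::complete.cases(per), , drop = FALSE]
  test <- if (nrow(per) >= 2) {
    paired_t(per$uncued, per$cued)
  } else {
    .na_ttest(nrow(per), paired = TRUE)
  }
  list(test = test, per_participant = per, n_retained = nrow(per))
}
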
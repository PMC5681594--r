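# Item-level vigilance covariates from the lexical-decision cover task, and
# per-association cueing benefits.

.check_ldt <- function(ldt) {
  needed <- c("participant_id", "trial_index", "iti_duration_s",
              "arrow_rts_ms", "lexical_rt_ms", "is_word", "cue_object_id")
  missing_cols <- setdiff(needed, names(ldt))
  if (length(missing_cols) > 0) {
    stop("ldt is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  invisible(ldt)
}

# mean arrow RT per ITI; arrow_rts_ms may be a list-column of numeric
# vectors or a semicolon-joined character column (the CSV form)
.iti_mean_rt <- function(arrow_rts_ms) {
  if (is.list(arrow_rts_ms)) {
    vapply(arrow_rts_ms,
           function(v) if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE),
           numeric(1))
  } else {
    vapply(strsplit(as.character(arrow_rts_ms), ";", fixed = TRUE),
           function(v) {
             v <- suppressWarnings(as.numeric(v))
             if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
           }, numeric(1))
  }
}

#' Normalised pre- and post-cue reaction times per cued object
#'
#' For each cued object, the pre-cue vigilance measure is the mean arrow-task
#' RT over the three ITIs that preceded its re-exposures, normalised within
#' participant by subtracting a reference mean: either the mean ITI RT over
#' ITIs with no cue event (`"noncued_itis"`, the default) or over all ITIs
#' (`"all_itis"`). The two modes differ only by a per-participant constant,
#' so item-level correlations are identical between them. The post-cue
#' measure is the mean lexical-decision RT on the three trials that followed
#' the object's re-exposures, normalised the same way against no-cue lexical
#' trials (or all trials).
#'
#' @param ldt An LDT session table (see [simulate_experiment()] or the
#'   `ldt.csv` schema): columns `participant_id`, `trial_index`,
#'   `iti_duration_s`, `arrow_rts_ms` (list-column or semicolon-joined
#'   string), `lexical_rt_ms`, `is_word`, `cue_object_id` (`NA` when no cue).
#' @param mode Normalisation reference, `"noncued_itis"` or `"all_itis"`.
#' @return A tibble with one row per (participant, cued object):
#'   `participant_id`, `object_id`, `pre_cue_rt`, `post_cue_rt`,
#'   `normalization_mode`.
#' @export
normalize_rts <- function(ldt, mode = c("noncued_itis", "all_itis")) {
  mode <- match.arg(mode)
  .check_ldt(ldt)
  d <- tibble::as_tibble(ldt)
  d$.iti_rt <- .iti_mean_rt(d$arrow_rts_ms)
  d$.has_cue <- !is.na(d$cue_object_id) & d$cue_object_id != ""

  counts <- dplyr::count(d[d$.has_cue, ], participant_id, cue_object_id)
  if (any(counts$n != 3)) {
    bad <- counts[counts$n != 3, ]
    stop("cued object(s) without exactly 3 re-exposures: ",
         paste(unique(bad$cue_object_id), collapse = ", "))
  }

  refs <- dplyr::summarise(
    dplyr::group_by(d, participant_id),
    ref_iti = if (mode == "noncued_itis") {
      mean(.iti_rt[!.has_cue], na.rm = TRUE)
    } else {
      mean(.iti_rt, na.rm = TRUE)
    },
    ref_lex = if (mode == "noncued_itis") {
      mean(lexical_rt_ms[!.has_cue], na.rm = TRUE)
    } else {
      mean(lexical_rt_ms, na.rm = TRUE)
    },
    .groups = "drop")

  cues <- dplyr::summarise(
    dplyr::group_by(d[d$.has_cue, ], participant_id,
                    object_id = cue_object_id),
    pre_raw = mean(.iti_rt, na.rm = TRUE),
    post_raw = mean(lexical_rt_ms, na.rm = TRUE),
    .groups = "drop")
  out <- dplyr::left_join(cues, refs, by = "participant_id")
  tibble::tibble(
    participant_id = out$participant_id,
    object_id = out$object_id,
    pre_cue_rt = out$pre_raw - out$ref_iti,
    post_cue_rt = out$post_raw - out$ref_lex,
    normalization_mode = mode)
}

#' Per-association cueing benefit
#'
#' The benefit for each cued association is that participant's mean
#' memory-stability error over all uncued associations minus the cued
#' association's own stability error, so positive values mean cueing reduced
#' error. Stability error is the distance between delayed and immediate
#' placement, averaged over the two delayed rounds by default.
#'
#' @param trials Trial table including `cue_status`.
#' @param rounds Which delayed rounds to average over (default `c(1, 2)`).
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cued association: `participant_id`,
#'   `object_id`, `stability_px`, `benefit_px`.
#' @export
cueing_benefit <- function(trials, rounds = c(1, 2), grid = grid_spec()) {
  stopifnot(all(rounds %in% c(1, 2)), length(rounds) >= 1)
  e <- spatial_errors(trials, grid)
  cols <- paste0("delayed", rounds, "_remembered_px")
  e$stability_px <- rowMeans(e[, cols, drop = FALSE])
  uncued_means <- dplyr::summarise(
    dplyr::group_by(e[e$cue_status == "uncued", ], participant_id),
    uncued_mean_px = mean(stability_px), .groups = "drop")
  cued <- e[e$cue_status == "cued",
            c("participant_id", "object_id", "stability_px")]
  out <- dplyr::left_join(cued, uncued_means, by = "participant_id")
  out$benefit_px <- out$uncued_mean_px - out$stability_px
  dplyr::select(out, participant_id, object_id, stability_px, benefit_px)
}

#' Item-level table for the vigilance-benefit analyses
#'
#' Joins [normalize_rts()] and [cueing_benefit()] into the one-row-per-cued-
#' association table consumed by the robust regression and permutation test.
#'
#' @param trials Trial table.
#' @param ldt LDT session table.
#' @param mode Normalisation mode for [normalize_rts()].
#' @param grid A [grid_spec()].
#' @return A tibble: `participant_id`, `object_id`, `pre_cue_rt`,
#'   `post_cue_rt`, `stability_px`, `benefit_px`.
#' @export
item_level_table <- function(trials, ldt, mode = "noncued_itis",
                             grid = grid_spec()) {
  dplyr::inner_join(normalize_rts(ldt, mode), cueing_benefit(trials, grid = grid),
                    by = c("participant_id", "object_id"))
}

#' Post-cue vs no-cue lexical RT contrast
#'
#' Compares each participant's mean lexical-decision RT on trials preceded
#' by an object re-exposure against trials without one, with a paired
#' t-test.
#'
#' @param ldt LDT session table.
#' @return A list: `per_participant` (tibble of per-participant means) and
#'   `test` (paired [paired_t()] of cue-trial minus no-cue-trial RTs).
#' @export
post_cue_rt_contrast <- function(ldt) {
  .check_ldt(ldt)
  d <- tibble::as_tibble(ldt)
  d$.has_cue <- !is.na(d$cue_object_id) & d$cue_object_id != ""
  per <- dplyr::summarise(
    dplyr::group_by(d, participant_id),
    rt_post_cue = mean(lexical_rt_ms[.has_cue], na.rm = TRUE),
    rt_no_cue = mean(lexical_rt_ms[!.has_cue], na.rm = TRUE),
    .groups = "drop")
  list(per_participant = per,
       test = paired_t(per$rt_post_cue, per$rt_no_cue))
}
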
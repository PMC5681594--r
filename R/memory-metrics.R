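#' Euclidean distance between placements
#'
#' Vectorised planar distance, the elementary spatial-error measure: how far
#' a placed location lies from a reference (studied or remembered) location.
#'
#' @param x1,y1 Coordinates of the first set of points (px).
#' @param x2,y2 Coordinates of the second set of points (px).
#' @return Non-negative numeric vector of distances in pixels.
#' @examples
#' euclidean_error(0, 0, 3, 4) # 5
#' @export
euclidean_error <- function(x1, y1, x2, y2) {
  stopifnot(all(is.finite(c(x1, y1, x2, y2))))
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Per-trial spatial errors and stability measures
#'
#' Expands a trial table into every distance the analysis pipeline consumes:
#' immediate-test error (placement vs. studied location), delayed errors on
#' each testing round relative to both anchors (the *studied* location and
#' the *remembered* location, i.e. the immediate-test placement), and the
#' across-round stability distance between the two delayed placements.
#'
#' @param trials A data frame with one row per (participant, object) holding
#'   columns `participant_id`, `object_id`, `studied_x/y`, `immediate_x/y`,
#'   `delayed1_x/y`, `delayed2_x/y` and (optionally) `cue_status`,
#'   `n_training_rounds`, `rating`.
#' @param grid A [grid_spec()]; used to add centimetre versions of each error.
#' @return A tibble with one row per trial and columns `immediate_error_px`,
#'   `delayed1_studied_px`, `delayed1_remembered_px`, `delayed2_studied_px`,
#'   `delayed2_remembered_px`, `across_round_px`, plus `_cm` twins, appended
#'   to the identifying columns of `trials`.
#' @export
spatial_errors <- function(trials, grid = grid_spec()) {
  needed <- c("participant_id", "object_id",
              "studied_x", "studied_y", "immediate_x", "immediate_y",
              "delayed1_x", "delayed1_y", "delayed2_x", "delayed2_y")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c("participant_id", "object_id", "cue_status",
                      "n_training_rounds", "rating"), names(trials))
  out <- dplyr::mutate(
    tibble::as_tibble(trials[, keep]),
    immediate_error_px = euclidean_error(trials$immediate_x, trials$immediate_y,
                                         trials$studied_x, trials$studied_y),
    delayed1_studied_px = euclidean_error(trials$delayed1_x, trials$delayed1_y,
                                          trials$studied_x, trials$studied_y),
    delayed1_remembered_px = euclidean_error(trials$delayed1_x, trials$delayed1_y,
                                             trials$immediate_x, trials$immediate_y),
    delayed2_studied_px = euclidean_error(trials$delayed2_x, trials$delayed2_y,
                                          trials$studied_x, trials$studied_y),
    delayed2_remembered_px = euclidean_error(trials$delayed2_x, trials$delayed2_y,
                                             trials$immediate_x, trials$immediate_y),
    across_round_px = euclidean_error(trials$delayed1_x, trials$delayed1_y,
                                      trials$delayed2_x, trials$delayed2_y)
  )
  px_cols <- grep("_px$", names(out), value = TRUE)
  for (col in px_cols) {
    out[[sub("_px$", "_cm", col)]] <- px_to_cm(out[[col]], grid)
  }
  out
}

#' Long error table
#'
#' Reshapes [spatial_errors()] output into one row per
#' (participant, object, round, anchor_mode), the layout used for CSV export
#' and for the repeated-measures models.
#'
#' @inheritParams spatial_errors
#' @return A tibble with columns `participant_id`, `object_id`, `cue_status`
#'   (if present), `round` (1 or 2), `anchor_mode` ("studied"/"remembered"),
#'   `error_px`, `error_cm`.
#' @export
error_table <- function(trials, grid = grid_spec()) {
  wide <- spatial_errors(trials, grid)
  id_cols <- intersect(c("participant_id", "object_id", "cue_status"), names(wide))
  long <- tidyr::pivot_longer(
    wide[, c(id_cols, "delayed1_studied_px", "delayed1_remembered_px",
             "delayed2_studied_px", "delayed2_remembered_px")],
    cols = dplyr::starts_with("delayed"),
    names_to = c("round", "anchor_mode"),
    names_pattern = "delayed([12])_(studied|remembered)_px",
    values_to = "error_px"
  )
  long$round <- as.integer(long$round)
  long$error_cm <- px_to_cm(long$error_px, grid)
  long
}

#' Fraction of delayed placements closer to the remembered anchor
#'
#' For each delayed placement (both testing rounds), compares its distance to
#' the remembered location (immediate-test placement) against its distance to
#' the studied location, and returns the proportion of trials strictly closer
#' to the remembered one. Exact ties count as not-closer.
#'
#' @inheritParams spatial_errors
#' @return A single proportion in \[0, 1\].
#' @export
fraction_closer_to_remembered <- function(trials, grid = grid_spec()) {
  stopifnot(nrow(trials) >= 1)
  e <- spatial_errors(trials, grid)
  closer <- c(e$delayed1_remembered_px < e$delayed1_studied_px,
              e$delayed2_remembered_px < e$delayed2_studied_px)
  mean(closer)
}

#' Flag high-error trials
#'
#' Returns the indices of errors lying strictly more than `k_sd` standard
#' deviations *above* the mean (one-sided; SD uses the n-1 denominator).
#' Used to identify poorly learned associations on the immediate test before
#' cue assignment.
#'
#' @param errors Numeric vector of spatial errors (px), length >= 3.
#' @param k_sd Threshold in SD units (default 2).
#' @return Integer vector of flagged indices (possibly empty).
#' @export
flag_high_error_trials <- function(errors, k_sd = 2) {
  stopifnot(is.numeric(errors), length(errors) >= 3, all(is.finite(errors)))
  which(errors > mean(errors) + k_sd * stats::sd(errors))
}
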
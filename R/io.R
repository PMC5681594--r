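# CSV and JSON interchange. Schemas (comma-separated, UTF-8, header row,
# "." decimal; pixel coordinates are 0-based with the origin at the top-left,
# x rightward and y downward):
#   trials.csv  participant_id, object_id, studied_x, studied_y,
#               immediate_x, immediate_y, delayed1_x, delayed1_y,
#               delayed2_x, delayed2_y, n_training_rounds, cue_status, rating
#   ldt.csv     participant_id, trial_index, iti_duration_s,
#               arrow_rts_ms (semicolon-joined), lexical_rt_ms, is_word,
#               cue_object_id (empty if none)
#   ratings.csv participant_id, object_id, rating, cue_status

#' Write a simulated experiment to a directory of CSV files
#'
#' Writes `trials.csv`, `ldt.csv` and `ratings.csv` (schemas above) plus the
#' generating configuration, seed included, as `config.json`.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "wakecue_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(experiment$trials, file.path(dir, "trials.csv"))
  ldt <- experiment$ldt
  ldt$arrow_rts_ms <- vapply(ldt$arrow_rts_ms,
                             function(v) paste(format(v, digits = 15, trim = TRUE),
                                               collapse = ";"),
                             character(1))
  readr::write_csv(ldt, file.path(dir, "ldt.csv"))
  readr::write_csv(experiment$ratings, file.path(dir, "ratings.csv"))
  cfg <- experiment$config
  cfg$grid <- unclass(cfg$grid)
  jsonlite::write_json(c(unclass(cfg), list(master_seed = experiment$seed)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment from a directory of CSV files
#'
#' Inverse of [write_experiment()]; also accepts user-supplied data in the
#' same schemas (the `truth` table and config are optional). Basic schema
#' validation is performed and violations are reported per table.
#'
#' @param dir Directory containing `trials.csv`, `ldt.csv` and
#'   `ratings.csv`.
#' @return A `wakecue_experiment` list (with `truth = NULL` and `config`
#'   read from `config.json` when present).
#' @export
read_experiment <- function(dir) {
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE)
  ldt <- readr::read_csv(file.path(dir, "ldt.csv"), show_col_types = FALSE,
                         col_types = readr::cols(
                           arrow_rts_ms = readr::col_character(),
                           cue_object_id = readr::col_character()))
  ratings <- readr::read_csv(file.path(dir, "ratings.csv"),
                             show_col_types = FALSE)
  ldt$arrow_rts_ms <- lapply(strsplit(ldt$arrow_rts_ms, ";", fixed = TRUE),
                             as.numeric)
  validate_experiment_tables(trials, ldt, ratings)
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path) else NULL
  structure(list(trials = trials, ldt = ldt, ratings = ratings,
                 truth = NULL, config = config,
                 seed = if (!is.null(config)) config$master_seed else NA_integer_),
            class = "wakecue_experiment")
}

#' Validate experiment tables against the pipeline schemas
#'
#' Checks column presence, that every participant in `trials` has an LDT
#' session, and the structural invariants of each session (96 trials, 24
#' cue events, 3 re-exposures per cued object). All violations are reported
#' together.
#'
#' @param trials,ldt,ratings Data frames in the schemas above.
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validate_experiment_tables <- function(trials, ldt, ratings) {
  problems <- character(0)
  t_cols <- c("participant_id", "object_id", "studied_x", "studied_y",
              "immediate_x", "immediate_y", "delayed1_x", "delayed1_y",
              "delayed2_x", "delayed2_y", "n_training_rounds", "cue_status")
  miss <- setdiff(t_cols, names(trials))
  if (length(miss)) problems <- c(problems,
    paste0("trials: missing columns ", paste(miss, collapse = ", ")))
  l_cols <- c("participant_id", "trial_index", "iti_duration_s",
              "arrow_rts_ms", "lexical_rt_ms", "is_word", "cue_object_id")
  miss <- setdiff(l_cols, names(ldt))
  if (length(miss)) problems <- c(problems,
    paste0("ldt: missing columns ", paste(miss, collapse = ", ")))
  if (length(problems) == 0) {
    no_ldt <- setdiff(unique(trials$participant_id), unique(ldt$participant_id))
    if (length(no_ldt)) problems <- c(problems,
      paste0("participants without an LDT session: ",
             paste(no_ldt, collapse = ", ")))
    for (pid in intersect(unique(trials$participant_id),
                          unique(ldt$participant_id))) {
      s <- ldt[ldt$participant_id == pid, ]
      n_cue <- sum(!is.na(s$cue_object_id) & s$cue_object_id != "")
      if (nrow(s) != 96) problems <- c(problems,
        paste0(pid, ": LDT has ", nrow(s), " trials, expected 96"))
      if (n_cue != 24) problems <- c(problems,
        paste0(pid, ": LDT has ", n_cue, " cue events, expected 24"))
    }
    if (any(trials$n_training_rounds < 2)) problems <- c(problems,
      "trials: n_training_rounds below the minimum of 2")
  }
  if (length(problems) > 0) {
    stop("experiment validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Write an analysis report bundle
#'
#' Serialises a [run_full_analysis()] result: one JSON file of headline
#' statistics (`report.json`), per-table CSVs, and the run manifest
#' (`manifest.json`: config snapshot, seeds and package version, from which
#' the run is fully reproducible).
#'
#' @param report A `wakecue_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "wakecue_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$errors, file.path(dir, "errors.csv"))
  readr::write_csv(report$item_level, file.path(dir, "item_level.csv"))
  invisible(dir)
}
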
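# Pre-cueing assignment: flag poorly learned associations, then split the
# remaining 16 into cued/uncued sets of 8 with matched immediate-test error.

# Cached 8-of-16 index matrix (8 x 12870 including complements handled via
# the 6435 unordered splits that contain object 1).
.partition_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- utils::combn(16L, 8L)
    }
    cache
  }
})

#' Select associations to flag as neither cued nor uncued
#'
#' Implements the outlier-flagging step of the assignment procedure: all
#' associations whose immediate-test error exceeds mean + 2 SD are flagged;
#' if more than `n_flag` qualify the `n_flag` largest errors are kept, and if
#' fewer qualify the set is filled up to `n_flag` by a seeded uniform draw
#' from the unflagged associations.
#'
#' @param errors Named numeric vector of immediate-test errors (px), one per
#'   object; names are object ids.
#' @param n_flag Number of objects to flag (default 2).
#' @param k_sd Outlier threshold in SD units (default 2).
#' @param seed Integer seed for the random fill (only used when fewer than
#'   `n_flag` outliers exist).
#' @return Character vector of `n_flag` flagged object ids.
#' @export
select_flagged <- function(errors, n_flag = 2L, k_sd = 2, seed = 1L) {
  stopifnot(is.numeric(errors), !is.null(names(errors)),
            n_flag < length(errors), length(errors) >= 3)
  out_idx <- flag_high_error_trials(errors, k_sd = k_sd)
  if (length(out_idx) >= n_flag) {
    ord <- out_idx[order(errors[out_idx], decreasing = TRUE)]
    return(names(errors)[ord[seq_len(n_flag)]])
  }
  flagged <- names(errors)[out_idx]
  pool <- setdiff(names(errors), flagged)
  extra <- withr::with_seed(seed, sample(pool, n_flag - length(flagged)))
  c(flagged, extra)
}

#' Balanced cued/uncued partition of 16 associations
#'
#' Exhaustively enumerates all 6,435 unordered 8-vs-8 splits of the 16
#' non-flagged associations and returns one minimising the absolute
#' difference in mean immediate-test error between the two halves. Ties are
#' broken by the lexicographically smallest index set of the half containing
#' the first object. Which half is labelled "cued" is decided by a seeded
#' coin flip (the means are matched, so the label is arbitrary); set
#' `deterministic_side = TRUE` to always label the half containing the first
#' object as cued.
#'
#' @param errors Named numeric vector of exactly 16 immediate-test errors.
#' @param seed Integer seed for the cued-side coin flip.
#' @param deterministic_side If `TRUE`, skip the coin flip.
#' @return A list of class `wakecue_assignment` with elements `cued`,
#'   `uncued` (character vectors of 8 object ids), `achieved_abs_mean_diff`
#'   (px) and `n_partitions_searched`.
#' @export
balanced_partition <- function(errors, seed = 1L, deterministic_side = FALSE) {
  if (length(errors) != 16L) {
    stop("balanced_partition() requires exactly 16 errors, got ", length(errors))
  }
  stopifnot(is.numeric(errors), !is.null(names(errors)), all(is.finite(errors)))
  cmb <- .partition_matrix()
  # unordered splits: keep only halves containing index 1
  keep <- cmb[1, ] == 1L
  halves <- cmb[, keep, drop = FALSE]
  half_means <- colMeans(matrix(errors[halves], nrow = 8L))
  total_mean <- mean(errors)
  # complement mean = (16*total - 8*half)/8
  diffs <- abs(half_means - (2 * total_mean - half_means))
  # combn() columns are lexicographically ordered, so the first minimiser is
  # the lexicographically smallest tied index set
  best <- which(diffs == min(diffs))[1]
  set_a <- names(errors)[halves[, best]]
  set_b <- setdiff(names(errors), set_a)
  a_is_cued <- if (deterministic_side) TRUE else {
    withr::with_seed(seed, stats::runif(1) < 0.5)
  }
  structure(
    list(
      cued = if (a_is_cued) set_a else set_b,
      uncued = if (a_is_cued) set_b else set_a,
      achieved_abs_mean_diff = diffs[best],
      n_partitions_searched = ncol(halves)
    ),
    class = "wakecue_assignment"
  )
}

#' Full pre-cueing assignment
#'
#' Runs the complete assignment procedure on one participant's immediate-test
#' errors: flag `n_flag` poorly learned associations ([select_flagged()]),
#' then split the rest into matched cued and uncued halves
#' ([balanced_partition()]).
#'
#' @param errors Named numeric vector of immediate-test errors, one per
#'   object (default design: 18 objects).
#' @param n_flag Number of associations to exclude from cueing comparisons.
#' @param seed Integer seed controlling the random fill of the flagged set
#'   and the cued-side coin flip.
#' @param deterministic_side Passed to [balanced_partition()].
#' @return A `wakecue_assignment` list with `cued`, `uncued`, `flagged`,
#'   `achieved_abs_mean_diff` and `n_partitions_searched`.
#' @examples
#' errs <- stats::setNames(stats::rgamma(18, 4, .05), paste0("obj", 1:18))
#' assign_cues(errs, seed = 7)
#' @export
assign_cues <- function(errors, n_flag = 2L, seed = 1L, deterministic_side = FALSE) {
  flagged <- select_flagged(errors, n_flag = n_flag, seed = seed)
  rest <- errors[setdiff(names(errors), flagged)]
  part <- balanced_partition(rest, seed = seed + 1L,
                             deterministic_side = deterministic_side)
  part$flagged <- flagged
  part
}

#' @export
print.wakecue_assignment <- function(x, ...) {
  cat("<wakecue_assignment>\n")
  cat("  cued:   ", paste(x$cued, collapse = " "), "\n")
  cat("  uncued: ", paste(x$uncued, collapse = " "), "\n")
  if (!is.null(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = " "), "\n")
  cat(sprintf("  |mean diff| = %.4g px over %d partitions\n",
              x$achieved_abs_mean_diff, x$n_partitions_searched))
  invisible(x)
}
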
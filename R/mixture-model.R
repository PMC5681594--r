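# Two-parameter mixture model of 2D placement: with probability p the
# placement is an isotropic bivariate Gaussian around its anchor (SD sigma),
# otherwise it is uniform over the screen. Fitted by constrained maximum
# likelihood (p in [0,1], sigma in [1,800] px).

.SIGMA_LO <- 1
.SIGMA_HI <- 800

# isotropic bivariate normal density at squared radius r2
.gauss2d_density <- function(r2, sigma_px) {
  exp(-r2 / (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
}

.check_mixture_data <- function(data) {
  needed <- c("anchor_x", "anchor_y", "x", "y")
  if (!all(needed %in% names(data))) {
    stop("mixture data needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(data) < 1) stop("mixture data has no trials")
  invisible(data)
}

#' Negative log-likelihood of the spatial mixture model
#'
#' Per-trial likelihood is
#' `p * N2(placement; anchor, sigma^2 I) + (1 - p) * g`, where `g` is the
#' uniform [guessing_density()] of the grid; the NLL is minus the sum of log
#' likelihoods. Per-trial likelihoods are floored at 1e-300 before the log so
#' the boundary `p = 1` cannot produce -Inf through tail underflow.
#'
#' @param p_success Mixing weight of the memory component, in \[0, 1\].
#' @param sigma_px SD of the isotropic Gaussian memory component, in
#'   \[1, 800\] px.
#' @param data Data frame with columns `anchor_x`, `anchor_y`, `x`, `y`
#'   (one row per trial).
#' @param grid A [grid_spec()].
#' @return The negative log-likelihood (finite scalar).
#' @export
mixture_nll <- function(p_success, sigma_px, data, grid = grid_spec()) {
  stopifnot(p_success >= 0, p_success <= 1,
            sigma_px >= .SIGMA_LO, sigma_px <= .SIGMA_HI)
  .check_mixture_data(data)
  r2 <- (data$x - data$anchor_x)^2 + (data$y - data$anchor_y)^2
  lik <- p_success * .gauss2d_density(r2, sigma_px) +
    (1 - p_success) * guessing_density(grid)
  -sum(log(pmax(lik, 1e-300)))
}

#' Fit the spatial mixture model by constrained maximum likelihood
#'
#' Minimises [mixture_nll()] over the box `p in [0,1]`, `sigma in [1,800]` px
#' with `L-BFGS-B`, restarting from a small grid of starting values
#' (p in \{0.5, 0.9, 0.99\} crossed with sigma in \{30, 80, 200\} px;
#' the first `n_starts` of a fixed rotation through that grid) and keeping
#' the best converged solution.
#'
#' @param data Data frame of trials with columns `anchor_x`, `anchor_y`,
#'   `x`, `y`; at least 2 rows.
#' @param grid A [grid_spec()].
#' @param anchor_mode Label recorded with the fit ("studied" or
#'   "remembered"); does not change the computation, which always uses the
#'   `anchor_*` columns supplied.
#' @param n_starts Number of multi-start optimisations (1-9, default 5).
#' @return A list of class `wakecue_mixture_fit` with `p_success`,
#'   `sigma_px`, `nll`, `anchor_mode`, `n_trials`, `n_starts`, `converged`.
#' @examples
#' samp <- simulate_mixture_sample(0.9, 60, n = 500, seed = 1)
#' fit_mixture(samp)
#' @export
fit_mixture <- function(data, grid = grid_spec(),
                        anchor_mode = c("remembered", "studied"),
                        n_starts = 5L) {
  anchor_mode <- match.arg(anchor_mode)
  .check_mixture_data(data)
  if (nrow(data) < 2) stop("fit_mixture() needs at least 2 trials")
  stopifnot(n_starts >= 1, n_starts <= 9)

  r2 <- (data$x - data$anchor_x)^2 + (data$y - data$anchor_y)^2
  g <- guessing_density(grid)
  nll_fun <- function(par) {
    lik <- par[1] * .gauss2d_density(r2, par[2]) + (1 - par[1]) * g
    -sum(log(pmax(lik, 1e-300)))
  }

  starts <- expand.grid(p = c(0.9, 0.5, 0.99), sigma = c(80, 30, 200))
  starts <- starts[seq_len(n_starts), , drop = FALSE]

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(c(starts$p[i], starts$sigma[i]), nll_fun,
                   method = "L-BFGS-B",
                   lower = c(0, .SIGMA_LO), upper = c(1, .SIGMA_HI),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    converged <- res$convergence == 0
    any_converged <- any_converged || converged
    if (is.null(best) || res$value < best$value ||
        (converged && !best$converged && res$value <= best$value + 1e-9)) {
      best <- res
      best$converged <- converged
    }
  }
  if (is.null(best)) stop("all mixture fits failed")

  structure(
    list(p_success = best$par[1], sigma_px = best$par[2], nll = best$value,
         anchor_mode = anchor_mode, n_trials = nrow(data),
         n_starts = as.integer(n_starts), converged = any_converged,
         grid = grid),
    class = "wakecue_mixture_fit"
  )
}

#' @export
print.wakecue_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<wakecue_mixture_fit> p = %.3f, sigma = %.1f px (anchor: %s, n = %d, NLL = %.2f%s)\n",
    x$p_success, x$sigma_px, x$anchor_mode, x$n_trials, x$nll,
    if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy wakecue_mixture_fit
#' @export
tidy.wakecue_mixture_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p_success", "sigma_px"),
    estimate = c(x$p_success, x$sigma_px)
  )
}

#' @method glance wakecue_mixture_fit
#' @export
glance.wakecue_mixture_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, n_trials = x$n_trials,
                 anchor_mode = x$anchor_mode, converged = x$converged,
                 n_starts = x$n_starts)
}

#' Classify trials as memory success or guess
#'
#' A trial counts as a memory success when the fitted Gaussian component
#' density at its placement exceeds the uniform guessing density (raw
#' component densities, unweighted by the mixing proportion; set
#' `weighted = TRUE` to compare mixture-weighted posteriors instead). The
#' unweighted rule is equivalent to a radial cutoff at
#' `sigma * sqrt(-2 * log(2 * pi * sigma^2 * g))` pixels from the anchor.
#'
#' @param fit A converged [fit_mixture()] result.
#' @param data Trials to classify (columns `anchor_x`, `anchor_y`, `x`, `y`).
#' @param grid A [grid_spec()].
#' @param weighted Compare `p * gauss` vs `(1 - p) * g` instead of the raw
#'   densities (default `FALSE`).
#' @return A tibble: the input columns plus `gaussian_density`,
#'   `guessing_density` and logical `success`.
#' @export
classify_trials <- function(fit, data, grid = grid_spec(), weighted = FALSE) {
  stopifnot(inherits(fit, "wakecue_mixture_fit"))
  if (!fit$converged) stop("refusing to classify trials with a non-converged fit")
  .check_mixture_data(data)
  r2 <- (data$x - data$anchor_x)^2 + (data$y - data$anchor_y)^2
  gd <- .gauss2d_density(r2, fit$sigma_px)
  g <- guessing_density(grid)
  success <- if (weighted) {
    fit$p_success * gd > (1 - fit$p_success) * g
  } else {
    gd > g
  }
  dplyr::mutate(tibble::as_tibble(data),
                gaussian_density = gd,
                guessing_density = g,
                success = success)
}

#' Group-level mixture fit for one cueing condition
#'
#' Pools the delayed placements (both testing rounds) of all participants'
#' trials in one cueing condition and fits a single mixture model, each trial
#' keeping its own anchor. Group-level pooling is used because eight trials
#' per condition per participant are too few for stable per-participant
#' estimates of (p, sigma).
#'
#' @param trials A trial table (see [spatial_errors()] for required columns)
#'   including `cue_status`.
#' @param condition `"cued"` or `"uncued"`.
#' @param anchor_mode `"remembered"` (anchor = immediate placement) or
#'   `"studied"`.
#' @param grid A [grid_spec()].
#' @param ... Passed to [fit_mixture()].
#' @return A `wakecue_mixture_fit`.
#' @export
group_fit_by_condition <- function(trials, condition = c("cued", "uncued"),
                                   anchor_mode = c("remembered", "studied"),
                                   grid = grid_spec(), ...) {
  condition <- match.arg(condition)
  anchor_mode <- match.arg(anchor_mode)
  sub <- trials[trials$cue_status == condition, , drop = FALSE]
  if (nrow(sub) == 0) stop("no trials with cue_status == ", condition)
  fit_mixture(.delayed_long(sub, anchor_mode), grid = grid,
              anchor_mode = anchor_mode, ...)
}

# stack the two delayed rounds into one (anchor, placement) table
.delayed_long <- function(trials, anchor_mode) {
  ax <- if (anchor_mode == "studied") trials$studied_x else trials$immediate_x
  ay <- if (anchor_mode == "studied") trials$studied_y else trials$immediate_y
  tibble::tibble(
    participant_id = rep(trials$participant_id, 2L),
    object_id = rep(trials$object_id, 2L),
    round = rep(1:2, each = nrow(trials)),
    anchor_x = rep(ax, 2L), anchor_y = rep(ay, 2L),
    x = c(trials$delayed1_x, trials$delayed2_x),
    y = c(trials$delayed1_y, trials$delayed2_y)
  )
}

#' Per-participant memory success rates by condition
#'
#' Averages trial-level success labels (from [classify_trials()] applied to
#' the group-level fits) within participant, condition and testing round.
#'
#' @param trials Trial table including `cue_status`.
#' @param anchor_mode Anchor used for the group fits and classification.
#' @param grid A [grid_spec()].
#' @return A tibble with `participant_id`, `cue_status`, `round` and
#'   `success_rate` (mean of the binary labels).
#' @export
participant_success_rates <- function(trials,
                                      anchor_mode = c("remembered", "studied"),
                                      grid = grid_spec()) {
  anchor_mode <- match.arg(anchor_mode)
  out <- lapply(c("cued", "uncued"), function(cond) {
    fit <- group_fit_by_condition(trials, cond, anchor_mode, grid)
    sub <- trials[trials$cue_status == cond, , drop = FALSE]
    labs <- classify_trials(fit, .delayed_long(sub, anchor_mode), grid)
    labs$cue_status <- cond
    labs
  })
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(out), participant_id, cue_status, round),
    success_rate = mean(success), .groups = "drop"
  )
}

#' Compare per-participant precision for studied vs remembered anchors
#'
#' Fits the mixture model separately for each participant using all delayed
#' trials (both rounds), once anchored at studied locations and once at
#' remembered (immediate-test) locations, and compares the fitted Gaussian
#' SDs with a paired t-test. Smaller SD = higher precision.
#'
#' @param trials Trial table for all participants.
#' @param grid A [grid_spec()].
#' @return A list with `per_participant` (tibble of `participant_id`,
#'   `sigma_studied_px`, `sigma_remembered_px` and `_cm` twins) and `test`
#'   (the paired [paired_t()] of studied vs remembered SDs).
#' @export
compare_anchor_precision <- function(trials, grid = grid_spec()) {
  per <- dplyr::group_by(tibble::as_tibble(trials), participant_id)
  per <- dplyr::group_modify(per, function(df, key) {
    df$participant_id <- key$participant_id
    fs <- fit_mixture(.delayed_long(df, "studied"), grid, "studied")
    fr <- fit_mixture(.delayed_long(df, "remembered"), grid, "remembered")
    tibble::tibble(sigma_studied_px = fs$sigma_px,
                   sigma_remembered_px = fr$sigma_px)
  })
  per <- dplyr::ungroup(per)
  per$sigma_studied_cm <- px_to_cm(per$sigma_studied_px, grid)
  per$sigma_remembered_cm <- px_to_cm(per$sigma_remembered_px, grid)
  list(per_participant = per,
       test = paired_t(per$sigma_studied_px, per$sigma_remembered_px))
}
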
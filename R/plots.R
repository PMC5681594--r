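# ggplot2 displays for the main result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a robust regression fit
#'
#' Scatter of the raw data coloured by each point's final IRLS weight (dark
#' points contributed little to the fit), with the robust regression line.
#'
#' @param object A `wakecue_robust_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wakecue_robust_fit
#' @export
autoplot.wakecue_robust_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y,
                      weight = if (length(object$weights) == length(object$x)) {
                        object$weights
                      } else {
                        rep(1, length(object$x))
                      })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$weight)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$beta,
                         linewidth = 0.8) +
    ggplot2::scale_colour_gradient(low = "black", high = "#3366cc",
                                   limits = c(0, 1)) +
    ggplot2::labs(colour = "IRLS weight",
                  subtitle = sprintf("beta = %.2f +/- %.2f, r = %.2f, t(%d) = %.2f",
                                     object$beta, object$se_beta, object$r,
                                     object$df, object$t_stat)) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution
#'
#' Histogram of permuted slope statistics with the observed slope marked.
#'
#' @param object A `wakecue_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wakecue_permutation
#' @export
autoplot.wakecue_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null_stats),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stat, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(x = "permuted slope",
                  subtitle = sprintf("observed = %.3g, p = %.3g (%d permutations)",
                                     object$observed_stat, object$p_value,
                                     object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Cued vs uncued memory stability per participant
#'
#' Paired-dot display of per-participant mean stability error (delayed vs
#' immediate placement, averaged over rounds) for cued and uncued
#' associations, in centimetres.
#'
#' @param trials Trial table including `cue_status`.
#' @param grid A [grid_spec()].
#' @return A ggplot object.
#' @export
plot_stability_contrast <- function(trials, grid = grid_spec()) {
  e <- spatial_errors(trials, grid)
  e <- e[e$cue_status %in% c("cued", "uncued"), ]
  e$stability_cm <- (e$delayed1_remembered_cm + e$delayed2_remembered_cm) / 2
  per <- dplyr::summarise(dplyr::group_by(e, participant_id, cue_status),
                          stability_cm = mean(stability_cm), .groups = "drop")
  ggplot2::ggplot(per, ggplot2::aes(x = .data$cue_status,
                                    y = .data$stability_cm,
                                    group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "point", size = 4, colour = "red") +
    ggplot2::labs(x = NULL, y = "memory stability error (cm)") +
    ggplot2::theme_minimal()
}
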
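# Outlier-resistant regression and permutation inference for the item-level
# RT-benefit and learning-benefit relationships.

# Lean IRLS core (simple regression, bisquare weights). Returns coefficients,
# weights and convergence info; used both by the rich user-facing fit and by
# the permutation loop, where speed matters.
.irls_core <- function(x, y, tuning_c = 4.685, tol = 1e-8, max_iter = 100L) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant; slope is not identifiable")
  # fixed (unweighted) leverage of the design, used to standardise residuals
  h <- 1 / n + (x - mean(x))^2 / sxx
  adj <- sqrt(pmax(1 - h, .Machine$double.eps))

  # start from OLS
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - b0 - b1 * x
    s <- stats::median(abs(r)) / 0.6745
    if (s <= .Machine$double.eps * max(abs(y), 1)) {
      converged <- TRUE
      w <- rep(1, n)
      break
    }
    u <- r / (tuning_c * s * adj)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    sw <- sum(w)
    xbw <- sum(w * x) / sw
    ybw <- sum(w * y) / sw
    sxxw <- sum(w * (x - xbw)^2)
    if (sxxw == 0) break # all weight collapsed; keep last coefficients
    b1_new <- sum(w * (x - xbw) * (y - ybw)) / sxxw
    b0_new <- ybw - b1_new * xbw
    if (max(abs(b1_new - b1), abs(b0_new - b0)) < tol) {
      b1 <- b1_new; b0 <- b0_new
      converged <- TRUE
      break
    }
    b1 <- b1_new; b0 <- b0_new
  }
  list(b0 = b0, b1 = b1, w = w, iterations = iter, converged = converged)
}

# slope only, for permutation resampling
.irls_slope <- function(x, y, tuning_c = 4.685, tol = 1e-6, max_iter = 50L) {
  .irls_core(x, y, tuning_c = tuning_c, tol = tol, max_iter = max_iter)$b1
}

#' Robust (bisquare IRLS) simple regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights:
#' starting from the OLS fit, residuals are standardised by a robust scale
#' (`median(|r|)/0.6745`) and a leverage adjustment, down-weighted by
#' `w = (1 - u^2)^2` for `|u| < 1` (0 outside), and the weighted fit is
#' repeated until coefficients change by less than `tol`. Standard errors and
#' the t statistic come from the final weighted least-squares fit with
#' `df = n - 2`; `r` is the plain Pearson correlation of the raw data.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of predictor and response.
#' @param tuning_c Bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `wakecue_robust_fit`: `beta`, `intercept`,
#'   `se_beta`, `t_stat`, `df`, `p_value`, `r`, `weights`, `iterations`,
#'   `converged`, `n`, plus the raw `x`/`y` for plotting.
#' @examples
#' d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
#' irls_regression(d, x, y)$beta
#' @export
irls_regression <- function(data, x, y, tuning_c = 4.685, tol = 1e-8,
                            max_iter = 100L) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("robust regression needs at least 3 complete points")

  core <- .irls_core(xv, yv, tuning_c, tol, max_iter)
  if (!core$converged) {
    warning("IRLS did not converge in ", max_iter, " iterations")
  }
  w <- core$w
  n <- length(xv)
  res <- yv - core$b0 - core$b1 * xv
  sw <- sum(w)
  xbw <- sum(w * xv) / sw
  sxxw <- sum(w * (xv - xbw)^2)
  s2 <- sum(w * res^2) / (n - 2)
  se_beta <- sqrt(s2 / sxxw)
  t_stat <- core$b1 / se_beta
  df <- n - 2L
  structure(
    list(beta = core$b1, intercept = core$b0, se_beta = se_beta,
         t_stat = t_stat, df = df,
         p_value = 2 * stats::pt(-abs(t_stat), df),
         r = stats::cor(xv, yv),
         weights = w, iterations = core$iterations,
         converged = core$converged, n = n, x = xv, y = yv),
    class = "wakecue_robust_fit"
  )
}

#' @export
print.wakecue_robust_fit <- function(x, ...) {
  cat(sprintf(
    "<wakecue_robust_fit> beta = %.3f +/- %.3f (s.e.), r = %.2f, t(%d) = %.2f, p = %.3g\n",
    x$beta, x$se_beta, x$r, x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' @method tidy wakecue_robust_fit
#' @export
tidy.wakecue_robust_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$beta),
    std.error = c(NA_real_, x$se_beta),
    statistic = c(NA_real_, x$t_stat),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @method glance wakecue_robust_fit
#' @export
glance.wakecue_robust_fit <- function(x, ...) {
  tibble::tibble(r = x$r, df = x$df, n = x$n,
                 iterations = x$iterations, converged = x$converged)
}

#' Ordinary least squares after z-score outlier exclusion
#'
#' Drops points whose predictor or response lies more than `k_sd` standard
#' deviations from the full-sample mean (z computed from the full sample),
#' then fits plain OLS on the remainder.
#'
#' @inheritParams irls_regression
#' @param k_sd Exclusion threshold in SD units (default 3; `Inf` disables
#'   exclusion).
#' @return A list of class `wakecue_robust_fit` (weights are the 0/1
#'   inclusion indicator) with an extra element `n_dropped`.
#' @export
ols_with_exclusion <- function(data, x, y, k_sd = 3) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  zx <- abs(xv - mean(xv)) / stats::sd(xv)
  zy <- abs(yv - mean(yv)) / stats::sd(yv)
  keep <- zx <= k_sd & zy <= k_sd
  if (sum(keep) < 3) stop("fewer than 3 points remain after exclusion")
  fit <- stats::lm(yv[keep] ~ xv[keep])
  sm <- summary(fit)
  structure(
    list(beta = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         se_beta = sm$coefficients[2, 2],
         t_stat = sm$coefficients[2, 3],
         df = fit$df.residual,
         p_value = sm$coefficients[2, 4],
         r = stats::cor(xv[keep], yv[keep]),
         weights = as.numeric(keep), iterations = 1L, converged = TRUE,
         n = sum(keep), n_dropped = sum(!keep), x = xv, y = yv),
    class = "wakecue_robust_fit"
  )
}

#' Permutation test for a regression slope
#'
#' Shuffles the response against the predictor `n_perm` times, recomputes
#' the slope statistic (robust IRLS slope by default) for each shuffle, and
#' returns the two-sided add-one p-value
#' `(1 + #\{|b*| >= |b_obs|\}) / (1 + n_perm)`, which is never exactly zero.
#'
#' @inheritParams irls_regression
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; the permutation stream is fully reproducible.
#' @param stat `"irls"` (default) or `"ols"` slope statistic.
#' @return A list of class `wakecue_permutation` with `observed_stat`,
#'   `n_perm`, `p_value`, `seed`, `two_sided = TRUE` and the vector of
#'   permuted statistics `null_stats`.
#' @export
permutation_test_slope <- function(data, x, y, n_perm = 10000L, seed = 1L,
                                   stat = c("irls", "ols")) {
  stat <- match.arg(stat)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 5) stop("permutation test needs at least 5 complete points")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")

  slope_fun <- if (stat == "irls") {
    function(yy) .irls_slope(xv, yy)
  } else {
    xc <- xv - mean(xv)
    sxx <- sum(xc^2)
    function(yy) sum(xc * yy) / sxx
  }
  observed <- slope_fun(yv)
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) slope_fun(sample(yv)), numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (1 + n_perm)
  structure(
    list(observed_stat = observed, n_perm = as.integer(n_perm), p_value = p,
         seed = as.integer(seed), two_sided = TRUE, null_stats = null_stats),
    class = "wakecue_permutation"
  )
}

#' @export
print.wakecue_permutation <- function(x, ...) {
  cat(sprintf("<wakecue_permutation> observed = %.4g, p = %.4g (%d permutations)\n",
              x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}
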
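test_that("guessing density is the reciprocal screen area", {
  expect_equal(guessing_density(grid_spec()), 1 / (1280 * 1024))
  expect_equal(guessing_density(grid_spec()), 7.629e-7, tolerance = 1e-4)
  expect_identical(guessing_density(grid_spec(1, 1)), 1)
  expect_equal(guessing_density(grid_spec(100, 200)), 5e-5)
})

test_that("mixture NLL matches closed forms and a literal direct sum", {
  g <- grid_spec()
  # pure guessing: every trial contributes log(screen area)
  d <- tibble::tibble(anchor_x = stats::runif(7, 0, 1280),
                      anchor_y = stats::runif(7, 0, 1024),
                      x = stats::runif(7, 0, 1280),
                      y = stats::runif(7, 0, 1024))
  expect_equal(mixture_nll(0, 50, d, g), 7 * log(1280 * 1024),
               tolerance = 1e-12)

  # pure memory, single trial at the anchor: peak Gaussian density
  one <- tibble::tibble(anchor_x = 640, anchor_y = 512, x = 640, y = 512)
  expect_equal(mixture_nll(1, 10, one, g), log(2 * pi * 100),
               tolerance = 1e-12)

  # independent literal reimplementation of the sum
  withr::with_seed(13, {
    d50 <- tibble::tibble(
      anchor_x = stats::runif(50, 0, 1280), anchor_y = stats::runif(50, 0, 1024),
      x = stats::runif(50, 0, 1280), y = stats::runif(50, 0, 1024))
  })
  p <- 0.8; s <- 120
  direct <- -sum(log(
    p * stats::dnorm(d50$x, d50$anchor_x, s) *
      stats::dnorm(d50$y, d50$anchor_y, s) +
      (1 - p) / (1280 * 1024)))
  expect_equal(mixture_nll(p, s, d50, g), direct, tolerance = 1e-10)

  expect_error(mixture_nll(0.5, 50, d50[0, ], g), "no trials")
  expect_error(mixture_nll(1.2, 50, d50, g))
  expect_error(mixture_nll(0.5, 900, d50, g))
})

test_that("fitting recovers parameters and respects the box constraints", {
  samp <- simulate_mixture_sample(0.93, 45, n = 2000, seed = 202)
  fit <- fit_mixture(samp)
  expect_true(fit$converged)
  expect_lt(abs(fit$p_success - 0.93), 0.02)
  expect_lt(abs(fit$sigma_px - 45) / 45, 0.05)

  # all placements at anchors: sigma pinned to its lower bound, p to 1
  at_anchor <- tibble::tibble(anchor_x = stats::runif(200, 100, 1100),
                              anchor_y = stats::runif(200, 100, 900))
  at_anchor$x <- at_anchor$anchor_x
  at_anchor$y <- at_anchor$anchor_y
  degen <- fit_mixture(at_anchor)
  expect_equal(degen$sigma_px, 1, tolerance = 1e-6)
  expect_gt(degen$p_success, 0.99)

  # uniform placements: the memory weight collapses
  unif <- simulate_mixture_sample(0, 45, n = 3000, seed = 303)
  expect_lt(fit_mixture(unif)$p_success, 0.05)

  expect_error(fit_mixture(samp[1, ]), "at least 2")
})

test_that("fitted NLL undercuts a dense grid search", {
  for (i in 1:2) {
    samp <- simulate_mixture_sample(c(0.9, 0.6)[i], c(60, 150)[i],
                                    n = 300, seed = 400 + i)
    fit <- fit_mixture(samp)
    ps <- seq(0, 1, length.out = 101)
    sigmas <- seq(1, 800, length.out = 101)
    grid_min <- min(vapply(sigmas, function(s) {
      gd <- exp(-((samp$x - samp$anchor_x)^2 + (samp$y - samp$anchor_y)^2) /
                  (2 * s^2)) / (2 * pi * s^2)
      min(vapply(ps, function(p) {
        -sum(log(pmax(p * gd + (1 - p) / (1280 * 1024), 1e-300)))
      }, numeric(1)))
    }, numeric(1)))
    expect_lte(fit$nll, grid_min + 1e-6)
  }
})

test_that("trial classification equals the closed-form radial cutoff", {
  g <- grid_spec()
  samp <- simulate_mixture_sample(0.9, 45, n = 500, seed = 77)
  fit <- fit_mixture(samp)

  at_anchor <- tibble::tibble(anchor_x = 640, anchor_y = 512, x = 640, y = 512)
  lab <- classify_trials(fit, at_anchor, g)
  expect_true(lab$success)
  expect_equal(lab$guessing_density, 1 / (1280 * 1024))

  far <- tibble::tibble(anchor_x = 640, anchor_y = 512,
                        x = 640 + 10 * fit$sigma_px, y = 512)
  expect_false(classify_trials(fit, far, g)$success)

  # label flips exactly at r* = sigma * sqrt(-2 log(2 pi sigma^2 g))
  s <- fit$sigma_px
  r_star <- s * sqrt(-2 * log(2 * pi * s^2 * guessing_density(g)))
  withr::with_seed(5, radii <- stats::runif(1000, 0, 600))
  pts <- tibble::tibble(anchor_x = 640, anchor_y = 512,
                        x = 640 + radii, y = 512)
  labs <- classify_trials(fit, pts, g)
  direct <- exp(-radii^2 / (2 * s^2)) / (2 * pi * s^2) > guessing_density(g)
  expect_identical(labs$success, direct)
  expect_identical(labs$success, radii < r_star)

  # weighted comparison shifts the cutoff when p != 0.5
  lab_w <- classify_trials(fit, pts, g, weighted = TRUE)
  r_star_w <- s * sqrt(-2 * log(2 * pi * s^2 * guessing_density(g) *
                                  (1 - fit$p_success) / fit$p_success))
  expect_identical(lab_w$success, radii < r_star_w)
})

test_that("recovered sigma increases with the generating sigma", {
  med_sigma <- vapply(c(30, 80, 200), function(true_s) {
    stats::median(vapply(1:5, function(r) {
      fit_mixture(simulate_mixture_sample(0.9, true_s, n = 500,
                                          seed = 1000 * true_s + r))$sigma_px
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_sigma) > 0))
})

test_that("group fits pool trials per condition and success rates average labels", {
  # all delayed placements exactly at the immediate anchor: every trial is
  # a success and rates are 1 in both conditions
  tr <- make_stability_trials(rep(0, 4), rep(0, 4))
  tr2 <- dplyr::mutate(tr, participant_id = "p2")
  both <- dplyr::bind_rows(tr, tr2)
  rates <- participant_success_rates(both)
  expect_equal(nrow(rates), 2 * 2 * 2) # participants x conditions x rounds
  expect_true(all(rates$success_rate == 1))

  fitc <- group_fit_by_condition(sim_default_small()$trials, "cued")
  fitu <- group_fit_by_condition(sim_default_small()$trials, "uncued")
  expect_equal(fitc$n_trials, 10 * 8 * 2)
  expect_true(fitc$converged && fitu$converged)
  # cueing shrinks placement noise in the generator
  expect_lt(fitc$sigma_px, fitu$sigma_px)

  # cueing also raises memory-success probability: cued mean success rate
  # exceeds uncued on a large simulation
  big_rates <- participant_success_rates(sim_default_big()$trials)
  means <- tapply(big_rates$success_rate, big_rates$cue_status, mean)
  expect_gt(means[["cued"]], means[["uncued"]])
})

test_that("per-participant precision is higher for remembered anchors", {
  exp <- sim_default_small()
  cmp <- compare_anchor_precision(exp$trials)
  expect_equal(nrow(cmp$per_participant), 10)
  # the generator anchors delayed placements on the immediate placement
  expect_gt(cmp$test$t, 0)
  expect_gt(mean(cmp$per_participant$sigma_studied_px -
                   cmp$per_participant$sigma_remembered_px), 0)
})

test_that("tidy and glance summarise fits in broom style", {
  fit <- fit_mixture(simulate_mixture_sample(0.9, 50, n = 300, seed = 8))
  td <- generics::tidy(fit)
  expect_identical(td$term, c("p_success", "sigma_px"))
  gl <- generics::glance(fit)
  expect_identical(gl$n_trials, 300L)
  expect_true(gl$converged)
})
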
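# Generative simulator of the object-location cueing experiment. The
# generator owns the ground truth every downstream analysis is validated
# against: placements follow the same guessing + isotropic-Gaussian mixture
# the fitting code assumes, cueing shrinks the delayed placement noise of
# cued associations, and an ITI-level vigilance latent couples arrow-task
# RTs to the size of the cueing benefit.

#' Simulation configuration
#'
#' All generative parameters of the simulated experiment. Defaults encode
#' the task design (18 objects split 8 cued / 8 uncued / 2 flagged; a
#' 96-trial lexical-decision session with 24 cue re-exposures on a
#' 1280 x 1024 px grid) and plausible behavioural magnitudes: immediate
#' placement noise around 55 px so that mean immediate error lands near
#' 75-80 px, delayed stability noise of 45 px, a cueing-related reduction in
#' that noise of about 8 px plus couplings to participant ability and to
#' pre-cue vigilance, and a guessing rate of a few percent.
#'
#' @param n_participants Number of simulated participants.
#' @param n_objects,n_cued,n_uncued,n_flagged Design counts; must satisfy
#'   `n_cued + n_uncued + n_flagged == n_objects`.
#' @param grid A [grid_spec()].
#' @param margin_px Minimum distance of studied locations from the screen
#'   edge (object sprites span 250 px, so 125 px keeps them on screen).
#' @param min_separation_px Minimum pairwise distance between studied
#'   locations.
#' @param sigma_immediate_base Immediate placement SD (px) for an
#'   average-ability participant.
#' @param participant_ability_sd Log-scale spread of ability: participant i
#'   places with SD `sigma_immediate_base * exp(participant_ability_sd *
#'   lambda_i)`, `lambda_i ~ N(0, 1)` (higher lambda = worse).
#' @param rounds_poisson_mean,rounds_link Training rounds per association
#'   are `2 + Poisson(rounds_poisson_mean * exp(rounds_link * lambda_i))`.
#' @param sigma_delay_uncued Delayed round-1 placement SD (px) around the
#'   immediate placement for uncued associations.
#' @param cueing_benefit_base Reduction (px) of that SD for cued
#'   associations.
#' @param benefit_ability_coupling Additional SD reduction per unit of
#'   ability lambda (worse learners gain more).
#' @param vigilance_benefit_coupling Additional SD reduction per unit of the
#'   object's mean pre-cue vigilance latent (slower = less vigilant = larger
#'   benefit).
#' @param sigma_floor Lower bound (px) on the cued delayed SD.
#' @param sigma_round2 SD (px) of the drift between delayed rounds 1 and 2.
#' @param guess_prob_immediate,guess_prob_delayed Probability that a
#'   placement is a uniform guess rather than a Gaussian recall
#'   (`guess_prob_delayed` applies to uncued and flagged associations).
#' @param guess_prob_delayed_cued Delayed guessing probability for cued
#'   associations; the default is below `guess_prob_delayed`, so cueing
#'   raises the probability of memory success as well as its precision.
#' @param rt_mean_ms,rt_participant_sd_ms,rt_iti_sd_ms,rt_arrow_noise_ms
#'   Arrow-task RT model: participant baseline `N(rt_mean_ms,
#'   rt_participant_sd_ms)`, an ITI-level vigilance shift of `rt_iti_sd_ms`
#'   per latent unit, and within-ITI arrow noise.
#' @param lex_rt_mean_ms,lex_rt_sd_ms Lexical-decision RT baseline mean and
#'   trial-level SD.
#' @param post_cue_rt_inflation_ms Added lexical RT on trials preceded by a
#'   cue re-exposure.
#' @param discrimination_dprime_mean,discrimination_dprime_sd Across-
#'   participant distribution of cue-discrimination sensitivity d'.
#' @param discrimination_ability_coupling Optional shift of d' by
#'   `-coupling * lambda_i` (positive values make better learners better
#'   discriminators); 0 keeps discrimination independent of benefit.
#' @param rating_hc_offset Distance of the high-confidence criteria from the
#'   unbiased criterion d'/2, in strength-axis units.
#' @param redraw_offgrid Redraw placements that land off the grid (keeps all
#'   coordinates on screen); set `FALSE` to allow off-grid placements.
#' @param deterministic_cue_side Passed to [balanced_partition()].
#' @param seed Master seed; per-participant substream seeds are derived from
#'   it deterministically.
#' @return A validated list of class `wakecue_config`.
#' @export
sim_config <- function(n_participants = 24L,
                       n_objects = 18L, n_cued = 8L, n_uncued = 8L,
                       n_flagged = 2L,
                       grid = grid_spec(),
                       margin_px = 125,
                       min_separation_px = 100,
                       sigma_immediate_base = 55,
                       participant_ability_sd = 0.25,
                       rounds_poisson_mean = 0.55,
                       rounds_link = 0.35,
                       sigma_delay_uncued = 45,
                       cueing_benefit_base = 10,
                       benefit_ability_coupling = 4,
                       vigilance_benefit_coupling = 15,
                       sigma_floor = 5,
                       sigma_round2 = 35,
                       guess_prob_immediate = 0.02,
                       guess_prob_delayed = 0.05,
                       guess_prob_delayed_cued = 0.025,
                       rt_mean_ms = 450,
                       rt_participant_sd_ms = 60,
                       rt_iti_sd_ms = 40,
                       rt_arrow_noise_ms = 60,
                       lex_rt_mean_ms = 750,
                       lex_rt_sd_ms = 150,
                       post_cue_rt_inflation_ms = 32,
                       discrimination_dprime_mean = 1,
                       discrimination_dprime_sd = 0.8,
                       discrimination_ability_coupling = 0,
                       rating_hc_offset = 0.8,
                       redraw_offgrid = TRUE,
                       deterministic_cue_side = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$guess_prob_immediate, cfg$guess_prob_delayed,
             cfg$guess_prob_delayed_cued)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: guess probabilities must lie in [0, 1]")
  }
  sds <- c(cfg$sigma_immediate_base, cfg$sigma_delay_uncued, cfg$sigma_floor,
           cfg$rt_participant_sd_ms, cfg$rt_iti_sd_ms, cfg$rt_arrow_noise_ms,
           cfg$lex_rt_sd_ms, cfg$discrimination_dprime_sd)
  if (any(sds <= 0)) {
    stop("configuration error: all SD parameters must be > 0")
  }
  if (cfg$sigma_round2 < 0) {
    stop("configuration error: sigma_round2 must be >= 0")
  }
  if (cfg$n_cued + cfg$n_uncued + cfg$n_flagged != cfg$n_objects) {
    stop("configuration error: n_cued + n_uncued + n_flagged must equal n_objects")
  }
  if (cfg$n_participants < 1 || cfg$n_objects < 3) {
    stop("configuration error: invalid counts")
  }
  stopifnot(inherits(cfg$grid, "wakecue_grid"))
  structure(cfg, class = "wakecue_config")
}

#' @export
print.wakecue_config <- function(x, ...) {
  cat(sprintf(
    "<wakecue_config> %d participants, %d objects (%d cued / %d uncued / %d flagged), seed %d\n",
    x$n_participants, x$n_objects, x$n_cued, x$n_uncued, x$n_flagged, x$seed))
  invisible(x)
}

# uniform placement on the grid
.runif_grid <- function(n, grid) {
  cbind(stats::runif(n, 0, grid$width_px), stats::runif(n, 0, grid$height_px))
}

# Gaussian placement around anchors, optionally redrawn until on-grid
.rgauss_placement <- function(ax, ay, sd, grid, redraw) {
  n <- length(ax)
  if (length(sd) == 1) sd <- rep(sd, n)
  x <- ax + stats::rnorm(n, 0, sd)
  y <- ay + stats::rnorm(n, 0, sd)
  if (redraw) {
    for (rep in 1:200) {
      off <- x < 0 | x > grid$width_px | y < 0 | y > grid$height_px
      if (!any(off)) break
      x[off] <- ax[off] + stats::rnorm(sum(off), 0, sd[off])
      y[off] <- ay[off] + stats::rnorm(sum(off), 0, sd[off])
    }
    # pathological SDs may never land on grid; clamp the stragglers
    x <- pmin(pmax(x, 0), grid$width_px)
    y <- pmin(pmax(y, 0), grid$height_px)
  }
  cbind(x, y)
}

#' Sample from the spatial memory mixture
#'
#' Draws `n` (anchor, placement) pairs: anchors uniform on the grid, and
#' each placement Gaussian around its anchor (SD `sigma_px`) with
#' probability `p_success`, otherwise uniform over the grid. This is the
#' recovery harness for [fit_mixture()]: the sample follows exactly the
#' model the fitter assumes.
#'
#' @param p_success Memory-success probability in \[0, 1\].
#' @param sigma_px Gaussian SD in \[1, 800\] px.
#' @param n Number of trials.
#' @param grid A [grid_spec()].
#' @param seed Integer seed (draws are reproducible).
#' @param redraw_offgrid Redraw Gaussian placements landing off the grid.
#'   Default `FALSE`: the sample then follows the untruncated mixture
#'   density exactly, which is what parameter-recovery studies need;
#'   redrawing conditions the Gaussian on the screen and biases the fitted
#'   SD slightly downward.
#' @return A tibble with columns `anchor_x`, `anchor_y`, `x`, `y` and a
#'   logical `is_guess` truth column.
#' @export
simulate_mixture_sample <- function(p_success, sigma_px, n, grid = grid_spec(),
                                    seed = 1L, redraw_offgrid = FALSE) {
  if (p_success < 0 || p_success > 1) {
    stop("domain error: p_success must lie in [0, 1]")
  }
  if (sigma_px < 1 || sigma_px > 800) {
    stop("domain error: sigma_px must lie in [1, 800]")
  }
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    anchors <- .runif_grid(n, grid)
    is_guess <- stats::runif(n) >= p_success
    pl <- .rgauss_placement(anchors[, 1], anchors[, 2], sigma_px, grid,
                            redraw_offgrid)
    if (any(is_guess)) {
      pl[is_guess, ] <- .runif_grid(sum(is_guess), grid)
    }
    tibble::tibble(anchor_x = anchors[, 1], anchor_y = anchors[, 2],
                   x = pl[, 1], y = pl[, 2], is_guess = is_guess)
  })
}

# studied locations: uniform within margins, minimum pairwise separation
# enforced by rejection (relaxed if the grid cannot fit the request)
.sample_studied <- function(n, grid, margin, min_sep) {
  xs <- numeric(0); ys <- numeric(0)
  sep <- min_sep
  attempts <- 0L
  while (length(xs) < n) {
    x <- stats::runif(1, margin, grid$width_px - margin)
    y <- stats::runif(1, margin, grid$height_px - margin)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    attempts <- attempts + 1L
    if (attempts > 5000L) { # unsatisfiable separation; relax
      sep <- sep * 0.8
      attempts <- 0L
    }
  }
  cbind(xs, ys)
}

# LDT structure for one participant: 96 trials in 3 thirds of 32; per third
# 8 trials of each ITI duration, 2 cue trials per duration (8 cue trials per
# third, one per cued object), cue trials split 4 word / 4 pseudo-word and
# each third split 16/16 overall
.build_ldt_structure <- function(cued_objects) {
  stopifnot(length(cued_objects) == 8)
  durations <- integer(0); has_cue <- logical(0)
  cue_obj <- character(0); is_word <- logical(0)
  for (third in 1:3) {
    dur <- sample(rep(c(10L, 12L, 14L, 16L), each = 8L))
    cue_here <- logical(32)
    for (d in c(10L, 12L, 14L, 16L)) {
      cue_here[sample(which(dur == d), 2L)] <- TRUE
    }
    obj <- rep(NA_character_, 32)
    obj[cue_here] <- sample(cued_objects)
    w <- logical(32)
    w[sample(which(cue_here), 4L)] <- TRUE
    w[sample(which(!cue_here), 12L)] <- TRUE
    durations <- c(durations, dur); has_cue <- c(has_cue, cue_here)
    cue_obj <- c(cue_obj, obj); is_word <- c(is_word, w)
  }
  tibble::tibble(trial_index = 1:96, iti_duration_s = durations,
                 is_word = is_word, cue_object_id = cue_obj)
}

# one participant's full session; RNG state is the caller's responsibility
.simulate_participant <- function(pid, cfg) {
  grid <- cfg$grid
  obj_ids <- sprintf("o%02d", seq_len(cfg$n_objects))

  lambda <- stats::rnorm(1)
  sigma_imm <- cfg$sigma_immediate_base * exp(cfg$participant_ability_sd * lambda)

  studied <- .sample_studied(cfg$n_objects, grid, cfg$margin_px,
                             cfg$min_separation_px)

  imm_guess <- stats::runif(cfg$n_objects) < cfg$guess_prob_immediate
  imm <- .rgauss_placement(studied[, 1], studied[, 2], sigma_imm, grid,
                           cfg$redraw_offgrid)
  if (any(imm_guess)) imm[imm_guess, ] <- .runif_grid(sum(imm_guess), grid)

  rounds <- 2L + stats::rpois(cfg$n_objects,
                              cfg$rounds_poisson_mean * exp(cfg$rounds_link * lambda))

  imm_err <- stats::setNames(
    euclidean_error(imm[, 1], imm[, 2], studied[, 1], studied[, 2]), obj_ids)
  assign_seed <- sample.int(2147483646L, 1L)
  assignment <- assign_cues(imm_err, n_flag = cfg$n_flagged, seed = assign_seed,
                            deterministic_side = cfg$deterministic_cue_side)
  cue_status <- rep("flagged", cfg$n_objects)
  cue_status[obj_ids %in% assignment$cued] <- "cued"
  cue_status[obj_ids %in% assignment$uncued] <- "uncued"

  # --- LDT session -----------------------------------------------------
  ldt <- .build_ldt_structure(assignment$cued)
  rt_base <- stats::rnorm(1, cfg$rt_mean_ms, cfg$rt_participant_sd_ms)
  lex_base <- stats::rnorm(1, cfg$lex_rt_mean_ms, cfg$rt_participant_sd_ms)
  vig <- stats::rnorm(96) # ITI-level vigilance latent, unit SD
  n_arrows <- ldt$iti_duration_s %/% 2L
  ldt$arrow_rts_ms <- lapply(1:96, function(j) {
    pmax(100, rt_base + cfg$rt_iti_sd_ms * vig[j] +
           stats::rnorm(n_arrows[j], 0, cfg$rt_arrow_noise_ms))
  })
  ldt$lexical_rt_ms <- pmax(
    200,
    lex_base + stats::rnorm(96, 0, cfg$lex_rt_sd_ms) +
      ifelse(is.na(ldt$cue_object_id), 0, cfg$post_cue_rt_inflation_ms))
  ldt$participant_id <- pid

  # mean vigilance latent over each cued object's three pre-cue ITIs
  vbar <- vapply(obj_ids, function(o) {
    idx <- which(!is.na(ldt$cue_object_id) & ldt$cue_object_id == o)
    if (length(idx) == 0) 0 else mean(vig[idx])
  }, numeric(1))

  # --- delayed placements ---------------------------------------------
  sd_delay <- ifelse(
    cue_status == "cued",
    pmax(cfg$sigma_floor,
         cfg$sigma_delay_uncued -
           (cfg$cueing_benefit_base +
              cfg$benefit_ability_coupling * lambda +
              cfg$vigilance_benefit_coupling * vbar)),
    cfg$sigma_delay_uncued)
  guess_p <- ifelse(cue_status == "cued", cfg$guess_prob_delayed_cued,
                    cfg$guess_prob_delayed)
  del_guess <- stats::runif(cfg$n_objects) < guess_p
  d1 <- .rgauss_placement(imm[, 1], imm[, 2], sd_delay, grid, cfg$redraw_offgrid)
  if (any(del_guess)) d1[del_guess, ] <- .runif_grid(sum(del_guess), grid)
  d2 <- if (cfg$sigma_round2 > 0) {
    .rgauss_placement(d1[, 1], d1[, 2], cfg$sigma_round2, grid, cfg$redraw_offgrid)
  } else {
    d1
  }

  # --- cue discrimination ratings -------------------------------------
  dprime <- stats::rnorm(1, cfg$discrimination_dprime_mean,
                         cfg$discrimination_dprime_sd) -
    cfg$discrimination_ability_coupling * lambda
  strength <- stats::rnorm(cfg$n_objects, ifelse(cue_status == "cued", dprime, 0), 1)
  mid <- dprime / 2
  rating <- cut(strength,
                breaks = c(-Inf, mid - cfg$rating_hc_offset, mid,
                           mid + cfg$rating_hc_offset, Inf),
                labels = c("HC_uncued", "LC_uncued", "LC_cued", "HC_cued"))

  trials <- tibble::tibble(
    participant_id = pid, object_id = obj_ids,
    studied_x = studied[, 1], studied_y = studied[, 2],
    immediate_x = imm[, 1], immediate_y = imm[, 2],
    delayed1_x = d1[, 1], delayed1_y = d1[, 2],
    delayed2_x = d2[, 1], delayed2_y = d2[, 2],
    n_training_rounds = rounds, cue_status = cue_status,
    rating = as.character(rating))

  list(
    trials = trials,
    ldt = ldt[, c("participant_id", "trial_index", "iti_duration_s",
                  "arrow_rts_ms", "lexical_rt_ms", "is_word", "cue_object_id")],
    ratings = tibble::tibble(participant_id = pid, object_id = obj_ids,
                             rating = as.character(rating),
                             cue_status = cue_status),
    truth = tibble::tibble(participant_id = pid, ability = lambda,
                           sigma_immediate_px = sigma_imm,
                           dprime = dprime, rt_base_ms = rt_base)
  )
}

#' Simulate a complete cueing experiment
#'
#' Generates every measurement the analysis pipeline consumes, for
#' `config$n_participants` participants: studied locations, immediate and
#' two delayed placements per object, training rounds to criterion, the
#' cued/uncued/flagged assignment (produced by running [assign_cues()] on
#' the simulated immediate errors), the 96-trial lexical-decision session
#' with 24 cue re-exposures and arrow-task RTs, and cue-discrimination
#' ratings. The dataset is bit-reproducible from `(config, seed)`:
#' per-participant substream seeds are drawn once from the master seed.
#'
#' @param config A [sim_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return A list of class `wakecue_experiment` with tibbles `trials`,
#'   `ldt`, `ratings`, `truth` (generative latents, for validation) and the
#'   `config` used.
#' @examples
#' exp <- simulate_experiment(sim_config(n_participants = 3, seed = 42))
#' dplyr::count(exp$trials, cue_status)
#' @export
simulate_experiment <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "wakecue_config"))
  part_seeds <- withr::with_seed(seed,
                                 sample.int(2147483646L, config$n_participants))
  pids <- sprintf("p%03d", seq_len(config$n_participants))
  parts <- lapply(seq_along(pids), function(i) {
    withr::with_seed(part_seeds[i], .simulate_participant(pids[i], config))
  })
  out <- list(
    trials = dplyr::bind_rows(lapply(parts, `[[`, "trials")),
    ldt = dplyr::bind_rows(lapply(parts, `[[`, "ldt")),
    ratings = dplyr::bind_rows(lapply(parts, `[[`, "ratings")),
    truth = dplyr::bind_rows(lapply(parts, `[[`, "truth")),
    config = config,
    seed = as.integer(seed)
  )
  class(out) <- "wakecue_experiment"
  out
}

#' @export
print.wakecue_experiment <- function(x, ...) {
  cat(sprintf(
    "<wakecue_experiment> %d participants x %d objects (seed %d)\n  tables: trials (%d rows), ldt (%d rows), ratings (%d rows)\n",
    x$config$n_participants, x$config$n_objects, x$seed,
    nrow(x$trials), nrow(x$ldt), nrow(x$ratings)))
  invisible(x)
}
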
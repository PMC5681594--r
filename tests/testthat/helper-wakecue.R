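# Shared fixtures, built in code. Simulated datasets used by several test
# files are cached per session so the suite does not regenerate them.

.fixture_env <- new.env(parent = emptyenv())

cached_sim <- function(name, config) {
  if (is.null(.fixture_env[[name]])) {
    .fixture_env[[name]] <- simulate_experiment(config)
  }
  .fixture_env[[name]]
}

# default-condition simulation, large enough for the structural properties
sim_default_big <- function() {
  cached_sim("big", sim_config(n_participants = 150, seed = 1L))
}

# small default-condition simulation for smoke tests
sim_default_small <- function() {
  cached_sim("small", sim_config(n_participants = 10, seed = 7L))
}

# hand-constructed trial table: one participant, explicit coordinates
make_manual_trials <- function() {
  tibble::tibble(
    participant_id = "p1",
    object_id = sprintf("o%02d", 1:4),
    studied_x = c(100, 200, 300, 400), studied_y = c(100, 100, 100, 100),
    immediate_x = c(110, 220, 290, 400), immediate_y = c(100, 120, 100, 130),
    delayed1_x = c(112, 230, 310, 420), delayed1_y = c(102, 125, 95, 140),
    delayed2_x = c(108, 225, 305, 415), delayed2_y = c(101, 128, 97, 135),
    n_training_rounds = c(2L, 3L, 4L, 2L),
    cue_status = c("cued", "cued", "uncued", "uncued"),
    rating = c("HC_cued", "LC_uncued", "HC_uncued", "LC_cued")
  )
}

# trial table where every placement distance is controlled exactly:
# immediate at origin + offset, delayed at a chosen stability distance
make_stability_trials <- function(stability_cued, stability_uncued,
                                  participant_id = "p1") {
  n_c <- length(stability_cued)
  n_u <- length(stability_uncued)
  tibble::tibble(
    participant_id = participant_id,
    object_id = sprintf("o%02d", seq_len(n_c + n_u)),
    studied_x = 0, studied_y = 0,
    immediate_x = 500, immediate_y = 500,
    delayed1_x = 500 + c(stability_cued, stability_uncued), delayed1_y = 500,
    delayed2_x = 500 + c(stability_cued, stability_uncued), delayed2_y = 500,
    n_training_rounds = 2L,
    cue_status = rep(c("cued", "uncued"), c(n_c, n_u)),
    rating = "LC_uncued"
  )
}
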
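test_that("degenerate generator (no tuning, no noise) yields flat baselines", {
  cfg <- sim_config(n_neurons = 4, n_trials_per_orientation = 2,
                    fraction_selective = 0, null_gain_range = c(0, 0),
                    noise_sd = 0, fraction_locomodulated = 0)
  s <- generate_session(cfg, seed = 21)$session
  per_neuron_sd <- apply(s$traces, 1, sd)
  expect_equal(per_neuron_sd, rep(0, 4))
  expect_true(all(s$traces > 0))
})

test_that("same seed gives bit-identical bundles, different seeds differ", {
  cfg <- sim_config(n_neurons = 3, n_trials_per_orientation = 2)
  a <- generate_session(cfg, seed = 22)
  b <- generate_session(cfg, seed = 22)
  expect_identical(a$session, b$session)
  expect_identical(a$truth, b$truth)
  c <- generate_session(cfg, seed = 23)
  expect_false(identical(a$session$traces, c$session$traces))
  v1 <- generate_session(cfg, seed = 24, type = "vr")
  v2 <- generate_session(cfg, seed = 24, type = "vr")
  expect_identical(v1$session, v2$session)
})

test_that("generated bundles always satisfy session invariants", {
  for (seed in 31:33) {
    cfg <- sim_config(n_neurons = 3, n_trials_per_orientation = 2,
                      n_trials_vr = 5)
    expect_silent(validate_session(generate_session(cfg, seed = seed)$session))
    expect_silent(validate_session(
      generate_session(cfg, seed = seed, type = "vr",
                       day_label = "D1")$session))
  }
})

test_that("mismatched ground-truth neuron count is a hard error", {
  cfg <- sim_config(n_neurons = 4, n_trials_per_orientation = 2)
  tr <- generate_ground_truth(sim_config(n_neurons = 7))
  expect_error(generate_session(cfg, truth = tr, seed = 25), "7 neurons")
})

test_that("recovered peak magnitude grows with tuning concentration", {
  # median recovered magnitude must be nondecreasing in kappa
  med_mag <- vapply(c(0.5, 2, 8), function(k) {
    mags <- unlist(lapply(41:43, function(seed) {
      cfg <- sim_config(n_neurons = 20, n_trials_per_orientation = 8,
                        fraction_selective = 1, kappa_range = c(k, k))
      res <- generate_session(cfg, seed = seed)
      resp <- extract_trial_responses(session_dff(res$session),
                                      res$session$epochs)
      vapply(tuning_curves(resp), `[[`, numeric(1), "peak_magnitude")
    }))
    median(mags)
  }, numeric(1))
  expect_true(all(diff(med_mag) >= 0))
})

test_that("tuned sessions let the tuning stage recover preferred orientation", {
  cfg <- sim_config(n_neurons = 30, n_trials_per_orientation = 20,
                    fraction_selective = 1, kappa_range = c(8, 8))
  res <- generate_session(cfg, seed = 44)
  resp <- extract_trial_responses(session_dff(res$session),
                                  res$session$epochs)
  curves <- tuning_curves(resp)
  err <- abs(((vapply(curves, `[[`, numeric(1), "peak_angle") -
                 res$truth$neurons$pref_deg + 90) %% 180) - 90)
  expect_true(all(err < 15))
})

test_that("experiment generator plants fates and stays reproducible", {
  cfg <- sim_config(n_neurons = 40, n_trials_per_orientation = 8)
  spec <- list(fates = c(remain = 0.5, gain = 0.2, lose = 0.1,
                         nonselective = 0.2),
               repetitive_orientation = 90)
  a <- generate_experiment(cfg, spec, seed = 45)
  b <- generate_experiment(cfg, spec, seed = 45)
  expect_identical(a$experiment$sessions$pre$traces,
                   b$experiment$sessions$pre$traces)
  expect_named(a$experiment$sessions, c("pre", "post"))
  f <- a$truths$pre$neurons$fate
  expect_setequal(unique(f), c("remain", "gain", "lose", "nonselective"))
  # fates drive the truth flags
  expect_true(all(a$truths$pre$neurons$is_selective[f == "remain"]))
  expect_false(any(a$truths$post$neurons$is_selective[f == "lose"]))
  expect_true(all(a$truths$post$neurons$pref_deg[f == "gain"] == 90))
  expect_error(
    generate_experiment(cfg, list(fates = c(remain = 0.5, gain = 0.2,
                                            lose = 0.1, nonselective = 0.1))),
    "sum to 1")
})

test_that("null experiment design leaves pre and post selectivity alike", {
  cfg <- sim_config(n_neurons = 80, n_trials_per_orientation = 15)
  spec <- list(fates = c(remain = 0.75, gain = 0, lose = 0,
                         nonselective = 0.25))
  ex <- generate_experiment(cfg, spec, seed = 46)
  tabs <- lapply(ex$experiment$sessions, function(s) {
    selectivity_table(extract_trial_responses(session_dff(s), s$epochs))
  })
  thr <- attr(tabs$pre, "threshold")
  post <- selectivity_table(
    extract_trial_responses(session_dff(ex$experiment$sessions$post),
                            ex$experiment$sessions$post$epochs),
    threshold = thr)
  diff_prop <- abs(mean(post$is_selective) - mean(tabs$pre$is_selective))
  expect_lt(diff_prop, 0.1)
})

test_that("training days carry VR streams when requested", {
  cfg <- sim_config(n_neurons = 6, n_trials_per_orientation = 2,
                    n_trials_vr = 5)
  ex <- generate_experiment(
    cfg, list(fates = c(remain = 0.5, gain = 0.2, lose = 0.1,
                        nonselective = 0.2),
              include_training_days = TRUE), seed = 47)
  expect_named(ex$experiment$sessions,
               c("pre", paste0("D", 1:5), "post"))
  d1 <- ex$experiment$sessions$D1
  expect_false(is.null(d1$position))
  expect_gt(length(d1$rewards), 0)
  expect_identical(unique(na.omit(d1$epochs$orientation)), 90)
})

test_that("YAML config round-trips through read_sim_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_neurons: 7", "noise_sd: 0.02",
               "corridor:", "  corridor_length: 200",
               "  reward_zone_start: 150", "  reward_zone_end: 200"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n_neurons, 7)
  expect_equal(cfg$noise_sd, 0.02)
  expect_equal(cfg$corridor$corridor_length, 200)
  expect_equal(cfg$n_trials_vr, sim_config()$n_trials_vr)
})
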
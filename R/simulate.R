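# Synthetic-session generator.  Produces session bundles with known ground
# truth that exhibit the statistical structure the downstream stages assume:
# axial (von Mises on 2*theta) orientation tuning, exponential-kernel calcium
# dynamics on a positive raw-fluorescence baseline, two-state locomotion
# bouts, reward-locked transients, and spatially concentrated licking.

#' Simulation configuration
#'
#' Defaults emulate a single-animal chronic V1 imaging study: 4 equally
#' spaced grating orientations, 15 presentations per orientation (2 s
#' stationary + 2 s moving, 5 s gray gaps), and rewarded virtual-corridor
#' sessions of 129 trials on a 160-cm corridor with the reward zone starting
#' at 120 cm.
#'
#' @param n_neurons number of neurons.
#' @param n_trials_per_orientation grating presentations per orientation.
#' @param orientations stimulus orientations in degrees, in \[0, 180).
#' @param stationary_dur_s,moving_dur_s,gray_dur_s grating-phase and gray-gap
#'   durations (s).
#' @param fraction_selective fraction of neurons that are genuinely tuned.
#' @param kappa_range von Mises concentration range for tuned neurons
#'   (untuned neurons have kappa = 0).
#' @param gain_range peak stimulus response (dF/F0 units) for tuned neurons.
#' @param null_gain_range stimulus response range for untuned (kappa = 0)
#'   but visually responsive neurons.
#' @param noise_sd additive Gaussian trace noise, dF/F0 units.
#' @param gain_jitter_sdlog lognormal sdlog of per-presentation response gain
#'   jitter (0 disables; makes the reliability CV nontrivial).
#' @param calcium_decay_s exponential calcium-kernel decay constant (s).
#' @param sampling_rate imaging rate (Hz).
#' @param baseline_range raw-fluorescence baseline range (a.u.).
#' @param fraction_locomodulated,loco_gain_range locomotion-modulated neuron
#'   fraction and their running-related dF/F0 gain.
#' @param run_bout_mean_s,stationary_bout_mean_s mean bout durations of the
#'   two-state locomotion chain (s).
#' @param run_speed_mean,run_speed_sd running-bout speed distribution (cm/s).
#' @param fraction_reward_responsive,reward_amp_range reward-responsive
#'   neuron fraction and reward-locked transient amplitude (dF/F0 units);
#'   the transient lasts 1 s from reward onset.
#' @param n_trials_vr corridor traversals per virtual-reality session.
#' @param lick_concentration probability that a lick is placed inside the
#'   success window (remaining licks are uniform along the corridor).
#' @param licks_per_trial_mean Poisson mean lick count per trial.
#' @param kappa_threshold,gain_threshold generator thresholds above which a
#'   neuron's ground-truth `is_selective` flag is set.
#' @param corridor default [corridor_geometry()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 100L,
                       n_trials_per_orientation = 15L,
                       orientations = c(0, 45, 90, 135),
                       stationary_dur_s = 2,
                       moving_dur_s = 2,
                       gray_dur_s = 5,
                       fraction_selective = 0.75,
                       kappa_range = c(8, 8),
                       gain_range = c(0.3, 0.8),
                       null_gain_range = c(0.05, 0.3),
                       noise_sd = 0.05,
                       gain_jitter_sdlog = 0,
                       calcium_decay_s = 0.6,
                       sampling_rate = 10,
                       baseline_range = c(80, 120),
                       fraction_locomodulated = 0.3,
                       loco_gain_range = c(0.05, 0.2),
                       run_bout_mean_s = 5,
                       stationary_bout_mean_s = 10,
                       run_speed_mean = 8,
                       run_speed_sd = 2,
                       fraction_reward_responsive = 0.3,
                       reward_amp_range = c(0.2, 0.6),
                       n_trials_vr = 129L,
                       lick_concentration = 0.9,
                       licks_per_trial_mean = 6,
                       kappa_threshold = 1,
                       gain_threshold = 0.1,
                       corridor = corridor_geometry()) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(cfg$n_neurons >= 1L, cfg$n_trials_per_orientation >= 1L,
            length(cfg$orientations) >= 2L,
            all(cfg$orientations >= 0 & cfg$orientations < 180),
            cfg$stationary_dur_s > 0, cfg$moving_dur_s > 0, cfg$gray_dur_s > 0,
            cfg$sampling_rate > 0, cfg$noise_sd >= 0,
            cfg$lick_concentration >= 0, cfg$lick_concentration <= 1)
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep defaults.
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$corridor)) {
    vals$corridor <- do.call(corridor_geometry, vals$corridor)
  }
  do.call(sim_config, vals)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Draw a ground-truth parameter table for one population
#'
#' @param config a [sim_config()].
#' @param vr logical; draw reward amplitudes for a rewarded VR session.
#' @return object of class `ground_truth`: a list with `neurons` (data.frame
#'   of per-neuron generating parameters and the `is_selective` flag) and the
#'   session-level lick concentration.
#' @export
generate_ground_truth <- function(config, vr = FALSE) {
  n <- config$n_neurons
  sel <- stats::runif(n) < config$fraction_selective
  kappa <- ifelse(sel, runif_range(n, config$kappa_range), 0)
  gain <- ifelse(sel, runif_range(n, config$gain_range),
                 runif_range(n, config$null_gain_range))
  pref <- sample(config$orientations, n, replace = TRUE)
  loco <- ifelse(stats::runif(n) < config$fraction_locomodulated,
                 runif_range(n, config$loco_gain_range), 0)
  reward <- if (vr) {
    ifelse(stats::runif(n) < config$fraction_reward_responsive,
           runif_range(n, config$reward_amp_range), 0)
  } else rep(0, n)
  neurons <- data.frame(
    neuron = seq_len(n), pref_deg = pref, kappa = kappa, gain = gain,
    noise_sd = config$noise_sd, loco_gain = loco, reward_amp = reward,
    is_selective = kappa >= config$kappa_threshold &
      gain >= config$gain_threshold)
  structure(list(neurons = neurons,
                 lick_concentration = config$lick_concentration),
            class = "ground_truth")
}

# von Mises tuning on the doubled angle, normalized to peak 1.
vonmises_axial <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos(2 * (theta_deg - pref_deg) * pi / 180) - 1))
}

# Two-state (stationary/running) locomotion bout chain -> per-frame speed.
simulate_speed <- function(n_frames, config) {
  fs <- config$sampling_rate
  speed <- numeric(n_frames)
  t <- 1L
  running <- stats::runif(1) < config$run_bout_mean_s /
    (config$run_bout_mean_s + config$stationary_bout_mean_s)
  while (t <= n_frames) {
    dur_s <- stats::rexp(1, 1 / (if (running) config$run_bout_mean_s else
      config$stationary_bout_mean_s))
    len <- max(1L, sec_to_frames(dur_s, fs))
    idx <- t:min(n_frames, t + len - 1L)
    if (running) {
      speed[idx] <- max(0.2, stats::rnorm(1, config$run_speed_mean,
                                          config$run_speed_sd))
    }
    t <- t + len
    running <- !running
  }
  speed
}

# Exponential calcium-kernel convolution (unit DC gain leaky integrator),
# applied along rows of a neurons x frames drive matrix.
calcium_convolve <- function(drive, decay_s, sampling_rate) {
  a <- exp(-1 / (decay_s * sampling_rate))
  out <- drive * (1 - a)
  for (t in seq_len(ncol(drive))[-1L]) {
    out[, t] <- out[, t] + a * out[, t - 1L]
  }
  out
}

finish_traces <- function(dff_true, truth, config) {
  n <- nrow(dff_true)
  baseline <- runif_range(n, config$baseline_range)
  noise <- matrix(stats::rnorm(length(dff_true), 0, config$noise_sd),
                  nrow = n)
  baseline * (1 + dff_true + noise)
}

#' Generate one synthetic session with known ground truth
#'
#' `type = "grating"` builds an orientation-testing session (the pre/post
#' design): randomized presentations of each orientation, stationary then
#' moving grating phases, separated by gray.  `type = "vr"` builds a rewarded
#' virtual-corridor session: each trial is a corridor traversal with the
#' grating on the walls until the reward zone (black walls), licks placed
#' with probability `lick_concentration` inside the success window, and a
#' reward per trial (self-initiated within the success window when licked
#' there, otherwise delivered at the default location beyond it).
#'
#' Neuronal drive is `gain * vonMises(2 theta)` during stimulus frames plus
#' `loco_gain` during running plus a 1-s reward-locked pulse, convolved with
#' an exponential calcium kernel, placed on a positive raw-fluorescence
#' baseline with additive Gaussian noise — so preprocessing must recover
#' dF/F0.
#'
#' @param config a [sim_config()].
#' @param truth optional [generate_ground_truth()] result to reuse (chronic
#'   designs); neuron count must match the config.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param day_label session day label.
#' @param type `"grating"` or `"vr"`.
#' @param corridors list of [corridor_geometry()] for VR sessions (two
#'   entries give a two-corridor session, alternating blocks of 5 trials).
#' @return list with elements `session` ([session_bundle()]) and `truth`.
#' @export
generate_session <- function(config, truth = NULL, seed = NULL,
                             day_label = "pre",
                             type = c("grating", "vr"),
                             corridors = list(config$corridor)) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) {
    truth <- generate_ground_truth(config, vr = identical(type, "vr"))
  } else if (nrow(truth$neurons) != config$n_neurons) {
    stop("ground truth has ", nrow(truth$neurons), " neurons; config says ",
         config$n_neurons)
  }
  if (identical(type, "grating")) {
    out <- build_grating_session(config, truth, day_label)
  } else {
    out <- build_vr_session(config, truth, day_label, corridors)
  }
  list(session = validate_session(out), truth = truth)
}

build_grating_session <- function(config, truth, day_label) {
  fs <- config$sampling_rate
  nb <- truth$neurons
  oris <- rep(config$orientations, each = config$n_trials_per_orientation)
  oris <- sample(oris)
  n_stat <- sec_to_frames(config$stationary_dur_s, fs)
  n_mov <- sec_to_frames(config$moving_dur_s, fs)
  n_gray <- sec_to_frames(config$gray_dur_s, fs)
  lead <- sec_to_frames(2, fs)

  onset <- lead
  rows <- vector("list", length(oris) * 3L)
  for (i in seq_along(oris)) {
    rows[[3L * i - 2L]] <- data.frame(
      onset_frame = onset, offset_frame = onset + n_stat,
      orientation = oris[i], phase = "stationary", trial = i)
    rows[[3L * i - 1L]] <- data.frame(
      onset_frame = onset + n_stat, offset_frame = onset + n_stat + n_mov,
      orientation = oris[i], phase = "moving", trial = i)
    rows[[3L * i]] <- data.frame(
      onset_frame = onset + n_stat + n_mov,
      offset_frame = onset + n_stat + n_mov + n_gray,
      orientation = NA_real_, phase = "gray", trial = NA_integer_)
    onset <- onset + n_stat + n_mov + n_gray
  }
  epochs <- do.call(rbind, rows)
  n_frames <- onset

  speed <- simulate_speed(n_frames, config)
  drive <- outer(nb$loco_gain, as.numeric(speed >= 0.1))
  tuning <- outer(seq_len(nrow(nb)), seq_along(config$orientations),
                  function(i, k) nb$gain[i] *
                    vonmises_axial(config$orientations[k], nb$pref_deg[i],
                                   nb$kappa[i]))
  stim_rows <- epochs$phase %in% c("stationary", "moving")
  jit <- if (config$gain_jitter_sdlog > 0) {
    matrix(stats::rlnorm(nrow(nb) * length(oris),
                         meanlog = -config$gain_jitter_sdlog^2 / 2,
                         sdlog = config$gain_jitter_sdlog),
           nrow = nrow(nb))
  } else NULL
  for (r in which(stim_rows)) {
    k <- match(epochs$orientation[r], config$orientations)
    fr <- (epochs$onset_frame[r] + 1L):epochs$offset_frame[r]
    resp <- tuning[, k]
    if (!is.null(jit)) resp <- resp * jit[, epochs$trial[r]]
    drive[, fr] <- drive[, fr] + resp
  }
  dff_true <- calcium_convolve(drive, config$calcium_decay_s, fs)
  traces <- finish_traces(dff_true, truth, config)

  session_bundle(animal_id = "sim", day_label = day_label,
                 sampling_rate = fs, traces = traces, speed = speed,
                 epochs = epochs, is_dff = FALSE)
}

build_vr_session <- function(config, truth, day_label, corridors) {
  fs <- config$sampling_rate
  nb <- truth$neurons
  n_trials <- config$n_trials_vr
  n_cor <- length(corridors)
  # alternating blocks of 5 trials when two corridors are presented
  cor_id <- if (n_cor == 1L) rep(1L, n_trials) else
    (((seq_len(n_trials) - 1L) %/% 5L) %% n_cor) + 1L
  gap <- sec_to_frames(2, fs)

  pos_all <- numeric(0); speed_all <- numeric(0)
  epochs <- list(); licks <- list(); rewards <- integer(0)
  stim_frames <- list()
  t0 <- gap  # lead-in gap (stationary, no position)
  pos_all <- rep(NA_real_, gap); speed_all <- rep(0, gap)
  for (i in seq_len(n_trials)) {
    g <- corridors[[cor_id[i]]]
    v <- max(5, stats::rnorm(1, 20, 3))
    nf <- max(2L, sec_to_frames(g$corridor_length / v, fs))
    pos <- (seq_len(nf) - 1L) / nf * g$corridor_length
    zone_f <- which(pos >= g$reward_zone_start)[1] - 1L  # 0-based in trial
    epochs[[length(epochs) + 1L]] <- data.frame(
      onset_frame = t0, offset_frame = t0 + zone_f,
      orientation = g$grating_orientation, phase = "moving", trial = i)
    epochs[[length(epochs) + 1L]] <- data.frame(
      onset_frame = t0 + zone_f, offset_frame = t0 + nf,
      orientation = NA_real_, phase = "black_zone", trial = i)
    stim_frames[[i]] <- list(frames = t0 + seq_len(zone_f) - 1L,
                             ori = g$grating_orientation)
    # licks: concentrated in the success window with prob lick_concentration
    n_l <- stats::rpois(1, config$licks_per_trial_mean)
    if (n_l > 0L) {
      inwin <- stats::runif(n_l) < truth$lick_concentration
      win_end <- g$reward_zone_start +
        (g$success_window_cm %||% (g$reward_zone_end - g$reward_zone_start))
      lp <- ifelse(inwin,
                   stats::runif(n_l, g$reward_zone_start, win_end),
                   stats::runif(n_l, 0, g$corridor_length))
      lf <- t0 + pmin(nf - 1L, pmax(0L, findInterval(lp, pos) - 1L))
      licks[[length(licks) + 1L]] <-
        data.frame(frame = as.integer(lf), position_cm = lp, trial = i)
      win_licks <- which(lp >= g$reward_zone_start & lp < win_end)
    } else win_licks <- integer(0)
    if (length(win_licks)) {
      rewards <- c(rewards,
                   as.integer(min(licks[[length(licks)]]$frame[win_licks])))
    } else {
      win_end <- g$reward_zone_start +
        (g$success_window_cm %||% (g$reward_zone_end - g$reward_zone_start))
      def_f <- which(pos >= min(win_end, g$corridor_length - 1e-9))[1]
      if (is.na(def_f)) def_f <- nf
      rewards <- c(rewards, as.integer(t0 + def_f - 1L))
    }
    pos_all <- c(pos_all, pos, rep(NA_real_, gap))
    speed_all <- c(speed_all, rep(v, nf), rep(0, gap))
    t0 <- t0 + nf + gap
  }
  n_frames <- t0
  epochs <- do.call(rbind, epochs)
  licks <- if (length(licks)) do.call(rbind, licks) else
    cbind(empty_licks(), trial = integer())

  drive <- outer(nb$loco_gain, as.numeric(speed_all >= 0.1))
  for (i in seq_len(n_trials)) {
    sf <- stim_frames[[i]]
    resp <- nb$gain * vonmises_axial(sf$ori, nb$pref_deg, nb$kappa)
    drive[, sf$frames + 1L] <- drive[, sf$frames + 1L] + resp
  }
  pulse_len <- sec_to_frames(1, fs)
  for (rf in rewards) {
    fr <- (rf + 1L):min(n_frames, rf + pulse_len)
    drive[, fr] <- drive[, fr] + nb$reward_amp
  }
  dff_true <- calcium_convolve(drive, config$calcium_decay_s, fs)
  traces <- finish_traces(dff_true, truth, config)
  # positions during inter-trial gaps are undefined; park at 0 cm
  pos_all[is.na(pos_all)] <- 0

  session_bundle(animal_id = "sim", day_label = day_label,
                 sampling_rate = fs, traces = traces, speed = speed_all,
                 epochs = epochs,
                 licks = licks[, c("frame", "position_cm")],
                 rewards = rewards, position = pos_all,
                 corridor = corridors[[1L]], is_dff = FALSE)
}

#' Generate a chronic pre/post experiment with planted cell fates
#'
#' Each neuron is assigned a fate: `remain` (tuned on both testing days),
#' `gain` (untuned pre, tuned to the repetitive orientation post), `lose`
#' (tuned pre, untuned post), or `nonselective` (never tuned).  Tuning
#' concentration and gain ramp linearly across the intervening days.
#'
#' @param config a [sim_config()].
#' @param plasticity_spec list with `fates` (named fractions over
#'   remain/gain/lose/nonselective, summing to 1), `repetitive_orientation`
#'   (degrees; default 90), and `include_training_days` (logical; adds
#'   rewarded VR sessions D1-D5 with the repetitive corridor grating).
#' @param seed integer seed.
#' @return list with `experiment` ([experiment_set()]) and `truths` (named
#'   list of per-day ground truth; each carries a `fate` column).
#' @export
generate_experiment <- function(config,
                                plasticity_spec = list(
                                  fates = c(remain = 0.55, gain = 0.1,
                                            lose = 0.1, nonselective = 0.25)),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fates <- plasticity_spec$fates
  need <- c("remain", "gain", "lose", "nonselective")
  if (!all(need %in% names(fates))) {
    stop("plasticity_spec$fates must name: ", paste(need, collapse = ", "))
  }
  if (abs(sum(fates) - 1) > 1e-8) stop("fate fractions must sum to 1")
  rep_ori <- plasticity_spec$repetitive_orientation %||% 90
  include_training <- isTRUE(plasticity_spec$include_training_days)

  n <- config$n_neurons
  counts <- stats::rmultinom(1, n, fates[need])[, 1]
  fate <- sample(rep(need, counts))

  draw_truth <- function(tuned, pref_fixed = NULL) {
    tr <- generate_ground_truth(config)
    nb <- tr$neurons
    nb$kappa <- ifelse(tuned, runif_range(n, config$kappa_range), 0)
    nb$gain <- ifelse(tuned, runif_range(n, config$gain_range),
                      runif_range(n, config$null_gain_range))
    if (!is.null(pref_fixed)) nb$pref_deg[!is.na(pref_fixed)] <-
      pref_fixed[!is.na(pref_fixed)]
    nb$is_selective <- nb$kappa >= config$kappa_threshold &
      nb$gain >= config$gain_threshold
    nb$fate <- fate
    tr$neurons <- nb
    tr
  }
  pre_tuned <- fate %in% c("remain", "lose")
  post_tuned <- fate %in% c("remain", "gain")
  truth_pre <- draw_truth(pre_tuned)
  # post: remain keeps its pre parameters; gain becomes tuned to the
  # repetitive orientation
  truth_post <- draw_truth(post_tuned,
                           pref_fixed = ifelse(fate == "gain", rep_ori,
                                               NA_real_))
  keep <- fate == "remain"
  truth_post$neurons$pref_deg[keep] <- truth_pre$neurons$pref_deg[keep]
  truth_post$neurons$kappa[keep] <- truth_pre$neurons$kappa[keep]
  truth_post$neurons$gain[keep] <- truth_pre$neurons$gain[keep]
  truth_post$neurons$is_selective[keep] <- truth_pre$neurons$is_selective[keep]

  sessions <- list()
  truths <- list()
  s <- generate_session(config, truth_pre, day_label = "pre")
  sessions$pre <- s$session; truths$pre <- s$truth
  if (include_training) {
    vr_cfg <- config
    vr_cfg$corridor$grating_orientation <- rep_ori
    for (d in 1:5) {
      w <- d / 6  # linear ramp pre -> post across the training days
      td <- truth_pre
      td$neurons$kappa <- (1 - w) * truth_pre$neurons$kappa +
        w * truth_post$neurons$kappa
      td$neurons$gain <- (1 - w) * truth_pre$neurons$gain +
        w * truth_post$neurons$gain
      td$neurons$reward_amp <- ifelse(
        stats::runif(n) < config$fraction_reward_responsive,
        runif_range(n, config$reward_amp_range), 0)
      lbl <- paste0("D", d)
      s <- generate_session(vr_cfg, td, day_label = lbl, type = "vr")
      sessions[[lbl]] <- s$session; truths[[lbl]] <- s$truth
    }
  }
  s <- generate_session(config, truth_post, day_label = "post")
  sessions$post <- s$session; truths$post <- s$truth

  list(experiment = experiment_set(unname(sessions),
                                   group = plasticity_spec$group %||%
                                     "goal-directed VR"),
       truths = truths)
}
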
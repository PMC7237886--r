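#' Segment a running-speed trace into locomotion / stationary / excluded
#'
#' Locomotion frames satisfy three criteria simultaneously: instantaneous
#' speed >= `speed_threshold`; 0.25 Hz zero-phase low-pass filtered speed >=
#' the threshold; and mean speed over a centered 2-s window >= the threshold.
#' Inter-locomotion gaps shorter than 500 ms are relabeled locomotion.
#' Frames less than 3 s after or 0.2 s before locomotion (and not locomotion
#' themselves) are excluded from the stationary class.
#'
#' @param speed per-frame speed (cm/s).
#' @param sampling_rate Hz.
#' @param speed_threshold cm/s, default 0.1.
#' @param filter_cutoff_hz low-pass cutoff for criterion 2, default 0.25.
#' @param window_s centered averaging window for criterion 3, default 2.
#' @param merge_ms maximum inter-locomotion gap to bridge, default 500.
#' @param post_exclusion_s,pre_exclusion_s stationary exclusion margins
#'   after/before locomotion, defaults 3 and 0.2.
#' @return object of class `locomotion_segmentation`: list with `state`
#'   (factor per frame: locomotion/stationary/excluded) and the thresholds.
#' @export
segment_locomotion <- function(speed, sampling_rate,
                               speed_threshold = 0.1,
                               filter_cutoff_hz = 0.25,
                               window_s = 2,
                               merge_ms = 500,
                               post_exclusion_s = 3,
                               pre_exclusion_s = 0.2) {
  stopifnot(all(is.finite(speed)), sampling_rate > 0)
  n <- length(speed)
  filt <- lowpass_zero_phase(speed, sampling_rate, filter_cutoff_hz)
  win <- max(1L, sec_to_frames(window_s, sampling_rate))
  avg <- rolling_mean_centered(speed, win)
  loco <- speed >= speed_threshold & filt >= speed_threshold &
    avg >= speed_threshold

  # bridge short inter-locomotion gaps
  r <- rle(loco)
  gap_max <- merge_ms / 1000 * sampling_rate
  k <- length(r$values)
  interior <- which(!r$values & seq_len(k) > 1L & seq_len(k) < k)
  r$values[interior[r$lengths[interior] < gap_max]] <- TRUE
  loco <- inverse.rle(r)

  state <- rep("stationary", n)
  state[loco] <- "locomotion"
  if (any(loco)) {
    post_n <- sec_to_frames(post_exclusion_s, sampling_rate)
    pre_n <- sec_to_frames(pre_exclusion_s, sampling_rate)
    idx <- which(loco)
    excl <- unique(c(outer(idx, seq_len(post_n), `+`),
                     outer(idx, seq_len(pre_n), `-`)))
    excl <- excl[excl >= 1L & excl <= n]
    excl <- excl[!loco[excl]]
    state[excl] <- "excluded"
  }
  structure(list(state = factor(state,
                                levels = c("locomotion", "stationary",
                                           "excluded")),
                 thresholds = list(speed = speed_threshold,
                                   filter_cutoff_hz = filter_cutoff_hz,
                                   window_s = window_s, merge_ms = merge_ms,
                                   post_exclusion_s = post_exclusion_s,
                                   pre_exclusion_s = pre_exclusion_s)),
            class = "locomotion_segmentation")
}

#' Locomotion modulation index per neuron
#'
#' LMI = (R_L - R_s) / (R_L + R_s), where R_L and R_s are the mean dF/F0
#' during locomotion and stationary frames (excluded frames contribute to
#' neither).  Neurons with R_L + R_s = 0, or with no frames in one state,
#' get `NA` with `defined = FALSE`.
#'
#' @param dff a `dff_trace`.
#' @param seg a [segment_locomotion()] result covering the same frames.
#' @return data.frame: `neuron`, `r_loco`, `r_stat`, `lmi`, `defined`.
#' @export
compute_lmi <- function(dff, seg) {
  stopifnot(length(seg$state) == ncol(dff$dff))
  lf <- seg$state == "locomotion"
  sf <- seg$state == "stationary"
  r_l <- if (any(lf)) rowMeans(dff$dff[, lf, drop = FALSE]) else
    rep(NA_real_, nrow(dff$dff))
  r_s <- if (any(sf)) rowMeans(dff$dff[, sf, drop = FALSE]) else
    rep(NA_real_, nrow(dff$dff))
  denom <- r_l + r_s
  defined <- is.finite(denom) & denom != 0
  lmi <- ifelse(defined, (r_l - r_s) / denom, NA_real_)
  data.frame(neuron = seq_len(nrow(dff$dff)), r_loco = r_l, r_stat = r_s,
             lmi = lmi, defined = defined)
}

success_window_bounds <- function(geometry) {
  if (is.null(geometry$success_window_cm)) {
    stop("geometry carries no spatial success window")
  }
  c(geometry$reward_zone_start,
    geometry$reward_zone_start + geometry$success_window_cm)
}

#' Lick success rate
#'
#' A trial is successful iff at least one lick falls inside the success
#' window.  With a spatial window (`success_window_cm`), licks are corridor
#' positions in cm and the window is the first `success_window_cm` of the
#' reward zone.  With a temporal window (`success_window_s`), licks are
#' times in seconds relative to reward-zone entry and the window is
#' `[0, success_window_s)`.
#'
#' @param licks_per_trial list with one numeric vector per trial: lick
#'   positions (cm) or lick times (s), see above.
#' @param geometry a [corridor_geometry()].
#' @return fraction of successful trials.
#' @export
compute_success_rate <- function(licks_per_trial, geometry) {
  if (length(licks_per_trial) == 0L) stop("at least one trial required")
  if (!is.null(geometry$success_window_cm)) {
    w <- success_window_bounds(geometry)
    hit <- vapply(licks_per_trial,
                  function(p) any(p >= w[1] & p < w[2]), logical(1))
  } else {
    hit <- vapply(licks_per_trial,
                  function(t) any(t >= 0 & t < geometry$success_window_s),
                  logical(1))
  }
  mean(hit)
}

#' Spatial modulation index (SMI) of licking
#'
#' The observed success rate is divided by the mean success rate of a
#' permutation null in which every trial's licks are redrawn uniformly along
#' the corridor (lick count preserved per trial).  SMI > 1 indicates licking
#' spatially concentrated on the reward zone; spatially indiscriminate
#' licking gives SMI near 1; frequent licking that misses the zone gives
#' SMI < 1.
#'
#' An alternative null (`scheme = "circular"`) circularly shifts each
#' trial's lick positions by a uniform offset along the corridor.
#'
#' @param licks_per_trial list of lick position vectors (cm), one per trial.
#' @param geometry a [corridor_geometry()] with a spatial success window.
#' @param n_permutations number of permutations (default 1000; must be >= 1).
#' @param seed integer seed for the permutation draws.
#' @param scheme `"uniform"` (default) or `"circular"`.
#' @return object of class `smi_result`: list with `success_rate`,
#'   `shuffled_mean`, `smi` (`NA` with `defined = FALSE` when the shuffled
#'   mean is 0), `n_permutations`, `n_trials`, `seed`.
#' @export
compute_smi <- function(licks_per_trial, geometry, n_permutations = 1000L,
                        seed = NULL, scheme = c("uniform", "circular")) {
  scheme <- match.arg(scheme)
  if (length(licks_per_trial) == 0L) stop("at least one trial required")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  w <- success_window_bounds(geometry)
  L <- geometry$corridor_length
  obs <- compute_success_rate(licks_per_trial, geometry)
  counts <- lengths(licks_per_trial)
  n_trials <- length(counts)
  shuffled <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    if (scheme == "uniform") {
      draws <- stats::runif(sum(counts), 0, L)
      trial_of <- rep.int(seq_len(n_trials), counts)
      hit <- draws >= w[1] & draws < w[2]
      shuffled[p] <- sum(tabulate(trial_of[hit], n_trials) > 0L) / n_trials
    } else {
      hits <- vapply(licks_per_trial, function(pos) {
        if (!length(pos)) return(FALSE)
        shifted <- (pos + stats::runif(1, 0, L)) %% L
        any(shifted >= w[1] & shifted < w[2])
      }, logical(1))
      shuffled[p] <- mean(hits)
    }
  }
  sm <- mean(shuffled)
  defined <- sm > 0
  structure(list(success_rate = obs, shuffled_mean = sm,
                 smi = if (defined) obs / sm else NA_real_,
                 defined = defined, n_permutations = n_permutations,
                 n_trials = n_trials, seed = seed, scheme = scheme),
            class = "smi_result")
}

#' @export
print.smi_result <- function(x, ...) {
  cat(sprintf(
    "SMI = %s (success rate %.3f / shuffled mean %.3f; %d trials, %d perms)\n",
    if (x$defined) sprintf("%.3f", x$smi) else "undefined",
    x$success_rate, x$shuffled_mean, x$n_trials, x$n_permutations))
  invisible(x)
}

#' Split a session's licks into per-trial position vectors
#'
#' Trials are the epochs table's trial indices; a lick belongs to the trial
#' whose epoch span contains its frame.
#' @param session a [session_bundle()].
#' @return named list of lick position vectors (cm), one per trial.
#' @export
licks_by_trial <- function(session) {
  ep <- session$epochs[!is.na(session$epochs$trial), ]
  trials <- sort(unique(ep$trial))
  spans <- lapply(trials, function(tr) {
    range(c(ep$onset_frame[ep$trial == tr], ep$offset_frame[ep$trial == tr]))
  })
  out <- lapply(spans, function(sp) {
    session$licks$position_cm[session$licks$frame >= sp[1] &
                                session$licks$frame < sp[2]]
  })
  names(out) <- trials
  out
}

#' Per-session behavior report
#'
#' @param session a VR [session_bundle()] with corridor geometry.
#' @param n_permutations,seed passed to [compute_smi()].
#' @return one-row data.frame: `success_rate`, `shuffled_mean`, `smi`,
#'   `pct_time_running`, `n_trials`.
#' @export
behavior_report <- function(session, n_permutations = 1000L, seed = NULL) {
  if (is.null(session$corridor)) stop("session has no corridor geometry")
  lt <- licks_by_trial(session)
  smi <- compute_smi(lt, session$corridor, n_permutations, seed)
  seg <- segment_locomotion(session$speed, session$sampling_rate)
  data.frame(success_rate = smi$success_rate,
             shuffled_mean = smi$shuffled_mean,
             smi = smi$smi,
             pct_time_running = 100 * mean(seg$state == "locomotion"),
             n_trials = smi$n_trials)
}
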
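# Small in-code fixtures shared across test files.

# A dff_trace object built directly from a dF/F0 matrix (bypasses
# compute_dff; for unit tests of downstream operations).
make_dff <- function(mat, sampling_rate = 10) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  structure(list(dff = mat, f0 = rep(1, nrow(mat)),
                 ok = rep(TRUE, nrow(mat)),
                 sampling_rate = sampling_rate, filter = NULL),
            class = "dff_trace")
}

# Epochs table for a sequence of presentations: each trial is
# gray(pre_s) | stationary(stat_s) | moving(mov_s), 0-based half-open frames.
make_epochs <- function(orientations, sampling_rate = 10, pre_s = 2,
                        stat_s = 2, mov_s = 2) {
  n_pre <- floor(pre_s * sampling_rate)
  n_st <- floor(stat_s * sampling_rate)
  n_mv <- floor(mov_s * sampling_rate)
  onset <- n_pre
  rows <- list()
  for (i in seq_along(orientations)) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset_frame = onset, offset_frame = onset + n_st,
      orientation = orientations[i], phase = "stationary", trial = i)
    rows[[length(rows) + 1L]] <- data.frame(
      onset_frame = onset + n_st, offset_frame = onset + n_st + n_mv,
      orientation = orientations[i], phase = "moving", trial = i)
    onset <- onset + n_st + n_mv + n_pre
  }
  do.call(rbind, rows)
}

# Trial-response table for one neuron from a vector of per-orientation mean
# responses, with optional per-trial noise.
make_responses <- function(means, orientations = c(0, 45, 90, 135),
                           n_trials = 10, noise_sd = 0, neuron = 1L) {
  stopifnot(length(means) == length(orientations))
  do.call(rbind, lapply(seq_along(orientations), function(k) {
    data.frame(neuron = neuron, trial = seq_len(n_trials),
               orientation = orientations[k],
               response = means[k] + stats::rnorm(n_trials, 0, noise_sd))
  }))
}

# Minimal selectivity-call table.
make_calls <- function(preferred, is_selective) {
  data.frame(neuron = seq_along(preferred), preferred = preferred,
             is_selective = is_selective)
}

# A tuning_curve stub carrying only a resultant vector at the given axial
# angle (degrees) and magnitude.
make_curve_at <- function(angle_deg, magnitude = 0.6) {
  structure(list(orientations = c(0, 45, 90, 135),
                 mean_responses = rep(NA_real_, 4),
                 resultant = magnitude * exp(2i * angle_deg * pi / 180),
                 peak_angle = angle_deg %% 180,
                 peak_magnitude = magnitude,
                 preferred = NA_real_, defined = TRUE),
            class = "tuning_curve")
}

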
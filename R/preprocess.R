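#' Compute dF/F0 from raw fluorescence traces
#'
#' The baseline F0 of each neuron is the 5th percentile of the smoothed
#' trace, where smoothing is a zero-phase low-pass FIR filter (1 Hz cutoff,
#' 60th order, Hamming window, applied forward-backward with edge-reflection
#' padding).  dF/F0 = (F - F0) / F0.
#'
#' Neurons whose baseline comes out non-positive cannot be normalized; they
#' are flagged (`ok = FALSE`), their dF/F0 rows set to `NA`, and a warning is
#' emitted so downstream stages can exclude them.
#'
#' @param raw numeric matrix, neurons x frames, raw fluorescence (a.u.);
#'   a vector is treated as a single neuron.
#' @param sampling_rate Hz; must exceed 2 Hz so the 1 Hz cutoff is below
#'   Nyquist.
#' @param percentile baseline percentile of the smoothed trace (default 5).
#' @param cutoff_hz smoothing low-pass cutoff (default 1 Hz).
#' @param order FIR filter order (default 60).
#' @return object of class `dff_trace`: list with `dff` (neurons x frames
#'   matrix), `f0` (per-neuron baseline), `ok` (per-neuron flag), and the
#'   filter spec.
#' @export
compute_dff <- function(raw, sampling_rate, percentile = 5,
                        cutoff_hz = 1, order = 60L) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  if (sampling_rate <= 2 * cutoff_hz) {
    stop("sampling_rate must exceed ", 2 * cutoff_hz,
         " Hz for a ", cutoff_hz, " Hz smoothing cutoff")
  }
  n <- nrow(raw)
  f0 <- numeric(n)
  dff <- matrix(NA_real_, n, ncol(raw))
  for (i in seq_len(n)) {
    sm <- lowpass_zero_phase(raw[i, ], sampling_rate, cutoff_hz, order)
    f0[i] <- stats::quantile(sm, percentile / 100, names = FALSE, na.rm = TRUE)
    if (is.finite(f0[i]) && f0[i] > 0) {
      dff[i, ] <- (raw[i, ] - f0[i]) / f0[i]
    }
  }
  ok <- is.finite(f0) & f0 > 0
  if (any(!ok)) {
    warning(sum(!ok), " neuron(s) with non-positive baseline F0 excluded")
  }
  structure(list(dff = dff, f0 = f0, ok = ok,
                 sampling_rate = sampling_rate,
                 filter = list(cutoff_hz = cutoff_hz, order = order,
                               percentile = percentile)),
            class = "dff_trace")
}

#' dF/F0 for a session bundle
#'
#' Convenience wrapper: returns the session's traces as a [compute_dff()]
#' result, passing through traces already flagged as dF/F0.
#' @param session a [session_bundle()].
#' @param ... passed to [compute_dff()].
#' @return a `dff_trace`.
#' @export
session_dff <- function(session, ...) {
  if (session$is_dff) {
    structure(list(dff = session$traces,
                   f0 = rep(NA_real_, nrow(session$traces)),
                   ok = rep(TRUE, nrow(session$traces)),
                   sampling_rate = session$sampling_rate,
                   filter = NULL),
              class = "dff_trace")
  } else {
    compute_dff(session$traces, session$sampling_rate, ...)
  }
}

#' Extract baseline-corrected trial responses
#'
#' For each grating presentation, the response of a neuron is the mean dF/F0
#' over the stimulation period minus the minimum dF/F0 in the window
#' preceding stimulation onset (local-baseline correction).  Which phases
#' count as "the stimulation period" is configurable: the moving-grating
#' phase only (default, used for the orientation-selectivity analysis), both
#' stationary and moving phases, or the first 2 s of the moving phase (the
#' single-neuron decoder convention).
#'
#' Presentations that start too close to the beginning of the recording for
#' a full pre-window are skipped with a warning.
#'
#' @param dff a `dff_trace` from [compute_dff()] / [session_dff()].
#' @param epochs stimulus epoch table (see [session_bundle()]).
#' @param pre_window_s local-baseline window length (s), default 2.
#' @param stim_period one of `"moving"`, `"both"`, `"moving_2s"`.
#' @param baseline_correct set `FALSE` to skip the pre-window subtraction
#'   (plain stimulus-period means, as used by the population decoder).
#' @return data.frame with columns `neuron`, `trial`, `orientation`,
#'   `response` (one row per neuron x presentation).
#' @export
extract_trial_responses <- function(dff, epochs, pre_window_s = 2,
                                    stim_period = c("moving", "both",
                                                    "moving_2s"),
                                    baseline_correct = TRUE) {
  stim_period <- match.arg(stim_period)
  fs <- dff$sampling_rate
  pre_n <- sec_to_frames(pre_window_s, fs)
  stim <- epochs[epochs$phase %in% c("stationary", "moving") &
                   !is.na(epochs$trial), ]
  trials <- sort(unique(stim$trial))
  keep_neurons <- which(dff$ok)
  out <- vector("list", length(trials))
  skipped <- 0L
  for (j in seq_along(trials)) {
    tr <- stim[stim$trial == trials[j], ]
    pres_onset <- min(tr$onset_frame)
    frames <- switch(stim_period,
      moving = {
        mv <- tr[tr$phase == "moving", ]
        unlist(Map(seq, mv$onset_frame, mv$offset_frame - 1L))
      },
      both = unlist(Map(seq, tr$onset_frame, tr$offset_frame - 1L)),
      moving_2s = {
        mv <- tr[tr$phase == "moving", ]
        on <- min(mv$onset_frame)
        seq(on, min(max(mv$offset_frame), on + sec_to_frames(2, fs)) - 1L)
      })
    if (baseline_correct && pres_onset - pre_n < 0L) {
      skipped <- skipped + 1L
      next
    }
    resp <- rowMeans(dff$dff[keep_neurons, frames + 1L, drop = FALSE])
    if (baseline_correct) {
      pre_frames <- seq(pres_onset - pre_n, pres_onset - 1L)
      base <- apply(dff$dff[keep_neurons, pre_frames + 1L, drop = FALSE],
                    1L, min)
      resp <- resp - base
    }
    out[[j]] <- data.frame(neuron = keep_neurons, trial = trials[j],
                           orientation = tr$orientation[1L],
                           response = resp)
  }
  if (skipped > 0L) {
    warning(skipped,
            " presentation(s) skipped: too close to recording start for a ",
            pre_window_s, " s pre-window")
  }
  do.call(rbind, out)
}
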
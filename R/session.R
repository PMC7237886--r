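#' Construct a single-session imaging bundle
#'
#' A `session_bundle` holds everything recorded in one imaging session: the
#' fluorescence trace matrix, the running-speed trace, the stimulus epoch
#' table, behavioral event streams (licks, rewards), and — for virtual-reality
#' sessions — the corridor position trace and corridor geometry.
#'
#' @param animal_id character scalar.
#' @param day_label one of `"pre"`, `"D1"`..`"D5"`, `"post"`, `"novice"`,
#'   `"training"`, `"expert"`.
#' @param sampling_rate imaging sampling rate in Hz (> 0).
#' @param traces numeric matrix, neurons x frames. Raw fluorescence in
#'   arbitrary units unless `is_dff = TRUE`.
#' @param speed numeric vector of per-frame running speed (cm/s), same frame
#'   count as `traces`.
#' @param epochs data.frame of stimulus epochs with columns `onset_frame`,
#'   `offset_frame` (0-based, half-open `[onset, offset)`), `orientation`
#'   (degrees in \[0, 180), `NA` for gray/black epochs), `phase` (one of
#'   `"stationary"`, `"moving"`, `"gray"`, `"black_zone"`) and `trial`
#'   (integer presentation index).
#' @param licks data.frame with columns `frame` and `position_cm` (`NA`
#'   position for non-VR sessions); may have zero rows.
#' @param rewards integer vector of reward-onset frames; may be empty.
#' @param position optional numeric per-frame corridor position (cm).
#' @param corridor optional [corridor_geometry()].
#' @param is_dff logical; `TRUE` if `traces` already hold dF/F0.
#' @return an object of class `session_bundle`.
#' @seealso [read_session()], [write_session()], [generate_session()]
#' @export
session_bundle <- function(animal_id, day_label, sampling_rate, traces, speed,
                           epochs, licks = empty_licks(), rewards = integer(),
                           position = NULL, corridor = NULL, is_dff = FALSE) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
  s <- structure(
    list(animal_id = as.character(animal_id),
         day_label = as.character(day_label),
         sampling_rate = as.numeric(sampling_rate),
         traces = traces,
         speed = as.numeric(speed),
         epochs = as.data.frame(epochs),
         licks = as.data.frame(licks),
         rewards = as.integer(rewards),
         position = if (is.null(position)) NULL else as.numeric(position),
         corridor = corridor,
         is_dff = isTRUE(is_dff)),
    class = "session_bundle")
  validate_session(s)
}

empty_licks <- function() {
  data.frame(frame = integer(), position_cm = numeric())
}

empty_epochs <- function() {
  data.frame(onset_frame = integer(), offset_frame = integer(),
             orientation = numeric(), phase = character(), trial = integer())
}

day_labels <- function() {
  c("pre", paste0("D", 1:5), "post", "novice", "training", "expert")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("session_bundle: animal %s, day %s\n", x$animal_id, x$day_label))
  cat(sprintf("  %d neurons x %d frames @ %.1f Hz (%s)\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate,
              if (x$is_dff) "dF/F0" else "raw fluorescence"))
  cat(sprintf("  %d stimulus epochs, %d licks, %d rewards%s\n",
              nrow(x$epochs), nrow(x$licks), length(x$rewards),
              if (is.null(x$position)) "" else ", VR position stream"))
  invisible(x)
}

validate_session <- function(s) {
  stopifnot(inherits(s, "session_bundle"))
  n_frames <- ncol(s$traces)
  if (nrow(s$traces) < 1L) stop("session must contain at least one neuron")
  if (!is.numeric(s$sampling_rate) || s$sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  if (!s$day_label %in% day_labels()) {
    stop("unknown day_label: ", s$day_label)
  }
  if (length(s$speed) != n_frames) {
    stop("frame-count mismatch: speed has ", length(s$speed),
         " frames, traces have ", n_frames)
  }
  if (!is.null(s$position) && length(s$position) != n_frames) {
    stop("frame-count mismatch: position has ", length(s$position),
         " frames, traces have ", n_frames)
  }
  ep <- s$epochs
  need <- c("onset_frame", "offset_frame", "orientation", "phase", "trial")
  if (!all(need %in% names(ep))) {
    stop("epochs table missing column(s): ",
         paste(setdiff(need, names(ep)), collapse = ", "))
  }
  if (nrow(ep)) {
    if (any(ep$onset_frame >= ep$offset_frame)) {
      stop("epoch onset_frame must be < offset_frame")
    }
    if (any(ep$onset_frame < 0L) || any(ep$offset_frame > n_frames)) {
      stop("epoch frames out of range [0, n_frames)")
    }
    ori <- ep$orientation[!is.na(ep$orientation)]
    if (any(ori < 0 | ori >= 180)) {
      stop("unknown orientation value: orientations must lie in [0, 180)")
    }
    o <- order(ep$onset_frame)
    if (any(ep$onset_frame[o][-1L] < ep$offset_frame[o][-nrow(ep)])) {
      stop("stimulus epochs overlap")
    }
  }
  ev_frames <- c(s$licks$frame, s$rewards)
  if (length(ev_frames) && (any(ev_frames < 0L) || any(ev_frames >= n_frames))) {
    stop("event frames out of range [0, n_frames)")
  }
  if (!is.null(s$corridor)) validate_corridor(s$corridor)
  s
}

#' Corridor geometry for virtual-reality sessions
#'
#' Describes the linear virtual corridor: total length, the reward zone
#' (black-walled segment), and the success window in which a self-initiated
#' lick triggers the reward.  The success window is spatial (`success_window_cm`
#' beyond the reward-zone onset) for position-coupled groups, or temporal
#' (`success_window_s` after reward-zone entry) for uncoupled groups; exactly
#' one of the two must be given.
#'
#' @param corridor_length corridor length in cm.
#' @param reward_zone_start,reward_zone_end reward-zone bounds in cm.
#' @param success_window_cm spatial success window length (cm), default 20.
#' @param success_window_s temporal success window (s), or `NULL`.
#' @param grating_orientation orientation (degrees) of the corridor grating.
#' @return an object of class `corridor_geometry`.
#' @export
corridor_geometry <- function(corridor_length = 160,
                              reward_zone_start = 120,
                              reward_zone_end = 160,
                              success_window_cm = 20,
                              success_window_s = NULL,
                              grating_orientation = 90) {
  g <- structure(
    list(corridor_length = corridor_length,
         reward_zone_start = reward_zone_start,
         reward_zone_end = reward_zone_end,
         success_window_cm = success_window_cm,
         success_window_s = success_window_s,
         grating_orientation = grating_orientation),
    class = "corridor_geometry")
  validate_corridor(g)
}

validate_corridor <- function(g) {
  stopifnot(inherits(g, "corridor_geometry"))
  if (!(0 < g$reward_zone_start && g$reward_zone_start < g$reward_zone_end &&
        g$reward_zone_end <= g$corridor_length)) {
    stop("corridor geometry must satisfy 0 < reward_zone_start < ",
         "reward_zone_end <= corridor_length")
  }
  if (is.null(g$success_window_cm) && is.null(g$success_window_s)) {
    stop("one of success_window_cm or success_window_s is required")
  }
  g
}

#' Bundle chronic sessions of one animal into an experiment set
#'
#' Sessions must share the neuron count (the same population tracked across
#' days) and carry unique day labels.
#'
#' @param sessions list of [session_bundle()] objects, in chronological order.
#' @param group experimental group label (e.g. `"goal-directed VR"`).
#' @return an object of class `experiment_set`.
#' @export
experiment_set <- function(sessions, group = "unspecified") {
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "session_bundle")))
  animals <- unique(vapply(sessions, `[[`, character(1), "animal_id"))
  if (length(animals) != 1L) {
    stop("experiment_set holds sessions of a single animal; got: ",
         paste(animals, collapse = ", "))
  }
  n <- vapply(sessions, function(s) nrow(s$traces), integer(1))
  if (length(unique(n)) != 1L) {
    stop("neuron count must be identical across sessions of one animal")
  }
  days <- vapply(sessions, `[[`, character(1), "day_label")
  if (anyDuplicated(days)) stop("day labels must be unique within an animal")
  names(sessions) <- days
  structure(list(animal_id = animals, group = group, sessions = sessions),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("experiment_set: animal %s (%s), %d sessions: %s\n",
              x$animal_id, x$group, length(x$sessions),
              paste(names(x$sessions), collapse = ", ")))
  invisible(x)
}
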
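# Session readers/writers.  A "csv-bundle" is a directory of tidy CSV files
# plus a JSON metadata file:
#   traces.csv   frames x neurons (columns n1..nN)
#   speed.csv    frame, speed_cmps [, position_cm]
#   epochs.csv   onset_frame, offset_frame, orientation, phase, trial
#   events.csv   kind (lick|reward), frame, position_cm
#   meta.json    animal_id, day_label, sampling_rate, is_dff, corridor
# Numeric streams are serialized with %.17g so that write -> read is
# bit-exact for doubles (NaN preserved).

fmt_num <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

#' Write a session bundle to disk
#'
#' @param session a [session_bundle()].
#' @param path destination directory (csv-bundle format); created if absent.
#' @param format only `"csv-bundle"` is supported.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = "csv-bundle") {
  validate_session(session)
  if (!identical(format, "csv-bundle")) {
    stop("unsupported format: ", format, " (supported: csv-bundle)")
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create session directory: ", path)
  }
  tr <- t(session$traces)                      # frames x neurons
  colnames(tr) <- paste0("n", seq_len(ncol(tr)))
  tr_chr <- as.data.table(apply(tr, 2L, fmt_num, simplify = FALSE))
  fwrite(tr_chr, file.path(path, "traces.csv"), quote = FALSE)

  sp <- data.table(frame = seq_along(session$speed) - 1L,
                   speed_cmps = fmt_num(session$speed))
  if (!is.null(session$position)) sp$position_cm <- fmt_num(session$position)
  fwrite(sp, file.path(path, "speed.csv"), quote = FALSE)

  ep <- as.data.table(session$epochs)
  ep$orientation <- fmt_num(ep$orientation)
  fwrite(ep, file.path(path, "epochs.csv"), quote = FALSE)

  ev <- rbind(
    data.table(kind = rep("lick", nrow(session$licks)),
               frame = session$licks$frame,
               position_cm = fmt_num(session$licks$position_cm)),
    data.table(kind = rep("reward", length(session$rewards)),
               frame = session$rewards,
               position_cm = rep("NA", length(session$rewards))))
  fwrite(ev, file.path(path, "events.csv"), quote = FALSE)

  meta <- list(animal_id = session$animal_id,
               day_label = session$day_label,
               sampling_rate = session$sampling_rate,
               is_dff = session$is_dff,
               n_neurons = nrow(session$traces),
               n_frames = ncol(session$traces),
               corridor = if (is.null(session$corridor)) NULL else
                 unclass(session$corridor))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path session directory written by [write_session()].
#' @param format only `"csv-bundle"` is supported.
#' @return a validated [session_bundle()].
#' @export
read_session <- function(path, format = "csv-bundle") {
  if (!identical(format, "csv-bundle")) {
    stop("unsupported format: ", format, " (supported: csv-bundle)")
  }
  if (!dir.exists(path)) stop("session directory not found: ", path)
  need <- c("traces.csv", "speed.csv", "epochs.csv", "events.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("missing stream: ", f, " in ", path)
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  tr <- fread(file.path(path, "traces.csv"), na.strings = "NA",
              colClasses = "character")
  traces <- t(vapply(tr, as.numeric, numeric(nrow(tr))))
  if (nrow(tr) == 1L) traces <- matrix(traces, ncol = 1L)
  dimnames(traces) <- NULL
  sp <- fread(file.path(path, "speed.csv"), na.strings = "NA",
              colClasses = "character")
  ep <- fread(file.path(path, "epochs.csv"), na.strings = "NA",
              colClasses = list(character = "orientation"))
  if (nrow(ep) == 0L) ep <- empty_epochs()
  ep <- as.data.frame(ep)
  ep$orientation <- as.numeric(ep$orientation)
  ev <- fread(file.path(path, "events.csv"), na.strings = "NA",
              colClasses = list(character = "position_cm"))
  licks <- ev[ev$kind == "lick", ]
  corridor <- NULL
  if (!is.null(meta$corridor)) {
    corridor <- do.call(corridor_geometry, meta$corridor)
  }
  session_bundle(
    animal_id = meta$animal_id,
    day_label = meta$day_label,
    sampling_rate = meta$sampling_rate,
    traces = traces,
    speed = as.numeric(sp$speed_cmps),
    epochs = ep,
    licks = data.frame(frame = as.integer(licks$frame),
                       position_cm = as.numeric(licks$position_cm)),
    rewards = as.integer(ev$frame[ev$kind == "reward"]),
    position = if ("position_cm" %in% names(sp))
      as.numeric(sp$position_cm) else NULL,
    corridor = corridor,
    is_dff = isTRUE(meta$is_dff))
}
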
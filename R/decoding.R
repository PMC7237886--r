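# Population template-matching decoder, single-neuron Bayesian
# maximum-likelihood decoder, and d' discriminability.

#' Build per-trial population vectors from a session
#'
#' One vector per presentation: each neuron's mean dF/F0 over the condition
#' period (no local-baseline subtraction — the decoders operate on raw
#' stimulus-period means).
#'
#' @param dff a `dff_trace`.
#' @param epochs stimulus epoch table.
#' @param stim_period window choice, see [extract_trial_responses()].
#' @return object of class `population_vectors`: list with `X` (trials x
#'   neurons matrix), `labels` (condition per trial), `trials`.
#' @export
population_vectors <- function(dff, epochs,
                               stim_period = c("moving", "both",
                                               "moving_2s")) {
  stim_period <- match.arg(stim_period)
  resp <- extract_trial_responses(dff, epochs, stim_period = stim_period,
                                  baseline_correct = FALSE)
  trials <- sort(unique(resp$trial))
  neurons <- sort(unique(resp$neuron))
  X <- matrix(NA_real_, length(trials), length(neurons))
  X[cbind(match(resp$trial, trials), match(resp$neuron, neurons))] <-
    resp$response
  labels <- resp$orientation[match(trials, resp$trial)]
  structure(list(X = X, labels = labels, trials = trials),
            class = "population_vectors")
}

#' Per-trial population vectors of a virtual-corridor session
#'
#' One vector per corridor traversal, from the first `window_s` seconds of
#' the grating presentation at the start of the trial; the condition label
#' is the corridor grating orientation (i.e. corridor identity).
#'
#' @param session a VR [session_bundle()].
#' @param dff optional precomputed `dff_trace` for the session.
#' @param window_s window length in seconds (default 2).
#' @return a `population_vectors` object.
#' @export
corridor_vectors <- function(session, dff = session_dff(session),
                             window_s = 2) {
  ep <- session$epochs
  gr <- ep[ep$phase == "moving" & !is.na(ep$trial), ]
  if (!nrow(gr)) stop("session has no labeled corridor grating epochs")
  fs <- dff$sampling_rate
  win <- sec_to_frames(window_s, fs)
  keep <- which(dff$ok)
  X <- matrix(NA_real_, nrow(gr), length(keep))
  for (i in seq_len(nrow(gr))) {
    fr <- gr$onset_frame[i]:min(gr$offset_frame[i], gr$onset_frame[i] + win)
    fr <- fr[fr < gr$offset_frame[i]]
    X[i, ] <- rowMeans(dff$dff[keep, fr + 1L, drop = FALSE])
  }
  structure(list(X = X, labels = gr$orientation, trials = gr$trial),
            class = "population_vectors")
}

argmax_random_tie <- function(x) {
  mx <- which(x == max(x))
  if (length(mx) == 1L) mx else sample(mx, 1L)
}

#' Template-matching population decoder (leave-one-trial-out)
#'
#' For each held-out trial, the template of condition theta is the mean
#' population vector over all *other* trials of that condition; the trial is
#' assigned the condition whose template has the highest cosine similarity
#' to its population vector.  Similarity ties are broken uniformly at
#' random (deterministic under the caller's seed) and logged.  Trials or
#' templates with zero norm are skipped with a warning.
#'
#' `loo = FALSE` uses plain per-condition mean templates including the
#' held-out trial (single-template variant).
#'
#' @param vectors a `population_vectors` object.
#' @param loo leave-one-out templates (default `TRUE`).
#' @return object of class `decoder_result`: per-trial decoded labels,
#'   overall and per-condition accuracy, confusion matrix (rows = true),
#'   `kind = "template"`.
#' @export
template_decode <- function(vectors, loo = TRUE) {
  X <- vectors$X
  labels <- vectors$labels
  conds <- sort(unique(labels))
  if (any(table(labels) < 2L)) stop("at least 2 trials per condition required")
  n <- nrow(X)
  decoded <- rep(NA_real_, n)
  ties <- 0L
  for (t in seq_len(n)) {
    v <- X[t, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    sims <- vapply(conds, function(th) {
      idx <- which(labels == th)
      if (loo) idx <- setdiff(idx, t)
      tm <- colMeans(X[idx, , drop = FALSE])
      nt <- sqrt(sum(tm^2))
      if (nt == 0) return(NA_real_)
      sum(v * tm) / (nv * nt)
    }, numeric(1))
    if (all(is.na(sims))) next
    mx <- which(sims == max(sims, na.rm = TRUE))
    if (length(mx) > 1L) ties <- ties + 1L
    decoded[t] <- conds[if (length(mx) == 1L) mx else sample(mx, 1L)]
  }
  if (ties > 0L) message("template_decode: ", ties, " similarity tie(s) ",
                         "broken at random")
  used <- !is.na(decoded)
  if (any(!used)) warning(sum(!used), " trial(s) skipped (zero-norm vector)")
  finalize_decoder(decoded[used], labels[used], conds, "template")
}

finalize_decoder <- function(decoded, truth, conds, kind) {
  confusion <- table(factor(truth, levels = conds),
                     factor(decoded, levels = conds))
  per_cond <- vapply(conds, function(th) {
    idx <- truth == th
    if (!any(idx)) return(NA_real_)
    mean(decoded[idx] == th)
  }, numeric(1))
  names(per_cond) <- conds
  structure(list(decoded = decoded, truth = truth,
                 accuracy = mean(decoded == truth),
                 per_condition = per_cond,
                 confusion = unclass(confusion), kind = kind),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("%s decoder: accuracy %.3f over %d trials (%d conditions)\n",
              x$kind, x$accuracy, length(x$decoded),
              length(x$per_condition)))
  invisible(x)
}

#' Single-neuron Bayesian maximum-likelihood decoder (leave-one-out)
#'
#' For each held-out trial, the response distribution of the neuron for each
#' orientation is approximated as a Gaussian with the mean and SD of the
#' remaining trials of that orientation (SD floored at `sd_floor`); under a
#' uniform prior, the decoded orientation maximizes the Gaussian likelihood
#' of the held-out response.  Likelihood ties are broken uniformly at
#' random under the caller's seed.
#'
#' @param responses one neuron's trial-response rows (columns `orientation`,
#'   `response`); at least 3 trials per orientation.
#' @param sd_floor minimum likelihood SD, dF/F0 units (default 1e-6).
#' @return a `decoder_result` with `kind = "bayes"` (per-orientation
#'   accuracy in `per_condition`).
#' @export
bayes_decode <- function(responses, sd_floor = 1e-6) {
  oris <- sort(unique(responses$orientation))
  if (any(table(responses$orientation) < 3L)) {
    stop("at least 3 trials per orientation required")
  }
  r <- responses$response
  lab <- responses$orientation
  n <- length(r)
  decoded <- numeric(n)
  floored <- FALSE
  for (t in seq_len(n)) {
    ll <- vapply(oris, function(th) {
      train <- r[lab == th & seq_len(n) != t]
      s <- stats::sd(train)
      if (!is.finite(s) || s < sd_floor) {
        s <- sd_floor
        floored <<- TRUE
      }
      stats::dnorm(r[t], mean(train), s, log = TRUE)
    }, numeric(1))
    mx <- which(ll == max(ll))
    decoded[t] <- oris[if (length(mx) == 1L) mx else sample(mx, 1L)]
  }
  if (floored) message("bayes_decode: SD floor applied")
  finalize_decoder(decoded, lab, oris, "bayes")
}

#' Bayesian decoder summary across a population
#'
#' Runs [bayes_decode()] per neuron and averages the per-orientation
#' accuracies across neurons (the animal-level summary).  Neurons with
#' fewer than 3 trials in any orientation are skipped.
#'
#' @param responses trial-response table over neurons.
#' @param ... passed to [bayes_decode()].
#' @return list with `per_neuron` (data.frame: neuron, orientation,
#'   accuracy) and `per_orientation` (mean accuracy per orientation).
#' @export
bayes_decode_population <- function(responses, ...) {
  rows <- lapply(split(responses, responses$neuron), function(rs) {
    if (any(table(rs$orientation) < 3L)) return(NULL)
    res <- bayes_decode(rs, ...)
    data.frame(neuron = rs$neuron[1L],
               orientation = as.numeric(names(res$per_condition)),
               accuracy = as.numeric(res$per_condition))
  })
  per_neuron <- do.call(rbind, rows)
  per_orientation <- tapply(per_neuron$accuracy, per_neuron$orientation, mean)
  list(per_neuron = per_neuron,
       per_orientation = per_orientation)
}

#' Stimulus discriminability (d-prime) of one neuron
#'
#' d' = |mu_1 - mu_2| / sqrt((sigma_1^2 + sigma_2^2)/2) with sample means
#' and variances of the two conditions' trial responses.
#'
#' @param responses1,responses2 numeric trial responses for the two
#'   conditions (>= 2 trials each).
#' @return list with `mu1`, `mu2`, `var1`, `var2`, `dprime`.
#' @export
compute_dprime <- function(responses1, responses2) {
  if (length(responses1) < 2L || length(responses2) < 2L) {
    stop("at least 2 trials per condition required")
  }
  mu1 <- mean(responses1); mu2 <- mean(responses2)
  v1 <- stats::var(responses1); v2 <- stats::var(responses2)
  denom <- sqrt((v1 + v2) / 2)
  list(mu1 = mu1, mu2 = mu2, var1 = v1, var2 = v2,
       dprime = if (denom > 0) abs(mu1 - mu2) / denom else
         if (mu1 == mu2) 0 else Inf)
}
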
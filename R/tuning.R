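# Orientation selectivity via the circular-variance resultant vector on the
# doubled angle (gratings are axial: theta and theta + 180 are the same
# stimulus, so tuning lives on [0, 180) and the resultant uses exp(2i*theta)).

#' Orientation tuning curve of one neuron
#'
#' Mean responses R(theta_k) are trial averages of the baseline-corrected
#' responses; negative means are rectified to 0 before entering the
#' resultant vector sum(R exp(2i theta)) / sum(R), whose modulus is the peak
#' magnitude (= 1 - circular variance, in \[0, 1\]) and half-argument the
#' peak angle in \[0, 180).
#'
#' @param responses data.frame with columns `orientation`, `response` (the
#'   trials of one neuron), e.g. one neuron's rows from
#'   [extract_trial_responses()].
#' @return object of class `tuning_curve`: list with `orientations`,
#'   `mean_responses` (unrectified trial means), `resultant` (complex),
#'   `peak_angle`, `peak_magnitude`, `preferred` (orientation with maximal
#'   mean response; resultant-vector tie-break), `defined` (`FALSE` when all
#'   rectified means are 0).
#' @export
compute_tuning_curve <- function(responses) {
  oris <- sort(unique(responses$orientation))
  if (!all(table(responses$orientation) >= 1L)) {
    stop("at least one trial per orientation required")
  }
  R <- vapply(oris, function(o) {
    mean(responses$response[responses$orientation == o])
  }, numeric(1))
  Rr <- pmax(R, 0)
  tot <- sum(Rr)
  if (tot > 0) {
    resultant <- sum(Rr * exp(2i * oris * pi / 180)) / tot
    peak_angle <- (Arg(resultant) * 180 / pi / 2) %% 180
    peak_magnitude <- Mod(resultant)
    defined <- TRUE
  } else {
    resultant <- complex(real = NA_real_, imaginary = NA_real_)
    peak_angle <- NA_real_
    peak_magnitude <- NA_real_
    defined <- FALSE
  }
  # preferred = argmax of R(theta_k); ties broken by proximity of the
  # orientation to the resultant peak angle
  mx <- which(R == max(R))
  if (length(mx) > 1L && defined) {
    d <- abs(wrap_axial(oris[mx] - peak_angle))
    mx <- mx[which.min(d)]
  } else {
    mx <- mx[1L]
  }
  structure(list(orientations = oris, mean_responses = R,
                 resultant = resultant, peak_angle = peak_angle,
                 peak_magnitude = peak_magnitude, preferred = oris[mx],
                 defined = defined),
            class = "tuning_curve")
}

#' Tuning curves for every neuron in a trial-response table
#'
#' @param responses data.frame from [extract_trial_responses()].
#' @return named list of [compute_tuning_curve()] results, one per neuron.
#' @export
tuning_curves <- function(responses) {
  out <- lapply(split(responses, responses$neuron), compute_tuning_curve)
  out[order(as.numeric(names(out)))]
}

#' Selectivity threshold from the pre testing day
#'
#' The 25th percentile (linear interpolation) of the pre-day peak magnitudes
#' of one animal; the same threshold is applied to that animal's pre and
#' post days.
#'
#' @param pre_curves list of `tuning_curve` (the animal's pre-day neurons).
#' @param probs percentile, default 0.25.
#' @return magnitude threshold.
#' @export
pre_day_threshold <- function(pre_curves, probs = 0.25) {
  mags <- vapply(pre_curves, `[[`, numeric(1), "peak_magnitude")
  mags <- mags[is.finite(mags)]
  if (length(mags) < 4L) stop("at least 4 neurons required for the pre-day ",
                              "magnitude threshold")
  stats::quantile(mags, probs, names = FALSE, type = 7)
}

#' Two-criterion orientation-selectivity call
#'
#' A neuron is selective iff (i) its peak magnitude exceeds the pre-day
#' 25th-percentile threshold of its animal, and (ii) its trialwise responses
#' to the preferred orientation are significantly higher than to the
#' orthogonal orientation (Wilcoxon signed rank across trial pairs,
#' two-sided p < 0.05, with the preferred trial mean required to exceed the
#' orthogonal one).  Trials are paired by repetition index.  Fewer than 5
#' pairs make criterion (ii) untestable: the neuron is called not selective
#' and flagged.
#'
#' @param curve the neuron's [compute_tuning_curve()].
#' @param responses the neuron's trial-response rows.
#' @param threshold magnitude threshold from [pre_day_threshold()].
#' @param alpha significance level, default 0.05.
#' @return object of class `selectivity_call`: list with `preferred`,
#'   `peak_magnitude`, `criterion1`, `criterion2`, `p_value`,
#'   `is_selective`, `testable`.
#' @export
classify_selectivity <- function(curve, responses, threshold, alpha = 0.05) {
  pref <- curve$preferred
  orth <- (pref + 90) %% 180
  x <- responses$response[responses$orientation == pref]
  y <- responses$response[responses$orientation == orth]
  m <- min(length(x), length(y))
  testable <- m >= 5L
  if (testable) {
    p <- suppressWarnings(
      stats::wilcox.test(x[seq_len(m)], y[seq_len(m)], paired = TRUE,
                         exact = m <= 25L, correct = TRUE)$p.value)
    crit2 <- is.finite(p) && p < alpha && mean(x) > mean(y)
  } else {
    p <- NA_real_
    crit2 <- FALSE
  }
  crit1 <- isTRUE(curve$defined) && curve$peak_magnitude > threshold
  structure(list(preferred = pref, peak_magnitude = curve$peak_magnitude,
                 criterion1 = crit1, criterion2 = crit2, p_value = p,
                 is_selective = crit1 && crit2, testable = testable),
            class = "selectivity_call")
}

#' Selectivity table for one session
#'
#' Runs [compute_tuning_curve()] and [classify_selectivity()] for every
#' neuron of a trial-response table.
#'
#' @param responses data.frame from [extract_trial_responses()].
#' @param threshold pre-day magnitude threshold; when `NULL`, computed from
#'   these same responses (i.e. this session *is* the pre day).
#' @param alpha criterion-(ii) significance level.
#' @return data.frame: `neuron`, `preferred`, `peak_angle`,
#'   `peak_magnitude`, `p_value`, `criterion1`, `criterion2`,
#'   `is_selective`, `testable`.
#' @export
selectivity_table <- function(responses, threshold = NULL, alpha = 0.05) {
  by_neuron <- split(responses, responses$neuron)
  curves <- lapply(by_neuron, compute_tuning_curve)
  if (is.null(threshold)) threshold <- pre_day_threshold(curves)
  rows <- Map(function(cv, rs, id) {
    call <- classify_selectivity(cv, rs, threshold, alpha)
    data.frame(neuron = as.integer(id), preferred = call$preferred,
               peak_angle = cv$peak_angle,
               peak_magnitude = cv$peak_magnitude,
               p_value = call$p_value, criterion1 = call$criterion1,
               criterion2 = call$criterion2,
               is_selective = call$is_selective, testable = call$testable)
  }, curves, by_neuron, names(by_neuron))
  out <- do.call(rbind, rows)
  out <- out[order(out$neuron), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Reliability of orientation tuning (coefficient of variation)
#'
#' Trials are grouped into repetitions by repetition index (the j-th trial
#' of every orientation forms repetition j); each repetition yields a
#' single-trial tuning curve and its peak magnitude; the CV is the sample
#' SD over the mean of those magnitudes.  `method = "bootstrap"` instead
#' resamples trials within orientation (with replacement) `n_boot` times.
#'
#' @param responses one neuron's trial-response rows; equal trial counts per
#'   orientation are required for the repetition pairing.
#' @param method `"repetition"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 100).
#' @return list with `cv`, `magnitudes`, `defined` (`FALSE` when the mean
#'   magnitude is 0).
#' @export
compute_reliability_cv <- function(responses,
                                   method = c("repetition", "bootstrap"),
                                   n_boot = 100L) {
  method <- match.arg(method)
  by_ori <- split(responses$response, responses$orientation)
  oris <- as.numeric(names(by_ori))
  if (method == "repetition") {
    n_rep <- unique(lengths(by_ori))
    if (length(n_rep) != 1L) {
      stop("repetition pairing requires equal trial counts per orientation")
    }
    mags <- vapply(seq_len(n_rep), function(j) {
      r <- pmax(vapply(by_ori, `[[`, numeric(1), j), 0)
      if (sum(r) == 0) return(NA_real_)
      Mod(sum(r * exp(2i * oris * pi / 180)) / sum(r))
    }, numeric(1))
  } else {
    mags <- vapply(seq_len(n_boot), function(b) {
      r <- pmax(vapply(by_ori, function(v) mean(sample(v, replace = TRUE)),
                       numeric(1)), 0)
      if (sum(r) == 0) return(NA_real_)
      Mod(sum(r * exp(2i * oris * pi / 180)) / sum(r))
    }, numeric(1))
  }
  mags <- mags[is.finite(mags)]
  mu <- mean(mags)
  defined <- length(mags) >= 2L && mu > 0
  list(cv = if (defined) stats::sd(mags) / mu else NA_real_,
       magnitudes = mags, defined = defined)
}

index_or_na <- function(a, b) {
  if ((a + b) == 0) NA_real_ else (a - b) / (a + b)
}

#' Pre/post selectivity proportions and indices
#'
#' Computes, per day, the proportions of neurons selective for the
#' repetitive orientation (R_select), its orthogonal (O_select, shown only
#' on testing days), the angled grating's orthogonal (OA_select) and the
#' repetitive grating's orthogonal (OR_select, = O_select), and the
#' contrasts RO_index = (R - O)/(R + O) and O_index = (OA - OR)/(OA + OR),
#' plus the pre-to-post change delta_RO.  Proportions are relative to the
#' total neuron count.  Indices with zero denominator are `NA`.
#'
#' @param pre_calls,post_calls [selectivity_table()] data.frames.
#' @param repetitive_orientation degrees; the daily-repeated grating.
#' @param angled_orientation degrees; default `repetitive + 45`.
#' @return object of class `index_set`: data.frame of per-day proportions
#'   and indices with `delta_ro` attribute, plus list elements.
#' @export
compute_indices <- function(pre_calls, post_calls, repetitive_orientation,
                            angled_orientation =
                              (repetitive_orientation + 45) %% 180) {
  day_stats <- function(calls) {
    n <- nrow(calls)
    prop_sel <- function(ori) {
      sum(calls$is_selective & calls$preferred == ori) / n
    }
    r <- prop_sel(repetitive_orientation)
    o <- prop_sel((repetitive_orientation + 90) %% 180)
    oa <- prop_sel((angled_orientation + 90) %% 180)
    or <- o
    list(r_select = r, o_select = o, oa_select = oa, or_select = or,
         ro_index = index_or_na(r, o), o_index = index_or_na(oa, or))
  }
  pre <- day_stats(pre_calls)
  post <- day_stats(post_calls)
  structure(list(pre = pre, post = post,
                 delta_ro = post$ro_index - pre$ro_index,
                 delta_o = post$o_index - pre$o_index,
                 repetitive_orientation = repetitive_orientation),
            class = "index_set")
}

#' Population orientation shift between two days
#'
#' The population vector of each day is the mean of the per-neuron resultant
#' vectors (on the doubled-angle circle); the shift is the signed circular
#' difference of the two population peak angles, wrapped to (-90, 90\], with
#' positive sign meaning the post-day angle moved toward the repetitive
#' orientation.
#'
#' @param pre_curves,post_curves lists of `tuning_curve` (same neurons).
#' @param repetitive_orientation degrees.
#' @return shift in degrees.
#' @export
population_shift <- function(pre_curves, post_curves,
                             repetitive_orientation) {
  day_angle <- function(curves) {
    vs <- vapply(curves, `[[`, complex(1), "resultant")
    vs <- vs[is.finite(Re(vs))]
    if (!length(vs)) stop("population resultant undefined: no finite ",
                          "per-neuron resultants")
    v <- mean(vs)
    if (Mod(v) == 0) stop("population resultant undefined: zero mean vector")
    (Arg(v) * 180 / pi / 2) %% 180
  }
  a_pre <- day_angle(pre_curves)
  a_post <- day_angle(post_curves)
  delta <- wrap_axial(a_post - a_pre)
  d_pre <- abs(wrap_axial(repetitive_orientation - a_pre))
  d_post <- abs(wrap_axial(repetitive_orientation - a_post))
  if (d_post == d_pre) return(delta)
  abs(delta) * if (d_post < d_pre) 1 else -1
}

#' Pre-to-post cell-fate tracking
#'
#' Maps each neuron's (pre, post) selectivity pair to a fate: `remain`
#' (selective on both days), `gain` (selective post only), `lose`
#' (selective pre only), `nonselective` (neither).  When an orientation of
#' interest is given, "selective" additionally requires the preferred
#' orientation to equal it.  Proportions use the bases of the chronic
#' design: remain over pre-day selective neurons, gain over pre-day
#' nonselective neurons, lose over all neurons.
#'
#' @param pre_calls,post_calls [selectivity_table()] data.frames with
#'   matching neuron order.
#' @param orientation optional orientation of interest (degrees).
#' @return list with `fates` (data.frame: neuron, fate) and `proportions`
#'   (named numeric: remain, gain, lose).
#' @export
track_fate <- function(pre_calls, post_calls, orientation = NULL) {
  stopifnot(nrow(pre_calls) == nrow(post_calls),
            all(pre_calls$neuron == post_calls$neuron))
  sel <- function(calls) {
    if (is.null(orientation)) calls$is_selective
    else calls$is_selective & calls$preferred == orientation
  }
  pre <- sel(pre_calls)
  post <- sel(post_calls)
  fate <- ifelse(pre & post, "remain",
                 ifelse(!pre & post, "gain",
                        ifelse(pre & !post, "lose", "nonselective")))
  props <- c(
    remain = if (sum(pre) > 0) sum(fate == "remain") / sum(pre) else NA_real_,
    gain = if (sum(!pre) > 0) sum(fate == "gain") / sum(!pre) else NA_real_,
    lose = sum(fate == "lose") / length(fate))
  list(fates = data.frame(neuron = pre_calls$neuron, fate = fate),
       proportions = props)
}
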
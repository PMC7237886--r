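# Reward-responsive and corridor-responsive/selective neuron classification.

#' Classify reward-responsive neurons
#'
#' Responses are aligned to reward onset; for each reward the mean dF/F0 in
#' a 1-s window before the event (-2 s to -1 s from onset) is compared to
#' the mean in the 1-s window after onset (onset to +1 s) with a paired t
#' test across rewards.  A neuron is reward-responsive iff p < `alpha` and
#' the post-window mean exceeds the pre-window mean.  The peak response is
#' the maximum of the reward-triggered average trace within +/-2 s of
#' onset.  Rewards whose windows would run off the recording are skipped;
#' fewer than `min_rewards` usable rewards make the neuron unclassifiable.
#'
#' @param dff a `dff_trace`.
#' @param rewards reward onset frames (0-based).
#' @param alpha significance level, default 0.05.
#' @param min_rewards minimum usable rewards, default 5.
#' @return data.frame: `neuron`, `pre_mean`, `post_mean`, `p_value`,
#'   `is_reward_responsive`, `peak`, `n_rewards`, `classifiable`.
#' @export
classify_reward_responsive <- function(dff, rewards, alpha = 0.05,
                                       min_rewards = 5L) {
  fs <- dff$sampling_rate
  n_frames <- ncol(dff$dff)
  w1 <- sec_to_frames(1, fs)
  w2 <- sec_to_frames(2, fs)
  usable <- rewards[rewards - w2 >= 0L & rewards + w2 <= n_frames]
  if (length(usable) < length(rewards)) {
    warning(length(rewards) - length(usable),
            " reward(s) too close to the recording edges skipped")
  }
  neurons <- seq_len(nrow(dff$dff))
  classifiable <- dff$ok & rep(length(usable) >= min_rewards, length(neurons))
  out <- data.frame(neuron = neurons, pre_mean = NA_real_,
                    post_mean = NA_real_, p_value = NA_real_,
                    is_reward_responsive = FALSE, peak = NA_real_,
                    n_rewards = length(usable),
                    classifiable = classifiable)
  if (!any(classifiable)) return(out)
  for (i in neurons[classifiable]) {
    tr <- dff$dff[i, ]
    pre <- vapply(usable, function(rf) {
      mean(tr[(rf - w2 + 1L):(rf - w1)])   # [-2 s, -1 s) before onset
    }, numeric(1))
    post <- vapply(usable, function(rf) {
      mean(tr[(rf + 1L):(rf + w1)])        # [onset, +1 s)
    }, numeric(1))
    p <- tryCatch(stats::t.test(post, pre, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
    avg <- rowMeans(vapply(usable, function(rf) {
      tr[(rf - w2 + 1L):(rf + w2)]
    }, numeric(2L * w2)))
    out$pre_mean[i] <- mean(pre)
    out$post_mean[i] <- mean(post)
    out$p_value[i] <- p
    out$is_reward_responsive[i] <- is.finite(p) && p < alpha &&
      mean(post) > mean(pre)
    out$peak[i] <- max(avg)
  }
  out
}

#' Classify corridor-responsive and corridor-selective neurons
#'
#' For each corridor, per-trial spatial means are taken in two 25-cm blocks
#' around the reward-zone onset: R_pre over \[-35, -10) cm before it (late
#' grating segment) and R_post over \[0, 25) cm after it (reward zone,
#' stimulus absent).  A neuron is responsive to a corridor iff R_pre is
#' significantly greater than R_post across trials (Wilcoxon signed rank,
#' p < `alpha`, direction required) — its activity drops where the visual
#' stimulus disappears.  Corridor-selective neurons are responsive to
#' exactly one of the presented corridors.  Trials in which the animal does
#' not traverse both blocks are dropped with a warning.
#'
#' @param dff a `dff_trace`.
#' @param session a VR [session_bundle()] with position stream; corridor
#'   identity of each trial is its grating epoch's orientation.
#' @param alpha significance level, default 0.001.
#' @return list with `per_corridor` (data.frame: neuron, corridor, r_pre,
#'   r_post, p_value, responsive) and `calls` (data.frame: neuron,
#'   n_responsive, corridor_selective).
#' @export
classify_corridor_responsive <- function(dff, session, alpha = 0.001) {
  if (is.null(session$position)) stop("session has no position stream")
  if (is.null(session$corridor)) stop("session has no corridor geometry")
  ep <- session$epochs
  gr <- ep[ep$phase == "moving" & !is.na(ep$trial), ]
  bz <- ep[ep$phase == "black_zone" & !is.na(ep$trial), ]
  pos <- session$position
  keep <- which(dff$ok)
  corridors <- sort(unique(gr$orientation))
  dropped <- 0L
  per_cor <- list()
  for (cor in corridors) {
    trials <- gr$trial[gr$orientation == cor]
    pre_m <- list(); post_m <- list()
    for (tr in trials) {
      span <- c(min(gr$onset_frame[gr$trial == tr]),
                max(c(gr$offset_frame[gr$trial == tr],
                      bz$offset_frame[bz$trial == tr])))
      fr <- span[1]:(span[2] - 1L)
      p <- pos[fr + 1L]
      # reward-zone onset of THIS trial's corridor: position where the
      # black-walled zone begins
      bz_on <- bz$onset_frame[bz$trial == tr]
      rz <- if (length(bz_on)) pos[min(bz_on) + 1L] else
        session$corridor$reward_zone_start
      pre_idx <- fr[p >= rz - 35 & p < rz - 10]
      post_idx <- fr[p >= rz & p < rz + 25]
      if (!length(pre_idx) || !length(post_idx)) {
        dropped <- dropped + 1L
        next
      }
      pre_m[[length(pre_m) + 1L]] <-
        rowMeans(dff$dff[keep, pre_idx + 1L, drop = FALSE])
      post_m[[length(post_m) + 1L]] <-
        rowMeans(dff$dff[keep, post_idx + 1L, drop = FALSE])
    }
    if (!length(pre_m)) next
    P <- do.call(cbind, pre_m)    # neurons x trials
    Q <- do.call(cbind, post_m)
    for (j in seq_along(keep)) {
      x <- P[j, ]; y <- Q[j, ]
      p_val <- if (length(x) >= 5L) suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE)$p.value) else NA_real_
      per_cor[[length(per_cor) + 1L]] <- data.frame(
        neuron = keep[j], corridor = cor,
        r_pre = mean(x), r_post = mean(y), p_value = p_val,
        responsive = is.finite(p_val) && p_val < alpha && mean(x) > mean(y))
    }
  }
  if (dropped > 0L) {
    warning(dropped, " trial(s) dropped: block not traversed")
  }
  per_corridor <- do.call(rbind, per_cor)
  n_resp <- tapply(per_corridor$responsive, per_corridor$neuron, sum)
  calls <- data.frame(neuron = as.integer(names(n_resp)),
                      n_responsive = as.integer(n_resp),
                      corridor_selective = as.integer(n_resp) == 1L &
                        length(corridors) > 1L)
  list(per_corridor = per_corridor, calls = calls)
}
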
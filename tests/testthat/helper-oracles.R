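# Independent brute-force oracles for the decoders (deliberately separate
# code paths from the package implementations).

# leave-one-out cosine classifier, plain loops
brute_template <- function(X, labels) {
  conds <- sort(unique(labels))
  vapply(seq_len(nrow(X)), function(t) {
    best <- -Inf; lab <- NA_real_
    for (th in conds) {
      idx <- setdiff(which(labels == th), t)
      tm <- colMeans(X[idx, , drop = FALSE])
      s <- sum(X[t, ] * tm) / sqrt(sum(X[t, ]^2) * sum(tm^2))
      if (s > best) { best <- s; lab <- th }
    }
    lab
  }, numeric(1))
}

# leave-one-out Gaussian-density comparison, plain loops
brute_bayes <- function(r, lab, floor = 1e-6) {
  oris <- sort(unique(lab))
  vapply(seq_along(r), function(t) {
    best <- -Inf; out <- NA_real_
    for (th in oris) {
      tr <- r[lab == th & seq_along(r) != t]
      s <- max(sd(tr), floor)
      d <- dnorm(r[t], mean(tr), s, log = TRUE)
      if (d > best) { best <- d; out <- th }
    }
    out
  }, numeric(1))
}
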
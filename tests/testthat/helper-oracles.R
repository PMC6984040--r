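# Independent oracles and small fixtures shared across tests.

# Exponential-time recursive DTW oracle, straight from the cost recursion
# (no dynamic programming), for short series only.
dtw_oracle <- function(x, y, metric = c("abs", "squared")) {
  metric <- match.arg(metric)
  d <- function(a, b) if (metric == "abs") abs(a - b) else (a - b)^2
  rec <- function(k, j) {
    if (k == 1 && j == 1) return(d(x[1], y[1]))
    best <- Inf
    if (k > 1) best <- min(best, rec(k - 1, j))
    if (k > 1 && j > 1) best <- min(best, rec(k - 1, j - 1))
    if (j > 1) best <- min(best, rec(k, j - 1))
    d(x[k], y[j]) + best
  }
  rec(length(x), length(y))
}

# Binary Matthews correlation coefficient from a 2x2 confusion table
# (rows = truth, cols = prediction).
mcc_binary <- function(m) {
  tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Dense noise-free sinusoid panel: N phase-shifted copies of one sinusoid
# sampled over whole periods, optionally under the monotone warp
# phi(t) = t + a sin(t).
sinusoid_series <- function(deltas, n_time = 300, periods = 1, warp_a = 0) {
  t <- seq(0, 2 * pi * periods, length.out = n_time + 1)[seq_len(n_time)]
  phi <- t + warp_a * sin(t)
  X <- t(vapply(deltas, function(d) cos(phi - d), numeric(n_time)))
  rownames(X) <- sprintf("ROI%02d", seq_along(deltas))
  X
}

# Noise-free generator settings used by ordering / closed-form probes.
quiet_params <- function(n_subjects = 1, n_rois = 8, n_time = 300,
                         seed = 1, ...) {
  synthetic_params(n_subjects = n_subjects, n_rois = n_rois,
                   n_time = n_time, seed = seed,
                   noise_sd = 0, reparam_strength = 0, global_amp = 0,
                   signature_strength = 0, ...)
}

relative_frobenius <- function(a, b) {
  norm(unclass(a) - unclass(b), "F") / norm(unclass(b), "F")
}
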
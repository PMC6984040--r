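#' Zero-lag Pearson correlation matrix
#'
#' @param series ROI x time matrix with non-constant rows.
#' @return Symmetric correlation matrix of class `"fi_corr"` with unit
#'   diagonal.
#' @export
correlation_matrix <- function(series) {
  stopifnot(is.matrix(series))
  sds <- apply(series, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant row(s): ",
                 paste(rownames(series)[sds == 0] %||% which(sds == 0),
                       collapse = ", ")))
  }
  C <- cor(t(series))
  dimnames(C) <- list(rownames(series), rownames(series))
  structure(C, class = c("fi_corr", "matrix", "array"))
}

#' Lagged cross-correlation: extremal correlation and time-delay matrices
#'
#' For every ROI pair the cross-correlation is evaluated at integer lags
#' \eqn{\tau \in [-L, L]} over the overlapping segment. The extremum is the
#' lag maximizing \eqn{|r|}; the signed correlation there is stored in the
#' lagged correlation matrix (LCM) and the lag, in seconds, in the
#' time-delay matrix (TDM). The TDM sign convention matches the lead
#' matrix: `tdm[k, l] > 0` when ROI `l` follows (is delayed relative to)
#' ROI `k`, and `tdm[l, k] = -tdm[k, l]`. Ties in \eqn{|r|} are broken
#' toward the smaller \eqn{|\tau|}, and at an exact tie between lags of
#' equal size (pure sinusoids a quarter period apart tie at \eqn{\pm\tau}
#' with opposite signs) toward the positively correlated lag. Optional
#' parabolic interpolation
#' refines the extremal lag with a 3-point parabola around the discrete
#' peak, addressing delays below the sampling interval.
#'
#' @param series ROI x time matrix.
#' @param max_lag Maximum lag in samples (default 5, i.e. 10 s at TR = 2 s;
#'   must be below `n_time / 4`).
#' @param tr Sampling interval in seconds (scales the TDM).
#' @param interpolate `"none"` or `"parabolic"`.
#' @return A list of class `"fi_lagged"`: `lcm` (symmetric, unit diagonal)
#'   and `tdm` (antisymmetric, seconds, zero diagonal).
#' @export
lagged_correlation <- function(series, max_lag = 5, tr = 2,
                               interpolate = c("none", "parabolic")) {
  interpolate <- match.arg(interpolate)
  stopifnot(is.matrix(series))
  n <- ncol(series); N <- nrow(series)
  if (max_lag < 0 || max_lag >= n / 4) {
    abort("max_lag must be a non-negative integer below n_time / 4")
  }
  lags <- -max_lag:max_lag
  # visit lags in order of increasing |tau| so strict-improvement search
  # breaks ties toward the smaller |tau|
  lag_order <- lags[order(abs(lags), lags)]
  lcm <- diag(1, N); tdm <- matrix(0, N, N)
  for (k in seq_len(N - 1)) {
    for (l in (k + 1):N) {
      x <- series[k, ]; y <- series[l, ]
      rr <- setNames(numeric(length(lags)), as.character(lags))
      for (tau in lags) {
        if (tau >= 0) {
          rr[as.character(tau)] <- cor(x[1:(n - tau)], y[(1 + tau):n])
        } else {
          rr[as.character(tau)] <- cor(x[(1 - tau):n], y[1:(n + tau)])
        }
      }
      best <- lag_order[1]; best_r <- rr[as.character(best)]
      tol <- 1e-12
      for (tau in lag_order[-1]) {
        r_tau <- rr[as.character(tau)]
        # strict improvement in |r| wins; at an exact |r| tie (e.g. pure
        # sinusoids, where +tau and -tau tie with opposite signs) prefer
        # the positively correlated lag
        if (abs(r_tau) > abs(best_r) + tol ||
            (abs(abs(r_tau) - abs(best_r)) <= tol && r_tau > best_r + tol)) {
          best <- tau; best_r <- r_tau
        }
      }
      tau_star <- best
      if (interpolate == "parabolic" && abs(best) < max_lag) {
        y0 <- abs(rr[as.character(best)])
        ym <- abs(rr[as.character(best - 1)])
        yp <- abs(rr[as.character(best + 1)])
        denom <- ym - 2 * y0 + yp
        if (denom < 0) tau_star <- best + 0.5 * (ym - yp) / denom
      }
      lcm[k, l] <- lcm[l, k] <- unname(best_r)
      tdm[k, l] <- tau_star * tr
      tdm[l, k] <- -tau_star * tr
    }
  }
  dimnames(lcm) <- dimnames(tdm) <- list(rownames(series), rownames(series))
  structure(list(lcm = lcm, tdm = tdm, max_lag = max_lag, tr = tr),
            class = "fi_lagged")
}
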
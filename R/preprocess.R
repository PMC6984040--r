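#' Preprocessing configuration for feature extraction
#'
#' Fixes the conditioning applied to each ROI x time record before feature
#' extraction, in the order: global signal regression (optional) ->
#' mean-centering and linear detrending -> end-matching (cyclicity path
#' only) -> scaling -> band-pass filtering (optional).
#'
#' @param do_gsr Regress out the across-ROI mean time course?
#' @param filter_band `NULL` for no filtering, or `c(low, high)` in Hz.
#'   The study baseline is `c(0.008, 0.08)`; the alternative `c(0.008, 0.2)`.
#' @param filter_order Order of the analog Bessel low-pass prototype.
#' @param scaling One of `"quadratic_variation"` (sum of squared successive
#'   differences scaled to 1), `"norm"` (sum of squares to 1) or `"std"`
#'   (sample standard deviation to 1).
#' @param zero_phase Apply the filter forward-backward (zero phase)? A causal
#'   pass would leave a frequency-dependent phase that distorts lag-sensitive
#'   features (lead matrix, time-delay matrix), so this defaults to `TRUE`.
#' @return A list of class `"fi_preprocess_config"`.
#' @export
preprocess_config <- function(do_gsr = FALSE,
                              filter_band = NULL,
                              filter_order = 4,
                              scaling = c("quadratic_variation", "norm", "std"),
                              zero_phase = TRUE) {
  scaling <- match.arg(scaling)
  if (!is.null(filter_band)) {
    if (length(filter_band) != 2 || filter_band[1] <= 0 ||
        filter_band[2] <= filter_band[1]) {
      abort("filter_band must be c(low, high) with 0 < low < high")
    }
  }
  structure(list(do_gsr = do_gsr, filter_band = filter_band,
                 filter_order = as.integer(filter_order), scaling = scaling,
                 zero_phase = zero_phase),
            class = "fi_preprocess_config")
}

#' Mean-center and linearly detrend each ROI row
#'
#' Removes, per row, the least-squares straight line in time, leaving zero
#' mean and zero best-fit slope. Constant rows become all-zero rows (with a
#' warning naming them).
#'
#' @param series ROI x time numeric matrix.
#' @return Matrix of the same shape.
#' @export
mean_center_detrend <- function(series) {
  stopifnot(is.matrix(series), ncol(series) >= 3)
  n <- ncol(series)
  tt <- seq_len(n)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  const_rows <- apply(series, 1, function(r) all(r == r[1]))
  if (any(const_rows)) {
    warn(paste0("constant rows detrended to zero: ",
                paste(rownames(series)[const_rows] %||%
                        which(const_rows), collapse = ", ")))
  }
  slopes <- (series %*% tc) / denom
  out <- series - rowMeans(series) - slopes %*% rbind(tc)
  dimnames(out) <- dimnames(series)
  out
}

#' Scale each ROI row by one of three normalizations
#'
#' @param series ROI x time matrix.
#' @param method `"quadratic_variation"` scales so the discrete quadratic
#'   variation (sum of squared successive differences) is 1; `"norm"` scales
#'   the sum of squares to 1; `"std"` scales the sample standard deviation
#'   to 1.
#' @return Scaled matrix.
#' @export
scale_rows <- function(series,
                       method = c("quadratic_variation", "norm", "std")) {
  method <- match.arg(method)
  stopifnot(is.matrix(series))
  denom <- switch(method,
    quadratic_variation = sqrt(rowSums(t(diff(t(series)))^2)),
    norm = sqrt(rowSums(series^2)),
    std = apply(series, 1, sd)
  )
  bad <- which(denom == 0)
  if (length(bad)) {
    abort(paste0("cannot scale row(s) with zero ", method, ": ",
                 paste(rownames(series)[bad] %||% bad, collapse = ", ")))
  }
  out <- series / denom
  dimnames(out) <- dimnames(series)
  out
}

#' End-match each ROI row by removing a linear ramp
#'
#' Subtracts from each row the line through its first and last samples minus
#' the first sample's value, so first and last samples become equal and the
#' path (viewed pairwise against any other end-matched row) closes. This is
#' the closure step the signed-area lead matrix requires. Idempotent.
#'
#' @param series ROI x time matrix.
#' @return End-matched matrix: `out[, 1] == out[, n]` per row.
#' @export
end_match <- function(series) {
  stopifnot(is.matrix(series), ncol(series) >= 2)
  n <- ncol(series)
  ramp <- (series[, n] - series[, 1]) %*% rbind((seq_len(n) - 1) / (n - 1))
  out <- series - ramp
  dimnames(out) <- dimnames(series)
  out
}

# ---- Bessel band-pass design -------------------------------------------

# Poles of the order-n analog Bessel low-pass prototype, frequency-scaled so
# the -3 dB point sits at omega = 1 rad/s. The prototype is the reverse
# Bessel polynomial theta_n(s); its -3 dB frequency is found numerically.
bessel_prototype <- function(order) {
  # reverse Bessel polynomial coefficients a_k = (2n-k)! / (2^(n-k) k! (n-k)!)
  k <- 0:order
  coefs <- factorial(2 * order - k) /
    (2^(order - k) * factorial(k) * factorial(order - k))
  p <- polyroot(coefs)  # ascending-degree coefficients
  gain_at <- function(w) {
    Mod(Re(prod(-p)) / prod(complex(imaginary = w) - p))
  }
  w3 <- stats::uniroot(function(w) gain_at(w) - 1 / sqrt(2),
                       c(1e-3, 10 * order))$root
  p / w3
}

# Digital band-pass Bessel filter as an Arma, via analog LP prototype ->
# analog band-pass (signal::sftrans) -> bilinear transform with prewarped
# band edges.
design_bessel_bandpass <- function(band, order, tr) {
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq) {
    abort(paste0("high cutoff ", band[2], " Hz >= Nyquist ", nyq, " Hz"))
  }
  p <- bessel_prototype(order)
  T <- tr
  warped <- 2 / T * tan(pi * band * T)  # prewarp analog edges
  zpg <- signal::Zpg(zero = numeric(0), pole = p, gain = Re(prod(-p)))
  bp <- signal::sftrans(zpg, W = warped, stop = FALSE)
  signal::as.Arma(signal::bilinear(bp, T = T))
}

#' Zero-phase Bessel band-pass filter for ROI time series
#'
#' Band-passes each row with a digital Bessel filter (analog prototype
#' designed from the reverse Bessel polynomial, transformed to a band-pass
#' and discretized by the prewarped bilinear transform). By default the
#' filter runs forward and backward ([signal::filtfilt()]) so the overall
#' response has zero phase and relative timing between ROIs -- which the
#' lead and time-delay matrices measure -- is preserved.
#'
#' @param series ROI x time matrix.
#' @param band `c(low, high)` cutoff frequencies in Hz.
#' @param order Analog prototype order (default 4).
#' @param tr Sampling interval in seconds.
#' @param zero_phase Forward-backward application (default) or single
#'   causal pass.
#' @return Filtered matrix.
#' @export
bandpass_bessel <- function(series, band = c(0.008, 0.08), order = 4, tr = 2,
                            zero_phase = TRUE) {
  stopifnot(is.matrix(series))
  arma <- design_bessel_bandpass(band, order, tr)
  out <- t(apply(series, 1, function(x) {
    if (zero_phase) signal::filtfilt(arma, x) else signal::filter(arma, x)
  }))
  dimnames(out) <- dimnames(series)
  out
}

# Magnitude response of the designed digital filter at frequency f (Hz);
# squared when the filter is applied forward-backward.
bessel_bandpass_gain <- function(f, band, order, tr, zero_phase = TRUE) {
  arma <- design_bessel_bandpass(band, order, tr)
  vapply(f, function(fi) {
    z <- exp(complex(imaginary = 2 * pi * fi * tr))
    g <- Mod(sum(arma$b * z^-(seq_along(arma$b) - 1)) /
               sum(arma$a * z^-(seq_along(arma$a) - 1)))
    if (zero_phase) g^2 else g
  }, numeric(1))
}

#' Global signal regression
#'
#' The global signal is the across-ROI mean time course. Each ROI row is
#' replaced by its least-squares residual against an intercept and the
#' global signal, so every output row is exactly orthogonal to the global
#' signal. If the global signal is constant only the intercept is removed
#' (with a warning).
#'
#' @param series ROI x time matrix with at least 2 rows.
#' @return Residual matrix of the same shape.
#' @export
global_signal_regress <- function(series) {
  stopifnot(is.matrix(series), nrow(series) >= 2)
  g <- colMeans(series)
  if (sd(g) == 0) {
    warn("global signal is constant; regressing intercept only")
    out <- series - rowMeans(series)
  } else {
    X <- cbind(1, g)
    # residual maker applied to each row: r = y - X (X'X)^-1 X' y
    coefs <- solve(crossprod(X), crossprod(X, t(series)))
    out <- series - t(X %*% coefs)
  }
  dimnames(out) <- dimnames(series)
  out
}

#' Run the full preprocessing pipeline over a panel
#'
#' Applies, per record and in this order: GSR (if enabled) -> mean-centering
#' and detrending -> end-matching (only when `feature_kind = "lm"`, the
#' cyclicity path, where end-matching must precede scaling) -> scaling ->
#' band-pass filtering (if enabled). The applied sequence is recorded in the
#' panel's `provenance` attribute. Pure function of its inputs.
#'
#' @param panel An `"fi_panel"`.
#' @param config An `"fi_preprocess_config"`.
#' @param feature_kind Which feature the series are destined for: `"lm"`
#'   (lead matrix; forces end-matching), `"cm"`, `"lcm"` or `"dm"`.
#' @return The preprocessed panel.
#' @export
preprocess_panel <- function(panel, config = preprocess_config(),
                             feature_kind = c("lm", "cm", "lcm", "dm")) {
  stopifnot(inherits(panel, "fi_panel"),
            inherits(config, "fi_preprocess_config"))
  feature_kind <- match.arg(feature_kind)
  tr <- attr(panel, "tr")
  steps <- character()
  if (config$do_gsr) steps <- c(steps, "gsr")
  steps <- c(steps, "center_detrend")
  if (feature_kind == "lm") steps <- c(steps, "end_match")
  steps <- c(steps, paste0("scale:", config$scaling))
  if (!is.null(config$filter_band)) {
    steps <- c(steps, paste0("bandpass:", config$filter_band[1], "-",
                             config$filter_band[2], "Hz",
                             if (config$zero_phase) ":zero_phase" else ""))
  }
  arma <- if (!is.null(config$filter_band)) {
    design_bessel_bandpass(config$filter_band, config$filter_order, tr)
  }
  panel$series <- lapply(panel$series, function(X) {
    if (config$do_gsr) X <- global_signal_regress(X)
    X <- mean_center_detrend(X)
    if (feature_kind == "lm") X <- end_match(X)
    X <- scale_rows(X, config$scaling)
    if (!is.null(arma)) {
      X <- t(apply(X, 1, function(x) {
        if (config$zero_phase) signal::filtfilt(arma, x)
        else signal::filter(arma, x)
      }))
      rownames(X) <- attr(panel, "roi_names")
    }
    X
  })
  attr(panel, "provenance") <- c(attr(panel, "provenance"), steps)
  panel
}
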
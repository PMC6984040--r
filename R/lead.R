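#' Signed-area lead matrix of a multivariate time series
#'
#' Cyclicity analysis assigns to every ordered pair of ROI series the signed
#' algebraic area enclosed by their closed planar trajectory,
#' \deqn{A_{kl} = \tfrac12 \oint (x_k\, dx_l - x_l\, dx_k),}
#' collecting all pairs into a skew-symmetric lead matrix. The sign is
#' oriented so that \eqn{A_{kl} > 0} when ROI `l` follows ROI `k`: for unit
#' sinusoids with `l` delayed by phase \eqn{\varphi \in (0, \pi)} over one
#' period, \eqn{A_{kl} = \pi \sin\varphi}. The discrete integral is the
#' shoelace rule over the closed polygon, including the segment closing the
#' last sample back to the first -- exact for polygonal paths.
#'
#' Because the integrand is a closed-loop 1-form, the lead matrix is
#' invariant to monotone time re-parameterizations (up to discretization)
#' and to adding constants to end-matched rows.
#'
#' @param series ROI x time matrix. Rows must be end-matched (first sample
#'   equals last) unless `end_matched = FALSE`, in which case end-matching
#'   is applied internally.
#' @param end_matched Declare the input already end-matched (checked), or
#'   `FALSE` to end-match internally.
#' @return An object of class `"fi_lead"`: the skew-symmetric matrix with
#'   ROI dimnames.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 301)[1:300]
#' X <- rbind(cos(2 * pi * t), cos(2 * pi * t - pi / 4))
#' lead_matrix(X, end_matched = FALSE)[1, 2]  # ~ pi * sin(pi/4)
lead_matrix <- function(series, end_matched = TRUE) {
  stopifnot(is.matrix(series), ncol(series) >= 3)
  if (end_matched) {
    gap <- max(abs(series[, 1] - series[, ncol(series)]))
    scale <- max(abs(series), 1e-12)
    if (gap > 1e-8 * scale) {
      abort(paste0("series is not end-matched (max first/last gap ",
                   format(gap), "); end-match it or pass end_matched = FALSE"))
    }
  } else {
    series <- end_match(series)
  }
  n <- ncol(series)
  Xs <- series[, c(2:n, 1), drop = FALSE]  # cyclic left shift closes the loop
  A <- (series %*% t(Xs) - Xs %*% t(series)) / 2
  A <- (A - t(A)) / 2  # kill numerical asymmetry
  dimnames(A) <- list(rownames(series), rownames(series))
  structure(A, class = c("fi_lead", "matrix", "array"))
}

#' Spectral analysis of a lead matrix
#'
#' Eigen-decomposes the skew-symmetric lead matrix. Its eigenvalues are
#' purely imaginary and come in conjugate pairs; the phase angles of the
#' components of the eigenvector belonging to the largest-magnitude
#' eigenvalue encode the collective temporal ordering of the ROIs. The
#' eigenvector of the eigenvalue with the largest positive imaginary part is
#' taken and rotated so the first component has phase zero (phases are
#' defined only up to a global rotation).
#'
#' @param lm A lead matrix (from [lead_matrix()] or any skew-symmetric
#'   matrix).
#' @return A list of class `"fi_spectrum"`: `eigenvalues` (complex, sorted
#'   by descending magnitude), `leading_eigenvector` (complex), `phases`
#'   (radians in `[0, 2*pi)`), `degenerate` flag.
#' @export
cyclicity_spectrum <- function(lm) {
  A <- unclass(lm)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  skew <- max(abs(A + t(A)))
  if (skew > 1e-10 * max(abs(A), 1e-300)) {
    abort("input is not skew-symmetric")
  }
  if (all(A == 0)) {
    return(structure(list(
      eigenvalues = complex(real = rep(0, nrow(A))),
      leading_eigenvector = complex(real = rep(0, nrow(A))),
      phases = rep(NA_real_, nrow(A)), degenerate = TRUE
    ), class = "fi_spectrum"))
  }
  e <- eigen(A)
  ord <- order(Mod(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  # leading pair: among the largest-magnitude conjugate pair, take the
  # member with positive imaginary part (fixes the ordering direction)
  lead_mag <- Mod(vals[1])
  cand <- which(Mod(e$values) > lead_mag * (1 - 1e-9) & Im(e$values) > 0)
  if (length(cand) == 0) cand <- which.max(Mod(e$values))
  i <- cand[1]
  v <- e$vectors[, i]
  ref <- if (Mod(v[1]) > 1e-12 * max(Mod(v))) v[1] else v[which.max(Mod(v))]
  v <- v * Conj(ref) / Mod(ref)  # rotate reference component to phase 0
  phases <- Arg(v) %% (2 * pi)
  structure(list(eigenvalues = vals, leading_eigenvector = v,
                 phases = phases, degenerate = FALSE),
            class = "fi_spectrum")
}

#' Recover the cyclic temporal ordering from a cyclicity spectrum
#'
#' Sorts ROIs by the phase angles of the leading eigenvector. The result is
#' a cyclic order: any rotation of it is equivalent (compare with
#' [cyclic_equal()]).
#'
#' @param spec An `"fi_spectrum"` from [cyclicity_spectrum()].
#' @param tie_tol Phases closer than this (radians) are flagged as tied.
#' @return Integer vector of ROI indices in recovered cyclic order; carries
#'   attribute `ties = TRUE` when near-equal phases were present.
#' @export
recover_ordering <- function(spec, tie_tol = 1e-9) {
  stopifnot(inherits(spec, "fi_spectrum"))
  if (isTRUE(spec$degenerate)) {
    abort("degenerate (all-zero) spectrum: no ordering to recover")
  }
  ord <- order(spec$phases)
  ties <- any(diff(sort(spec$phases)) < tie_tol)
  if (ties) warn("near-equal eigenvector phases; tied ROIs ordered by index")
  structure(ord, ties = ties)
}
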
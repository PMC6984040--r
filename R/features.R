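#' Vectorize the upper triangle of a feature matrix
#'
#' Symmetric and skew-symmetric feature matrices carry `N(N-1)/2`
#' independent entries; machine-learning stages operate on this row-major
#' upper-triangle vector (528 entries for the 33-ROI design).
#'
#' @param m Square numeric matrix.
#' @return Numeric vector of length `N(N-1)/2` in row-major order:
#'   (1,2), (1,3), ..., (1,N), (2,3), ...
#' @seealso [matricize_upper()]
#' @export
vectorize_upper <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("matrix must be square")
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a feature matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] given the matrix kind: symmetric kinds
#' mirror the triangle; skew-symmetric kinds negate it below the diagonal.
#'
#' @param v Vector of length `N(N-1)/2`.
#' @param kind `"symmetric"` or `"skew"`.
#' @param diag Diagonal value (1 for correlation kinds, 0 otherwise).
#' @return N x N matrix.
#' @export
matricize_upper <- function(v, kind = c("symmetric", "skew"), diag = 0) {
  kind <- match.arg(kind)
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) {
    abort("length of v is not N(N-1)/2 for integer N")
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- if (kind == "symmetric") m + t(m) else m - t(m)
  diag(m) <- diag
  m
}

#' Compute a feature matrix of one kind for every record of a panel
#'
#' The panel is preprocessed per the configuration (the lead-matrix path
#' additionally end-matches before scaling) and the requested feature is
#' extracted per record:
#' \describe{
#'   \item{`"lm"`}{skew-symmetric signed-area lead matrix ([lead_matrix()]);}
#'   \item{`"cm"`}{zero-lag Pearson correlation ([correlation_matrix()]);}
#'   \item{`"lcm"`}{extremal lagged correlation; the time-delay matrix rides
#'     along in a `tdm` list-column ([lagged_correlation()]);}
#'   \item{`"dm"`}{all-pairs dynamic time warping distance ([dtw_matrix()]).}
#' }
#'
#' @param panel An `"fi_panel"` (raw; preprocessing happens here).
#' @param kind Feature kind: `"lm"`, `"cm"`, `"lcm"` or `"dm"`.
#' @param config An `"fi_preprocess_config"`.
#' @param max_lag,interpolate Passed to [lagged_correlation()] for
#'   `kind = "lcm"`.
#' @param window Passed to [dtw_matrix()] for `kind = "dm"`.
#' @return A tibble of class `"fi_features"` with the panel's id columns and
#'   a `feature` list-column of matrices (plus `tdm` for `"lcm"`); the kind
#'   and preprocessing provenance are carried as attributes.
#' @export
#' @examples
#' p <- synthetic_params(n_subjects = 2, n_rois = 6, n_time = 100, seed = 3)
#' feats <- compute_features(make_panel(p), "cm")
#' dim(feats$feature[[1]])
compute_features <- function(panel, kind = c("lm", "cm", "lcm", "dm"),
                             config = preprocess_config(),
                             max_lag = 5, interpolate = "none",
                             window = NULL) {
  kind <- match.arg(kind)
  pp <- preprocess_panel(panel, config, feature_kind = kind)
  tr <- attr(panel, "tr")
  feats <- lapply(pp$series, function(X) {
    switch(kind,
      lm  = lead_matrix(X, end_matched = is.null(config$filter_band)),
      cm  = correlation_matrix(X),
      lcm = lagged_correlation(X, max_lag = max_lag, tr = tr,
                               interpolate = interpolate),
      dm  = dtw_matrix(X, window = window)
    )
  })
  out <- pp
  out$series <- NULL
  if (kind == "lcm") {
    out$feature <- lapply(feats, function(f) f$lcm)
    out$tdm <- lapply(feats, function(f) f$tdm)
  } else {
    out$feature <- lapply(feats, function(f) unclass(f))
  }
  structure(as_tibble(out),
            kind = kind, tr = tr,
            roi_names = attr(panel, "roi_names"),
            provenance = attr(pp, "provenance"),
            class = c("fi_features", class(tibble())))
}

#' Feature vectors (upper triangles) for every record of a feature set
#'
#' @param features An `"fi_features"` tibble.
#' @return The same tibble with the `feature` list-column replaced by a
#'   `vector` list-column of upper-triangle vectors.
#' @export
feature_vectors <- function(features) {
  stopifnot(inherits(features, "fi_features"))
  features$vector <- lapply(features$feature, vectorize_upper)
  features
}
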
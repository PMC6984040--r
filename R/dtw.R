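#' Dynamic time warping distance between two series
#'
#' Computes the DTW distance by the standard dynamic-programming recursion
#' \deqn{C_{kj} = d_{kj} + \min(C_{(k-1)j}, C_{(k-1)(j-1)}, C_{k(j-1)}),}
#' with \eqn{C_{11} = d_{11}} and boundary accumulation along the first row
#' and column, where \eqn{d_{kj}} is the local distance between samples.
#' The warping path is the backtracked index sequence; it is monotone and
#' continuous, and for identical series it is the diagonal. For scalar
#' samples the Euclidean local distance reduces to the absolute difference,
#' the default.
#'
#' @param x,y Numeric vectors (lengths may differ, each >= 1).
#' @param local_metric `"abs"` (default) or `"squared"` per-sample distance.
#' @param window `NULL` for unconstrained alignment (the default), or an
#'   integer Sakoe-Chiba band half-width in samples.
#' @return A list with `distance` (non-negative scalar) and `path`
#'   (two-column integer matrix of aligned indices).
#' @export
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 3))$distance  # 1 under the |.| metric
dtw_distance <- function(x, y, local_metric = c("abs", "squared"),
                         window = NULL) {
  local_metric <- match.arg(local_metric)
  if (length(x) < 1 || length(y) < 1) abort("empty series")
  metric <- match(local_metric, c("abs", "squared")) - 1L
  w <- if (is.null(window)) -1L else as.integer(window)
  res <- .dtw_dp(as.numeric(x), as.numeric(y), metric, w)
  colnames(res$path) <- c("x", "y")
  res
}

#' All-pairs DTW distance matrix over the rows of a series matrix
#'
#' Each unordered ROI pair is aligned once; the result is symmetric with a
#' zero diagonal.
#'
#' @param series ROI x time matrix.
#' @inheritParams dtw_distance
#' @return Symmetric non-negative matrix of class `"fi_dtw"`.
#' @export
dtw_matrix <- function(series, local_metric = c("abs", "squared"),
                       window = NULL) {
  local_metric <- match.arg(local_metric)
  stopifnot(is.matrix(series))
  metric <- match(local_metric, c("abs", "squared")) - 1L
  w <- if (is.null(window)) -1L else as.integer(window)
  D <- .dtw_all_pairs(series, metric, w)
  dimnames(D) <- list(rownames(series), rownames(series))
  structure(D, class = c("fi_dtw", "matrix", "array"))
}
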
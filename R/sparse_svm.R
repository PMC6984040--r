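# Upper-triangle index -> ROI pair map (row-major, matching
# vectorize_upper()).
pair_index_map <- function(n_rois, roi_names = NULL) {
  idx <- which(upper.tri(matrix(0, n_rois, n_rois)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- tibble(index = seq_len(nrow(idx)),
                roi_i = idx[, 1], roi_j = idx[, 2])
  if (!is.null(roi_names)) {
    out$name_i <- roi_names[out$roi_i]
    out$name_j <- roi_names[out$roi_j]
  }
  out
}

# Proximal subgradient descent for the L1-regularized hinge-loss SVM:
# minimize mean(max(0, 1 - t(Xw + b))) + lambda * ||w||_1.
l1_hinge_fit <- function(X, t, lambda, iters = 2000, lr = 0.1) {
  n <- nrow(X); d <- ncol(X)
  w <- numeric(d); b <- 0
  for (it in seq_len(iters)) {
    eta <- lr / sqrt(it)
    margins <- t * (drop(X %*% w) + b)
    viol <- margins < 1
    if (any(viol)) {
      gw <- -drop(crossprod(X[viol, , drop = FALSE], t[viol])) / n
      gb <- -sum(t[viol]) / n
    } else {
      gw <- numeric(d); gb <- 0
    }
    w <- w - eta * gw
    # soft-thresholding (proximal step for the L1 term)
    w <- sign(w) * pmax(abs(w) - eta * lambda, 0)
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

#' Sparse L1-regularized linear SVM and salience selection
#'
#' Minimizes the hinge loss \eqn{\ell(y) = \max(0, 1 - t\,y)} with
#' \eqn{y = w \cdot x + b} plus an \eqn{\ell_1} penalty
#' \eqn{\lambda \lVert w \rVert_1}, trading margin for sparsity so the
#' non-zero weight components single out the ROI-pair interactions that
#' dominate the separating hyperplane. Fitted by proximal subgradient
#' descent (soft-thresholding after each hinge subgradient step). The
#' support is mapped back to ROI pairs through the row-major upper-triangle
#' index map, yielding a salience graph.
#'
#' @param vectors Standardized matrix (samples x `N(N-1)/2` dims).
#' @param labels Two-class label vector.
#' @param lambda L1 strength (> 0), or `NULL` to choose it by 5-fold
#'   cross-validation on a logarithmic grid within the training data.
#' @param positive_class Label coded +1.
#' @param roi_names Optional ROI names for the salience graph.
#' @param support_tol Weights with `|w| <=` this are treated as zero.
#' @param iters,lr Optimizer iterations and base learning rate.
#' @return An `"fi_sparse_svm"` model with fields `w`, `b`, `lambda`,
#'   `support` (indices) and `graph` (tibble of ROI-pair edges with
#'   `weight = |w|`); predict with [predict.fi_sparse_svm()].
#' @export
sparse_svm_select <- function(vectors, labels, lambda = NULL,
                              positive_class = "patient", roi_names = NULL,
                              support_tol = 1e-6, iters = 2000, lr = 0.1) {
  X <- as.matrix(vectors)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) abort("sparse SVM needs exactly 2 classes")
  if (!positive_class %in% classes) positive_class <- classes[2]
  t_ <- ifelse(labels == positive_class, 1, -1)
  if (!is.null(lambda) && lambda <= 0) abort("lambda must be > 0")
  if (is.null(lambda)) {
    lambda <- cv_lambda(X, t_, iters = max(400, iters %/% 4), lr = lr)
  }
  fit <- l1_hinge_fit(X, t_, lambda, iters = iters, lr = lr)
  support <- which(abs(fit$w) > support_tol)
  n <- (1 + sqrt(1 + 8 * ncol(X))) / 2
  graph <- NULL
  if (abs(n - round(n)) < 1e-9) {
    map <- pair_index_map(as.integer(round(n)), roi_names)
    graph <- dplyr::mutate(map[support, , drop = FALSE],
                           weight = abs(fit$w[support]))
  }
  structure(list(w = fit$w, b = fit$b, lambda = lambda, support = support,
                 graph = graph, positive_class = positive_class,
                 negative_class = setdiff(classes, positive_class)),
            class = "fi_sparse_svm")
}

# 5-fold CV over a log-spaced lambda grid; picks the sparsest lambda within
# one-SE of the best mean accuracy
cv_lambda <- function(X, t_, grid = 10^seq(-3, 0, length.out = 7),
                      folds = 5, iters = 400, lr = 0.1) {
  n <- nrow(X)
  fold_id <- rep(seq_len(folds), length.out = n)[sample.int(n)]
  acc <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(t_[tr])) < 2 || length(unique(t_[!tr])) < 2) next
    for (g in seq_along(grid)) {
      fit <- l1_hinge_fit(X[tr, , drop = FALSE], t_[tr], grid[g],
                          iters = iters, lr = lr)
      pred <- sign(drop(X[!tr, , drop = FALSE] %*% fit$w) + fit$b)
      pred[pred == 0] <- 1
      acc[f, g] <- mean(pred == t_[!tr])
    }
  }
  mu <- colMeans(acc, na.rm = TRUE)
  se <- apply(acc, 2, sd, na.rm = TRUE) / sqrt(folds)
  best <- which.max(mu)
  ok <- which(mu >= mu[best] - se[best])
  grid[max(ok)]  # largest lambda (sparsest) within one SE
}

#' @rdname sparse_svm_select
#' @param object An `"fi_sparse_svm"` model.
#' @param newdata Matrix of samples (same standardization as training).
#' @param ... Unused.
#' @export
predict.fi_sparse_svm <- function(object, newdata, ...) {
  dec <- drop(as.matrix(newdata) %*% object$w) + object$b
  ifelse(dec >= 0, object$positive_class, object$negative_class)
}

#' @export
print.fi_sparse_svm <- function(x, ...) {
  cat("<fi_sparse_svm> lambda = ", format(x$lambda), ", |support| = ",
      length(x$support), " of ", length(x$w), "\n", sep = "")
  invisible(x)
}
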
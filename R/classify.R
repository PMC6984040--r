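#' Monte Carlo cross-validation splits at the subject level
#'
#' Draws `n_reps` independent train/test partitions of the subjects,
#' deterministic given the seed. Splitting is by subject -- all of a
#' subject's records fall on one side, so visits/runs never straddle the
#' split. The train size is `floor(train_frac * n)`; stratified splits
#' allocate `floor(train_frac * n_c)` per class and hand remaining slots to
#' the classes with the largest fractional parts, preserving the class
#' ratio within one subject.
#'
#' @param labels Named vector: subject id -> class label.
#' @param n_reps Number of repetitions (default 100).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param stratified Preserve class proportions in each split?
#' @return List of `n_reps` lists with `train` and `test` subject-id
#'   vectors; every rep has both classes on both sides (non-stratified
#'   draws violating this are redrawn, with a message).
#' @export
mc_splits <- function(labels, n_reps = 100, train_frac = 0.7, seed = 1,
                      stratified = TRUE) {
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0,1)")
  classes <- unique(labels)
  if (length(classes) < 2) abort("need >= 2 classes")
  subjects <- names(labels)
  n <- length(subjects)
  n_train <- floor(train_frac * n)
  with_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      repeat {
        if (stratified) {
          per_class <- table(labels)[as.character(classes)]
          raw <- train_frac * as.numeric(per_class)
          take <- floor(raw)
          extra <- n_train - sum(take)
          if (extra > 0) {
            ord <- order(raw - take, decreasing = TRUE)
            take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
          }
          train <- unlist(lapply(seq_along(classes), function(ci) {
            pool <- subjects[labels == classes[ci]]
            sample(pool, take[ci])
          }), use.names = FALSE)
        } else {
          train <- sample(subjects, n_train)
        }
        test <- setdiff(subjects, train)
        ok <- length(unique(labels[train])) == length(classes) &&
          length(unique(labels[test])) == length(classes)
        if (ok) break
        inform("redrawing split: a class was absent from train or test")
      }
      list(train = sort(train), test = sort(test))
    })
  })
}

#' Fit a standardizer on training data and apply it
#'
#' Per-dimension Z-scoring `(x - mu) / sigma` with parameters estimated on
#' the training rows only; zero-variance dimensions are dropped with a
#' warning.
#'
#' @param train,test Numeric matrices (rows = samples).
#' @return List with standardized `train`, `test`, and the `mu`, `sigma`,
#'   `keep` parameters.
#' @export
standardize_fit <- function(train, test = NULL) {
  mu <- colMeans(train)
  sigma <- apply(train, 2, sd)
  keep <- sigma > 0
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " zero-variance dimension(s)"))
  }
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sigma[keep], "/")
  te <- if (!is.null(test)) {
    sweep(sweep(test[, keep, drop = FALSE], 2, mu[keep]), 2,
          sigma[keep], "/")
  }
  list(train = tr, test = te, mu = mu, sigma = sigma, keep = keep)
}

#' PCA projection fit on training data only
#'
#' Components are fit on the training rows; test rows are projected with
#' the training parameters (no leakage).
#'
#' @param train,test Numeric matrices.
#' @param n_components Dimensions to keep (10 for the discriminant path,
#'   20 for the SVM path in the reference design).
#' @return List with projected `train`, `test`, the `rotation`, `center`
#'   and per-component `explained` variance fractions.
#' @export
pca_fit_transform <- function(train, test = NULL, n_components) {
  if (n_components > min(nrow(train), ncol(train))) {
    abort("n_components exceeds what the training data can support")
  }
  pc <- prcomp(train, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  tr <- pc$x[, seq_len(n_components), drop = FALSE]
  te <- if (!is.null(test)) {
    sweep(test, 2, pc$center) %*% rot
  }
  list(train = tr, test = te, rotation = rot, center = pc$center,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Gaussian discriminant classifier (LDA or QDA)
#'
#' Thin wrapper over the standard shared-covariance (LDA) or per-class
#' covariance (QDA) Gaussian classifiers, intended to run on PCA-reduced
#' input. A singular covariance triggers a ridge-style retry: a small
#' scaled jitter is added to the training matrix, with a warning.
#'
#' @param train Matrix of training samples (rows).
#' @param labels Factor/character class labels.
#' @param kind `"lda"` or `"qda"`.
#' @return An `"fi_da"` model; predict with [predict.fi_da()].
#' @export
fit_discriminant <- function(train, labels, kind = c("lda", "qda")) {
  kind <- match.arg(kind)
  fit_fun <- if (kind == "lda") MASS::lda else MASS::qda
  labels <- factor(labels)
  model <- tryCatch(fit_fun(train, grouping = labels), error = function(e) e)
  eps <- 1e-6 * mean(apply(train, 2, sd))
  tries <- 0
  while (inherits(model, "error") && tries < 3) {
    tries <- tries + 1
    warn(paste0(kind, " covariance singular; retrying with jitter epsilon = ",
                format(eps)))
    jit <- train + matrix(rnorm(length(train), sd = eps), nrow(train))
    model <- tryCatch(fit_fun(jit, grouping = labels), error = function(e) e)
    eps <- eps * 10
  }
  if (inherits(model, "error")) stop(model)
  structure(list(model = model, kind = kind), class = "fi_da")
}

#' @rdname fit_discriminant
#' @param object An `"fi_da"` model.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @export
predict.fi_da <- function(object, newdata, ...) {
  as.character(predict(object$model, newdata)$class)
}

#' Soft-margin kernel support vector machine
#'
#' Wrapper over the standard C-SVM with the three kernels of the reference
#' design: linear, quadratic (polynomial of degree 2) and Gaussian (RBF).
#' Input should be standardized and PCA-reduced upstream.
#'
#' @param train Matrix of training samples.
#' @param labels Class labels (2 classes required).
#' @param kernel `"linear"`, `"quadratic"` or `"rbf"`.
#' @param C Soft-margin cost.
#' @return An `"fi_svm"` model; predict with [predict.fi_svm()].
#' @export
fit_svm <- function(train, labels, kernel = c("linear", "quadratic", "rbf"),
                    C = 1) {
  kernel <- match.arg(kernel)
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("training data contains a single class")
  model <- switch(kernel,
    linear = e1071::svm(train, labels, kernel = "linear", cost = C,
                        scale = FALSE),
    quadratic = e1071::svm(train, labels, kernel = "polynomial", degree = 2,
                           coef0 = 1, cost = C, scale = FALSE),
    rbf = e1071::svm(train, labels, kernel = "radial", cost = C,
                     scale = FALSE)
  )
  structure(list(model = model, kernel = kernel), class = "fi_svm")
}

#' @rdname fit_svm
#' @param object An `"fi_svm"` model.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @export
predict.fi_svm <- function(object, newdata, ...) {
  as.character(predict(object$model, newdata))
}

#' Classification rates from predicted and true labels
#'
#' Sensitivity is `TP / (TP + FN)` with the patient group as the positive
#' class (clinical convention); specificity is `TN / (TN + FP)`.
#'
#' @param preds,truth Aligned label vectors.
#' @param positive_class Label treated as positive (default `"patient"`).
#' @return One-row tibble: sensitivity, specificity, accuracy, balanced
#'   accuracy. A class absent from `truth` yields `NA` for its rate.
#' @export
evaluate_predictions <- function(preds, truth, positive_class = "patient") {
  if (length(preds) != length(truth)) abort("length mismatch")
  pos <- truth == positive_class
  sens <- if (any(pos)) mean(preds[pos] == positive_class) else NA_real_
  spec <- if (any(!pos)) mean(preds[!pos] != positive_class) else NA_real_
  tibble(sensitivity = sens, specificity = spec,
         accuracy = mean(preds == truth),
         balanced_accuracy = mean(c(sens, spec)))
}

# classifier registry used by run_mccv; each entry fits on reduced training
# data and predicts test labels
fit_predict_classical <- function(classifier, tr, te, y_tr, C = 1) {
  model <- switch(classifier,
    lda = fit_discriminant(tr, y_tr, "lda"),
    qda = fit_discriminant(tr, y_tr, "qda"),
    svm_linear = fit_svm(tr, y_tr, "linear", C),
    svm_quadratic = fit_svm(tr, y_tr, "quadratic", C),
    svm_rbf = fit_svm(tr, y_tr, "rbf", C),
    abort(paste0("unknown classifier: ", classifier))
  )
  predict(model, te)
}

#' Monte Carlo cross-validated group classification
#'
#' Runs the full per-repetition pipeline on subject-level feature vectors:
#' subject-stratified split -> standardization fit on the training fold ->
#' PCA fit on the training fold (10 components for `lda`/`qda`, 20 for the
#' SVM kernels, following the reference design) -> fit -> evaluation on the
#' held-out fold. Every learned transform sees training subjects only.
#'
#' @param vectors Matrix (subjects x dims) with subject-id rownames.
#' @param labels Named vector subject id -> class.
#' @param classifier One of `"lda"`, `"qda"`, `"svm_linear"`,
#'   `"svm_quadratic"`, `"svm_rbf"`, `"sparse_svm"`.
#' @param n_reps,train_frac,seed,stratified Split parameters ([mc_splits()]).
#' @param n_components PCA dimension; `NULL` picks 10 for discriminant and
#'   20 for SVM classifiers (capped by fold size).
#' @param C Soft-margin cost for the kernel SVMs.
#' @param lambda L1 strength for `"sparse_svm"` (`NULL` = nested CV).
#' @param positive_class Positive label for sensitivity.
#' @return An `"fi_classification"` object: per-rep rates, their summary,
#'   and the configuration.
#' @export
run_mccv <- function(vectors, labels, classifier = "svm_linear",
                     n_reps = 100, train_frac = 0.7, seed = 1,
                     stratified = TRUE, n_components = NULL, C = 1,
                     lambda = NULL, positive_class = "patient") {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  labels <- labels[rownames(vectors)]
  splits <- mc_splits(labels, n_reps, train_frac, seed, stratified)
  if (is.null(n_components)) {
    n_components <- if (classifier %in% c("lda", "qda")) 10 else 20
  }
  seeds <- with_seed(seed, fan_seeds(seed, n_reps))
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sp <- splits[[r]]
    tr_raw <- vectors[sp$train, , drop = FALSE]
    te_raw <- vectors[sp$test, , drop = FALSE]
    y_tr <- labels[sp$train]; y_te <- labels[sp$test]
    preds <- with_seed(seeds[r], {
      if (classifier == "sparse_svm") {
        std <- standardize_fit(tr_raw, te_raw)
        m <- sparse_svm_select(std$train, y_tr, lambda = lambda,
                               positive_class = positive_class)
        predict(m, std$test)
      } else {
        std <- standardize_fit(tr_raw, te_raw)
        k <- min(n_components, nrow(std$train) - 1, ncol(std$train))
        red <- pca_fit_transform(std$train, std$test, k)
        fit_predict_classical(classifier, red$train, red$test, y_tr, C)
      }
    })
    dplyr::mutate(evaluate_predictions(preds, y_te, positive_class), rep = r)
  })
  summ <- dplyr::summarise(per_rep, dplyr::across(
    c("sensitivity", "specificity", "accuracy", "balanced_accuracy"),
    list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))))
  structure(list(per_rep = per_rep, summary = summ, classifier = classifier,
                 n_reps = n_reps, positive_class = positive_class),
            class = "fi_classification")
}

#' @export
print.fi_classification <- function(x, ...) {
  cat("<fi_classification> ", x$classifier, ", ", x$n_reps, " MC reps\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
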
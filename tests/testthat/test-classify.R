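test_that("MC splits have contracted sizes, determinism and stratification", {
  labels <- setNames(rep(c("patient", "control"), c(50, 29)),
                     sprintf("S%03d", 1:79))
  sp <- mc_splits(labels, n_reps = 20, train_frac = 0.7, seed = 1)
  expect_length(sp, 20)
  for (s in sp) {
    expect_length(s$train, 55)  # floor(0.7 * 79)
    expect_length(s$test, 24)
    expect_length(intersect(s$train, s$test), 0)
    # stratification: class ratio preserved within one subject
    expect_equal(sum(labels[s$train] == "patient"), 35, tolerance = 1)
  }
  sp2 <- mc_splits(labels, n_reps = 20, train_frac = 0.7, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- mc_splits(labels, n_reps = 20, train_frac = 0.7, seed = 2)
  expect_false(identical(sp, sp3))
})

test_that("PCA transform is train-fitted, ordered and reconstructive", {
  set.seed(20)
  basis <- matrix(rnorm(10 * 3), 10, 3)
  scores <- matrix(rnorm(40 * 3), 40, 3)
  X <- scores %*% t(basis)  # exactly 3-dimensional data
  red <- pca_fit_transform(X[1:30, ], X[31:40, ], 3)
  recon <- red$train %*% t(red$rotation)
  recon <- sweep(recon, 2, -red$center)
  expect_equal(recon, X[1:30, ], tolerance = 1e-8)
  expect_true(all(diff(red$explained) <= 1e-12))
  expect_error(pca_fit_transform(X[1:5, ], NULL, 50), "n_components")
})

test_that("discriminant analysis separates what it should and QDA wins on scale", {
  set.seed(21)
  make_blobs <- function(n, gap) {
    X <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2) + gap, n, 2))
    list(X = X, y = rep(c("a", "b"), each = n))
  }
  tr <- make_blobs(40, 6); te <- make_blobs(40, 6)
  m <- fit_discriminant(tr$X, tr$y, "lda")
  expect_gt(mean(predict(m, te$X) == te$y), 0.95)
  # identical class distributions: accuracy compatible with chance
  tr0 <- make_blobs(60, 0); te0 <- make_blobs(60, 0)
  m0 <- fit_discriminant(tr0$X, tr0$y, "lda")
  acc0 <- mean(predict(m0, te0$X) == te0$y)
  expect_lt(abs(acc0 - 0.5), 2 * sqrt(0.25 / 120) * 2.5)
  # classes differing only in covariance scale: QDA beats LDA on average
  wins <- replicate(30, {
    Xa <- matrix(rnorm(40 * 2, sd = 1), 40, 2)
    Xb <- matrix(rnorm(40 * 2, sd = 3), 40, 2)
    y <- rep(c("a", "b"), each = 40)
    Xte <- rbind(matrix(rnorm(30 * 2, sd = 1), 30, 2),
                 matrix(rnorm(30 * 2, sd = 3), 30, 2))
    yte <- rep(c("a", "b"), each = 30)
    q <- mean(predict(fit_discriminant(rbind(Xa, Xb), y, "qda"), Xte) == yte)
    l <- mean(predict(fit_discriminant(rbind(Xa, Xb), y, "lda"), Xte) == yte)
    q - l
  })
  expect_gt(mean(wins), 0)
})

test_that("kernel SVMs behave per the classic separations", {
  set.seed(22)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2) + 5, n, 2))
  y <- rep(c("a", "b"), each = n)
  m <- fit_svm(X, y, "linear")
  expect_equal(mean(predict(m, X) == y), 1)
  # XOR layout: linear fails, RBF succeeds
  xor_data <- function(n) {
    q <- sample(1:4, n, replace = TRUE)
    cx <- c(-2, 2, -2, 2)[q]; cy <- c(-2, -2, 2, 2)[q]
    list(X = cbind(cx + rnorm(n, sd = 0.4), cy + rnorm(n, sd = 0.4)),
         y = ifelse(q %in% c(1, 4), "a", "b"))
  }
  tr <- xor_data(200); te <- xor_data(200)
  lin <- mean(predict(fit_svm(tr$X, tr$y, "linear"), te$X) == te$y)
  rbf <- mean(predict(fit_svm(tr$X, tr$y, "rbf"), te$X) == te$y)
  # a linear cut can recover at most 3 of the 4 XOR corners (~0.75)
  expect_lt(lin, 0.85)
  expect_gt(rbf, 0.9)
  expect_gt(rbf - lin, 0.1)
  # vanishing C degenerates toward one class
  weak <- fit_svm(X, y, "linear", C = 1e-6)
  expect_gte(max(table(predict(weak, X))) / nrow(X), 0.5)
  expect_error(fit_svm(X[1:40, ], rep("a", 40), "linear"), "single class")
})

test_that("classification rates come out of the confusion counts", {
  expect_equal(evaluate_predictions(c("patient", "control"),
                                    c("patient", "control"))$sensitivity, 1)
  r <- evaluate_predictions(rep("patient", 10),
                            rep(c("patient", "control"), 5))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0)
  # confusion [[40,10],[5,45]] with patient-first rows
  preds <- c(rep("patient", 40), rep("control", 10),
             rep("patient", 5), rep("control", 45))
  truth <- rep(c("patient", "control"), c(50, 50))
  r2 <- evaluate_predictions(preds, truth)
  expect_equal(r2$sensitivity, 0.8)
  expect_equal(r2$specificity, 0.9)
})

test_that("sparse SVM finds single-coordinate separations and goes empty", {
  set.seed(23)
  n <- 40; d <- 15
  X <- matrix(rnorm(2 * n * d), 2 * n, d)
  X[1:n, 7] <- X[1:n, 7] + 4  # classes differ only in coordinate 7
  X <- scale(X)
  y <- rep(c("patient", "control"), each = n)
  m <- sparse_svm_select(X, y, lambda = 0.25)
  expect_equal(m$support, 7L)
  expect_gt(mean(predict(m, X) == y), 0.95)
  # huge lambda empties the support
  m0 <- sparse_svm_select(X, y, lambda = 50)
  expect_length(m0$support, 0)
  expect_error(sparse_svm_select(X, y, lambda = -1), "lambda")
  # support size is non-increasing in lambda
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.5, 2),
                  function(l) length(sparse_svm_select(X, y,
                                                       lambda = l)$support),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("MC-CV classification calibrates on shuffled labels", {
  set.seed(24)
  n <- 40
  V <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  labels <- setNames(rep(c("patient", "control"), each = n / 2),
                     rownames(V))  # labels independent of features
  for (clf in c("lda", "svm_linear")) {
    rep_out <- run_mccv(V, labels, clf, n_reps = 30, seed = 7,
                        n_components = 5)
    # reps reuse the same 40 subjects, so the mean does not concentrate
    # like independent draws; 0.15 is ~1 single-rep SD around chance
    expect_lt(abs(rep_out$summary$accuracy_mean - 0.5), 0.15)
  }
})
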
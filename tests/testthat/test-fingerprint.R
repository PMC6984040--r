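test_that("R_K reduces to binary MCC and handles degenerate tables", {
  expect_equal(rk_coefficient(diag(7) * 3), 1)
  m <- rbind(c(40, 10), c(5, 45))
  expect_equal(rk_coefficient(m), mcc_binary(m), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:200) {
    m <- matrix(sample(0:50, 4, replace = TRUE), 2, 2)
    if (sum(m) == 0) next
    expect_equal(rk_coefficient(m), mcc_binary(m), tolerance = 1e-12)
  }
  # all mass in one predicted column: zero by convention
  expect_equal(rk_coefficient(rbind(c(10, 0), c(10, 0))), 0)
  expect_error(rk_coefficient(rbind(c(-1, 2), c(0, 3))), "negative")
})

test_that("1-NN identification is exact on identical or permuted vectors", {
  set.seed(15)
  V <- matrix(rnorm(6 * 20), 6, 20,
              dimnames = list(sprintf("S%02d", 1:6), NULL))
  fp <- one_nn_identify(V, V)
  expect_equal(fp$accuracy, 1)
  expect_equal(fp$rk, 1)
  # a known label permutation shows up as that permutation matrix
  perm <- c(2, 3, 1, 5, 6, 4)
  V2 <- V[perm, ]
  rownames(V2) <- rownames(V)
  d <- one_nn_identify(V, V2)$directions$visit1_to_visit2
  expect_equal(unname(d$confusion), diag(6)[perm, ], ignore_attr = TRUE)
  expect_equal(sum(d$confusion), 6)
  expect_equal(unname(diag(d$confusion)), rep(0, 6))
  # cosine scale invariance: positive rescaling changes nothing
  fp_scaled <- one_nn_identify(V * 17, V2 * 0.01)
  fp_plain <- one_nn_identify(V, V2)
  expect_identical(fp_scaled$directions$visit1_to_visit2$confusion,
                   fp_plain$directions$visit1_to_visit2$confusion)
  expect_error(one_nn_identify(rbind(a = c(0, 0)), rbind(a = c(1, 1))),
               "zero")
})

test_that("strong subject signatures give high cross-visit accuracy", {
  p <- synthetic_params(n_subjects = 12, n_rois = 12, n_time = 150,
                        signature_strength = 1.2, noise_sd = 0.2,
                        seed = 16)
  panel <- make_panel(p)
  fp <- fingerprint_panel(panel, "lm")
  expect_gte(fp$accuracy, 0.9)
  fp_cm <- fingerprint_panel(panel, "cm")
  expect_gte(fp_cm$accuracy, 0.9)
})

test_that("GSR robustness distances obey the cosine geometry", {
  p <- synthetic_params(n_subjects = 3, n_rois = 8, n_time = 100, seed = 17)
  panel <- make_panel(p)
  f1 <- compute_features(panel, "cm", preprocess_config(do_gsr = TRUE))
  d0 <- gsr_robustness(f1, f1)
  expect_equal(d0$distance, rep(0, nrow(d0)))
  # negated and orthogonal vectors via direct construction
  f2 <- f1
  f2$feature <- lapply(f1$feature, function(m) {
    m2 <- -unclass(m); diag(m2) <- 1; m2
  })
  d2 <- gsr_robustness(f1, f2)
  expect_equal(d2$distance, rep(2, nrow(d2)), tolerance = 1e-12)
  f0 <- compute_features(panel, "cm", preprocess_config(do_gsr = FALSE))
  dg <- gsr_robustness(f1, f0)
  expect_true(all(dg$distance >= 0 & dg$distance <= 2))
})

test_that("robustness comparison calibrates under the null and sees effects", {
  set.seed(18)
  # null: identically distributed groups keep p above 0.05 most of the time
  rejections <- vapply(1:60, function(i) {
    g <- split(rnorm(60), rep(1:3, each = 20))
    compare_robustness(g)$kruskal$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.10)
  # power: two groups 5 pooled SDs apart are flagged after correction
  g <- list(a = rnorm(30), b = rnorm(30) + 5)
  res <- compare_robustness(g)
  expect_lt(res$pairwise$p_adj[1], 0.01)
  expect_error(compare_robustness(list(a = rnorm(5))), "2 groups")
  expect_warning(compare_robustness(list(a = rnorm(5), b = 1, c = rnorm(5))),
                 "dropping")
})

test_that("the stability sweep covers the full preprocessing grid", {
  p <- synthetic_params(n_subjects = 5, n_rois = 8, n_time = 120,
                        signature_strength = 1.2, noise_sd = 0.2, seed = 19)
  panel <- make_panel(p)
  tbl <- stability_sweep(panel, feature_kinds = c("lm", "cm"),
                         bands = list(NULL, c(0.008, 0.08)),
                         gsr = c(FALSE, TRUE))
  expect_equal(nrow(tbl), 2 * 2 * 2)
  expect_true(all(tbl$accuracy >= 1 / 5 - 1e-9))
  full_grid <- tidyr::expand_grid(feature = c("lm", "cm"),
                                  gsr = c(FALSE, TRUE),
                                  band = c("none", "0.008-0.08"))
  expect_setequal(paste(tbl$feature, tbl$gsr, tbl$band),
                  paste(full_grid$feature, full_grid$gsr, full_grid$band))
})
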
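test_that("noise-free single-harmonic panel is an exact sampled sinusoid", {
  p <- synthetic_params(
    n_subjects = 1, n_rois = 4, n_time = 200, tr = 2,
    driver_harmonics = cbind(freq = 0.02, amp = 1),
    phase_offsets = c(0, pi / 2, pi, 3 * pi / 2),
    noise_sd = 0, signature_strength = 0, reparam_strength = 0,
    global_amp = 0, seed = 5)
  panel <- make_panel(p)
  X <- panel$series[[1]]
  t_grid <- (0:199) * 2
  for (k in 1:4) {
    expected <- cos(2 * pi * 0.02 * t_grid - p$phase_offsets[k])
    expect_equal(X[k, ], expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("generation is deterministic and has the contracted shape", {
  p <- synthetic_params(n_subjects = 5, n_rois = 6, n_time = 80, seed = 42)
  a <- make_panel(p)
  b <- make_panel(p)
  expect_identical(a$series, b$series)
  expect_equal(nrow(a), 10)  # 5 subjects x 2 visits x 1 run
  expect_true(all(vapply(a$series, function(m) all(dim(m) == c(6, 80)),
                         logical(1))))
  expect_true(all(is.finite(unlist(a$series))))
  # both visits present for every subject
  expect_true(all(table(a$subject_id, a$visit_id) == 1))
})

test_that("subject signatures are visit-stable in the deterministic limit", {
  p <- synthetic_params(n_subjects = 3, n_rois = 5, n_time = 60,
                        noise_sd = 0, reparam_strength = 0, global_amp = 0,
                        signature_strength = 0.8, seed = 9)
  panel <- make_panel(p)
  for (s in unique(panel$subject_id)) {
    v1 <- panel$series[[which(panel$subject_id == s & panel$visit_id == 1)]]
    v2 <- panel$series[[which(panel$subject_id == s & panel$visit_id == 2)]]
    expect_identical(v1, v2)
  }
  # distinct subjects still differ (signatures are per subject)
  expect_gt(max(abs(panel$series[[1]] - panel$series[[3]])), 1e-3)
})

test_that("non-monotone warp requests are rejected with a diagnostic", {
  expect_error(synthetic_params(reparam_strength = 1.0), "non-monotone")
  expect_error(synthetic_params(reparam_strength = 1.7), "non-monotone")
  p <- synthetic_params(n_subjects = 1, n_rois = 3, n_time = 50,
                        reparam_strength = 0.95, seed = 2)
  expect_true(check_warp_monotone(p))
})

test_that("planted ordering sorts by phase offset and flags ties", {
  p <- synthetic_params(n_rois = 4,
                        phase_offsets = c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(as.integer(planted_ordering(p)), 1:4)
  p2 <- synthetic_params(n_rois = 3, phase_offsets = c(1.0, 0.2, 2.5))
  expect_equal(as.integer(planted_ordering(p2)), c(2, 1, 3))
  p3 <- synthetic_params(n_rois = 3, phase_offsets = c(1, 1, 1))
  expect_warning(ord <- planted_ordering(p3), "ties")
  expect_true(attr(ord, "ties"))
})

test_that("group effects touch only patient records and the named pairs", {
  eff <- list(list(roi_i = 2, roi_j = 5, delta = 1.5, type = "coupling"))
  p0 <- synthetic_params(n_subjects = 4, n_rois = 6, n_time = 80,
                         n_patients = 2, seed = 11)
  p1 <- synthetic_params(n_subjects = 4, n_rois = 6, n_time = 80,
                         n_patients = 2, group_effect = eff, seed = 11)
  base <- make_panel(p0)
  hit <- make_panel(p1)
  for (i in seq_len(nrow(base))) {
    diff_rows <- which(rowSums(abs(hit$series[[i]] - base$series[[i]])) > 0)
    if (base$group[i] == "patient") {
      expect_equal(diff_rows, 5L, ignore_attr = TRUE)
    } else {
      expect_length(diff_rows, 0)
    }
  }
  # zero effect size is the identity
  pz <- synthetic_params(n_subjects = 4, n_rois = 6, n_time = 80,
                         n_patients = 2, seed = 11,
                         group_effect = list(list(roi_i = 2, roi_j = 5,
                                                  delta = 0)))
  expect_identical(make_panel(pz)$series, base$series)
  # unknown ROI index rejected
  expect_error(
    synthetic_params(n_rois = 6,
                     group_effect = list(list(roi_i = 2, roi_j = 9,
                                              delta = 1))),
    "ROI")
})

test_that("a large phase effect moves the pair's lead-matrix entry", {
  # noise-free closed forms: recompute the signed area with and without the
  # phase shift on the target pair
  eff <- list(list(roi_i = 2, roi_j = 4, delta = pi / 2, type = "phase"))
  base_p <- quiet_params(n_subjects = 2, n_rois = 6, n_time = 300, seed = 3)
  hit_p <- quiet_params(n_subjects = 2, n_rois = 6, n_time = 300, seed = 3,
                        group_effect = eff, n_patients = 1)
  base <- make_panel(base_p)
  hit <- make_panel(hit_p)
  lm_of <- function(X) lead_matrix(end_match(X))
  pat <- which(hit$group == "patient" & hit$visit_id == 1)
  ctl <- which(hit$group == "control" & hit$visit_id == 1)
  a_pat <- lm_of(hit$series[[pat]])[2, 4]
  a_ctl <- lm_of(hit$series[[ctl]])[2, 4]
  a_base <- lm_of(base$series[[1]])[2, 4]
  expect_equal(a_ctl, a_base, tolerance = 1e-10)
  expect_gt(abs(a_pat - a_ctl), 0.1 * max(abs(a_ctl), 1))
})

test_that("monotone warp holds numerically at every sample", {
  p <- synthetic_params(n_subjects = 2, n_rois = 4, n_time = 150,
                        reparam_strength = 0.9, noise_sd = 0,
                        global_amp = 0, seed = 13)
  expect_true(check_warp_monotone(p, n_probe = 16))
  panel <- make_panel(p)
  expect_true(all(is.finite(unlist(panel$series))))
})
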
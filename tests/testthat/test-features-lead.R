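test_that("signed area matches the closed form pi*sin(phi) with sign", {
  # symbolic oracle: for f = cos(theta), g = cos(theta - phi) over one
  # period, the enclosed signed area is pi * sin(phi) under the
  # follower-positive orientation
  for (phi in c(pi / 6, pi / 4, pi / 2)) {
    X <- sinusoid_series(c(0, phi), n_time = 300)
    A <- lead_matrix(X, end_matched = FALSE)
    expect_equal(A[1, 2], pi * sin(phi), tolerance = 0.01)
    expect_gt(A[1, 2], 0)  # ROI 2 follows ROI 1
    # sign flips with the sign of the phase gap
    Xn <- sinusoid_series(c(0, -phi), n_time = 300)
    expect_lt(lead_matrix(Xn, end_matched = FALSE)[1, 2], 0)
  }
  # identical rows enclose no area
  X <- sinusoid_series(c(0.3, 0.3), n_time = 200)
  expect_equal(lead_matrix(X, end_matched = FALSE)[1, 2], 0,
               tolerance = 1e-12)
  # phi = pi/2 encloses the unit circle: |A| = pi within 1%
  Xc <- sinusoid_series(c(0, pi / 2), n_time = 300)
  expect_equal(abs(lead_matrix(Xc, end_matched = FALSE)[1, 2]), pi,
               tolerance = 0.01 * pi)
})

test_that("lead matrix is skew-symmetric with closed-loop invariances", {
  set.seed(7)
  X <- end_match(matrix(rnorm(6 * 100), 6, 100))
  A <- lead_matrix(X)
  expect_lt(max(abs(unclass(A) + t(unclass(A)))), 1e-10)
  expect_equal(diag(unclass(A)), rep(0, 6), ignore_attr = TRUE)
  # translation invariance: constants added to end-matched rows change nothing
  Xt <- X + matrix(runif(6, -5, 5), 6, 100)
  expect_equal(unclass(lead_matrix(Xt)), unclass(A), tolerance = 1e-10)
  # time reversal negates the area
  Ar <- lead_matrix(X[, ncol(X):1])
  expect_equal(unclass(Ar), -unclass(A), tolerance = 1e-10)
  # refusing non-end-matched input without the flag
  expect_error(lead_matrix(matrix(rnorm(4 * 50), 4, 50)), "end-match")
})

test_that("spectrum of a phase-shifted sinusoid panel is rank-2 and imaginary", {
  deltas <- 2 * pi * (0:7) / 8
  A <- lead_matrix(sinusoid_series(deltas, n_time = 400), end_matched = FALSE)
  sp <- cyclicity_spectrum(A)
  mags <- Mod(sp$eigenvalues)
  expect_lt(mags[3] / mags[1], 1e-6)  # one conjugate pair dominates
  expect_lt(max(abs(Re(sp$eigenvalues))), 1e-8 * mags[1])
  # zero matrix is flagged degenerate
  z <- cyclicity_spectrum(matrix(0, 4, 4))
  expect_true(z$degenerate)
  expect_equal(Mod(z$eigenvalues), rep(0, 4))
  expect_error(recover_ordering(z), "degenerate")
})

test_that("ordering recovery matches the planted order on noise-free panels", {
  deltas <- c(0, pi / 3, 2 * pi / 3, pi, 4 * pi / 3, 5 * pi / 3)
  p <- quiet_params(n_rois = 6, n_time = 300, seed = 21,
                    phase_offsets = deltas,
                    driver_harmonics = cbind(freq = 0.02, amp = 1))
  panel <- make_panel(p)
  A <- lead_matrix(end_match(panel$series[[1]]))
  ord <- recover_ordering(cyclicity_spectrum(A))
  expect_true(cyclic_equal(as.integer(ord), as.integer(planted_ordering(p))))
  # reversing time reverses the recovered cyclic order
  Ar <- lead_matrix(end_match(panel$series[[1]][, 300:1]))
  ord_r <- recover_ordering(cyclicity_spectrum(Ar))
  expect_true(cyclic_equal(as.integer(ord_r), rev(as.integer(ord))))
})

test_that("equal-phase ROIs are flagged as ties and stay adjacent", {
  deltas <- c(0, pi / 2, pi / 2, pi)
  A <- lead_matrix(sinusoid_series(deltas, n_time = 400),
                   end_matched = FALSE)
  sp <- cyclicity_spectrum(A)
  expect_warning(ord <- recover_ordering(sp, tie_tol = 1e-6), "phases")
  pos <- match(c(2, 3), as.integer(ord))
  expect_equal(abs(diff(pos)), 1)
})

test_that("lead matrix is the most reparameterization-stable feature", {
  deltas <- 2 * pi * (0:4) / 5
  dense_n <- 2000
  base <- sinusoid_series(deltas, n_time = dense_n, periods = 3, warp_a = 0)
  warp <- sinusoid_series(deltas, n_time = dense_n, periods = 3,
                          warp_a = 0.3)
  rel_lead <- relative_frobenius(lead_matrix(base, end_matched = FALSE),
                                 lead_matrix(warp, end_matched = FALSE))
  offdiag <- function(m) { m <- unclass(m); diag(m) <- 0; m }
  rel_corr <- norm(offdiag(correlation_matrix(warp)) -
                   offdiag(correlation_matrix(base)), "F") /
    norm(offdiag(correlation_matrix(base)), "F")
  rel_dtw <- relative_frobenius(dtw_matrix(warp), dtw_matrix(base))
  expect_lt(rel_lead, 0.02)
  expect_lt(rel_lead, rel_corr)
  expect_lt(rel_lead, rel_dtw)
})
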
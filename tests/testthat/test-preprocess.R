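test_that("mean-centering and detrending remove exactly the linear part", {
  # pure linear trend vanishes
  X <- rbind(1:5, c(2, 2, 2, 2, 2) + 3 * (1:5))
  out <- mean_center_detrend(X)
  expect_equal(out, matrix(0, 2, 5), ignore_attr = TRUE)
  # idempotence on already-clean input
  set.seed(1)
  Y <- mean_center_detrend(matrix(rnorm(3 * 40), 3, 40))
  expect_equal(mean_center_detrend(Y), Y, tolerance = 1e-12)
  # sine + line leaves the least-squares-detrended sine (lm oracle)
  t <- 1:60
  s <- sin(2 * pi * t / 12)
  row <- s + 0.3 * t + 2
  res_oracle <- unname(residuals(lm(row ~ t)))
  expect_equal(mean_center_detrend(rbind(row, row))[1, ], res_oracle,
               tolerance = 1e-10, ignore_attr = TRUE)
  # constant rows flagged and zeroed
  expect_warning(z <- mean_center_detrend(rbind(rep(4, 10), 1:10)),
                 "constant")
  expect_equal(z[1, ], rep(0, 10), ignore_attr = TRUE)
})

test_that("the three scaling modes hit their defining normalizations", {
  set.seed(2)
  X <- matrix(rnorm(4 * 50), 4, 50)
  qv <- scale_rows(X, "quadratic_variation")
  expect_equal(rowSums(t(diff(t(qv)))^2), rep(1, 4), ignore_attr = TRUE)
  nm <- scale_rows(rbind(c(0, 1, 0, 1)), "norm")
  expect_equal(nm[1, ], c(0, 1, 0, 1) / sqrt(2), ignore_attr = TRUE)
  sdx <- scale_rows(X, "std")
  expect_equal(apply(sdx, 1, sd), rep(1, 4), ignore_attr = TRUE)
  # standard-normal draws are near-unchanged under std scaling
  big <- matrix(rnorm(2 * 5000), 2, 5000)
  expect_lt(max(abs(scale_rows(big, "std") - big)) / max(abs(big)), 0.05)
  expect_error(scale_rows(rbind(rep(1, 5)), "std"), "zero")
})

test_that("end-matching closes every row and is idempotent", {
  set.seed(3)
  X <- matrix(rnorm(5 * 30), 5, 30)
  em <- end_match(X)
  expect_equal(em[, 1], em[, 30])
  expect_equal(end_match(em), em, tolerance = 1e-14)
  lin <- rbind(seq(2, 9, length.out = 20))
  expect_equal(end_match(lin), matrix(2, 1, 20), ignore_attr = TRUE)
})

test_that("Bessel band-pass attenuates out-of-band and passes in-band", {
  tr <- 2
  t <- (0:299) * tr
  stop_sin <- rbind(sin(2 * pi * 0.15 * t))
  pass_sin <- rbind(sin(2 * pi * 0.03 * t))
  band <- c(0.008, 0.08)
  out_stop <- bandpass_bessel(stop_sin, band, 4, tr)
  out_pass <- bandpass_bessel(pass_sin, band, 4, tr)
  mid <- 60:240  # avoid filter edge transients
  expect_lt(max(abs(out_stop[1, mid])), 0.10)
  expect_gt(max(abs(out_pass[1, mid])), 0.80)
  expect_equal(bandpass_bessel(matrix(0, 2, 100), band, 4, tr),
               matrix(0, 2, 100), ignore_attr = TRUE)
  expect_error(bandpass_bessel(pass_sin, c(0.01, 0.3), 4, tr), "Nyquist")
})

test_that("measured filter gain tracks the analytic magnitude response", {
  tr <- 2; band <- c(0.008, 0.08)
  probe <- c(0.02, 0.04, 0.06, 0.10, 0.15, 0.20)
  n <- 4000  # long record so the steady-state amplitude is clean
  t <- (seq_len(n) - 1) * tr
  for (f in probe) {
    x <- rbind(sin(2 * pi * f * t))
    y <- cyclofi:::bessel_bandpass_gain(f, band, 4, tr, zero_phase = TRUE)
    out <- bandpass_bessel(x, band, 4, tr)
    measured <- max(abs(out[1, 1000:3000]))
    expect_lt(abs(measured - y), 0.05)
  }
})

test_that("GSR residuals are orthogonal to the global signal", {
  set.seed(4)
  X <- matrix(rnorm(6 * 120), 6, 120)
  out <- global_signal_regress(X)
  g <- colMeans(X)
  for (k in 1:6) expect_lt(abs(cor(out[k, ], g)), 1e-10)
  # OLS oracle: residuals match lm() per row
  oracle <- t(apply(X, 1, function(r) unname(residuals(lm(r ~ g)))))
  expect_equal(out, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("GSR removes a shared sinusoid riding on independent noise", {
  set.seed(5)
  n <- 300; tr <- 2
  t <- (seq_len(n) - 1) * tr
  shared <- 3 * sin(2 * pi * 0.02 * t)
  X <- matrix(rnorm(10 * n, sd = 0.5), 10, n)
  Xs <- sweep(X, 2, -shared)
  out <- global_signal_regress(Xs)
  pow_at <- function(x) {
    sp <- stats::spec.pgram(ts(x, deltat = tr), plot = FALSE, taper = 0,
                            detrend = FALSE)
    sp$spec[which.min(abs(sp$freq - 0.02))]
  }
  before <- mean(apply(Xs, 1, pow_at))
  after <- mean(apply(out, 1, pow_at))
  expect_lt(after / before, 0.05)
})

test_that("pipeline order and purity are honoured", {
  p <- synthetic_params(n_subjects = 2, n_rois = 5, n_time = 100, seed = 6)
  panel <- make_panel(p)
  cfg <- preprocess_config(do_gsr = FALSE, filter_band = NULL)
  out1 <- preprocess_panel(panel, cfg, "cm")
  out2 <- preprocess_panel(panel, cfg, "cm")
  expect_identical(out1$series, out2$series)
  prov <- attr(out1, "provenance")
  expect_false(any(grepl("gsr|bandpass|end_match", prov)))
  expect_true(any(grepl("center_detrend", prov)))
  # cyclicity path end-matches before scaling, in the recorded order
  lmprov <- attr(preprocess_panel(panel, cfg, "lm"), "provenance")
  expect_lt(which(lmprov == "end_match"), which(grepl("^scale", lmprov)))
  # lm records come out end-matched
  lm_out <- preprocess_panel(panel, cfg, "lm")
  X <- lm_out$series[[1]]
  expect_equal(X[, 1], X[, ncol(X)], tolerance = 1e-12)
})
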
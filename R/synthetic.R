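#' Parameters for the synthetic cyclic time-series generator
#'
#' Builds and validates the parameter set for [make_panel()]. The generator
#' emulates the statistical structure that cyclicity analysis assumes: every
#' region of interest (ROI) carries a shared cyclic driver \eqn{r(\cdot)} --
#' a periodic waveform observed through a monotone time re-parameterization
#' \eqn{\phi(t)} -- with a per-ROI phase offset \eqn{\delta_k} that plants a
#' known temporal (leader--follower) ordering. On top of the driver sit a
#' low-frequency global signal shared by all ROIs, AR(1)-autocorrelated
#' Gaussian noise emulating hemodynamic serial dependence, and
#' subject-specific signatures (phase jitter and mixing weights) that are
#' stable across the two visits and make cross-visit fingerprinting possible.
#'
#' The warp is \eqn{\phi(t) = t + (s/\omega)\sin(\omega t + u)} with
#' \eqn{s} = `reparam_strength` and \eqn{u} redrawn per visit, so
#' \eqn{\phi'(t) = 1 + s\cos(\omega t + u) > 0} whenever \eqn{s < 1};
#' requests with `reparam_strength >= 1` are rejected rather than allowed to
#' produce a non-monotone warp.
#'
#' @param n_subjects Number of subjects; each gets two visits.
#' @param n_rois Number of ROIs (33 in the study design this emulates).
#' @param n_time Samples per record (300 volumes).
#' @param tr Sampling interval in seconds (repetition time; 2 s).
#' @param phase_offsets Per-ROI phase offsets \eqn{\delta_k} in radians in
#'   `[0, 2*pi)`; defaults to an even spacing, planting the identity cyclic
#'   ordering. Offsets are applied as time delays
#'   \eqn{\delta_k / (2\pi f_1)} of the driver, \eqn{f_1} its fundamental.
#' @param driver_harmonics Two-column matrix (or data frame) with columns
#'   `freq` (Hz) and `amp`: harmonics of the periodic driver. The first row
#'   is the fundamental.
#' @param reparam_strength Dimensionless warp amplitude in `[0, 1)`.
#' @param warp_freq Angular frequency \eqn{\omega} of the warp, rad/s.
#' @param signature_strength Scale of subject-specific phase jitter (radians)
#'   and of the spread of per-ROI mixing weights; 0 removes all
#'   subject-identifying structure so fingerprinting falls to chance.
#' @param noise_sd Stationary standard deviation of the additive noise.
#' @param noise_ar_coeff AR(1) coefficient of the noise in `[0, 1)`.
#' @param global_amp Amplitude of the shared low-frequency global signal
#'   (redrawn per visit, identical across ROIs within a visit).
#' @param group_effect Optional list of group effects applied to patient
#'   subjects, each a list with fields `roi_i`, `roi_j`, `delta` and `type`
#'   (`"coupling"` adds `delta * x_i` to ROI `j`; `"phase"` circularly
#'   shifts ROI `j` by `delta` radians of the fundamental).
#' @param n_patients Number of subjects labelled `"patient"`; the rest are
#'   `"control"`. Defaults to the study's 50/79 imbalance, rounded.
#' @param runs_per_visit Records generated per visit (default 1).
#' @param seed Integer master seed; the generator is deterministic given it.
#' @return A validated parameter list of class `"fi_params"`.
#' @seealso [make_panel()], [planted_ordering()], [inject_group_effect()]
#' @export
synthetic_params <- function(n_subjects = 79,
                             n_rois = 33,
                             n_time = 300,
                             tr = 2,
                             phase_offsets = NULL,
                             driver_harmonics = cbind(freq = c(0.02, 0.04),
                                                      amp  = c(1, 0.4)),
                             reparam_strength = 0.3,
                             warp_freq = 2 * pi * 0.01,
                             signature_strength = 0.5,
                             noise_sd = 0.3,
                             noise_ar_coeff = 0.5,
                             global_amp = 0.5,
                             group_effect = list(),
                             n_patients = NULL,
                             runs_per_visit = 1,
                             seed = 1) {
  if (n_time < 2) abort("n_time must be >= 2")
  if (n_rois < 2) abort("n_rois must be >= 2")
  if (tr <= 0) abort("tr must be positive")
  if (reparam_strength < 0 || reparam_strength >= 1) {
    abort(paste0("reparam_strength must lie in [0, 1): a value of ",
                 reparam_strength,
                 " would produce a non-monotone time warp (phi' <= 0)"))
  }
  if (noise_ar_coeff < 0 || noise_ar_coeff >= 1) {
    abort("noise_ar_coeff must lie in [0, 1)")
  }
  if (is.null(phase_offsets)) {
    phase_offsets <- 2 * pi * (seq_len(n_rois) - 1) / n_rois
  }
  if (length(phase_offsets) != n_rois) {
    abort("phase_offsets must have one entry per ROI")
  }
  phase_offsets <- phase_offsets %% (2 * pi)
  dh <- as.matrix(as.data.frame(driver_harmonics))
  if (ncol(dh) != 2 || any(dh[, 1] <= 0)) {
    abort("driver_harmonics needs columns (freq > 0, amp)")
  }
  colnames(dh) <- c("freq", "amp")
  if (is.null(n_patients)) n_patients <- round(n_subjects * 50 / 79)
  n_patients <- min(max(n_patients, 0L), n_subjects)
  for (ef in group_effect) {
    if (!all(c("roi_i", "roi_j", "delta") %in% names(ef))) {
      abort("each group effect needs roi_i, roi_j, delta")
    }
    if (any(c(ef$roi_i, ef$roi_j) < 1) || any(c(ef$roi_i, ef$roi_j) > n_rois)) {
      abort(paste0("group effect names unknown ROI index (n_rois = ", n_rois, ")"))
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    n_time = as.integer(n_time), tr = tr,
    phase_offsets = phase_offsets, driver_harmonics = dh,
    reparam_strength = reparam_strength, warp_freq = warp_freq,
    signature_strength = signature_strength,
    noise_sd = noise_sd, noise_ar_coeff = noise_ar_coeff,
    global_amp = global_amp, group_effect = group_effect,
    n_patients = as.integer(n_patients),
    runs_per_visit = as.integer(runs_per_visit),
    seed = as.integer(seed)
  ), class = "fi_params")
}

# Driver waveform evaluated at warped, ROI-delayed times (seconds).
driver_eval <- function(times, harmonics) {
  out <- numeric(length(times))
  for (h in seq_len(nrow(harmonics))) {
    out <- out + harmonics[h, "amp"] * cos(2 * pi * harmonics[h, "freq"] * times)
  }
  out
}

# Low-frequency global signal: white noise low-passed below `cutoff` Hz via
# a hard FFT mask, standardized to unit sd.
global_process <- function(n_time, tr, cutoff = 0.05) {
  z <- rnorm(n_time)
  fz <- stats::fft(z)
  freqs <- c(0:(floor(n_time / 2)), -(ceiling(n_time / 2) - 1):-1) / (n_time * tr)
  fz[abs(freqs) > cutoff] <- 0
  g <- Re(stats::fft(fz, inverse = TRUE)) / n_time
  s <- sd(g)
  if (s > 0) g <- g / s
  g
}

ar1_noise <- function(n_rois, n_time, sd_target, a) {
  if (sd_target == 0) return(matrix(0, n_rois, n_time))
  innov_sd <- sd_target * sqrt(1 - a^2)
  t(vapply(seq_len(n_rois), function(i) {
    as.numeric(stats::filter(rnorm(n_time, sd = innov_sd), a,
                             method = "recursive"))
  }, numeric(n_time)))
}

#' Generate a synthetic cohort panel of cyclic multivariate time series
#'
#' Produces one ROI x time matrix per subject, visit and run. ROI `k`'s
#' series is
#' \deqn{a_k\, r(\phi_v(t) - \Delta_k - s_k) + \mathrm{global\_amp}\cdot
#'   g_v(t) + \varepsilon_k(t)}
#' where the phase offset \eqn{\Delta_k} and subject signature \eqn{s_k} are
#' time delays of the driver, the mixing weights \eqn{a_k} and signatures
#' are drawn once per subject (shared across visits), and the warp phase,
#' global signal \eqn{g_v} and AR(1) noise \eqn{\varepsilon} are redrawn per
#' visit. Group effects listed in the parameters are applied to patient
#' subjects via [inject_group_effect()].
#'
#' @param params A `"fi_params"` object from [synthetic_params()].
#' @return A panel tibble of class `"fi_panel"` with columns `subject_id`,
#'   `visit_id`, `run_id`, `group`, and a `series` list-column of
#'   ROI x time matrices; attributes `tr`, `roi_names` and the generating
#'   parameters ride along. Deterministic given `params$seed`.
#' @export
#' @examples
#' p <- synthetic_params(n_subjects = 4, n_rois = 8, n_time = 120, seed = 7)
#' panel <- make_panel(p)
#' dplyr::count(panel, visit_id)
make_panel <- function(params) {
  stopifnot(inherits(params, "fi_params"))
  n_s <- params$n_subjects; n_r <- params$n_rois; n_t <- params$n_time
  tr <- params$tr
  f1 <- params$driver_harmonics[1, "freq"]
  t_grid <- (seq_len(n_t) - 1) * tr
  delay_k <- params$phase_offsets / (2 * pi * f1)

  subject_ids <- sprintf("S%03d", seq_len(n_s))
  groups <- c(rep("patient", params$n_patients),
              rep("control", n_s - params$n_patients))

  seeds <- with_seed(params$seed, fan_seeds(params$seed, n_s))
  records <- vector("list", n_s * 2L * params$runs_per_visit)
  idx <- 0L
  for (s in seq_len(n_s)) {
    rec_s <- with_seed(seeds[s], {
      sig_phase <- rnorm(n_r, sd = params$signature_strength)
      a_k <- exp(rnorm(n_r, sd = params$signature_strength / 2))
      sig_delay <- sig_phase / (2 * pi * f1)
      lapply(1:2, function(v) {
        lapply(seq_len(params$runs_per_visit), function(run) {
          u <- runif(1, 0, 2 * pi)
          if (params$reparam_strength > 0) {
            phi <- t_grid + (params$reparam_strength / params$warp_freq) *
              sin(params$warp_freq * t_grid + u)
            if (any(diff(phi) <= 0)) {
              abort("internal: generated warp not strictly increasing")
            }
          } else {
            phi <- t_grid
          }
          g <- if (params$global_amp > 0) {
            params$global_amp * global_process(n_t, tr)
          } else {
            numeric(n_t)
          }
          noise <- ar1_noise(n_r, n_t, params$noise_sd, params$noise_ar_coeff)
          X <- matrix(0, n_r, n_t)
          for (k in seq_len(n_r)) {
            X[k, ] <- a_k[k] *
              driver_eval(phi - delay_k[k] - sig_delay[k],
                          params$driver_harmonics) + g + noise[k, ]
          }
          rownames(X) <- sprintf("ROI%02d", seq_len(n_r))
          X
        })
      })
    })
    for (v in 1:2) {
      for (run in seq_len(params$runs_per_visit)) {
        idx <- idx + 1L
        records[[idx]] <- tibble(
          subject_id = subject_ids[s], visit_id = v, run_id = run,
          group = groups[s], series = list(rec_s[[v]][[run]])
        )
      }
    }
  }
  panel <- dplyr::bind_rows(records)
  panel <- new_fi_panel(panel, tr = tr,
                        roi_names = sprintf("ROI%02d", seq_len(n_r)),
                        params = params)
  if (length(params$group_effect) > 0) {
    panel <- inject_group_effect(panel, params)
  }
  panel
}

new_fi_panel <- function(df, tr, roi_names, params = NULL, provenance = character()) {
  structure(df, tr = tr, roi_names = roi_names, params = params,
            provenance = provenance,
            class = c("fi_panel", class(tibble())))
}

#' @export
print.fi_panel <- function(x, ...) {
  cat("<fi_panel> ", length(unique(x$subject_id)), " subjects, ",
      nrow(x), " records, ", length(attr(x, "roi_names")), " ROIs x ",
      ncol(x$series[[1]]), " time points (TR = ", attr(x, "tr"), " s)\n",
      sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("preprocessing:", paste(prov, collapse = " -> "), "\n")
  NextMethod()
}

#' Ground-truth cyclic ordering planted by the generator
#'
#' ROIs sorted by their phase offset \eqn{\delta_k}: the temporal ordering
#' that the lead-matrix spectral analysis is expected to recover (up to
#' cyclic rotation).
#'
#' @param params A `"fi_params"` object.
#' @return Integer vector of ROI indices in planted cyclic order. If any
#'   offsets tie the result carries attribute `ties = TRUE` and the order
#'   within tied blocks is arbitrary.
#' @export
planted_ordering <- function(params) {
  stopifnot(inherits(params, "fi_params"))
  ord <- order(params$phase_offsets)
  ties <- anyDuplicated(params$phase_offsets) > 0
  if (ties) {
    warn("phase offsets contain ties; ordering within tied blocks is arbitrary")
  }
  structure(ord, ties = ties)
}

#' Inject a known group effect into patient subjects' ROI pairs
#'
#' Alters the listed ROI pairs for records whose `group == "patient"`,
#' leaving controls untouched, so that classifiers can be tested against a
#' known effect size and salience selection against known ROI pairs.
#' `"coupling"` effects add `delta * x_i` to ROI `j`; `"phase"` effects
#' rotate ROI `j` by `delta` radians of the driver fundamental via a
#' circular Fourier shift.
#'
#' @param panel An `"fi_panel"`.
#' @param params An `"fi_params"` whose `group_effect` field lists the
#'   effects (see [synthetic_params()]).
#' @return The modified panel.
#' @export
inject_group_effect <- function(panel, params) {
  stopifnot(inherits(panel, "fi_panel"), inherits(params, "fi_params"))
  effects <- params$group_effect
  if (length(effects) == 0) return(panel)
  n_r <- length(attr(panel, "roi_names"))
  for (ef in effects) {
    if (ef$roi_i < 1 || ef$roi_i > n_r || ef$roi_j < 1 || ef$roi_j > n_r) {
      abort(paste0("group effect references unknown ROI index (n_rois = ",
                   n_r, ")"))
    }
  }
  f1 <- params$driver_harmonics[1, "freq"]
  tr <- attr(panel, "tr")
  rows <- which(panel$group == "patient")
  for (r in rows) {
    X <- panel$series[[r]]
    for (ef in effects) {
      type <- ef$type %||% "coupling"
      if (type == "coupling") {
        X[ef$roi_j, ] <- X[ef$roi_j, ] + ef$delta * X[ef$roi_i, ]
      } else if (type == "phase") {
        shift_s <- ef$delta / (2 * pi * f1)
        X[ef$roi_j, ] <- fourier_shift(X[ef$roi_j, ], shift_s / tr)
      } else {
        abort(paste0("unknown group effect type: ", type))
      }
    }
    panel$series[[r]] <- X
  }
  panel
}

# Circular shift of a sampled series by a (possibly fractional) number of
# samples, via an FFT phase ramp.
fourier_shift <- function(x, shift_samples) {
  n <- length(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  fx <- stats::fft(x) * exp(-2i * pi * k * shift_samples / n)
  Re(stats::fft(fx, inverse = TRUE)) / n
}

#' Numerically verify that the generator's time warp is monotone
#'
#' @param params A `"fi_params"` object.
#' @param n_probe Number of warp phases probed.
#' @return `TRUE` invisibly; errors if any probed warp has a non-positive
#'   derivative at any sample.
#' @export
check_warp_monotone <- function(params, n_probe = 8) {
  t_grid <- (seq_len(params$n_time) - 1) * params$tr
  for (u in seq(0, 2 * pi, length.out = n_probe)) {
    phi <- t_grid + (params$reparam_strength / params$warp_freq) *
      sin(params$warp_freq * t_grid + u)
    if (any(diff(phi) <= 0)) {
      abort("warp is not strictly increasing for this parameter set")
    }
  }
  invisible(TRUE)
}
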
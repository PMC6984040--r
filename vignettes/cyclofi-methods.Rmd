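---
title: "Methods: cyclicity analysis and functional-interactivity measures in cyclofi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclicity analysis and functional-interactivity measures in cyclofi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclofi)
```

## The problem

Resting-state fMRI yields one BOLD time course per region of interest
(ROI). Classical functional-connectivity analysis summarizes the pairwise
relationships among these series by *similarity*: zero-lag Pearson
correlation, lagged cross-correlation, or dynamic time warping (DTW)
distance. None of these captures the *temporal ordering* of activity — the
leader–follower structure of an underlying cyclic process. Cyclicity
analysis does: it treats the multivariate series as a closed path and
assigns every ROI pair the signed algebraic area swept in their joint
plane. `cyclofi` implements all four measures behind one preprocessing and
evaluation pipeline so that their information content can be compared on
equal footing: who can identify an individual across scan sessions
(fingerprinting), and who carries group-level (patient vs. control)
information.

Because fMRI cohorts are rarely shareable, the package ships a synthetic
generator that emulates the statistical structure these analyses assume,
with ground truth planted for every property the pipeline is supposed to
recover.

## The four interactivity features

### Lead matrix (cyclicity analysis)

For two series $f(t)$, $g(t)$ observed on $[0, T]$ and equivalued at the
endpoints, the signed area is

$$A_{fg} = \tfrac12 \oint \left( f\, dg - g\, df \right),$$

the area enclosed by the planar curve $(f(t), g(t))$. Orientation is fixed
so that $A_{kl} > 0$ when ROI $l$ *follows* ROI $k$: for unit sinusoids
with $l$ delayed by phase $\varphi \in (0, \pi)$ over one period,
$A_{kl} = \pi \sin\varphi$. (The two possible orientations of the loop
integral differ only by a global sign; the follower-positive convention is
calibrated once against this closed form and frozen in a regression test.)
Collecting all pairs gives a skew-symmetric $N \times N$ *lead matrix*.
The discrete integral is the shoelace rule over the closed polygon
including the segment from the last sample back to the first — exact for
polygonal paths, which is why `lead_matrix()` requires (or internally
applies) end-matching.

Two properties make the lead matrix special among the four features, and
both are asserted in the test suite: it is invariant under monotone
re-parameterizations of time (the defining property of *cyclic* — repetitive
but aperiodic — signals), and invariant under adding constants to
end-matched rows.

Spectral analysis (`cyclicity_spectrum()`): a skew-symmetric matrix has
purely imaginary eigenvalues in conjugate pairs. When the data are
noise-free phase-shifted copies of one waveform the lead matrix has rank 2
and a single dominant pair; the phase angles of the leading eigenvector's
components encode the collective temporal ordering. We take the
eigenvector of the eigenvalue with the largest positive imaginary part and
rotate it so the first component has phase zero (phases are defined only up
to a global rotation, so recovered orderings are *cyclic* orders; rotations
compare equal via `cyclic_equal()`). The positive-imaginary choice fixes
the direction of the cycle and was calibrated once against the generator's
planted ordering.

### Correlation, lagged correlation, DTW

* `correlation_matrix()` — zero-lag Pearson, symmetric, unit diagonal.
* `lagged_correlation()` — for every pair, the cross-correlation is
  evaluated at integer lags $\tau \in [-L, L]$ on the overlapping segment;
  the extremum is the lag maximizing $|r|$. The signed correlation at the
  extremum goes to the lagged correlation matrix (LCM), the lag in seconds
  to the time-delay matrix (TDM), antisymmetric with the same
  follower-positive sign convention as the lead matrix. The default
  $L = 5$ samples (10 s at TR = 2 s) covers hemodynamic-scale lags.
  Tie-breaks: smaller $|\tau|$ wins; at an exact $|r|$ tie between
  $\pm\tau$ (pure sinusoids a quarter period apart) the positively
  correlated lag wins, which keeps the TDM sign interpretable. Optional
  parabolic interpolation refines sub-sample delays with a three-point
  parabola around the discrete peak.
* `dtw_distance()` / `dtw_matrix()` — the standard dynamic program
  $C_{kj} = d_{kj} + \min(C_{(k-1)j}, C_{(k-1)(j-1)}, C_{k(j-1)})$ with
  absolute-difference local cost by default (for scalar samples the
  Euclidean metric reduces to $|x - y|$), implemented in C++ with an
  optional Sakoe–Chiba band. The warping path is backtracked and is
  monotone and continuous; identical series give the diagonal path and
  distance zero. Tests pin the DP against an exhaustive-enumeration oracle
  on short series.

Feature matrices are vectorized for machine learning as the row-major
upper triangle (`vectorize_upper()`): $N(N-1)/2 = 528$ entries for the
33-ROI design; `matricize_upper()` inverts this given the symmetry kind.

## Preprocessing

`preprocess_panel()` applies, in order: GSR (optional) → mean-centering
and linear detrending → end-matching (lead-matrix path only, before
scaling) → scaling → band-pass filtering (optional). Each step is a pure
function; the applied sequence is recorded as provenance on the panel and
in every written feature's sidecar.

* **Scaling** — three normalizations: discrete quadratic variation
  $\sum_i (x_{i+1} - x_i)^2 = 1$ (the default throughout the stability
  analyses), unit sum of squares, or unit sample standard deviation.
* **Band-pass filter** — a Bessel filter, chosen in this field for its
  maximally flat group delay. The analog low-pass prototype is built from
  the roots of the order-$n$ reverse Bessel polynomial with the −3 dB
  point normalized numerically, transformed to a band-pass and discretized
  by the prewarped bilinear transform. Default order 4 (common practice,
  gentle rolloff); default band 0.008–0.08 Hz with 0.008–0.2 Hz as the
  standard alternative. The filter is applied forward–backward
  (zero-phase) by default: a causal pass would impose a
  frequency-dependent phase that distorts exactly the lag structure the
  lead and time-delay matrices measure. A config switch restores the
  causal variant. The measured amplitude response is tested against the
  analytic magnitude response on a probe grid.
* **GSR** — the global signal is the across-ROI mean time course (only
  ROI series enter this pipeline; a voxelwise mean is unavailable by
  design). Each row is replaced by its least-squares residual against an
  intercept and the global signal, so residuals are exactly orthogonal to
  the global signal. Note a subtlety verified in the tests: contamination
  *along the global direction* ($c(t) \in \mathrm{span}\{1, g\}$) is
  absorbed exactly — features are bit-for-bit unchanged — while an
  arbitrary shared component is absorbed only approximately, because the
  regression span itself shifts from $\{1, g\}$ to $\{1, g + c\}$. For a
  shared sinusoid riding on independent noise the tests assert a >95%
  drop in spectral power at the shared frequency rather than exact
  removal. GSR runs before detrending, matching the position of the
  optional GSR step right after time-series extraction.

## The synthetic cohort generator

`make_panel()` produces, per subject and visit, an ROI × time matrix

$$x_k(t) = a_k\, r\!\left(\phi_v(t) - \Delta_k - s_k\right)
  + \gamma\, g_v(t) + \varepsilon_k(t)$$

* $r(\cdot)$ — periodic driver, a sum of harmonics; default 0.02 Hz
  (amplitude 1) plus 0.04 Hz (amplitude 0.4), inside the resting-state
  band and commensurate on the default 600-s record.
* $\Delta_k = \delta_k / (2\pi f_1)$ — the per-ROI phase offset applied as
  a time delay of the driver; the offsets $\delta_k$ (default: even
  spacing) plant the ground-truth cyclic ordering
  (`planted_ordering()`).
* $\phi_v(t) = t + (s/\omega) \sin(\omega t + u_v)$ — monotone time warp
  making the signals cyclic rather than periodic; $s < 1$ guarantees
  $\phi' > 0$ (violations are rejected at construction, and
  `check_warp_monotone()` re-verifies numerically). Default $s = 0.3$,
  $\omega = 2\pi \cdot 0.01$ rad/s, warp phase redrawn per visit.
* Subject signatures — per-ROI phase jitter $s_k$ (SD =
  `signature_strength` radians) and log-normal mixing weights $a_k$, drawn
  once per subject and reused across visits: the stable individual
  structure that cross-visit fingerprinting detects. Strength 0 removes
  all subject identity, and the suite checks that 1-NN identification then
  falls to the 1/S chance band.
* $g_v(t)$ — global signal: Gaussian noise low-passed below 0.05 Hz (hard
  FFT mask), unit variance, added identically to every ROI; default
  amplitude 0.5. Adding it with unit coefficient everywhere is what makes
  the GSR step's target well-defined.
* $\varepsilon_k$ — AR(1) Gaussian noise (default coefficient 0.5,
  stationary SD 0.3) emulating the serial dependence that the slow
  hemodynamic response induces.
* Cohort defaults mirror the study design this emulates: 79 subjects with
  a 50/29 patient/control imbalance, 33 ROIs, 300 time points at TR = 2 s,
  two visits, one run per visit (how the study's two runs per visit were
  combined is not documented, so runs are kept as separate records and the
  fingerprinting step averages feature vectors across runs within a
  visit).
* Group effects (`inject_group_effect()`) alter listed ROI pairs for
  patient records only: `coupling` adds $\delta \cdot x_i$ to ROI $j$,
  `phase` rotates ROI $j$ by $\delta$ radians of the fundamental via an
  exact circular Fourier shift. These give classifiers and salience
  selection a known target.

What the generator does **not** emulate: hemodynamic response convolution,
spatial/anatomical structure, motion and physiological artifacts, scanner
noise, or non-stationary connectivity. Passing tests therefore demonstrate
that the pipeline recovers structure *of the kind the analyses assume*, at
known effect sizes — not that any particular empirical accuracy from real
cohorts is reproduced.

## Fingerprinting and robustness

`one_nn_identify()` trains a 1-nearest-neighbour classifier with cosine
similarity on one visit's feature vectors and tests on the other, in both
directions; ties go to the lowest subject index for reproducibility.
Accuracy (fraction of subjects matched to themselves) and Gorodkin's
$R_K$ — the multi-class generalization of the Matthews correlation
coefficient, exactly the binary MCC on 2×2 tables — are reported per
direction; the headline number is the mean of the two directions (the
combination used in single-number summaries; both directions are always
retained). $R_K$'s degenerate-denominator convention is 0.
`stability_sweep()` runs the full 3 filter × 2 GSR × 4 feature grid on any
two-visit panel. `gsr_robustness()` computes per-record cosine distances
between features with and without GSR, and `compare_robustness()` applies
the Kruskal–Wallis omnibus test with Mann–Whitney U post-hoc tests,
Bonferroni-corrected by the number of pairs (Bonferroni, not Holm, to
match the reference analysis).

## Group classification

`run_mccv()` is the Monte Carlo cross-validation driver: default 100
repetitions, 70/30 train/test. Splits are by *subject* (all records of a
subject stay together — visits of one person are not independent) and
stratified by class, because a 50/29 imbalance occasionally empties a class
in unstratified 30% folds. Inside each repetition, standardization
(per-dimension Z-score; zero-variance dimensions dropped with a warning)
and PCA are fitted on the training fold only — 10 components for LDA/QDA,
20 for the SVM kernels — and applied to the held-out fold; the suite
includes shuffled-label calibration checks confirming no leakage path.
Sensitivity uses the patient group as the positive class (clinical
convention). The null-calibration band around the 0.5 prior is the
subject-level binomial interval: repetition means cannot concentrate
faster than the finite subject pool allows, since repetitions reuse the
same subjects.

The sparse linear SVM (`sparse_svm_select()`) minimizes the hinge loss
$\max(0, 1 - t(w \cdot x + b))$ plus $\lambda \lVert w \rVert_1$ by
proximal subgradient descent (a soft-thresholding step after each hinge
subgradient step, step size $\eta_0/\sqrt{t}$). The support maps back to
ROI pairs through the upper-triangle index map, giving the salience graph
(`plot_salience_graph()`). By default $\lambda$ is chosen by 5-fold CV on
the training fold with a one-standard-error rule favouring sparsity. One
behaviour worth knowing: when two planted ROI pairs are *individually*
separating, the one-SE $\lambda$ often keeps only one of them — L1 prunes
redundant features by design — so support-recovery experiments use a fixed
moderate $\lambda$ (0.01 on standardized 528-dimensional input) instead.

The VAE (`vae_fit()`) and CNN (`cnn_fit_eval()`) are compact from-scratch
implementations in base matrix operations with hand-written
backpropagation and Adam, sized for this package's few-dozen-subject,
528-dimension regime. The VAE has two fully connected encoder layers
(256/64, mirrored decoder), a 2-D Gaussian latent space, mean-squared
reconstruction loss plus KL divergence; samples are drawn from the prior,
decoded, and mean-adjusted/rescaled to the class moments, then matricized
with the feature kind's symmetry enforced by construction. The CNN follows
the connectome-network pattern for interaction matrices: a 1×N "row"
convolution (64 filters), an N×1 "column" stage (128 filters), dense(96)
with dropout 0.5, softmax output; full-batch Adam with early stopping on a
validation slice of the training fold. With augmentation enabled, a VAE is
fitted per class on the training fold only and its samples double the
effective training count; a structural guard errors if augmentation ever
draws on a test subject.

## Embedding diagnostics

`embed_2d()` offers exact (dense) t-SNE — per-point precision calibrated
to the target perplexity by bisection, early exaggeration, momentum
gradient descent, deterministic given the seed — and Isomap via classical
scaling of graph geodesics. Exact t-SNE is quadratic in the number of
samples, which is irrelevant at cohort sizes of ≤ a few hundred. Isomap's
neighbourhood size defaults to 10 and is doubled automatically (with a
warning) when the kNN graph is fragmented, since geodesics are undefined
across components. The "two visible clusters" reading of such embeddings
is formalized as 2-means on the coordinates
(`cluster_and_associate()`), and each metadata field is tested for
association with the cluster label — chi-squared for categorical fields,
Mann–Whitney U for continuous ones, Bonferroni-corrected across fields.

## Numerical choices and degenerate inputs

* Constant rows: detrending zeroes them with a warning naming the ROI;
  scaling and correlation refuse them by name.
* All-zero lead matrices yield a flagged degenerate spectrum;
  `recover_ordering()` refuses it. Near-equal eigenvector phases are
  flagged as ties and ordered by index.
* Skew-symmetry/symmetry invariants are enforced at 1e-10 relative on
  construction and re-validated (with the maximal deviation reported) when
  features are read back from disk; feature tables are written at 17
  significant digits so round trips are bit-stable.
* All stochastic stages take explicit seeds; a master seed fans out to
  stage seeds (each below $2^{31}$) so stages are independently
  reproducible, and the CLI pipeline is byte-reproducible end to end.

## Problem sizes in the shipped checks

The test suite and the acceptance script run: closed-form signed-area
probes at 300 samples; warp-sensitivity probes on 5-ROI panels at 2000
samples; ordering recovery over 20 panels of 8 ROIs; 200 short-series DTW
oracle comparisons plus 100 symmetry pairs; fingerprinting at 40 subjects
(33 ROIs × 300 time points, both visits) with a 20-seed null; classifier
calibration and power at 40 subjects over 100 MC repetitions and 50
salience-recovery repetitions. These sizes were chosen so the full suite
completes in about a minute on one core while keeping every stochastic
margin wide.

## Known limitations

* The pipeline starts at ROI × time tables; raw-volume preprocessing
  (realignment, normalization, smoothing, ROI extraction) is out of scope.
* The lagged-correlation extremum search assumes the cross-correlation
  has a usable extremum within ±`max_lag`; band-passed data can have
  multiple comparable peaks, in which case the smaller-lag tie rule
  decides.
* DTW on long series is quadratic per pair; the Sakoe–Chiba band trades
  exactness for speed.
* The CNN and VAE are deliberately small stand-ins in the spirit of the
  connectome-CNN family, configurable but not a reproduction of any
  specific published architecture.
* No empirical claim is made about real tinnitus cohorts; all quantitative
  statements in the README and tests are computed by this package on
  synthetic panels.
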
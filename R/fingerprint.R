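#' Gorodkin's R_K: multi-class Matthews correlation coefficient
#'
#' For a square confusion matrix with rows = true classes and columns =
#' predicted classes, computes
#' \deqn{R_K = \frac{c\,s - \sum_k p_k t_k}
#'   {\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}}
#' with \eqn{c} the trace, \eqn{s} the total count, \eqn{p_k} the column
#' sums and \eqn{t_k} the row sums. On 2x2 tables this reduces exactly to
#' the binary Matthews correlation coefficient. A zero denominator (e.g.
#' all mass in one predicted class) returns 0 by the standard convention.
#'
#' @param confusion Square matrix of non-negative counts, total > 0.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' rk_coefficient(diag(5) * 10)  # 1
rk_coefficient <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) abort("confusion matrix must be square")
  if (any(m < 0)) abort("confusion matrix has negative counts")
  s <- sum(m)
  if (s <= 0) abort("confusion matrix is empty")
  c_ <- sum(diag(m))
  p <- colSums(m); t_ <- rowSums(m)
  denom2 <- (s^2 - sum(p^2)) * (s^2 - sum(t_^2))
  if (denom2 <= 0) return(0)
  (c_ * s - sum(p * t_)) / sqrt(denom2)
}

# core 1-NN pass: rows of `train` and `test` are matched subjects
one_nn_direction <- function(train, test) {
  S <- nrow(train)
  subjects <- rownames(train)
  conf <- matrix(0L, S, S, dimnames = list(true = subjects, pred = subjects))
  for (i in seq_len(S)) {
    sims <- vapply(seq_len(S), function(j) {
      cosine_sim(test[i, ], train[j, ], who = subjects[j])
    }, numeric(1))
    # deterministic tie-break: lowest subject index
    pred <- which(sims == max(sims))[1]
    conf[i, pred] <- conf[i, pred] + 1L
  }
  list(confusion = conf,
       accuracy = sum(diag(conf)) / S,
       rk = rk_coefficient(conf))
}

#' Cross-visit 1-nearest-neighbour subject identification
#'
#' Trains a 1-NN classifier with cosine similarity on one visit's feature
#' vectors and tests on the other visit's, in both directions. Accuracy is
#' the fraction of test subjects matched to themselves; R_K is Gorodkin's
#' multi-class Matthews correlation of the confusion matrix. The headline
#' values are the means of the two directions (both directions are kept).
#'
#' @param visit1,visit2 Matrices (subjects x feature dims) with matching
#'   rownames (subject ids), or named lists of vectors.
#' @return An `"fi_fingerprint"` object: per-direction confusion matrices,
#'   accuracies and R_K, plus their means.
#' @export
one_nn_identify <- function(visit1, visit2) {
  as_mat <- function(v) {
    if (is.list(v)) do.call(rbind, v) else as.matrix(v)
  }
  m1 <- as_mat(visit1); m2 <- as_mat(visit2)
  if (is.null(rownames(m1)) || is.null(rownames(m2))) {
    abort("feature matrices need subject ids as rownames/names")
  }
  if (!setequal(rownames(m1), rownames(m2)) || ncol(m1) != ncol(m2)) {
    abort("visits must share the same subjects and feature length")
  }
  m2 <- m2[rownames(m1), , drop = FALSE]
  d12 <- one_nn_direction(train = m1, test = m2)
  d21 <- one_nn_direction(train = m2, test = m1)
  structure(list(
    directions = list(visit1_to_visit2 = d12, visit2_to_visit1 = d21),
    accuracy = mean(c(d12$accuracy, d21$accuracy)),
    rk = mean(c(d12$rk, d21$rk)),
    n_subjects = nrow(m1)
  ), class = "fi_fingerprint")
}

#' @export
print.fi_fingerprint <- function(x, ...) {
  cat("<fi_fingerprint> ", x$n_subjects, " subjects\n",
      "  accuracy (mean of directions): ", round(x$accuracy, 3), "\n",
      "  R_K      (mean of directions): ", round(x$rk, 3), "\n", sep = "")
  invisible(x)
}

# Subject x feature-vector matrix for one visit of a feature set; multiple
# runs per visit are averaged.
visit_vectors <- function(features, visit) {
  fv <- feature_vectors(features)
  fv <- dplyr::filter(fv, .data$visit_id == visit)
  if (nrow(fv) == 0) abort(paste0("no records for visit ", visit))
  split_vecs <- split(fv$vector, fv$subject_id)
  do.call(rbind, lapply(split_vecs, function(vs) Reduce(`+`, vs) / length(vs)))
}

#' Fingerprint a two-visit panel with one feature kind
#'
#' Convenience wrapper: extracts features for both visits and runs
#' [one_nn_identify()] across them.
#'
#' @param panel An `"fi_panel"` with two visits per subject.
#' @param kind Feature kind (see [compute_features()]).
#' @param config Preprocessing configuration.
#' @param ... Passed to [compute_features()].
#' @return An `"fi_fingerprint"`.
#' @export
fingerprint_panel <- function(panel, kind = "lm",
                              config = preprocess_config(), ...) {
  miss <- setdiff(unique(panel$subject_id),
                  panel$subject_id[panel$visit_id == 2])
  if (length(miss)) {
    abort(paste0("subject(s) missing visit 2: ", paste(miss, collapse = ", ")))
  }
  feats <- compute_features(panel, kind, config, ...)
  one_nn_identify(visit_vectors(feats, 1), visit_vectors(feats, 2))
}

#' Per-subject cosine distance between features with and without GSR
#'
#' @param features_with_gsr,features_without_gsr `"fi_features"` tibbles
#'   over the same records.
#' @return Tibble with the id columns and a `distance` column,
#'   `1 - cosine similarity`, in `[0, 2]`.
#' @export
gsr_robustness <- function(features_with_gsr, features_without_gsr) {
  a <- feature_vectors(features_with_gsr)
  b <- feature_vectors(features_without_gsr)
  key <- function(d) paste(d$subject_id, d$visit_id, d$run_id)
  if (!identical(key(a), key(b))) {
    abort("feature sets do not cover the same records in the same order")
  }
  tibble(subject_id = a$subject_id, visit_id = a$visit_id,
         run_id = a$run_id,
         distance = vapply(seq_len(nrow(a)), function(i) {
           1 - cosine_sim(a$vector[[i]], b$vector[[i]],
                          who = a$subject_id[i])
         }, numeric(1)))
}

#' Compare robustness distributions across conditions
#'
#' Omnibus Kruskal-Wallis test across the groups followed by all pairwise
#' Mann-Whitney U tests with Bonferroni correction (multiplier = number of
#' pairs), the standard non-parametric post-hoc for cosine-distance
#' distributions.
#'
#' @param distance_groups Named list of numeric vectors (one per condition),
#'   each with at least 2 observations; smaller groups are dropped with a
#'   warning.
#' @return An `"fi_robustness"` list: `kruskal` (statistic, p), `pairwise`
#'   tibble (group1, group2, U, p, p_adj), `groups`.
#' @export
compare_robustness <- function(distance_groups) {
  sizes <- vapply(distance_groups, length, integer(1))
  if (any(sizes < 2)) {
    warn(paste0("dropping group(s) with < 2 observations: ",
                paste(names(distance_groups)[sizes < 2], collapse = ", ")))
    distance_groups <- distance_groups[sizes >= 2]
  }
  if (length(distance_groups) < 2) {
    abort("need at least 2 groups with >= 2 observations each")
  }
  kw <- kruskal.test(distance_groups)
  nm <- names(distance_groups)
  pairs <- utils::combn(seq_along(distance_groups), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    wt <- suppressWarnings(
      wilcox.test(distance_groups[[g1]], distance_groups[[g2]]))
    tibble(group1 = nm[g1], group2 = nm[g2],
           U = unname(wt$statistic), p = wt$p.value,
           p_adj = min(1, wt$p.value * n_pairs))
  })
  structure(list(
    kruskal = list(statistic = unname(kw$statistic), p = kw$p.value),
    pairwise = pw, groups = distance_groups
  ), class = "fi_robustness")
}

#' Cross-visit stability over the full preprocessing grid
#'
#' Reproduces the experimental grid of the stability analysis -- three
#' filter settings (none, 0.008--0.08 Hz, 0.008--0.2 Hz) by GSR on/off by
#' feature kind -- on any two-visit panel, reporting 1-NN identification
#' accuracy and R_K per cell.
#'
#' @param panel Two-visit `"fi_panel"`.
#' @param feature_kinds Feature kinds to sweep.
#' @param bands List of filter settings (`NULL` = no filter).
#' @param gsr Logical vector of GSR settings.
#' @param scaling Scaling method for all cells.
#' @param ... Passed to [compute_features()].
#' @return A tibble of class `"fi_stability"` with columns `feature`, `gsr`,
#'   `band`, `accuracy`, `rk` and per-direction accuracies.
#' @export
stability_sweep <- function(panel,
                            feature_kinds = c("lm", "cm", "lcm", "dm"),
                            bands = list(NULL, c(0.008, 0.08), c(0.008, 0.2)),
                            gsr = c(FALSE, TRUE),
                            scaling = "quadratic_variation", ...) {
  grid <- tidyr::expand_grid(
    feature = feature_kinds,
    gsr = gsr,
    band_id = seq_along(bands)
  )
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    band <- bands[[grid$band_id[i]]]
    cfg <- preprocess_config(do_gsr = grid$gsr[i], filter_band = band,
                             scaling = scaling)
    fp <- fingerprint_panel(panel, grid$feature[i], cfg, ...)
    tibble(
      feature = grid$feature[i], gsr = grid$gsr[i],
      band = if (is.null(band)) "none" else paste(band, collapse = "-"),
      accuracy = fp$accuracy, rk = fp$rk,
      accuracy_12 = fp$directions$visit1_to_visit2$accuracy,
      accuracy_21 = fp$directions$visit2_to_visit1$accuracy
    )
  })
  structure(rows, class = c("fi_stability", class(tibble())))
}
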
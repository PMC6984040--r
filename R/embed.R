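# Exact (dense) t-SNE, adequate for the <= few-hundred-sample panels this
# package works with: per-point precision calibrated to the target
# perplexity by bisection, early exaggeration, momentum gradient descent.
tsne_exact <- function(X, perplexity, seed, max_iter = 500, lr = NULL) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) p <- rep(1e-12, length(di)) else p <- p / sump
      H <- -sum(p * log(pmax(p, 1e-12)))
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  lr <- lr %||% max(n / 12, 50)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(max_iter)) {
      mult <- if (iter <= 100) 12 else 1
      mom <- if (iter <= 250) 0.5 else 0.8
      W <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(W) <- 0
      Q <- pmax(W / sum(W), 1e-12)
      L <- (mult * P - Q) * W
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      G <- mom * G - lr * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Two-dimensional non-linear embedding of feature vectors
#'
#' Maps samples into the plane with t-SNE (exact dense implementation,
#' deterministic given the seed) or Isomap (classical scaling of graph
#' geodesics, via [vegan::isomap()]).
#'
#' @param vectors Matrix (samples x dims), rownames = sample ids.
#' @param method `"tsne"` or `"isomap"`.
#' @param perplexity t-SNE perplexity; must be below `n / 3`.
#' @param n_neighbors Isomap neighbourhood size (default 10).
#' @param seed RNG seed (t-SNE initialization).
#' @param max_iter t-SNE gradient iterations.
#' @return An `"fi_embedding"`: `coords` (n x 2, rownames kept), `method`,
#'   `params`; `cluster_assignments` and `association` are filled by
#'   [cluster_and_associate()].
#' @export
embed_2d <- function(vectors, method = c("tsne", "isomap"),
                     perplexity = 50, n_neighbors = 10, seed = 1,
                     max_iter = 500) {
  method <- match.arg(method)
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 5) abort("need at least 5 samples to embed")
  if (method == "tsne") {
    if (perplexity >= n / 3) {
      abort(paste0("perplexity must be below n/3 = ", round(n / 3, 1),
                   "; feasible range is (1, ", round(n / 3, 1), ")"))
    }
    Y <- tsne_exact(X, perplexity, seed, max_iter)
    params <- list(perplexity = perplexity, seed = seed)
  } else {
    # grow the neighbourhood until the kNN graph is connected (geodesics
    # are undefined on a fragmented graph)
    k <- n_neighbors
    repeat {
      iso <- tryCatch(vegan::isomap(dist(X), ndim = 2, k = k),
                      error = function(e) e)
      if (!inherits(iso, "error")) break
      if (!grepl("fragmented", conditionMessage(iso)) || k >= n - 1) {
        abort(conditionMessage(iso))
      }
      k <- min(n - 1, k * 2)
      warn(paste0("neighbourhood graph fragmented; increasing k to ", k))
    }
    Y <- iso$points[, 1:2, drop = FALSE]
    params <- list(n_neighbors = k, seed = seed)
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("dim1", "dim2")
  structure(list(coords = Y, method = method, params = params,
                 cluster_assignments = NULL, association = NULL),
            class = "fi_embedding")
}

#' Cluster an embedding and test association with metadata
#'
#' Formalizes the visual "two distinct clusters" reading of an embedding as
#' a 2-means partition of the coordinates, then tests each metadata field
#' for association with the cluster label: chi-squared for categorical
#' fields, Mann-Whitney U for continuous ones, Bonferroni-corrected over
#' fields. Constant fields are skipped with a warning.
#'
#' @param result An `"fi_embedding"` from [embed_2d()].
#' @param metadata Data frame of per-sample fields, rows aligned with the
#'   embedded samples (or with rownames matching them).
#' @param seed Seed for the k-means initialization.
#' @return The embedding with `cluster_assignments` (integer vector) and
#'   `association` (tibble: field, type, statistic, p, p_adj) filled.
#' @export
cluster_and_associate <- function(result, metadata, seed = 1) {
  stopifnot(inherits(result, "fi_embedding"))
  metadata <- as.data.frame(metadata)
  if (!is.null(rownames(result$coords)) &&
      all(rownames(result$coords) %in% rownames(metadata))) {
    metadata <- metadata[rownames(result$coords), , drop = FALSE]
  }
  if (nrow(metadata) != nrow(result$coords)) {
    abort("metadata rows do not match embedded samples")
  }
  km <- with_seed(seed, kmeans(result$coords, centers = 2, nstart = 10))
  cl <- km$cluster
  fields <- names(metadata)
  rows <- purrr::map_dfr(fields, function(f) {
    x <- metadata[[f]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warn(paste0("skipping constant metadata field: ", f))
      return(tibble())
    }
    if (is.numeric(x)) {
      wt <- suppressWarnings(wilcox.test(x[cl == 1], x[cl == 2]))
      tibble(field = f, type = "continuous",
             statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(table(cl, x)))
      tibble(field = f, type = "categorical",
             statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  if (nrow(rows) > 0) {
    rows$p_adj <- pmin(1, rows$p * nrow(rows))
  }
  result$cluster_assignments <- cl
  result$association <- rows
  result
}
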
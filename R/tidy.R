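# broom-style accessors and ggplot2 displays for the package's result types

#' @export
tidy.fi_fingerprint <- function(x, ...) {
  purrr::map_dfr(names(x$directions), function(d) {
    tibble(direction = d,
           accuracy = x$directions[[d]]$accuracy,
           rk = x$directions[[d]]$rk)
  })
}

#' @export
glance.fi_fingerprint <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, accuracy = x$accuracy, rk = x$rk)
}

#' @export
tidy.fi_classification <- function(x, ...) {
  tibble::as_tibble(x$per_rep)
}

#' @export
glance.fi_classification <- function(x, ...) {
  dplyr::mutate(x$summary, classifier = x$classifier, n_reps = x$n_reps)
}

#' @export
tidy.fi_spectrum <- function(x, ...) {
  tibble(roi = seq_along(x$phases),
         phase = x$phases,
         magnitude = Mod(x$leading_eigenvector))
}

#' @export
glance.fi_spectrum <- function(x, ...) {
  mags <- Mod(x$eigenvalues)
  tibble(leading_magnitude = mags[1],
         second_ratio = if (length(mags) >= 3) mags[3] / mags[1] else NA_real_,
         degenerate = x$degenerate)
}

#' @export
tidy.fi_embedding <- function(x, ...) {
  out <- tibble(sample = rownames(x$coords) %||%
                  as.character(seq_len(nrow(x$coords))),
                dim1 = x$coords[, 1], dim2 = x$coords[, 2])
  if (!is.null(x$cluster_assignments)) out$cluster <- x$cluster_assignments
  out
}

#' @export
tidy.fi_sparse_svm <- function(x, ...) {
  if (is.null(x$graph)) {
    return(tibble(index = x$support, weight = abs(x$w[x$support])))
  }
  tibble::as_tibble(x$graph)
}

#' @export
tidy.fi_robustness <- function(x, ...) {
  tibble::as_tibble(x$pairwise)
}

#' @export
glance.fi_robustness <- function(x, ...) {
  tibble(statistic = x$kruskal$statistic, p = x$kruskal$p,
         n_groups = length(x$groups))
}

#' Heatmap display of a feature matrix
#'
#' @param m Feature matrix (lead, correlation, time-delay or DTW).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_feature_matrix <- function(m, title = NULL) {
  m <- unclass(m)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fi_embedding <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  if (!is.null(df$cluster)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                                 size = 2) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                    title = paste0("2-D embedding (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fi_stability <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$condition <- paste0(ifelse(df$gsr, "GSR", "no GSR"), ", ", df$band)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$accuracy,
                                   fill = .data$feature)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cross-visit 1-NN accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.fi_fingerprint <- function(object, direction = "visit1_to_visit2",
                                    ...) {
  conf <- object$directions[[direction]]$confusion
  df <- tidyr::expand_grid(true = seq_len(nrow(conf)),
                           pred = seq_len(ncol(conf)))
  df$count <- conf[cbind(df$true, df$pred)]
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "predicted subject", y = "true subject",
                  title = paste0("1-NN confusion (", direction, ")")) +
    ggplot2::theme_minimal()
}

#' Salience graph display: ROI-pair edges weighted by |w|
#'
#' @param model An `"fi_sparse_svm"` with a pair-mapped support.
#' @return A ggplot object placing ROIs on a circle with edges for the
#'   support pairs.
#' @export
plot_salience_graph <- function(model) {
  stopifnot(inherits(model, "fi_sparse_svm"))
  g <- model$graph
  if (is.null(g) || nrow(g) == 0) abort("empty support: nothing to plot")
  n <- max(g$roi_j)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble(roi = seq_len(n), x = cos(theta), y = sin(theta))
  edges <- dplyr::mutate(g,
    x = cos(2 * pi * (.data$roi_i - 1) / n),
    y = sin(2 * pi * (.data$roi_i - 1) / n),
    xend = cos(2 * pi * (.data$roi_j - 1) / n),
    yend = sin(2 * pi * (.data$roi_j - 1) / n))
  ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "#2166ac", alpha = 0.7) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$roi),
                       nudge_x = 0.08, nudge_y = 0.08, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "|w|")
}
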
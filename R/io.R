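#' Write a panel to disk as delimited tables plus a manifest
#'
#' Each record becomes one tab-delimited table (first column `roi`, then
#' one column per time point) under `dir`; a YAML manifest lists the
#' records (subject, visit, run, path), group labels, TR, provenance and --
#' when the panel came from the generator -- the generator parameters.
#'
#' @param panel An `"fi_panel"`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "fi_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(seq_len(nrow(panel)), function(i) {
    fname <- sprintf("%s_v%d_r%d.tsv", panel$subject_id[i],
                     panel$visit_id[i], panel$run_id[i])
    X <- panel$series[[i]]
    chr <- matrix(sprintf("%.17g", X), nrow(X), ncol(X))  # lossless round trip
    df <- data.frame(roi = rownames(X), chr, check.names = FALSE)
    colnames(df) <- c("roi", sprintf("t%03d", seq_len(ncol(X))))
    utils::write.table(df, file.path(dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(subject_id = panel$subject_id[i], visit_id = panel$visit_id[i],
         run_id = panel$run_id[i], path = fname)
  })
  labels <- as.list(setNames(
    panel$group[!duplicated(panel$subject_id)],
    panel$subject_id[!duplicated(panel$subject_id)]))
  params <- attr(panel, "params")
  manifest <- list(
    tr = attr(panel, "tr"),
    roi_names = attr(panel, "roi_names"),
    n_time = ncol(panel$series[[1]]),
    records = records, labels = labels,
    provenance = as.list(attr(panel, "provenance") %||% character()),
    generator = if (!is.null(params)) {
      p <- unclass(params)
      p$driver_harmonics <- apply(p$driver_harmonics, 1, as.list,
                                  simplify = FALSE)
      p
    }
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

#' Read a panel from a manifest
#'
#' Validates every record against the manifest: the file must exist, parse
#' as numeric, have the declared number of time points, and list the ROIs
#' in the manifest's order (no silent reordering). Errors name the
#' offending record.
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [write_panel()].
#' @return An `"fi_panel"`.
#' @export
read_panel <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  roi_names <- unlist(man$roi_names)
  rows <- lapply(man$records, function(rec) {
    f <- file.path(dir, rec$path)
    if (!file.exists(f)) {
      abort(paste0("record ", rec$subject_id, " visit ", rec$visit_id,
                   ": missing file ", rec$path))
    }
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = NA)
    X <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(X) || anyNA(X)) {
      abort(paste0("record ", rec$subject_id, " visit ", rec$visit_id,
                   ": non-numeric cell(s) in ", rec$path))
    }
    if (ncol(X) != man$n_time) {
      abort(paste0("record ", rec$subject_id, " visit ", rec$visit_id,
                   ": has ", ncol(X), " time points, manifest says ",
                   man$n_time))
    }
    if (!identical(as.character(df$roi), roi_names)) {
      abort(paste0("record ", rec$subject_id, " visit ", rec$visit_id,
                   ": ROI names/order differ from the manifest"))
    }
    X <- unname(X)
    rownames(X) <- roi_names
    tibble(subject_id = rec$subject_id, visit_id = as.integer(rec$visit_id),
           run_id = as.integer(rec$run_id),
           group = man$labels[[rec$subject_id]] %||% NA_character_,
           series = list(X))
  })
  panel <- dplyr::bind_rows(rows)
  new_fi_panel(panel, tr = man$tr, roi_names = roi_names,
               provenance = unlist(man$provenance) %||% character())
}

#' Write a feature matrix with a metadata sidecar
#'
#' The matrix goes to a tab-delimited table with ROI-name headers; a YAML
#' sidecar (`<path>.meta.yaml`) records the kind tag, units (seconds for
#' time-delay matrices), and preprocessing provenance, so a later
#' [read_feature()] can re-validate the kind's invariants.
#'
#' @param m Feature matrix.
#' @param kind One of `"lm"`, `"cm"`, `"lcm"`, `"tdm"`, `"dm"`.
#' @param path Output path for the table.
#' @param provenance Character vector of preprocessing steps.
#' @return `path`, invisibly.
#' @export
write_feature <- function(m, kind, path, provenance = character()) {
  m <- unclass(m)
  validate_feature(m, kind)
  roi <- rownames(m) %||% sprintf("ROI%02d", seq_len(nrow(m)))
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))  # bit-stable round trip
  df <- data.frame(roi = roi, chr, check.names = FALSE)
  colnames(df) <- c("roi", roi)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(kind = kind,
               units = if (kind == "tdm") "seconds" else "dimensionless",
               provenance = as.list(provenance))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

validate_feature <- function(m, kind) {
  tol <- 1e-8 * max(abs(m), 1e-300)
  dev <- switch(kind,
    lm = max(abs(m + t(m))),
    tdm = max(abs(m + t(m))),
    cm = max(max(abs(m - t(m))), max(abs(diag(m) - 1))),
    lcm = max(max(abs(m - t(m))), max(abs(diag(m) - 1))),
    dm = max(max(abs(m - t(m))), max(abs(diag(m))), -min(min(m), 0)),
    abort(paste0("unknown feature kind: ", kind))
  )
  if (dev > tol) {
    abort(paste0(kind, " invariant violated (max deviation ", format(dev), ")"))
  }
  invisible(TRUE)
}

#' Read a feature matrix and re-validate its invariants
#'
#' @param path Table path written by [write_feature()].
#' @return The matrix, with attributes `kind`, `units` and `provenance`
#'   restored from the sidecar; skew/symmetry invariants are re-checked and
#'   violations abort with the maximal deviation.
#' @export
read_feature <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$roi
  validate_feature(m, meta$kind)
  attr(m, "kind") <- meta$kind
  attr(m, "units") <- meta$units
  attr(m, "provenance") <- unlist(meta$provenance) %||% character()
  m
}
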
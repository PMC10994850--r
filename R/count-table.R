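#' Sample x feature count tables
#'
#' The central container downstream of read assignment: a samples-by-features
#' matrix of non-negative counts with a feature-class label per column
#' (endogenous_16S, barcode_tag, spike_tag, plant_ITS, fungal_ITS,
#' unassigned) and a per-sample read depth (row sum, including any
#' unassigned column).
#'
#' @param counts Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param feature_class Character vector of class labels, named by feature or
#'   in column order.
#' @param integer_counts Require integral entries (default TRUE; corrected
#'   tables produced by [apply_correction()] are real-valued).
#' @return A `count_table` object.
#' @export
count_table <- function(counts, feature_class, integer_counts = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must have sample rownames and feature colnames",
         call. = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (integer_counts && any(counts != round(counts))) {
    stop("counts must be integral", call. = FALSE)
  }
  if (!is.null(names(feature_class))) {
    feature_class <- feature_class[colnames(counts)]
  }
  if (length(feature_class) != ncol(counts) || anyNA(feature_class)) {
    stop("feature_class must label every feature column", call. = FALSE)
  }
  bad <- setdiff(unique(feature_class), FEATURE_CLASSES)
  if (length(bad)) {
    stop("unknown feature classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(counts = counts,
                 feature_class = stats::setNames(as.character(feature_class),
                                                 colnames(counts)),
                 depth = rowSums(counts),
                 corrected = !integer_counts),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d features%s\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(x$corrected)) " (corrected, real-valued)" else ""))
  cls <- table(x$feature_class)
  cat("classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  cat("depth:", paste(range(x$depth), collapse = "-"), "\n")
  invisible(x)
}

features_of_class <- function(table, classes) {
  names(table$feature_class)[table$feature_class %in% classes]
}

#' Remove features from a count table (in-silico depletion)
#'
#' Drops the named feature columns, leaving all other entries untouched;
#' depth metadata is recomputed and the pre-depletion depth retained as
#' provenance (attribute `original_depth`). Used e.g. to deplete a focal
#' strain's 16S feature before community-level analysis.
#'
#' @param table A `count_table`.
#' @param feature_ids Features to remove (must all exist in `table`).
#' @return The depleted `count_table`.
#' @export
deplete_features <- function(table, feature_ids) {
  stopifnot(inherits(table, "count_table"))
  unknown <- setdiff(feature_ids, colnames(table$counts))
  if (length(unknown)) {
    stop("unknown feature ids: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- setdiff(colnames(table$counts), feature_ids)
  out <- count_table(table$counts[, keep, drop = FALSE],
                     table$feature_class[keep],
                     integer_counts = !isTRUE(table$corrected))
  attr(out, "original_depth") <- table$depth
  out
}

#' Read / write count tables as TSV
#'
#' Counts are written as a tab-separated table with samples as rows (first
#' column `sample_id`, one column per feature) plus a sidecar TSV of feature
#' classes (`feature_id`, `class`), with provenance comment lines.
#'
#' @param table A `count_table`.
#' @param path Counts TSV path; the sidecar is written next to it with
#'   suffix `.classes.tsv`.
#' @param provenance Optional provenance comment lines.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a `count_table`.
#' @export
write_count_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write_tsv(df, path, provenance = provenance)
  classes <- data.frame(feature_id = names(table$feature_class),
                        class = unname(table$feature_class))
  write_tsv(classes, sidecar_path(path), provenance = provenance)
  invisible(path)
}

sidecar_path <- function(path) sub("(\\.tsv)?$", ".classes.tsv", path)

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample_id") {
    stop("count table TSV must start with a sample_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  classes <- read_tsv(sidecar_path(path))
  count_table(m, stats::setNames(classes$class, classes$feature_id),
              integer_counts = all(m == round(m)))
}
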
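#' Reference feature sets for read assignment
#'
#' A reference set maps amplicon sequences to features: endogenous 16S V5--V7
#' per strain, barcode tags, spike tags, plant ITS, fungal ITS. Near-isogenic
#' strains (wild type vs mutants) share a single endogenous_16S feature;
#' strain resolution comes only from their barcode tags, so identical
#' sequences across features are rejected.
#'
#' @param features Data frame with columns `feature_id`, `class` (one of the
#'   five reference classes), `sequence`, and optionally `strain_id`.
#' @return A `reference_set`.
#' @export
reference_set <- function(features) {
  required <- c("feature_id", "class", "sequence")
  if (!all(required %in% names(features))) {
    stop("features needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) == 0L) stop("empty reference set", call. = FALSE)
  if (!"strain_id" %in% names(features)) features$strain_id <- NA_character_
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature ids: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(features$class, setdiff(FEATURE_CLASSES, "unassigned"))
  if (length(bad_class)) {
    stop("unknown reference classes: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  features$sequence <- toupper(features$sequence)
  if (any(!is_dna(features$sequence))) {
    stop("reference sequences must be non-empty A/C/G/T strings",
         call. = FALSE)
  }
  seqs <- features$sequence
  rc <- revcomp(seqs)
  same <- outer(seqs, seqs, "==") | outer(seqs, rc, "==")
  diag(same) <- FALSE
  if (any(same)) {
    idx <- which(same, arr.ind = TRUE)[1, ]
    stop("features '", features$feature_id[idx[1]], "' and '",
         features$feature_id[idx[2]],
         "' share an identical sequence (forward or reverse complement); ",
         "collapse them into one shared feature", call. = FALSE)
  }
  rownames(features) <- NULL
  structure(list(features = features), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cls <- table(x$features$class)
  cat(sprintf("<reference_set> %d features (%s)\n", nrow(x$features),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @rdname reference_set
#' @param paths One or more FASTA files whose headers carry the class (and
#'   optionally strain) as pipe-separated tokens:
#'   `>feature_id|class` or `>feature_id|class|strain_id`.
#' @return `build_reference_set()` returns a validated `reference_set`.
#' @export
build_reference_set <- function(paths) {
  seqs <- unlist(lapply(paths, read_fasta))
  if (length(seqs) == 0L) stop("no sequences in FASTA input", call. = FALSE)
  tok <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(tok) < 2L)) {
    stop("reference FASTA headers must be 'feature_id|class[|strain_id]'",
         call. = FALSE)
  }
  reference_set(data.frame(
    feature_id = vapply(tok, `[`, character(1), 1L),
    class = vapply(tok, `[`, character(1), 2L),
    sequence = unname(seqs),
    strain_id = vapply(tok, function(t)
      if (length(t) >= 3L) t[3] else NA_character_, character(1))))
}

#' Write a reference set to FASTA
#'
#' Headers use the `feature_id|class[|strain_id]` token convention read back
#' by [build_reference_set()].
#'
#' @param refs A `reference_set`.
#' @param path Output path.
#' @export
write_reference_set <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  f <- refs$features
  hdr <- ifelse(is.na(f$strain_id),
                paste(f$feature_id, f$class, sep = "|"),
                paste(f$feature_id, f$class, f$strain_id, sep = "|"))
  write_fasta(stats::setNames(f$sequence, hdr), path)
}
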
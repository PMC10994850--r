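#' Assign amplicon reads to reference features by bounded edit distance
#'
#' Each read is compared against every reference on both strands and
#' assigned to the reference with minimum Levenshtein distance, provided
#' that distance is at most `max_distance` and the runner-up reference is at
#' least `margin` edits worse; otherwise the read is `"unassigned"`. Ties at
#' the best distance are never broken arbitrarily: an ambiguous read is
#' always unassigned, which makes assignment independent of read and
#' reference order. Reads containing non-ACGT characters are skipped with a
#' warning and counted as unassigned.
#'
#' @param reads Character vector of reads (named with read ids), a
#'   `DNAStringSet`, or a FASTA/FASTQ path (qualities are ignored).
#' @param refs A [reference_set()].
#' @param max_distance Maximum accepted edit distance (default 3).
#' @param margin Minimum lead over the runner-up distance (default 1).
#' @return An `assignment_result`: `assignments`, a data frame with one row
#'   per read (`read_id`, `label`, `distance`, `ambiguous`), and `counts`, a
#'   named vector over all reference features plus `"unassigned"` summing to
#'   the number of input reads.
#' @export
assign_reads <- function(reads, refs, max_distance = 3L, margin = 1L) {
  stopifnot(inherits(refs, "reference_set"), max_distance >= 0, margin >= 1)
  if (inherits(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  } else if (is.character(reads) && length(reads) == 1L &&
             is.null(names(reads)) && file.exists(reads)) {
    reads <- read_reads_file(reads)
  }
  stopifnot(is.character(reads))
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    names(reads) <- paste0("read", seq_along(reads))
  }
  reads <- toupper(reads)
  ids <- refs$features$feature_id
  ref_seq <- refs$features$sequence
  ref_rc <- revcomp(ref_seq)

  n <- length(reads)
  label <- rep("unassigned", n)
  distance <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)

  ok <- is_dna(reads)
  if (any(!ok)) {
    warning(sum(!ok), " read(s) with non-ACGT characters counted as ",
            "unassigned", call. = FALSE)
  }
  todo <- which(ok)

  # fast path: exact matches are unambiguous whenever margin == 1, because
  # reference sequences are validated pairwise distinct on both strands
  if (margin == 1L && length(todo)) {
    hit <- match(reads[todo], ref_seq)
    hit_rc <- match(reads[todo], ref_rc)
    exact <- !is.na(hit) | !is.na(hit_rc)
    idx <- ifelse(is.na(hit), hit_rc, hit)
    label[todo[exact]] <- ids[idx[exact]]
    distance[todo[exact]] <- 0L
    todo <- todo[!exact]
  }

  if (length(todo)) {
    uniq <- unique(reads[todo])
    d <- pmin(utils::adist(uniq, ref_seq), utils::adist(uniq, ref_rc))
    best_i <- max.col(-d, ties.method = "first")
    best <- d[cbind(seq_along(uniq), best_i)]
    runner <- apply(d, 1L, function(r) {
      if (length(r) == 1L) Inf else sort(r, partial = 2L)[2L]
    })
    assignable <- best <= max_distance & (runner - best) >= margin
    tie <- best <= max_distance & !assignable & (runner - best) < margin
    m <- match(reads[todo], uniq)
    label[todo] <- ifelse(assignable[m], ids[best_i[m]], "unassigned")
    distance[todo] <- as.integer(best[m])
    ambiguous[todo] <- tie[m]
  }

  counts <- table(factor(label, levels = c(ids, "unassigned")))
  structure(list(
    assignments = data.frame(read_id = names(reads), label = label,
                             distance = distance, ambiguous = ambiguous),
    counts = stats::setNames(as.integer(counts), names(counts))),
    class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("<assignment_result> %d reads, %d assigned (%.1f%%), %d ambiguous\n",
              n, n - x$counts[["unassigned"]],
              100 * (n - x$counts[["unassigned"]]) / max(n, 1L),
              sum(x$assignments$ambiguous)))
  invisible(x)
}

#' Build a count table from per-sample read sets
#'
#' Runs [assign_reads()] on each element of `read_sets` and stacks the
#' resulting count rows into a [count_table()], with feature classes taken
#' from the reference set and an `unassigned` column.
#'
#' @param read_sets Named list of read vectors (or FASTA/FASTQ paths), one
#'   per sample.
#' @inheritParams assign_reads
#' @return A `count_table` whose row sums equal the per-sample read counts.
#' @export
assign_samples <- function(read_sets, refs, max_distance = 3L, margin = 1L) {
  stopifnot(is.list(read_sets), length(read_sets) >= 1)
  if (is.null(names(read_sets))) {
    names(read_sets) <- paste0("sample", seq_along(read_sets))
  }
  rows <- lapply(read_sets, function(r)
    assign_reads(r, refs, max_distance, margin)$counts)
  m <- do.call(rbind, rows)
  rownames(m) <- names(read_sets)
  classes <- c(stats::setNames(refs$features$class, refs$features$feature_id),
               unassigned = "unassigned")
  count_table(m, classes)
}
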
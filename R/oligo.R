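#' Oligonucleotide ligation units
#'
#' A barcode tag is assembled by random blunt-end ligation of short
#' double-stranded oligonucleotide units. Each unit is exactly 38 nt long and
#' is the concatenation of four pyrosequencing-friendly sub-barcodes, designed
#' so that neither homopolymer runs nor tandem dinucleotide tracts exceed a
#' configured maximum. `oligo_unit()` validates a single unit;
#' `load_oligo_set()` validates a labelled set (for example read from FASTA).
#'
#' @param label Single-letter unit identifier (conventionally `a`--`j`).
#' @param sequence DNA string of length 38 (A/C/G/T only).
#' @param sub_barcodes Optional character vector of four contiguous
#'   sub-barcodes whose concatenation equals `sequence`. Defaults to a
#'   10/9/10/9 split.
#' @param max_homopolymer Longest allowed single-base run (default 2).
#' @param max_dinucleotide_repeats Longest allowed tandem repeat count of any
#'   dinucleotide (default 2, i.e. `ACACAC` is rejected).
#' @return An object of class `oligo_unit`.
#' @export
oligo_unit <- function(label, sequence, sub_barcodes = NULL,
                       max_homopolymer = 2, max_dinucleotide_repeats = 2) {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!is_dna(sequence)) {
    stop("oligo '", label, "': sequence contains non-ACGT characters",
         call. = FALSE)
  }
  if (nchar(sequence) != 38L) {
    stop("oligo '", label, "': sequence must be exactly 38 nt, got ",
         nchar(sequence), call. = FALSE)
  }
  if (has_homopolymer(sequence, max_homopolymer)) {
    stop("oligo '", label, "': homopolymer run longer than ",
         max_homopolymer, call. = FALSE)
  }
  if (has_dinucleotide_tract(sequence, max_dinucleotide_repeats)) {
    stop("oligo '", label, "': dinucleotide tract repeated more than ",
         max_dinucleotide_repeats, " times", call. = FALSE)
  }
  if (sequence == revcomp(sequence)) {
    stop("oligo '", label, "': sequence is palindromic (equal to its ",
         "reverse complement)", call. = FALSE)
  }
  if (is.null(sub_barcodes)) {
    cut <- cumsum(c(10L, 9L, 10L, 9L))
    sub_barcodes <- substring(sequence, c(1L, utils::head(cut, -1) + 1L), cut)
  }
  if (paste(sub_barcodes, collapse = "") != sequence) {
    stop("oligo '", label, "': sub-barcodes do not concatenate to sequence",
         call. = FALSE)
  }
  structure(list(label = label, sequence = sequence,
                 sub_barcodes = sub_barcodes),
            class = "oligo_unit")
}

#' @export
print.oligo_unit <- function(x, ...) {
  cat(sprintf("<oligo_unit %s> %s (%d nt, %d sub-barcodes)\n",
              x$label, x$sequence, nchar(x$sequence), length(x$sub_barcodes)))
  invisible(x)
}

#' @rdname oligo_unit
#' @param x For `load_oligo_set()`: a named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file; names are the unit
#'   labels.
#' @param ... Passed on to `oligo_unit()` (constraint maxima).
#' @return `load_oligo_set()` returns an `oligo_set`, a validated list of
#'   `oligo_unit` objects.
#' @export
load_oligo_set <- function(x, ...) {
  if (inherits(x, "Biostrings::DNAStringSet") || inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             file.exists(x)) {
    x <- read_fasta(x)
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("expected named sequences (or a FASTA path)", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate oligo labels: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  units <- mapply(oligo_unit, label = names(x), sequence = unname(x),
                  MoreArgs = list(...), SIMPLIFY = FALSE)
  seqs <- toupper(unname(x))
  if (anyDuplicated(seqs)) {
    stop("duplicate oligo sequences (labels ",
         paste(names(x)[seqs %in% seqs[duplicated(seqs)]], collapse = ", "),
         ")", call. = FALSE)
  }
  rc <- revcomp(seqs)
  hit <- outer(seqs, rc, "==")
  diag(hit) <- FALSE   # self reverse-complement already rejected per unit
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)[1, ]
    stop("oligo '", names(x)[idx[1]], "' equals the reverse complement of '",
         names(x)[idx[2]], "'", call. = FALSE)
  }
  structure(units, names = names(x), class = "oligo_set")
}

#' @export
print.oligo_set <- function(x, ...) {
  cat(sprintf("<oligo_set> %d units (%s), 38 nt each\n",
              length(x), paste(names(x), collapse = "")))
  invisible(x)
}

oligo_sequences <- function(oligos) {
  vapply(oligos, `[[`, character(1), "sequence")
}

#' Generate a constraint-compliant oligo unit set
#'
#' Draws random 38-nt units composed of four sub-barcodes (10/9/10/9 nt) under
#' the design constraints: no homopolymer run or tandem dinucleotide tract
#' beyond the configured maxima, all sub-barcodes across the whole set at
#' pairwise Levenshtein distance >= `min_sub_distance`, no palindromic units,
#' and no unit equal to another unit or its reverse complement. Deterministic
#' given `seed`.
#'
#' @param n Number of units (default 10, labelled `a`--`j`).
#' @param seed Integer seed.
#' @param sub_lengths Lengths of the four sub-barcodes; must sum to 38.
#' @param min_sub_distance Minimum pairwise edit distance between any two
#'   sub-barcodes in the set (default 3).
#' @inheritParams oligo_unit
#' @return An `oligo_set`.
#' @export
generate_oligo_set <- function(n = 10, seed = 1L,
                               sub_lengths = c(10L, 9L, 10L, 9L),
                               max_homopolymer = 2,
                               max_dinucleotide_repeats = 2,
                               min_sub_distance = 3) {
  stopifnot(n >= 1, sum(sub_lengths) == 38L, length(sub_lengths) == 4L)
  set.seed(as.integer(seed))
  labels <- make.unique(rep(letters, length.out = n), sep = "")
  subs <- character(0)
  seqs <- character(0)
  units <- vector("list", n)
  compliant <- function(s) {
    !has_homopolymer(s, max_homopolymer) &&
      !has_dinucleotide_tract(s, max_dinucleotide_repeats)
  }
  i <- 1L
  while (i <= n) {
    cand <- character(0)
    for (len in sub_lengths) {
      repeat {
        s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        pool <- c(subs, cand)
        if (compliant(s) &&
            (!length(pool) || min(utils::adist(s, pool)) >= min_sub_distance)) {
          cand <- c(cand, s)
          break
        }
      }
    }
    full <- paste(cand, collapse = "")
    if (!compliant(full) || full == revcomp(full) ||
        full %in% seqs || full %in% revcomp(seqs)) {
      next
    }
    units[[i]] <- oligo_unit(labels[i], full, cand,
                             max_homopolymer = max_homopolymer,
                             max_dinucleotide_repeats = max_dinucleotide_repeats)
    subs <- c(subs, cand)
    seqs <- c(seqs, full)
    i <- i + 1L
  }
  structure(units, names = labels, class = "oligo_set")
}

#' Default frozen oligo unit set
#'
#' The ten-unit fixture shipped with the package
#' (`inst/extdata/synthetic_oligos.fasta`), generated with
#' `generate_oligo_set(10, seed = 101)`. These are synthetic stand-ins
#' satisfying the published design constraints; the original unit sequences
#' are not public.
#'
#' @return An `oligo_set` of ten 38-nt units labelled `a`--`j`.
#' @export
default_oligo_set <- function() {
  path <- system.file("extdata", "synthetic_oligos.fasta", package = "bartag",
                      mustWork = TRUE)
  load_oligo_set(path)
}
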
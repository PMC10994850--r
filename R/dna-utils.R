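# Internal DNA string helpers. Sequences live as plain uppercase character
# vectors; Biostrings is used at I/O boundaries and for reverse complement.

DNA_BASES <- c("A", "C", "G", "T")

FEATURE_CLASSES <- c("endogenous_16S", "barcode_tag", "spike_tag",
                     "plant_ITS", "fungal_ITS", "unassigned")

is_dna <- function(x) {
  nzchar(x) & grepl("^[ACGT]+$", x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

max_homopolymer_run <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(b) max(rle(b)$lengths), integer(1))
}

# TRUE when x contains a dinucleotide unit repeated more than max_repeats
# times in tandem (e.g. ACACAC for max_repeats = 2).
has_dinucleotide_tract <- function(x, max_repeats = 2) {
  grepl(sprintf("([ACGT]{2})\\1{%d,}", max_repeats), x)
}

has_homopolymer <- function(x, max_run = 2) {
  max_homopolymer_run(x) > max_run
}

read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

read_reads_file <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  # FASTQ descriptions may carry comments after the id
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

provenance_header <- function(seed = NULL, inputs = character()) {
  lines <- c(
    sprintf("# bartag %s", as.character(utils::packageVersion("bartag"))),
    sprintf("# created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (length(inputs)) {
    digests <- vapply(inputs, function(f) {
      if (file.exists(f)) sprintf("%s (%d bytes)", basename(f), file.size(f)) else f
    }, character(1))
    lines <- c(lines, paste0("# input: ", digests))
  }
  lines
}

# TSV dialect: tab-separated, UTF-8, mandatory header, no quoting, floats at
# 12 significant digits, '#'-prefixed provenance comment lines before header.
write_tsv <- function(df, path, provenance = NULL) {
  if (file.exists(path)) {
    stop("refusing to overwrite existing output: ", path, call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance)) writeLines(provenance, con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}
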
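#' Default primer binding sites of a tag scaffold
#'
#' The eight primer sites flanking the barcode array: bacterial 16S V5--V7
#' (799F/1192R, degenerate bases resolved), fungal ITS (ITS1F/ITS2), plant
#' ITS (p4/p5) and the barcode-specific pair. The plant-ITS and barcode
#' primer sequences shipped here are synthetic placeholders with the same
#' role and typical length; the 16S and fungal ITS sites are the standard
#' published primer sequences.
#'
#' @return Named character vector of eight primer sequences (each given
#'   5'->3' as the primer oligo itself).
#' @export
default_primer_set <- function() {
  c(`16S_fwd`        = "AACAGGATTAGATACCCTG",     # 799F (M->A, K->T)
    `16S_rev`        = "ACGTCATCCCCACCTTCC",      # 1192R
    fungal_ITS_fwd   = "CTTGGTCATTTAGAGGAAGTAA",  # ITS1F
    fungal_ITS_rev   = "GCTGCGTTCTTCATCGATGC",    # ITS2
    plant_ITS_p4     = "GATGCGTAGACGACCTAAGC",    # synthetic placeholder
    plant_ITS_p5     = "CCGATTGTTCACGGTAGCAT",    # synthetic placeholder
    barcode_fwd      = "ACGTTAGCGGATCCTACGAA",    # synthetic placeholder
    barcode_rev      = "TGCAACGTTCGGATGCTACC")    # synthetic placeholder
}

#' @rdname default_primer_set
#' @return `default_scaffold_layout()`: the order of elements along the
#'   forward strand of the scaffold. Sites listed before `"array"` are
#'   inserted as given (+ strand); sites after it are inserted as their
#'   reverse complement (- strand), so that every primer pair's amplicon
#'   spans the array and the pairs are nested with the barcode pair
#'   innermost.
#' @export
default_scaffold_layout <- function() {
  c("16S_fwd", "fungal_ITS_fwd", "plant_ITS_p4", "barcode_fwd",
    "array",
    "barcode_rev", "plant_ITS_p5", "fungal_ITS_rev", "16S_rev")
}

scaffold_primer_pairs <- function() {
  list(`16S`       = c("16S_fwd", "16S_rev"),
       fungal_ITS  = c("fungal_ITS_fwd", "fungal_ITS_rev"),
       plant_ITS   = c("plant_ITS_p4", "plant_ITS_p5"),
       barcode     = c("barcode_fwd", "barcode_rev"))
}

#' In-silico PCR on a linear template
#'
#' Finds exact binding sites of the forward primer on the plus strand and of
#' the reverse primer on the minus strand, and returns every amplicon
#' delimited by a forward site upstream of a reverse site.
#'
#' @param template DNA string.
#' @param fwd,rev Primer sequences, 5'->3'.
#' @return Data frame with columns `start`, `end` (1-based inclusive on the
#'   plus strand), `length`, `sequence`; zero rows if no amplicon forms.
#' @export
insilico_pcr <- function(template, fwd, rev) {
  find_all <- function(pat) {
    hit <- gregexpr(pat, template, fixed = TRUE)[[1]]
    if (hit[1] == -1L) integer(0) else as.integer(hit)
  }
  f_start <- find_all(fwd)
  r_site <- revcomp(rev)
  r_start <- find_all(r_site)
  out <- expand.grid(start = f_start, r = r_start)
  if (nrow(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0)))
  }
  out$end <- out$r + nchar(r_site) - 1L
  out <- out[out$end > out$start, c("start", "end"), drop = FALSE]
  out$length <- out$end - out$start + 1L
  out$sequence <- substring(template, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Assemble a full tag scaffold around a barcode array
#'
#' Concatenates, in layout order, the forward-side primer sites, the barcode
#' array, and the reverse complements of the reverse-side primer sites, and
#' validates the result: every primer site must occur exactly once on its
#' designated strand, every primer pair's in-silico amplicon must contain the
#' complete array, and both the barcode-pair and the 16S-pair amplicons must
#' be shorter than the endogenous 16S V5--V7 amplicon produced by the same
#' 16S primers (the two products are size-separable on a gel).
#'
#' @param array A single-product `barcode_arrays` object (or a collection of
#'   length one).
#' @param primers Named primer set, see [default_primer_set()].
#' @param layout Element order, see [default_scaffold_layout()].
#' @param spacer Spacer sequence inserted between consecutive elements
#'   (default none).
#' @param id Scaffold identifier.
#' @param endogenous_16s_length Length in nt of the endogenous V5--V7
#'   amplicon used for the size-separability check (default 400).
#' @return A `tag_scaffold`: `id`, `array_sequence`, `full_sequence`,
#'   `features` (name/start/end/strand, 1-based inclusive), `amplicons` (one
#'   row per primer pair), `primers`, `endogenous_16s_length`.
#' @export
assemble_scaffold <- function(array, primers = default_primer_set(),
                              layout = default_scaffold_layout(),
                              spacer = "", id = "tag1",
                              endogenous_16s_length = 400L) {
  if (inherits(array, "barcode_arrays")) {
    if (array$n != 1L) stop("assemble_scaffold takes a single array; got ",
                            array$n, call. = FALSE)
    array_seq <- array$sequence
    array_units <- array$units
  } else if (is.character(array) && length(array) == 1L) {
    array_seq <- toupper(array)
    array_units <- NULL
  } else {
    stop("array must be a single barcode array or a DNA string", call. = FALSE)
  }
  stopifnot(is_dna(array_seq))
  site_names <- setdiff(layout, "array")
  missing <- setdiff(unlist(scaffold_primer_pairs()), names(primers))
  if (length(missing)) {
    stop("primer set lacks sites: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  arr_at <- match("array", layout)
  if (is.na(arr_at)) stop("layout must contain 'array'", call. = FALSE)

  pieces <- character(length(layout))
  strand <- character(length(layout))
  for (i in seq_along(layout)) {
    el <- layout[i]
    if (el == "array") {
      pieces[i] <- array_seq
      strand[i] <- "+"
    } else if (i < arr_at) {
      pieces[i] <- primers[[el]]
      strand[i] <- "+"
    } else {
      pieces[i] <- revcomp(primers[[el]])
      strand[i] <- "-"
    }
  }
  full <- paste(pieces, collapse = spacer)
  len <- nchar(pieces)
  gap <- nchar(spacer)
  start <- cumsum(c(1L, utils::head(len + gap, -1)))
  features <- data.frame(name = layout, start = start,
                         end = start + len - 1L, strand = strand)
  arr_row <- features[features$name == "array", ]

  # each primer site exactly once on its designated strand
  for (i in which(layout != "array")) {
    site_plus <- pieces[i]  # plus-strand representation of the site
    n_occ <- length(gregexpr(site_plus, full, fixed = TRUE)[[1]])
    if (gregexpr(site_plus, full, fixed = TRUE)[[1]][1] == -1L) n_occ <- 0L
    if (n_occ != 1L) {
      stop("primer site '", layout[i], "' occurs ", n_occ,
           " times in the assembled scaffold (collision)", call. = FALSE)
    }
  }

  pairs <- scaffold_primer_pairs()
  amplicons <- do.call(rbind, lapply(names(pairs), function(p) {
    amp <- insilico_pcr(full, primers[[pairs[[p]][1]]],
                        primers[[pairs[[p]][2]]])
    if (nrow(amp) != 1L) {
      stop("primer pair '", p, "' yields ", nrow(amp),
           " amplicons on the scaffold; expected exactly 1", call. = FALSE)
    }
    if (!(amp$start <= arr_row$start && amp$end >= arr_row$end)) {
      stop("amplicon of primer pair '", p,
           "' does not contain the complete barcode array", call. = FALSE)
    }
    cbind(pair = p, amp[, c("start", "end", "length")])
  }))
  for (p in c("barcode", "16S")) {
    l <- amplicons$length[amplicons$pair == p]
    if (l >= endogenous_16s_length) {
      stop("scaffold ", p, "-pair amplicon (", l, " nt) is not shorter than ",
           "the endogenous 16S V5-V7 amplicon (", endogenous_16s_length,
           " nt); products would not be size-separable", call. = FALSE)
    }
  }
  structure(list(id = id, array_sequence = array_seq,
                 array_units = array_units, full_sequence = full,
                 features = features, amplicons = amplicons,
                 primers = primers[site_names],
                 endogenous_16s_length = as.integer(endogenous_16s_length)),
            class = "tag_scaffold")
}

#' @export
print.tag_scaffold <- function(x, ...) {
  cat(sprintf("<tag_scaffold %s> %d nt, array %d nt\n", x$id,
              nchar(x$full_sequence), nchar(x$array_sequence)))
  print(x$amplicons, row.names = FALSE)
  invisible(x)
}

#' Write / read a tag scaffold as a GenBank-style feature record
#'
#' Emits the scaffold as a flat-file record with `primer_bind` features for
#' the eight sites and a `misc_feature` for the barcode array (1-based
#' inclusive coordinates, minus-strand features in `complement(..)`
#' notation), followed by the origin sequence. `read_scaffold_record()`
#' parses such a record back; re-extracting the array feature reproduces the
#' input array sequence exactly.
#'
#' @param scaffold A `tag_scaffold`.
#' @param path Output (input) file path.
#' @return `write_scaffold_record()` returns `path` invisibly;
#'   `read_scaffold_record()` returns a list with `id`, `sequence`,
#'   `features` and the re-extracted `array_sequence`.
#' @export
write_scaffold_record <- function(scaffold, path) {
  stopifnot(inherits(scaffold, "tag_scaffold"))
  seq <- tolower(scaffold$full_sequence)
  n <- nchar(seq)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     linear   SYN",
                     scaffold$id, n),
             sprintf("DEFINITION  barcode tag scaffold %s.", scaffold$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  for (i in seq_len(nrow(scaffold$features))) {
    f <- scaffold$features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$name == "array") "misc_feature" else "primer_bind"
    lines <- c(lines,
               sprintf("     %-15s %s", key, loc),
               sprintf("                     /label=\"%s\"",
                       if (f$name == "array") "barcode_array" else f$name))
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, n), by = 10L)
    chunk <- substring(seq, starts, pmin(starts + 9L, n))
    lines <- c(lines, sprintf("%9d %s", p, paste(chunk, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scaffold_record
#' @export
read_scaffold_record <- function(path) {
  lines <- readLines(path)
  id <- strsplit(trimws(sub("^LOCUS", "", lines[grepl("^LOCUS", lines)][1])),
                 "\\s+")[[1]][1]
  ori <- which(lines == "ORIGIN")
  seq_lines <- lines[(ori + 1L):(length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  feat_idx <- grep("^\\s{5}(primer_bind|misc_feature)\\s", lines)
  features <- do.call(rbind, lapply(feat_idx, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    loc <- parts[2]
    strand <- if (grepl("^complement", loc)) "-" else "+"
    nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
    lab <- sub(".*/label=\"([^\"]+)\".*", "\\1", lines[i + 1L])
    data.frame(name = lab, start = nums[1], end = nums[2], strand = strand)
  }))
  arr <- features[features$name == "barcode_array", ]
  array_sequence <- if (nrow(arr) == 1L)
    substring(sequence, arr$start, arr$end) else NA_character_
  list(id = id, sequence = sequence, features = features,
       array_sequence = array_sequence)
}

#' Validate distinguishability of a tag set
#'
#' Computes all pairwise Levenshtein distances between array sequences,
#' taking for each pair the minimum over strand orientations, and flags pairs
#' below the required minimum as well as arrays carrying homopolymer runs or
#' tandem dinucleotide tracts beyond the configured maxima (such tracts can
#' arise at unit junctions even when every unit is compliant).
#'
#' @param tags List of `tag_scaffold` objects (or a `barcode_arrays`
#'   collection).
#' @param min_pairwise_edit_distance Distance threshold below which a pair is
#'   flagged (default 1, i.e. only identical/strand-identical arrays flag).
#' @param max_homopolymer,max_dinucleotide_repeats Sequence-composition
#'   maxima, as in [oligo_unit()].
#' @return A `tag_set_report`: `distances` (long-format pair table with
#'   `flagged`), `sequence_flags`, and `pass` (no flags of either kind).
#' @export
check_tag_set <- function(tags, min_pairwise_edit_distance = 1L,
                          max_homopolymer = 2, max_dinucleotide_repeats = 2) {
  if (inherits(tags, "barcode_arrays")) {
    ids <- paste0("array", seq_len(tags$n))
    seqs <- tags$sequence
  } else {
    stopifnot(is.list(tags), length(tags) >= 1,
              all(vapply(tags, inherits, logical(1), "tag_scaffold")))
    ids <- vapply(tags, `[[`, character(1), "id")
    seqs <- vapply(tags, `[[`, character(1), "array_sequence")
  }
  rc <- revcomp(seqs)
  n <- length(seqs)
  pairs <- if (n > 1L) utils::combn(n, 2L) else matrix(integer(0), nrow = 2)
  distances <- data.frame(tag1 = ids[pairs[1, ]], tag2 = ids[pairs[2, ]],
                          distance = integer(ncol(pairs)))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    distances$distance[j] <- as.integer(min(utils::adist(seqs[a], seqs[b]),
                                            utils::adist(seqs[a], rc[b])))
  }
  distances$flagged <- distances$distance < min_pairwise_edit_distance
  seq_flags <- data.frame(tag = character(0), issue = character(0))
  hp <- has_homopolymer(seqs, max_homopolymer)
  dp <- has_dinucleotide_tract(seqs, max_dinucleotide_repeats)
  if (any(hp)) seq_flags <- rbind(seq_flags,
    data.frame(tag = ids[hp], issue = "homopolymer"))
  if (any(dp)) seq_flags <- rbind(seq_flags,
    data.frame(tag = ids[dp], issue = "dinucleotide_tract"))
  structure(list(distances = distances, sequence_flags = seq_flags,
                 pass = !any(distances$flagged) && nrow(seq_flags) == 0L),
            class = "tag_set_report")
}

#' @export
print.tag_set_report <- function(x, ...) {
  cat(sprintf("<tag_set_report> %s\n", if (x$pass) "PASS" else "FLAGGED"))
  if (nrow(x$distances)) {
    cat(sprintf("pairwise array distances: min %d, %d pair(s) flagged\n",
                min(x$distances$distance), sum(x$distances$flagged)))
  }
  if (nrow(x$sequence_flags)) {
    cat("sequence flags:\n"); print(x$sequence_flags, row.names = FALSE)
  }
  invisible(x)
}

#' Enumerate antibiotic x fluorophore marker combinations
#'
#' Full Cartesian product of the selectable antibiotic resistances and
#' fluorescent markers available for tag vectors (the standard palette of 4
#' antibiotics and 5 fluorophores yields 20 combinations), in deterministic
#' antibiotic-major order.
#'
#' @param antibiotics,fluorophores Non-empty character vectors.
#' @return Data frame with columns `antibiotic` and `fluorophore`, one row
#'   per combination.
#' @export
enumerate_marker_combinations <- function(antibiotics, fluorophores) {
  if (length(antibiotics) == 0L || length(fluorophores) == 0L) {
    stop("antibiotics and fluorophores must be non-empty", call. = FALSE)
  }
  data.frame(
    antibiotic = rep(antibiotics, each = length(fluorophores)),
    fluorophore = rep(fluorophores, times = length(antibiotics)))
}
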
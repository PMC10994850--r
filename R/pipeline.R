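#' Run the full synthetic pipeline end to end
#'
#' Convenience driver tying the modules together in dependency order:
#' simulate a community and reads (synthetic data), assign reads to
#' references (read assignment), calibrate correction factors
#' (quantification), and emit abundance summaries. All artifacts are written
#' as TSV/FASTA with provenance headers into `outdir`; no stage mutates its
#' inputs and outputs are write-once (an existing file is an error).
#'
#' @param outdir Output directory (created if needed; must not already
#'   contain pipeline outputs).
#' @param spec A [community_spec()]; the default is a small demonstration
#'   community of three tagged near-isogenic strains plus two untagged
#'   strains.
#' @param n_samples Community samples to simulate (default 3).
#' @param calibration_samples Pure-culture calibration samples per tag
#'   (default 16).
#' @param max_distance,margin Assignment parameters, see [assign_reads()].
#' @param seed Master seed; the spec seed takes precedence when a spec is
#'   supplied explicitly.
#' @return Invisibly, a list with the key objects (`counts`, `cf`,
#'   `abundance`, `load`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(outdir, spec = NULL, n_samples = 3L,
                         calibration_samples = 16L,
                         max_distance = 3L, margin = 1L, seed = 1L) {
  if (is.null(spec)) spec <- demo_community_spec(seed)
  stopifnot(inherits(spec, "community_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_header(seed = spec$seed)
  paths <- list(refs = file.path(outdir, "references.fasta"),
                counts = file.path(outdir, "counts.tsv"),
                cf = file.path(outdir, "correction_factors.tsv"),
                abundance = file.path(outdir, "abundance.tsv"),
                load = file.path(outdir, "load.tsv"))

  # stage 1: synthetic truth + reads
  refs <- generate_reference_set(spec)
  write_reference_set(refs, paths$refs)
  read_sets <- lapply(seq_len(n_samples), function(i) {
    s <- spec
    s$seed <- spec$seed + i
    generate_reads(s, refs)
  })
  names(read_sets) <- paste0("sample", seq_len(n_samples))

  # stage 2: assignment
  counts <- assign_samples(read_sets, refs, max_distance, margin)
  write_count_table(counts, paths$counts, provenance = prov)

  # stage 3: calibration
  tagged <- spec$strains[!is.na(spec$strains$tag_id), , drop = FALSE]
  cf <- NULL
  if (nrow(tagged)) {
    calib <- generate_calibration(
      stats::setNames(tagged$tag_bias, tagged$tag_id),
      n_samples = calibration_samples, seed = spec$seed + 1000L)
    cf <- estimate_correction_factor(calib, seed = spec$seed + 2000L)
    write_tsv(as.data.frame(cf), paths$cf, provenance = prov)
  }

  # stage 4: quantification
  sd <- spike_design(spike_16s = names(spec$spike_propensity)[1],
                     spike_pits = if (length(spec$spike_propensity) > 1L)
                       names(spec$spike_propensity)[2] else NA_character_)
  abundance <- summarize_abundance(counts, sd, cf)
  write_tsv(abundance, paths$abundance, provenance = prov)
  norm <- normalize_to_spike(
    if (is.null(cf)) counts else apply_correction(counts, cf), sd)
  load <- if (nrow(norm$np) > 0L) bacteria_to_plant_load(norm) else NULL
  if (!is.null(load)) write_tsv(load, paths$load, provenance = prov)

  invisible(list(spec = spec, refs = refs, counts = counts, cf = cf,
                 abundance = abundance, load = load, paths = paths))
}

#' @rdname run_pipeline
#' @export
demo_community_spec <- function(seed = 1L) {
  strains <- data.frame(
    strain_id = c("WT", "mutA", "mutB", "R61", "R1310"),
    abundance = c(0.25, 0.15, 0.10, 0.30, 0.20),
    copy_number = c(4L, 4L, 4L, 2L, 6L),
    tag_id = c("tag119", "tag120", "tag190", NA, NA),
    tag_bias = c(3.5, 1.9, 1.8, 1, 1),
    shared_16s = c("WCS", "WCS", "WCS", "R61", "R1310"))
  community_spec(strains,
                 spike_propensity = c(spike16S = 0.05, spikePITS = 0.05),
                 plant_propensity = 0.5, depth = 5000L,
                 error_rate = 0.001, seed = seed)
}
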
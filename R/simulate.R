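#' Specification of a synthetic community
#'
#' Defines the generative model behind all synthetic fixtures: strains with
#' true relative abundances, 16S copy numbers and (optionally) barcode tags
#' with tag-specific amplification biases; spike tags with fixed read
#' propensities; a plant-ITS read propensity; a total read depth; and a
#' per-base substitution error rate for read simulation. Strains sharing the
#' same `shared_16s` group id contribute to one common endogenous_16S
#' feature (the near-isogenic wild-type/mutant situation).
#'
#' Expected feature propensities are `abundance * copy_number` for 16S
#' features and `abundance * tag_bias` for tag features; counts are drawn
#' multinomially at the stated depth (optionally with gamma-multiplicative
#' overdispersion), so the model matches the quantification assumptions the
#' package is built to test.
#'
#' @param strains Data frame with columns `strain_id`, `abundance` (summing
#'   to 1), and optionally `copy_number` (integer >= 1, default 1), `tag_id`
#'   (NA = untagged), `tag_bias` (> 0, default 1), `shared_16s` (group id,
#'   default one group per strain).
#' @param spike_propensity Named numeric vector of spike-tag propensities on
#'   the same scale as the strain propensities, e.g.
#'   `c(spike16S = 0.05, spikePITS = 0.05)`.
#' @param plant_propensity Propensity of the plant-ITS feature (default 0.5).
#' @param depth Total reads per sample (> 0).
#' @param error_rate Per-base substitution probability in [0, 0.1].
#' @param read_length Reference/read length in nt for read simulation
#'   (default 250, a merged short-read amplicon scale).
#' @param overdispersion Gamma shape parameter for optional
#'   negative-binomial-like replicate noise; `Inf` (default) disables it.
#' @param seed Integer seed.
#' @return A `community_spec`.
#' @export
community_spec <- function(strains,
                           spike_propensity = c(spike16S = 0.05,
                                                spikePITS = 0.05),
                           plant_propensity = 0.5,
                           depth = 100000L,
                           error_rate = 0,
                           read_length = 250L,
                           overdispersion = Inf,
                           seed = 1L) {
  stopifnot(is.data.frame(strains),
            all(c("strain_id", "abundance") %in% names(strains)))
  if (abs(sum(strains$abundance) - 1) > 1e-9) {
    stop("strain abundances must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (!"copy_number" %in% names(strains)) strains$copy_number <- 1L
  if (!"tag_id" %in% names(strains)) strains$tag_id <- NA_character_
  if (!"tag_bias" %in% names(strains)) strains$tag_bias <- 1
  if (!"shared_16s" %in% names(strains)) strains$shared_16s <- strains$strain_id
  stopifnot(all(strains$copy_number >= 1),
            all(strains$copy_number == round(strains$copy_number)),
            all(strains$tag_bias > 0))
  if (!(depth > 0)) stop("depth must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  stopifnot(is.numeric(spike_propensity), !is.null(names(spike_propensity)),
            all(spike_propensity > 0), plant_propensity >= 0)
  structure(list(strains = strains, spike_propensity = spike_propensity,
                 plant_propensity = plant_propensity,
                 depth = as.integer(depth), error_rate = error_rate,
                 read_length = as.integer(read_length),
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "community_spec")
}

# Feature table of a community spec: id, class, propensity, strain/tag links.
spec_features <- function(spec) {
  st <- spec$strains
  g16 <- stats::aggregate(abundance * copy_number ~ shared_16s, st, sum)
  names(g16) <- c("group", "propensity")
  feats <- data.frame(feature_id = paste0(g16$group, "_16S"),
                      class = "endogenous_16S",
                      propensity = g16$propensity,
                      strain_id = g16$group)
  tagged <- st[!is.na(st$tag_id), , drop = FALSE]
  if (nrow(tagged)) {
    feats <- rbind(feats, data.frame(
      feature_id = tagged$tag_id, class = "barcode_tag",
      propensity = tagged$abundance * tagged$tag_bias,
      strain_id = tagged$strain_id))
  }
  feats <- rbind(feats, data.frame(
    feature_id = names(spec$spike_propensity), class = "spike_tag",
    propensity = unname(spec$spike_propensity), strain_id = NA))
  if (spec$plant_propensity > 0) {
    feats <- rbind(feats, data.frame(
      feature_id = "plant_ITS", class = "plant_ITS",
      propensity = spec$plant_propensity, strain_id = NA))
  }
  rownames(feats) <- NULL
  feats
}

#' Generate multinomial community count tables with known ground truth
#'
#' Draws per-sample feature counts from a multinomial at the spec's depth,
#' with expected propensities `abundance * copy_number` (16S features,
#' summed over strains sharing a 16S group), `abundance * tag_bias` (tag
#' features) and the fixed spike/plant propensities. With finite
#' `overdispersion` the propensities are perturbed per sample by
#' gamma-distributed multiplicative noise. Deterministic given the spec
#' seed.
#'
#' @param spec A [community_spec()].
#' @param n_samples Number of samples to draw.
#' @return List with `table` (a [count_table()]), `truth` (the feature table
#'   with expected proportions) and `spec`.
#' @export
generate_community_counts <- function(spec, n_samples = 1L) {
  stopifnot(inherits(spec, "community_spec"), n_samples >= 1)
  set.seed(spec$seed)
  feats <- spec_features(spec)
  p <- feats$propensity / sum(feats$propensity)
  draw <- function() {
    pi <- p
    if (is.finite(spec$overdispersion)) {
      pi <- p * stats::rgamma(length(p), shape = spec$overdispersion,
                              rate = spec$overdispersion)
      pi <- pi / sum(pi)
    }
    stats::rmultinom(1L, spec$depth, pi)[, 1]
  }
  m <- t(vapply(seq_len(n_samples), function(i) draw(),
                numeric(nrow(feats))))
  dimnames(m) <- list(paste0("sample", seq_len(n_samples)),
                      feats$feature_id)
  truth <- feats
  truth$expected_proportion <- p
  list(table = count_table(m, stats::setNames(feats$class, feats$feature_id)),
       truth = truth, spec = spec)
}

#' Random reference sequences for a community spec
#'
#' Draws one random reference amplicon of length `spec$read_length` per
#' feature. Random sequences of this length are pairwise distant (expected
#' edit distance far above any assignment threshold), which makes them
#' convenient assignment references.
#'
#' @param spec A [community_spec()].
#' @param seed Seed for sequence generation (separate from the count seed).
#' @return A [reference_set()].
#' @export
generate_reference_set <- function(spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(as.integer(seed))
  feats <- spec_features(spec)
  seqs <- vapply(seq_len(nrow(feats)), function(i)
    paste(sample(DNA_BASES, spec$read_length, replace = TRUE),
          collapse = ""), character(1))
  reference_set(data.frame(feature_id = feats$feature_id,
                           class = feats$class, sequence = seqs,
                           strain_id = feats$strain_id))
}

#' Simulate error-bearing amplicon reads with truth labels
#'
#' Draws a feature per read according to the community count model, emits
#' the feature's reference sequence with independent per-base substitutions
#' at `spec$error_rate`, on a random strand, and retains the true source
#' feature of every read.
#'
#' @param spec A [community_spec()].
#' @param refs A [reference_set()] covering every feature of the spec.
#' @param n_reads Number of reads (default `spec$depth`).
#' @return Named character vector of reads with attributes `truth` (data
#'   frame `read_id`/`feature_id`/`strand`/`n_errors`).
#' @export
generate_reads <- function(spec, refs, n_reads = spec$depth) {
  stopifnot(inherits(spec, "community_spec"), inherits(refs, "reference_set"))
  feats <- spec_features(spec)
  missing <- setdiff(feats$feature_id, refs$features$feature_id)
  if (length(missing)) {
    stop("reference set lacks sequences for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  p <- feats$propensity / sum(feats$propensity)
  src <- sample(feats$feature_id, n_reads, replace = TRUE, prob = p)
  ref_seq <- stats::setNames(refs$features$sequence,
                             refs$features$feature_id)
  reads <- unname(ref_seq[src])
  width <- nchar(reads)
  n_err <- stats::rbinom(n_reads, width, spec$error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(width[i], n_err[i])
    b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p_i in pos) b[p_i] <- sample(setdiff(DNA_BASES, b[p_i]), 1L)
    reads[i] <- paste(b, collapse = "")
  }
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  flip <- strand == "-"
  if (any(flip)) reads[flip] <- revcomp(reads[flip])
  names(reads) <- sprintf("read%06d", seq_len(n_reads))
  attr(reads, "truth") <- data.frame(read_id = names(reads),
                                     feature_id = src, strand = strand,
                                     n_errors = n_err)
  reads
}

#' Synthetic pure-culture calibration counts
#'
#' Simulates calibration samples of pure barcoded cultures for
#' [estimate_correction_factor()]: per sample, the 16S count is
#' Poisson(`mean_16s`) and the tag count, conditionally on the realized 16S
#' count, is Poisson(`bias * n_16s`). Conditioning ties the two counts to
#' the same library, as in real calibration samples where tag and 16S reads
#' are drawn from one amplicon pool and co-fluctuate with sampling depth.
#' The tag biases are the generative tag-to-16S amplification ratios to be
#' recovered.
#'
#' @param tag_bias Named numeric vector of generative biases, e.g.
#'   `c(tag119 = 3.5)`.
#' @param n_samples Calibration samples per tag (default 16).
#' @param mean_16s Expected 16S count per sample (default 1000).
#' @param seed Integer seed.
#' @return Data frame `tag`/`sample`/`n_tag`/`n_16s` suitable for
#'   [estimate_correction_factor()].
#' @export
generate_calibration <- function(tag_bias, n_samples = 16L,
                                 mean_16s = 1000, seed = 1L) {
  stopifnot(is.numeric(tag_bias), !is.null(names(tag_bias)),
            all(tag_bias > 0), n_samples >= 2, mean_16s > 0)
  set.seed(as.integer(seed))
  do.call(rbind, lapply(names(tag_bias), function(tg) {
    s16 <- stats::rpois(n_samples, mean_16s)
    s16[s16 == 0L] <- 1L   # guard the n_16s > 0 precondition at tiny means
    data.frame(tag = tg, sample = seq_len(n_samples),
               n_tag = stats::rpois(n_samples, tag_bias[[tg]] * s16),
               n_16s = s16)
  }))
}

#' Simulate a spike dilution series
#'
#' Holds the community fixed and scales the propensity of the dilution
#' spike proportionally to the spiked mass, one sample per mass (the
#' standard design is a tenfold series from 1.5 ng down to 0.00015 ng,
#' spanning four orders of magnitude).
#'
#' @param spec A [community_spec()] whose `spike_propensity` names include
#'   `dilution_spike`.
#' @param masses Vector of spiked masses in ng (non-empty, positive).
#' @param dilution_spike Name of the spike feature being diluted.
#' @param reference_mass Mass (ng) at which the spec's stated propensity
#'   applies (default `max(masses)`).
#' @param lognormal_sd Standard deviation of optional multiplicative
#'   lognormal noise on the diluted spike's propensity (default 0, exact
#'   proportionality).
#' @return List with `table` (one sample per mass), `masses`, `truth`.
#' @export
generate_dilution_series <- function(spec, masses,
                                     dilution_spike = "spike2",
                                     reference_mass = max(masses),
                                     lognormal_sd = 0) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(masses) == 0L) stop("empty mass list", call. = FALSE)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (!dilution_spike %in% names(spec$spike_propensity)) {
    stop("spike_propensity has no entry '", dilution_spike, "'",
         call. = FALSE)
  }
  set.seed(spec$seed)
  feats <- spec_features(spec)
  base <- feats$propensity
  i_dil <- which(feats$feature_id == dilution_spike)
  rows <- lapply(seq_along(masses), function(j) {
    p <- base
    scale <- masses[j] / reference_mass
    if (lognormal_sd > 0) {
      scale <- scale * stats::rlnorm(1L, meanlog = 0, sdlog = lognormal_sd)
    }
    p[i_dil] <- p[i_dil] * scale
    stats::rmultinom(1L, spec$depth, p / sum(p))[, 1]
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("dilution%02d", seq_along(masses)),
                      feats$feature_id)
  list(table = count_table(m, stats::setNames(feats$class,
                                              feats$feature_id)),
       masses = masses, truth = feats)
}
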
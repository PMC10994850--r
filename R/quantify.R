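#' Spike-in design
#'
#' Describes the spike plasmid(s) added at known mass during library
#' preparation: the spike tag amplified alongside bacterial 16S, optionally a
#' second spike tag co-amplified with plant ITS (identical spike amounts in
#' both libraries enable cross-normalization), and the masses per PCR. The
#' default masses, 6 ng of sample DNA and 0.001 ng of spike plasmid, give the
#' standard sample:spike mass ratio of 6000.
#'
#' @param spike_16s Feature id of the spike tag in the 16S library.
#' @param spike_pits Feature id of the spike tag in the plant-ITS library
#'   (optional; `NA` disables plant cross-normalization).
#' @param spike_mass_ng Spike plasmid mass per reaction (ng, default 0.001).
#' @param sample_mass_ng Sample DNA mass per reaction (ng, default 6).
#' @return A `spike_design` with derived field `mass_ratio =
#'   sample_mass_ng / spike_mass_ng`.
#' @export
spike_design <- function(spike_16s, spike_pits = NA_character_,
                         spike_mass_ng = 0.001, sample_mass_ng = 6) {
  if (!(spike_mass_ng > 0) || !(sample_mass_ng > 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  structure(list(spike_16s = spike_16s, spike_pits = spike_pits,
                 spike_mass_ng = spike_mass_ng,
                 sample_mass_ng = sample_mass_ng,
                 mass_ratio = sample_mass_ng / spike_mass_ng),
            class = "spike_design")
}

#' @export
print.spike_design <- function(x, ...) {
  cat(sprintf("<spike_design> 16S spike '%s', plant-ITS spike '%s'\n",
              x$spike_16s, x$spike_pits))
  cat(sprintf("sample %g ng : spike %g ng  (mass ratio %g)\n",
              x$sample_mass_ng, x$spike_mass_ng, x$mass_ratio))
  invisible(x)
}

#' Spike-normalize a count table
#'
#' Computes, per sample, normalized bacterial reads `Nb = Rb / Rs_16S` for
#' every bacterial feature (endogenous 16S and barcode tags) and normalized
#' plant reads `Np = Rp / Rs_pITS` for every plant-ITS feature, where the
#' denominators are the spike-tag read counts of the same library. Samples
#' whose spike count is zero are flagged and excluded: their normalized
#' values are undefined (a spike failure is a library failure, not a
#' biological zero), so no value is emitted for them.
#'
#' @param table A [count_table()] containing the spike features.
#' @param spike A [spike_design()].
#' @return A `normalized_abundance`: `nb` (tidy `sample_id`/`feature_id`/
#'   `reads`/`nb`), `np` (same shape, or zero rows when no plant spike),
#'   `samples` (per-sample spike counts and validity), `flagged` (ids of
#'   excluded samples).
#' @export
normalize_to_spike <- function(table, spike) {
  stopifnot(inherits(table, "count_table"), inherits(spike, "spike_design"))
  feats <- colnames(table$counts)
  if (!spike$spike_16s %in% feats) {
    stop("16S spike feature '", spike$spike_16s, "' not in count table",
         call. = FALSE)
  }
  rs16 <- table$counts[, spike$spike_16s]
  has_pits <- !is.na(spike$spike_pits)
  if (has_pits && !spike$spike_pits %in% feats) {
    stop("plant-ITS spike feature '", spike$spike_pits,
         "' not in count table", call. = FALSE)
  }
  rspits <- if (has_pits) table$counts[, spike$spike_pits] else
    rep(NA_real_, nrow(table$counts))

  valid <- rs16 > 0 & (!has_pits | rspits > 0)
  flagged <- rownames(table$counts)[!valid]
  if (length(flagged)) {
    message("excluding ", length(flagged),
            " sample(s) with zero spike reads: ",
            paste(flagged, collapse = ", "))
  }
  bact <- features_of_class(table, c("endogenous_16S", "barcode_tag"))
  plant <- features_of_class(table, "plant_ITS")
  tidy <- function(features, denom) {
    if (length(features) == 0L || !any(valid)) {
      return(data.frame(sample_id = character(0), feature_id = character(0),
                        reads = numeric(0), value = numeric(0)))
    }
    s <- rownames(table$counts)[valid]
    data.frame(
      sample_id = rep(s, times = length(features)),
      feature_id = rep(features, each = length(s)),
      reads = as.vector(table$counts[valid, features, drop = FALSE]),
      value = as.vector(table$counts[valid, features, drop = FALSE] /
                          denom[valid]))
  }
  nb <- tidy(bact, rs16); names(nb)[4] <- "nb"
  np <- if (has_pits) tidy(plant, rspits) else
    data.frame(sample_id = character(0), feature_id = character(0),
               reads = numeric(0), value = numeric(0))
  names(np)[4] <- "np"
  structure(list(nb = nb, np = np,
                 samples = data.frame(sample_id = rownames(table$counts),
                                      rs_16s = unname(rs16),
                                      rs_pits = unname(rspits),
                                      valid = unname(valid)),
                 flagged = flagged, spike = spike),
            class = "normalized_abundance")
}

#' @export
print.normalized_abundance <- function(x, ...) {
  cat(sprintf("<normalized_abundance> %d valid sample(s), %d flagged\n",
              sum(x$samples$valid), length(x$flagged)))
  invisible(x)
}

#' Microbial load: normalized bacterial reads per normalized plant read
#'
#' For each valid sample, divides total normalized bacterial reads by
#' normalized plant reads, `load = Nb / Np`, and verifies the closed-form
#' identity `load = (Rb * Rs_pITS) / (Rp * Rs_16S)` to within 1e-12 relative
#' error. `Rb` is the summed bacterial read count (endogenous 16S plus
#' barcode tags) and `Rp` the summed plant-ITS read count of the sample.
#'
#' @param norm A `normalized_abundance` from [normalize_to_spike()], built
#'   with a plant-ITS spike.
#' @return Data frame with one row per sample: `sample_id`, `rb`, `rp`,
#'   `nb_total`, `np_total`, `load`.
#' @export
bacteria_to_plant_load <- function(norm) {
  stopifnot(inherits(norm, "normalized_abundance"))
  if (nrow(norm$np) == 0L) {
    stop("no plant-ITS normalization available (no plant spike or plant ",
         "features)", call. = FALSE)
  }
  nb_tot <- stats::aggregate(cbind(reads, nb) ~ sample_id, norm$nb, sum)
  np_tot <- stats::aggregate(cbind(reads, np) ~ sample_id, norm$np, sum)
  merged <- merge(nb_tot, np_tot, by = "sample_id",
                  suffixes = c("_b", "_p"))
  undef <- merged$sample_id[merged$np == 0]
  if (length(undef)) {
    stop("plant-normalized load undefined (zero plant reads) for sample(s): ",
         paste(undef, collapse = ", "), call. = FALSE)
  }
  load <- merged$nb / merged$np
  s <- norm$samples[match(merged$sample_id, norm$samples$sample_id), ]
  direct <- (merged$reads_b * s$rs_pits) / (merged$reads_p * s$rs_16s)
  rel <- abs(load - direct) / pmax(abs(direct), .Machine$double.xmin)
  if (any(rel > 1e-12)) {
    stop("internal error: composed Nb/Np deviates from the closed form",
         call. = FALSE)
  }
  data.frame(sample_id = merged$sample_id, rb = merged$reads_b,
             rp = merged$reads_p, nb_total = merged$nb,
             np_total = merged$np, load = load)
}

#' Fit a spike standard curve over a dilution series
#'
#' Ordinary least squares of log10 normalized dilution-spike reads on log10
#' spiked mass. Read counts of the diluted spike (spike 2) are first
#' normalized by the constant-mass spike (spike 1) to compensate for
#' sequencing-depth differences. Points with zero normalized reads are
#' dropped with a warning; at least three surviving points are required.
#'
#' @param masses Spiked plasmid mass per reaction (ng), one per sample; all
#'   positive, at least three distinct values.
#' @param spike2_reads,spike1_reads Read counts of the diluted and the
#'   constant spike in each sample.
#' @return A `standard_curve`: `slope`, `intercept`, `r_squared`,
#'   `dynamic_range` (log10 of max/min surviving mass) and the fitted
#'   `points` table.
#' @export
fit_standard_curve <- function(masses, spike2_reads, spike1_reads) {
  stopifnot(length(masses) == length(spike2_reads),
            length(masses) == length(spike1_reads))
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (length(unique(masses)) < 3L) {
    stop("need at least three distinct masses", call. = FALSE)
  }
  if (any(spike1_reads <= 0)) {
    stop("spike-1 (depth normalizer) reads must be positive", call. = FALSE)
  }
  norm <- spike2_reads / spike1_reads
  keep <- norm > 0
  if (any(!keep)) {
    warning(sum(!keep), " point(s) with zero normalized spike reads dropped",
            call. = FALSE)
  }
  if (sum(keep) < 3L) {
    stop("fewer than three points survive zero-read filtering", call. = FALSE)
  }
  x <- log10(masses[keep])
  y <- log10(norm[keep])
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    dynamic_range = log10(max(masses[keep]) / min(masses[keep])),
    points = data.frame(mass_ng = masses[keep], log10_mass = x,
                        log10_normalized_reads = y)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> slope %.3f, intercept %.3f, ",
                     "R^2 %.4f, %.1f orders of magnitude (%d points)\n"),
              x$slope, x$intercept, x$r_squared, x$dynamic_range,
              nrow(x$points)))
  invisible(x)
}

#' Estimate tag-to-16S correction factors from pure-culture calibration
#'
#' Individual barcode tags amplify with tag-specific efficiency relative to
#' the endogenous 16S amplicon of the same strain (reported biases range
#' from below 1 up to 3.5-fold). The correction factor of a tag is estimated
#' from calibration samples of pure barcoded cultures as the zero-intercept
#' least-squares slope of normalized tag reads on normalized 16S reads
#' (default), or as the mean per-sample ratio. A nonparametric bootstrap over
#' calibration samples yields a percentile 95% CI.
#'
#' @param calibration Data frame with columns `tag`, `n_tag`, `n_16s`, one
#'   row per calibration sample per tag; at least two samples per tag, all
#'   `n_16s > 0`.
#' @param method `"slope"` (zero-intercept regression, default) or `"ratio"`
#'   (mean of per-sample ratios).
#' @param n_boot Bootstrap resamples (default 1000). The 95% CI is the
#'   t-interval `factor +/- t(0.975, n-1) * se_boot` with the bootstrap
#'   standard error; at calibration-typical n the plain percentile interval
#'   undercovers, which the t quantile corrects.
#' @param seed Bootstrap seed (mandatory for reproducibility).
#' @return A `correction_factor_set`: data frame with `tag`, `factor`,
#'   `ci_lower`, `ci_upper`, `n`, `method`.
#' @export
estimate_correction_factor <- function(calibration,
                                       method = c("slope", "ratio"),
                                       n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c("tag", "n_tag", "n_16s") %in% names(calibration)))
  set.seed(as.integer(seed))
  est <- function(tag_r, s16_r) {
    if (method == "slope") sum(tag_r * s16_r) / sum(s16_r^2)
    else mean(tag_r / s16_r)
  }
  out <- do.call(rbind, lapply(split(calibration, calibration$tag),
                               function(d) {
    if (nrow(d) < 2L) {
      stop("tag '", d$tag[1], "': need at least 2 calibration samples",
           call. = FALSE)
    }
    if (any(d$n_16s <= 0)) {
      stop("tag '", d$tag[1], "': all 16S counts must be positive",
           call. = FALSE)
    }
    if (all(d$n_tag == 0)) {
      stop("tag '", d$tag[1], "': all tag reads are zero (unlabelled or ",
           "failed strain)", call. = FALSE)
    }
    point <- est(d$n_tag, d$n_16s)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(d), replace = TRUE)
      est(d$n_tag[idx], d$n_16s[idx])
    }, numeric(1))
    half <- stats::qt(0.975, nrow(d) - 1L) * stats::sd(boot)
    data.frame(tag = d$tag[1], factor = point,
               ci_lower = point - half, ci_upper = point + half,
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out$method <- method
  class(out) <- c("correction_factor_set", "data.frame")
  out
}

#' Apply correction factors to barcode-tag counts
#'
#' Divides each barcode-tag feature's counts by that tag's correction factor
#' so tag counts report strain abundance on the 16S scale; all non-tag
#' features are left unchanged. Every tag feature in the table must have a
#' factor.
#'
#' @param table A [count_table()].
#' @param cf A `correction_factor_set` from [estimate_correction_factor()],
#'   or a named numeric vector of factors.
#' @return A real-valued corrected `count_table`; the factors used are
#'   attached as attribute `correction_factors`.
#' @export
apply_correction <- function(table, cf) {
  stopifnot(inherits(table, "count_table"))
  factors <- if (inherits(cf, "correction_factor_set"))
    stats::setNames(cf$factor, cf$tag) else cf
  stopifnot(is.numeric(factors), !is.null(names(factors)))
  if (any(factors <= 0)) stop("correction factors must be positive",
                              call. = FALSE)
  tags <- features_of_class(table, "barcode_tag")
  missing <- setdiff(tags, names(factors))
  if (length(missing)) {
    stop("no correction factor for tag(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- table$counts
  storage.mode(m) <- "double"
  for (tg in tags) m[, tg] <- m[, tg] / factors[[tg]]
  out <- count_table(m, table$feature_class, integer_counts = FALSE)
  attr(out, "correction_factors") <- factors[tags]
  out
}

#' Per-sample abundance summaries in three views
#'
#' Emits, for every bacterial feature (endogenous 16S and correction-applied
#' barcode tags) in every valid sample, the three complementary abundance
#' views: `relative` (share of the sample's bacterial reads, summing to 1),
#' `spike` (spike-normalized reads Nb), and -- when a plant spike and plant
#' features are present -- `plant` (Nb/Np, load-scaled abundance). Relative
#' abundance is compositional: a change in total microbial load can move
#' relative abundances in directions opposite to the true absolute changes,
#' which the spike view exposes.
#'
#' @param table A [count_table()] of raw integer counts.
#' @param spike A [spike_design()].
#' @param cf Optional correction factors for barcode tags (see
#'   [apply_correction()]); mandatory when the table contains tag features.
#' @param pseudocount Optional pseudocount added to bacterial counts for the
#'   relative view only (default 0).
#' @return Tidy data frame: `sample_id`, `feature_id`, `view`, `value`.
#' @export
summarize_abundance <- function(table, spike, cf = NULL, pseudocount = 0) {
  stopifnot(inherits(table, "count_table"), inherits(spike, "spike_design"))
  tags <- features_of_class(table, "barcode_tag")
  if (length(tags) && is.null(cf)) {
    stop("table contains barcode tags; correction factors are required",
         call. = FALSE)
  }
  corrected <- if (length(tags)) apply_correction(table, cf) else table
  norm <- normalize_to_spike(corrected, spike)
  bact <- features_of_class(corrected, c("endogenous_16S", "barcode_tag"))
  valid <- norm$samples$sample_id[norm$samples$valid]
  m <- corrected$counts[valid, bact, drop = FALSE] + pseudocount
  rel <- data.frame(
    sample_id = rep(valid, times = length(bact)),
    feature_id = rep(bact, each = length(valid)),
    view = "relative",
    value = as.vector(m / rowSums(m)))
  spk <- data.frame(sample_id = norm$nb$sample_id,
                    feature_id = norm$nb$feature_id,
                    view = "spike", value = norm$nb$nb)
  out <- rbind(rel, spk)
  if (nrow(norm$np) > 0L) {
    np_tot <- stats::aggregate(np ~ sample_id, norm$np, sum)
    np_of <- stats::setNames(np_tot$np, np_tot$sample_id)
    ok <- norm$nb$sample_id %in% names(np_of)[np_of > 0]
    plant <- data.frame(sample_id = norm$nb$sample_id[ok],
                        feature_id = norm$nb$feature_id[ok],
                        view = "plant",
                        value = norm$nb$nb[ok] /
                          np_of[norm$nb$sample_id[ok]])
    out <- rbind(out, plant)
  }
  rownames(out) <- NULL
  out
}
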
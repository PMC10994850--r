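test_that("the default spike design reproduces the 6000:1 sample:spike ratio", {
  sd <- spike_design("spike16S", "spikePITS")
  expect_identical(sd$mass_ratio, 6000)
  expect_error(spike_design("s", spike_mass_ng = 0), "positive")
})

test_that("spike normalization divides by same-library spike reads", {
  ct <- toy_count_table()
  sd <- spike_design("spike16S", "spikePITS")
  norm <- normalize_to_spike(ct, sd)
  nb <- norm$nb
  expect_identical(nb$nb[nb$sample_id == "s1" &
                           nb$feature_id == "strainA_16S"], 6)
  np <- norm$np
  expect_identical(np$np[np$sample_id == "s1"], 10)

  # ratio invariance: scaling all counts of a sample leaves Nb unchanged
  ct10 <- toy_count_table(toy_count_table()$counts * 10L)
  norm10 <- normalize_to_spike(ct10, sd)
  expect_equal(norm10$nb$nb, nb$nb, tolerance = 1e-15)
})

test_that("zero-spike samples are flagged and excluded, not zeroed", {
  counts <- toy_count_table()$counts
  counts["s2", "spike16S"] <- 0L
  ct <- toy_count_table(counts)
  expect_message(norm <- normalize_to_spike(ct, spike_design("spike16S",
                                                             "spikePITS")),
                 "zero spike")
  expect_identical(norm$flagged, "s2")
  expect_false(any(norm$nb$sample_id == "s2"))
  expect_false(any(norm$np$sample_id == "s2"))
})

test_that("bacterial-to-plant load matches the closed-form identity", {
  counts <- rbind(s1 = c(500L, 100L, 2000L, 200L))
  colnames(counts) <- c("b_16S", "spike16S", "plant_ITS", "spikePITS")
  ct <- count_table(counts, c(b_16S = "endogenous_16S",
                              spike16S = "spike_tag",
                              plant_ITS = "plant_ITS",
                              spikePITS = "spike_tag"))
  norm <- normalize_to_spike(ct, spike_design("spike16S", "spikePITS"))
  load <- bacteria_to_plant_load(norm)
  expect_identical(load$load, (500 * 200) / (2000 * 100))  # 0.5

  zero_b <- counts; zero_b[1, "b_16S"] <- 0L
  ct0 <- count_table(zero_b, ct$feature_class)
  expect_identical(
    bacteria_to_plant_load(normalize_to_spike(ct0,
      spike_design("spike16S", "spikePITS")))$load, 0)

  no_plant <- counts; no_plant[1, "plant_ITS"] <- 0L
  ctp <- count_table(no_plant, ct$feature_class)
  expect_error(
    bacteria_to_plant_load(normalize_to_spike(ctp,
      spike_design("spike16S", "spikePITS"))), "s1")
})

test_that("standard curves recover exact proportionality and the 4-order range", {
  masses <- c(1.5, 0.15, 0.015, 0.0015, 0.00015)
  spike1 <- rep(2000, 5)
  spike2 <- round(1e5 * masses)
  fit <- fit_standard_curve(masses, spike2, spike1)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_identical(fit$dynamic_range, 4)

  expect_warning(
    fit0 <- fit_standard_curve(masses, c(spike2[1:4], 0), spike1),
    "dropped")
  expect_identical(nrow(fit0$points), 4L)
  suppressWarnings(
    expect_error(fit_standard_curve(masses[1:3], c(10, 0, 0), rep(100, 3)),
                 "fewer than three"))
  expect_error(fit_standard_curve(c(1, 1, 1), 1:3, rep(1, 3)), "distinct")
})

test_that("correction factors are recovered exactly from ratio-embodying pairs", {
  calib <- data.frame(tag = "tag119", n_tag = c(350, 700, 1750),
                      n_16s = c(100, 200, 500))
  cf <- estimate_correction_factor(calib, seed = 4)
  expect_equal(cf$factor, 3.5, tolerance = 1e-12)
  expect_true(cf$ci_lower <= cf$factor && cf$factor <= cf$ci_upper)

  ident <- data.frame(tag = "t", n_tag = rep(42, 4), n_16s = rep(42, 4))
  expect_equal(estimate_correction_factor(ident, seed = 1)$factor, 1)
  expect_equal(estimate_correction_factor(ident, method = "ratio",
                                          seed = 1)$factor, 1)
})

test_that("degenerate calibrations raise the documented errors", {
  expect_error(estimate_correction_factor(
    data.frame(tag = "t", n_tag = c(0, 0), n_16s = c(100, 120)), seed = 1),
    "all tag reads are zero")
  expect_error(estimate_correction_factor(
    data.frame(tag = "t", n_tag = c(5, 5), n_16s = c(100, 0)), seed = 1),
    "positive")
  expect_error(estimate_correction_factor(
    data.frame(tag = "t", n_tag = 5, n_16s = 100), seed = 1),
    "at least 2")
})

test_that("bootstrap CIs cover a Poisson-noise truth at nominal-ish rate", {
  # true ratio 1.6, n = 16 calibration samples; coverage over replications
  hits <- 0L
  for (rep_i in 1:100) {
    calib <- generate_calibration(c(t = 1.6), n_samples = 16,
                                  mean_16s = 1000, seed = 5000 + rep_i)
    cf <- estimate_correction_factor(calib, n_boot = 500,
                                     seed = 6000 + rep_i)
    if (cf$ci_lower <= 1.6 && 1.6 <= cf$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.93)
})

test_that("applying a factor divides tag counts and leaves the rest alone", {
  ct <- toy_count_table()
  corr <- apply_correction(ct, c(tag119 = 3.5))
  expect_equal(corr$counts[, "tag119"], ct$counts[, "tag119"] / 3.5)
  expect_equal(corr$counts[, "strainA_16S"],
               ct$counts[, "strainA_16S"] + 0)
  expect_identical(corr$counts["s1", "tag119"], 100)
  one <- apply_correction(ct, c(tag119 = 1))
  expect_equal(one$counts[, "tag119"], ct$counts[, "tag119"] + 0)
  expect_error(apply_correction(ct, c(other = 2)), "tag119")
})

test_that("abundance views behave definitionally", {
  counts <- rbind(s1 = c(800L, 50L))
  colnames(counts) <- c("only_16S", "spike16S")
  ct <- count_table(counts, c(only_16S = "endogenous_16S",
                              spike16S = "spike_tag"))
  ab <- summarize_abundance(ct, spike_design("spike16S"))
  expect_identical(ab$value[ab$view == "relative"], 1)
  expect_identical(ab$value[ab$view == "spike"], 16)

  # doubling bacterial counts with spike fixed doubles Nb, not relatives
  ct2 <- toy_count_table()
  doubled <- ct2$counts
  bact <- c("strainA_16S", "strainB_16S", "tag119")
  doubled[, bact] <- doubled[, bact] * 2L
  sd <- spike_design("spike16S", "spikePITS")
  cf <- c(tag119 = 3.5)
  a1 <- summarize_abundance(ct2, sd, cf)
  a2 <- summarize_abundance(toy_count_table(doubled), sd, cf)
  key <- function(a, v) a$value[a$view == v]
  expect_equal(key(a2, "spike"), 2 * key(a1, "spike"), tolerance = 1e-12)
  expect_equal(key(a2, "relative"), key(a1, "relative"), tolerance = 1e-12)
  # relative abundances sum to 1 per sample
  rel <- a1[a1$view == "relative", ]
  sums <- tapply(rel$value, rel$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # tags require correction factors
  expect_error(summarize_abundance(ct2, sd), "correction factors")
})
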
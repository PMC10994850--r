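# Shared fixtures, built in code at test time.

# Small compliant oligo set (deterministic).
test_oligos <- function(n = 4, seed = 42) generate_oligo_set(n, seed = seed)

# A reference set of random, mutually distant sequences.
random_refs <- function(n = 4, len = 60, seed = 7,
                        classes = rep("endogenous_16S", n)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  reference_set(data.frame(feature_id = paste0("ref", seq_len(n)),
                           class = classes, sequence = seqs))
}

# Minimal count table: one spike, one plant, two bacterial features.
toy_count_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- rbind(s1 = c(6000, 1500, 350, 1000, 2000, 200),
                    s2 = c(3000, 900, 700, 500, 1500, 150))
  }
  colnames(counts) <- c("strainA_16S", "strainB_16S", "tag119",
                        "spike16S", "plant_ITS", "spikePITS")
  count_table(counts, c(strainA_16S = "endogenous_16S",
                        strainB_16S = "endogenous_16S",
                        tag119 = "barcode_tag",
                        spike16S = "spike_tag",
                        plant_ITS = "plant_ITS",
                        spikePITS = "spike_tag"))
}

mutate_read <- function(seq, positions, bases) {
  b <- strsplit(seq, "")[[1]]
  b[positions] <- bases
  paste(b, collapse = "")
}
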
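test_that("reference sets validate ids, classes and sequence uniqueness", {
  # 15 community strains + 3 tags + 1 spike + 1 plant ITS = 20 features
  set.seed(1)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1))
  df <- data.frame(
    feature_id = c(sprintf("strain%02d_16S", 1:15),
                   c("tag119", "tag120", "tag190"), "spike16S", "plant_ITS"),
    class = c(rep("endogenous_16S", 15), rep("barcode_tag", 3),
              "spike_tag", "plant_ITS"),
    sequence = seqs)
  refs <- reference_set(df)
  expect_identical(nrow(refs$features), 20L)

  dup <- df
  dup$sequence[17] <- dup$sequence[16]
  expect_error(reference_set(dup), "tag119.*tag120|tag120.*tag119")
  rc_dup <- df
  rc_dup$sequence[17] <- revcomp(dup$sequence[16])
  expect_error(reference_set(rc_dup), "reverse complement")
  expect_error(reference_set(df[0, ]), "empty")
  bad_id <- df
  bad_id$feature_id[2] <- bad_id$feature_id[1]
  expect_error(reference_set(bad_id), "duplicate feature ids")
})

test_that("reference FASTA headers carry class and strain tokens", {
  refs <- random_refs(3, classes = c("endogenous_16S", "barcode_tag",
                                     "spike_tag"))
  refs$features$strain_id <- c("WCS358", "WCS358", NA)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_reference_set(refs, path)
  back <- build_reference_set(path)
  expect_identical(back$features, refs$features)
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(build_reference_set(empty), "no sequences")
})

test_that("exact and reverse-complement reads are assigned at distance 0", {
  refs <- random_refs(4, len = 60)
  r <- refs$features$sequence
  res <- assign_reads(c(a = r[2], b = revcomp(r[3])), refs)
  expect_identical(res$assignments$label, c("ref2", "ref3"))
  expect_identical(res$assignments$distance, c(0L, 0L))
})

test_that("ambiguous reads are unassigned, never tie-broken", {
  base <- strrep("ACGT", 15)
  refs <- reference_set(data.frame(
    feature_id = c("r1", "r2"), class = "endogenous_16S",
    sequence = c(mutate_read(base, 5, "C"), mutate_read(base, 5, "G"))))
  # read equidistant (d = 1) from both references
  res <- assign_reads(c(x = mutate_read(base, 5, "T")), refs,
                      max_distance = 3, margin = 1)
  expect_identical(res$assignments$label, "unassigned")
  expect_true(res$assignments$ambiguous)
  expect_identical(res$assignments$distance, 1L)
})

test_that("distance bound and margin are both enforced", {
  refs <- random_refs(3, len = 60)
  read4 <- mutate_read(refs$features$sequence[1], 1:4, c("T", "G", "C", "A"))
  # check the mutation really moved 4 edits away, then exceed max_distance 3
  d <- utils::adist(read4, refs$features$sequence[1])[1]
  if (d > 3) {
    res <- assign_reads(c(x = read4), refs, max_distance = 3)
    expect_identical(res$assignments$label, "unassigned")
  }
  res2 <- assign_reads(c(x = read4), refs, max_distance = 10, margin = 1)
  expect_identical(res2$assignments$label, "ref1")
})

test_that("counts conserve reads and assignment ignores input order", {
  spec <- demo_community_spec(5)
  spec$depth <- 1500L
  refs <- generate_reference_set(spec)
  reads <- generate_reads(spec, refs)
  res <- assign_reads(reads, refs)
  expect_identical(sum(res$counts), length(reads))

  perm <- sample(length(reads))
  res_perm <- assign_reads(reads[perm], refs)
  expect_identical(res_perm$counts, res$counts)
  refs_rev <- reference_set(refs$features[rev(seq_len(nrow(refs$features))), ])
  res_refrev <- assign_reads(reads, refs_rev, max_distance = 3)
  expect_identical(res_refrev$counts[names(res$counts)], res$counts)
})

test_that("non-DNA reads are warned about and counted unassigned", {
  refs <- random_refs(2, len = 30)
  expect_warning(
    res <- assign_reads(c(ok = refs$features$sequence[1], bad = "ACGTNN"),
                        refs),
    "non-ACGT")
  expect_identical(res$assignments$label, c("ref1", "unassigned"))
  expect_identical(sum(res$counts), 2L)
})

test_that("FASTQ input is parsed with qualities ignored", {
  refs <- random_refs(2, len = 40)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@readA", refs$features$sequence[1], "+",
               strrep("I", 40),
               "@readB", revcomp(refs$features$sequence[2]), "+",
               strrep("#", 40)), fq)
  res <- assign_reads(fq, refs)
  expect_identical(res$assignments$label, c("ref1", "ref2"))
})

test_that("in-silico depletion removes columns without touching the rest", {
  ct <- toy_count_table()
  dep <- deplete_features(ct, "strainA_16S")
  expect_identical(dep$counts[, c("strainB_16S", "tag119")],
                   ct$counts[, c("strainB_16S", "tag119")])
  expect_identical(attr(dep, "original_depth"), ct$depth)
  expect_identical(dep$depth, ct$depth - ct$counts[, "strainA_16S"])
  # depleting nothing is the identity on counts
  expect_identical(deplete_features(ct, character(0))$counts, ct$counts)
  # depleting everything leaves a valid zero-feature table
  all_gone <- deplete_features(ct, colnames(ct$counts))
  expect_identical(ncol(all_gone$counts), 0L)
  expect_identical(unname(all_gone$depth), c(0, 0))
  expect_error(deplete_features(ct, "nope"), "unknown feature")
})
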
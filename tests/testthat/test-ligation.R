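test_that("array length is exactly 38 x unit count and reconstructable", {
  oligos <- test_oligos(5)
  cfg <- ligation_config(n_products = 200, k_dist = k_poisson(3), seed = 3)
  arr <- simulate_ligation(oligos, cfg)
  expect_identical(nchar(arr$sequence), 38L * arr$k)
  # rebuild every product from its unit list; sequences must match bit-exact
  per_product <- split(arr$units, arr$units$product)
  rebuilt <- barcode_arrays_from_units(per_product, oligos)
  expect_identical(rebuilt$sequence, arr$sequence)
})

test_that("fixed k = 4 products are all 152 nt", {
  arr <- simulate_ligation(test_oligos(10, seed = 1),
                           ligation_config(n_products = 50,
                                           k_dist = k_fixed(4), seed = 2))
  expect_true(all(nchar(arr$sequence) == 152L))
})

test_that("two oligos at k = 2 span exactly the 16 enumerable products", {
  oligos <- test_oligos(2, seed = 5)
  # oracle: exhaustive enumeration over (2 oligos x 2 orientations)^2
  combos <- expand.grid(l1 = names(oligos), o1 = c("F", "R"),
                        l2 = names(oligos), o2 = c("F", "R"),
                        stringsAsFactors = FALSE)
  enum <- barcode_arrays_from_units(
    lapply(seq_len(nrow(combos)), function(i)
      data.frame(label = c(combos$l1[i], combos$l2[i]),
                 orientation = c(combos$o1[i], combos$o2[i]))), oligos)
  expect_identical(length(unique(enum$sequence)), 16L)

  sim <- simulate_ligation(oligos,
                           ligation_config(n_products = 16000,
                                           k_dist = k_fixed(2), seed = 11))
  expect_setequal(unique(sim$sequence), enum$sequence)
  # empirical frequencies uniform within multinomial sampling error
  tab <- table(factor(sim$sequence, levels = enum$sequence))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("simulation is deterministic given the seed and rejects bad configs", {
  oligos <- test_oligos(3)
  cfg <- ligation_config(n_products = 100, seed = 21)
  expect_identical(simulate_ligation(oligos, cfg),
                   simulate_ligation(oligos, cfg))
  expect_error(ligation_config(n_products = 0), "positive")
  expect_error(ligation_config(orientation_prob_forward = 1.2), "\\[0, 1\\]")
  expect_error(ligation_config(size_window = c(300, 200)), "min < max")
  expect_error(simulate_ligation(test_oligos(1), cfg), "at least 2")
})

test_that("size selection keeps exactly the unit counts inside the window", {
  oligos <- test_oligos(4)
  mk <- function(k) data.frame(label = rep(names(oligos)[1], k),
                               orientation = rep("F", k))
  arr <- barcode_arrays_from_units(lapply(2:6, mk), oligos)
  cfg100 <- ligation_config(flank_length = 100, size_window = c(200, 300))
  kept <- size_select(arr, cfg100)
  expect_identical(sort(unique(kept$k)), 3:5)  # 214, 252, 290 in window
  cfg0 <- ligation_config(flank_length = 0, size_window = c(200, 300))
  arr07 <- barcode_arrays_from_units(lapply(2:8, mk), oligos)
  expect_identical(sort(unique(size_select(arr07, cfg0)$k)), 6:7)
  # empty result is valid
  none <- size_select(arr, ligation_config(flank_length = 0,
                                           size_window = c(1000, 2000)))
  expect_identical(none$n, 0L)
})

test_that("positional frequencies handle degenerate and short inputs", {
  oligos <- test_oligos(3)
  units <- data.frame(label = c("a", "b"), orientation = c("F", "F"))
  arr <- barcode_arrays_from_units(list(units, units, units), oligos)
  pf <- positional_frequencies(arr)
  expect_identical(pf$freq["a:F", "p1"], 1)
  expect_identical(pf$freq["b:F", "p2"], 1)
  expect_identical(sum(pf$freq[, 1:2]), 2)
  # k = 2 arrays have no p3..p5: flagged as empty, NA columns
  expect_identical(pf$empty_positions, 3:5)
  expect_true(all(is.na(pf$freq[, 3:5])))
  expect_error(positional_frequencies(arr[integer(0)]), "empty")
})

test_that("equimolar simulation is uniform over oriented oligos per position", {
  oligos <- test_oligos(10, seed = 2)
  cfg <- ligation_config(n_products = 30000, k_dist = k_fixed(4), seed = 13)
  pf <- positional_frequencies(simulate_ligation(oligos, cfg),
                               max_positions = 4)
  # every cell near 1/20; 4 s.e. band to cover 80 simultaneous cells
  expect_true(all(abs(pf$freq - 0.05) < 4 * sqrt(0.05 * 0.95 / 30000)))
})

test_that("forward:reverse orientation converges to 1:1 per oligo", {
  oligos <- test_oligos(10, seed = 2)
  arr <- simulate_ligation(oligos,
                           ligation_config(n_products = 100000,
                                           k_dist = k_fixed(1), seed = 17))
  u <- arr$units
  for (lab in names(oligos)) {
    n_f <- sum(u$label == lab & u$orientation == "F")
    n_tot <- sum(u$label == lab)
    expect_gt(stats::binom.test(n_f, n_tot, 0.5)$p.value, 0.01)
  }
})
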
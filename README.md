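# bartag

Design and spike-normalized quantification of chromosomal barcode tags for
amplicon sequencing of near-isogenic bacterial strains.

## The problem

16S rRNA amplicon profiling cannot tell apart strains that share identical
marker sequences — a wild type and its single-gene mutants look the same in
a count table. Chromosomally integrated synthetic DNA barcode tags solve
this: each strain carries a unique barcode array flanked by the same primer
binding sites used for bacterial 16S (V5–V7, primers 799/1192), fungal ITS
and plant ITS amplification, so barcode reads are co-amplified with the
community's endogenous markers in one library. A barcode-bearing spike-in
plasmid added at known mass (sample:spike mass ratio 6 ng : 0.001 ng =
6,000) anchors all counts on an absolute scale.

`bartag` is for microbiome researchers running such experiments — and for
anyone who wants to study the method's statistics without wet-lab data. It
implements:

* **Tag design**: in-silico random blunt-end ligation of 38-nt
  oligonucleotide units (four pyrosequencing-friendly sub-barcodes each,
  no homopolymer or dinucleotide tracts beyond 2), fragment size selection
  (200–300 bp), positional composition statistics, assembly of full tag
  scaffolds with the four nested primer pairs, and distinguishability
  checks (both-strand Levenshtein distances).
* **Read assignment**: a bounded nearest-reference classifier (edit
  distance ≤ `max_distance`, runner-up at least `margin` worse, ties never
  broken) producing sample × feature count tables; in-silico depletion of
  focal features.
* **Quantification**: the spike normalization equations

  ```
  Nb = Rb / Rs_16S        Np = Rp / Rs_pITS
  microbial load = Nb / Np = (Rb · Rs_pITS) / (Rp · Rs_16S)
  ```

  standard curves over tenfold spike dilution series (log–log OLS),
  tag-to-16S correction factors (zero-intercept regression over
  pure-culture calibration samples, bootstrap CI), and per-sample
  relative / spike-normalized / plant-normalized abundance views.
* **Synthetic data**: multinomial community count generator with 16S copy
  numbers and tag amplification biases as generative parameters,
  error-bearing read simulation, calibration sets and dilution series with
  known ground truth.

Individual barcode tags amplify with tag-specific efficiency relative to
the endogenous 16S amplicon of the same strain (observed biases span
roughly 1.4- to 3.5-fold); dividing tag counts by a per-tag calibration
factor puts them on the 16S scale, which is what makes cumulative
tag-based strain abundances comparable across mixtures of 2, 3 or 4 tagged
strains.

## Worked example

```r
library(bartag)

## 1. simulate barcode-tag assembly: random ligation + 200-300 bp selection
oligos <- default_oligo_set()                 # ten 38-nt units, a-j
cfg    <- ligation_config(n_products = 10000, seed = 7)
arrays <- size_select(simulate_ligation(oligos, cfg), cfg)
arrays
#> <barcode_arrays> 5672 products, unit counts 3-5, lengths 114-190 nt

## 2. calibrate tag-to-16S correction factors from pure cultures
calib <- generate_calibration(c(tag119 = 3.5, tag104 = 1.6, tag94 = 1.4),
                              n_samples = 16, seed = 7)
cf <- estimate_correction_factor(calib, seed = 8)
cf
#>      tag   factor ci_lower ci_upper  n method
#> 1 tag104 1.624764 1.613236 1.636291 16  slope
#> 2 tag119 3.515336 3.492977 3.537694 16  slope
#> 3  tag94 1.408144 1.395828 1.420461 16  slope

## 3. spike-normalize a root sample and estimate microbial load
counts <- rbind(root1 = c(WCS358_16S = 5200L, tag119 = 1210L,
                          spike16S = 400L, plant_ITS = 2600L,
                          spikePITS = 380L))
ct <- count_table(counts, c(WCS358_16S = "endogenous_16S",
                            tag119 = "barcode_tag",
                            spike16S = "spike_tag",
                            plant_ITS = "plant_ITS",
                            spikePITS = "spike_tag"))
sd <- spike_design("spike16S", "spikePITS")   # 6 ng : 0.001 ng = 6000
corrected <- apply_correction(ct, cf)
bacteria_to_plant_load(normalize_to_spike(corrected, sd))
#>   sample_id       rb   rp nb_total np_total     load
#> 1     root1 5544.206 2600 13.86052 6.842105 2.025768
```

Reading the output: the retained ligation products are preferentially
four-unit arrays averaging ~150 nt; the three correction factors are
re-estimated within about 1% of their generative biases; and the sample
carries ≈ 2.0 normalized bacterial reads per normalized plant read — the
microbial-load estimate that stays comparable across samples of different
sequencing depth. The tag119 column of the corrected table (1210 / 3.52 ≈
344) now matches the strain's share of 16S reads rather than its inflated
raw tag count.

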
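---
title: "Models and methods behind bartag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bartag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartag)
```

`bartag` implements the computational side of chromosomal barcode tagging:
designing synthetic barcode tags that are co-amplified with endogenous
marker genes, assigning amplicon reads to reference features, and turning
read counts into absolute-scale strain abundances via spike-in
normalization and tag-specific correction factors. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## 1. The ligation model for barcode-tag assembly

Barcode arrays are assembled experimentally by random blunt-end ligation of
an equimolar mix of ten double-stranded 38-nt oligonucleotide units,
followed by selection of 200–300 bp fragments. `simulate_ligation()`
mirrors this as a three-stage generative model:

1. the number of ligated units `k` is drawn from a configurable
   pre-selection distribution (`k_dist`);
2. each of the `k` positions receives one unit, drawn independently and
   uniformly (equimolar mixing; per-unit weights are configurable to model
   batch effects), in forward orientation with probability
   `orientation_prob_forward` (default 0.5 — blunt-end ligation has no
   orientation preference);
3. size selection retains products with `38·k + flank_length` inside
   `size_window`.

**Why a truncated Poisson for `k`.** Only the *post*-selection statistics
are observable: retained arrays are preferentially four units long with a
mean length of roughly 150 nt. With the default `flank_length = 100` and
window 200–300 bp, selection retains `k ∈ {3, 4, 5}`. A
monotonically decaying pre-selection distribution (for instance geometric
decay with ratio 0.7, available as `k_geometric()`) necessarily makes
`k = 3` the retained mode and pulls the mean length down to ~143 nt. The
default is therefore a zero-truncated Poisson with λ = 4.2 on `k ∈ [1, 8]`
(`k_poisson()`), under which the retained mode is 4 and the expected mean
array length is 150.5 nt — consistent with a ligation that favours
mid-sized concatemers before any selection. Both the distribution and the
flank length are exposed in `ligation_config()`; the flank is a free
parameter because the adapter content present during size selection is not
part of the retained array (it reconciles the 200–300 bp window with
~150-nt arrays).

The unit sequences themselves are not public, so the package ships a
generator (`generate_oligo_set()`) of constraint-compliant stand-ins —
four sub-barcodes of 10/9/10/9 nt per unit, maximum homopolymer run 2,
no dinucleotide tract repeated more than twice, pairwise sub-barcode edit
distance ≥ 3, no palindromic units — plus a frozen fixture
(`default_oligo_set()`, generated with seed 101 and stored as
`inst/extdata/synthetic_oligos.fasta`; the `synthetic_` prefix marks it as
a stand-in). All ligation draws are governed by the single integer seed in
`ligation_config()`; identical seeds give bit-identical product lists.

`positional_frequencies()` reports the oriented-unit frequency per array
position (the heat-map view of tag composition) and flags positions that
no retained array reaches. Positions beyond the longest array are `NA`,
not zero: absence of evidence, not evidence of absence.

## 2. Tag scaffolds and their invariants

`assemble_scaffold()` surrounds an array with the eight primer binding
sites — bacterial 16S 799F/1192R, fungal ITS1F/ITS2, plant ITS p4/p5, and
a barcode-specific pair — nested so that every pair's amplicon contains the
complete array, with the barcode pair innermost. Three invariants are
enforced at construction: each site occurs exactly once on its strand
(a second verbatim occurrence, e.g. inside the array, is a collision
error); every pair's in-silico amplicon spans the array; and both the
barcode-pair and the 16S-pair amplicons are shorter than the endogenous
V5–V7 amplicon (default 400 nt) so genotyping PCR yields size-separable
products. The 16S and fungal ITS primer sequences are the standard
published ones (degenerate bases resolved to a single instance); the plant
ITS and barcode primers shipped in `default_primer_set()` are synthetic
placeholders with the same role, since the originals are not in the
package's sources. Coordinates are 1-based inclusive throughout, the
native convention of both R/Bioconductor ranges and the GenBank-style
records emitted by `write_scaffold_record()`; using one convention
end-to-end removes the converter layer where off-by-one errors breed.

`check_tag_set()` quantifies distinguishability as the pairwise Levenshtein
distance between array sequences, minimized over strand pairings (a tag and
its reverse complement are the same molecule). It also re-screens full
arrays for homopolymer/dinucleotide tracts: unit junctions can create
tracts that every individual unit avoids, and such tags are reported rather
than silently accepted.

## 3. Read assignment

Reads are assigned by bounded nearest-reference edit distance: a read goes
to the reference (either strand) with minimum Levenshtein distance if that
distance is at most `max_distance` (default 3) and the runner-up reference
is at least `margin` (default 1) edits worse. Everything else — too
distant, ambiguous, or containing non-ACGT characters — is `unassigned`.
Ties are never broken, which makes counts independent of read and
reference order. Reference-based error-correction pipelines (Rbec and
kin) solve a harder statistical problem; here the classifier is
deliberately simple because the references are a small, known set of
mutually distant amplicons, and the package's contribution is downstream
of assignment. Near-isogenic strains must share one `endogenous_16S`
feature (the constructor rejects duplicate sequences): strain resolution
comes only from `barcode_tag` features, which is the method's premise.

Exact-match reads take a hash-lookup fast path (valid because references
are validated pairwise distinct on both strands); only inexact reads pay
for dynamic-programming alignment via `utils::adist`.

## 4. Quantification

The three normalization equations are implemented literally:

* `Nb = Rb / Rs_16S` per bacterial feature,
* `Np = Rp / Rs_pITS` per plant feature,
* `load = Nb / Np`, verified at run time against the closed form
  `(Rb · Rs_pITS) / (Rp · Rs_16S)` to within 1e-12 relative error.

Samples with zero spike reads are excluded with a logged reason rather
than pseudocounted: a spike failure invalidates the library, and a
pseudocount would fabricate a denominator. No pseudocounts are used
anywhere by default; an optional pseudocount exists only for the
relative-abundance view of `summarize_abundance()`. A per-host plant ITS
copy-number scalar is deliberately out of the default path (host ITS copy
number varies between species; the plant-normalized view accepts corrected
inputs).

**Standard curves.** `fit_standard_curve()` regresses log10 normalized
dilution-spike reads on log10 spiked mass. Counts of the diluted spike are
first divided by the constant-mass spike's counts, which cancels
sequencing-depth differences. Zero-count points are dropped with a warning
(log10 is undefined there and a zero observation at the bottom of a
dilution series carries no slope information); at least three surviving
points are required.

**Correction factors.** The tag-to-16S amplification bias of each tag is
estimated from pure-culture calibration samples as the zero-intercept
least-squares slope of normalized tag reads on normalized 16S reads,
`b = Σ(N_tag·N_16S) / Σ(N_16S²)`. The slope is preferred over the mean of
per-sample ratios (also available, `method = "ratio"`) because it weights
samples by their 16S depth, down-weighting the noisiest ratios. The 95%
CI is a t-interval, `b ± t(0.975, n−1) · se_boot`, with the standard error
from a nonparametric bootstrap over calibration samples (1000 seeded
resamples by default). At calibration-typical sample counts (n ≈ 16) the
plain percentile bootstrap interval undercovers (~91% measured over 1000
simulation replications) while the t-form reaches ~95%. `apply_correction()`
divides tag counts by their factor, leaving all other features untouched;
corrected tables are real-valued and flagged as such.

## 5. What the synthetic-data generator emulates

`generate_community_counts()` draws feature counts from a multinomial at
fixed depth with propensities `abundance × copy_number` for 16S features
(summed over strains sharing a 16S group), `abundance × tag_bias` for tag
features, and fixed spike/plant propensities. This is exactly the
generative structure the quantification assumes, which is the point: it
lets every estimator be tested against known truth. Real data differ in
ways the generator does not model — PCR chimeras, index hopping,
quality-score structure, taxon-specific extraction efficiency, and
replicate-to-replicate dispersion beyond the multinomial (an optional
gamma-multiplicative overdispersion parameter exists, off by default,
since no replicate-level dispersion estimates constrain it). Passing tests
therefore demonstrate correctness of the estimators under the stated count
model, not robustness to every artefact of real libraries.

`generate_calibration()` models pure-culture calibration counts as
`n_16s ~ Poisson(mean)` and, conditionally, `n_tag | n_16s ~
Poisson(bias · n_16s)`: tag and 16S reads come from the same amplicon
library, so they co-fluctuate with realized sampling depth. Under this
model the slope estimator recovers biases in the reported 1.4–3.5-fold
range within 2% at n = 16 samples and mean 16S count 1000.

`generate_reads()` emits reads from reference amplicons with independent
per-base substitutions (no indels) on a random strand; with mutually
distant references the unassignment rate is the binomial tail
`P(Bin(L, ε) > max_distance)`, which the tests check in closed form.
`generate_dilution_series()` scales the diluted spike's propensity
proportionally to mass while holding everything else fixed; its fixtures
put the top of the series high enough (propensity 0.3 at 1.5 ng, depth
10^6) that the bottom 0.00015 ng step still yields ~30 expected reads —
mirroring the reported experiments, where the series stayed linear over
its full range rather than dropping below detection.

## 6. Problem sizes, determinism, degenerate inputs

The shipped tests run the ligation model at 10^4–10^5 products, read
assignment at 2 × 10^4 reads against five 250-nt references, calibration
recovery at n = 16 samples per tag, CI coverage at 100 replications × 500
resamples, and mixtures at depth 10^5 with six replicates — sizes chosen
so each statistical check has the power its tolerance implies while the
whole suite stays in the tens of seconds. Every stochastic routine takes
an explicit integer seed and is bit-reproducible given it. Degenerate
inputs fail loudly and early: empty references, non-simplex abundances,
zero spike counts, all-zero tag calibrations, palindromic units, colliding
primer sites and overlong amplicons are all errors with named culprits,
not silent repairs.

## 7. Known limitations

* The classifier is not an error-correction model; at error rates far
  above typical merged-read levels, or with references closer than
  `2 · max_distance`, its guarantees lapse (the constructor cannot see
  reference distances; `check_tag_set()` can).
* Correction factors are per-tag × per-strain constants; any
  context-dependent amplification (matrix effects between root and soil
  samples, say) is averaged over by calibration.
* In-planta biological results (mutant colonization deficits, >100-fold
  strain depletion) require the deposited sequencing data and are outside
  what synthetic fixtures can reproduce; the package instead demonstrates
  the *compositionality* phenomenon behind them — under a halved total
  load, relative abundances can rise while every spike-normalized
  abundance falls — as a property of `summarize_abundance()`.
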
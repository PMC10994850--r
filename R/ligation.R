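#' Pre-selection distributions of the number of ligated units
#'
#' Helpers returning a discrete distribution over the number of oligo units
#' `k` in a ligation product before size selection, as a list with components
#' `k` (support) and `prob`. `k_poisson()` (zero-truncated, the default in
#' [ligation_config()]) reproduces the observed post-selection statistics
#' (modal 4 units, ~150 nt mean array length); `k_geometric()` models pure
#' decay with ratio `r`; `k_fixed()` is degenerate at one value.
#'
#' @param lambda Poisson mean (default 4.2).
#' @param r Geometric decay ratio in (0, 1).
#' @param k Fixed unit count for `k_fixed()`.
#' @param k_min,k_max Truncation bounds of the support (defaults 1 and 8).
#' @return A list with integer vector `k` and numeric `prob` summing to 1.
#' @export
k_poisson <- function(lambda = 4.2, k_min = 1L, k_max = 8L) {
  stopifnot(lambda > 0, k_min >= 1, k_max >= k_min)
  k <- seq.int(k_min, k_max)
  p <- stats::dpois(k, lambda)
  list(k = k, prob = p / sum(p))
}

#' @rdname k_poisson
#' @export
k_geometric <- function(r = 0.7, k_min = 1L, k_max = 8L) {
  stopifnot(r > 0, r < 1, k_min >= 1, k_max >= k_min)
  k <- seq.int(k_min, k_max)
  p <- r^k
  list(k = k, prob = p / sum(p))
}

#' @rdname k_poisson
#' @export
k_fixed <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  list(k = as.integer(k), prob = 1)
}

#' Configuration of a simulated random-ligation experiment
#'
#' Parameters of the in-silico analogue of random blunt-end ligation of an
#' equimolar oligo mix followed by fragment size selection.
#'
#' @param n_products Number of ligation products to draw (> 0).
#' @param k_dist Distribution of the unit count per product before selection;
#'   see [k_poisson()]. Default: zero-truncated Poisson(4.2) on 1..8.
#' @param orientation_prob_forward Probability that a unit ligates in forward
#'   orientation (default 0.5; blunt-end ligation is orientation-agnostic).
#' @param oligo_weights Optional per-oligo sampling weights (default
#'   equimolar). Named vector matching the oligo labels, or unnamed in set
#'   order.
#' @param flank_length Nucleotides of non-array (adapter/vector) sequence
#'   carried through size selection together with the array (default 100).
#' @param size_window Retained fragment size window in bp, `(min, max)`
#'   (default `c(200, 300)`).
#' @param seed Integer seed governing all draws; identical seed implies an
#'   identical product list.
#' @return A `ligation_config` list.
#' @export
ligation_config <- function(n_products = 10000L,
                            k_dist = k_poisson(),
                            orientation_prob_forward = 0.5,
                            oligo_weights = NULL,
                            flank_length = 100L,
                            size_window = c(200L, 300L),
                            seed = 1L) {
  if (length(n_products) != 1L || is.na(n_products) || n_products <= 0) {
    stop("n_products must be a positive count", call. = FALSE)
  }
  stopifnot(is.list(k_dist), length(k_dist$k) == length(k_dist$prob),
            all(k_dist$prob >= 0), abs(sum(k_dist$prob) - 1) < 1e-9)
  if (orientation_prob_forward < 0 || orientation_prob_forward > 1) {
    stop("orientation_prob_forward must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(size_window) == 2L)
  if (!(size_window[1] < size_window[2])) {
    stop("size_window must satisfy min < max", call. = FALSE)
  }
  structure(list(n_products = as.integer(n_products), k_dist = k_dist,
                 orientation_prob_forward = orientation_prob_forward,
                 oligo_weights = oligo_weights,
                 flank_length = as.integer(flank_length),
                 size_window = as.integer(size_window),
                 seed = as.integer(seed)),
            class = "ligation_config")
}

new_barcode_arrays <- function(units, k, sequence, oligo_labels) {
  structure(list(units = units, k = as.integer(k), sequence = sequence,
                 n = length(k), oligo_labels = oligo_labels),
            class = "barcode_arrays")
}

#' @export
print.barcode_arrays <- function(x, ...) {
  cat(sprintf("<barcode_arrays> %d products, unit counts %s, lengths %s nt\n",
              x$n, paste(range(x$k), collapse = "-"),
              paste(range(nchar(x$sequence)), collapse = "-")))
  invisible(x)
}

#' @export
length.barcode_arrays <- function(x) x$n

# Subset a barcode_arrays collection by product index, preserving order.
#' @export
`[.barcode_arrays` <- function(x, i) {
  keep <- seq_len(x$n)[i]
  units <- x$units[x$units$product %in% keep, , drop = FALSE]
  units$product <- match(units$product, keep)
  new_barcode_arrays(units, x$k[keep], x$sequence[keep], x$oligo_labels)
}

#' Construct barcode arrays from explicit unit lists
#'
#' Mostly for tests and degenerate cases: build a `barcode_arrays` collection
#' from a list of `(label, orientation)` unit tables.
#'
#' @param unit_list List of data frames with columns `label` and
#'   `orientation` (`"F"`/`"R"`), one per product, in ligation order.
#' @param oligos An `oligo_set` providing the unit sequences.
#' @return A `barcode_arrays` object; each product's `sequence` is the
#'   concatenation of its oriented unit sequences (length `38 * k`).
#' @export
barcode_arrays_from_units <- function(unit_list, oligos) {
  stopifnot(inherits(oligos, "oligo_set"), length(unit_list) >= 1)
  fwd <- oligo_sequences(oligos)
  rev <- revcomp(fwd)
  names(rev) <- names(fwd)
  k <- vapply(unit_list, nrow, integer(1))
  units <- do.call(rbind, Map(function(df, i) {
    stopifnot(all(df$label %in% names(fwd)),
              all(df$orientation %in% c("F", "R")))
    data.frame(product = i, position = seq_len(nrow(df)),
               label = df$label, orientation = df$orientation)
  }, unit_list, seq_along(unit_list)))
  oriented <- ifelse(units$orientation == "F",
                     fwd[units$label], rev[units$label])
  sequence <- vapply(split(oriented, units$product), paste,
                     character(1), collapse = "")
  sequence <- unname(sequence[order(as.integer(names(sequence)))])
  new_barcode_arrays(units, k, sequence, names(fwd))
}

#' Simulate random blunt-end ligation of oligo units
#'
#' Each product draws its unit count `k` from `config$k_dist`, then fills each
#' of the `k` positions independently with one oligo (equimolar by default)
#' and an orientation (forward with probability
#' `config$orientation_prob_forward`). The product sequence is the
#' concatenation of the oriented 38-nt unit sequences, so every array length
#' is exactly `38 * k`.
#'
#' @param oligos An `oligo_set` with at least two units.
#' @param config A [ligation_config()].
#' @return A `barcode_arrays` object with fields `units` (long-format table
#'   `product`/`position`/`label`/`orientation`), `k`, and `sequence`.
#' @export
simulate_ligation <- function(oligos, config = ligation_config()) {
  stopifnot(inherits(oligos, "oligo_set"), inherits(config, "ligation_config"))
  if (length(oligos) < 2L) {
    stop("need at least 2 oligo units to ligate", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_products
  labels <- names(oligos)
  w <- config$oligo_weights
  if (!is.null(w)) {
    if (!is.null(names(w))) w <- w[labels]
    stopifnot(length(w) == length(labels), all(w >= 0), sum(w) > 0)
  }
  kd <- config$k_dist
  k <- if (length(kd$k) == 1L) rep(kd$k, n) else
    sample(kd$k, n, replace = TRUE, prob = kd$prob)
  total <- sum(k)
  lab <- sample(labels, total, replace = TRUE, prob = w)
  ori <- sample(c("F", "R"), total, replace = TRUE,
                prob = c(config$orientation_prob_forward,
                         1 - config$orientation_prob_forward))
  product <- rep.int(seq_len(n), k)
  position <- sequence(k)
  fwd <- oligo_sequences(oligos)
  rev <- revcomp(fwd)
  names(rev) <- names(fwd)
  oriented <- ifelse(ori == "F", fwd[lab], rev[lab])
  seqs <- vapply(split(oriented, product), paste, character(1), collapse = "")
  seqs <- unname(seqs[order(as.integer(names(seqs)))])
  units <- data.frame(product = product, position = position,
                      label = lab, orientation = ori)
  new_barcode_arrays(units, k, seqs, labels)
}

#' Size-select ligation products
#'
#' Retains products whose selectable fragment length, `38 * k +
#' flank_length`, falls inside the configured size window (default
#' 200--300 bp), preserving order. May return an empty collection.
#'
#' @param arrays A `barcode_arrays` object from [simulate_ligation()].
#' @param config The [ligation_config()] supplying `flank_length` and
#'   `size_window`.
#' @return A `barcode_arrays` object containing the retained products.
#' @export
size_select <- function(arrays, config = ligation_config()) {
  stopifnot(inherits(arrays, "barcode_arrays"),
            inherits(config, "ligation_config"))
  frag <- 38L * arrays$k + config$flank_length
  keep <- which(frag >= config$size_window[1] & frag <= config$size_window[2])
  arrays[keep]
}

#' Positional oriented-oligo frequencies of a barcode array collection
#'
#' For each array position `p1..p_max` computes the frequency of every
#' oriented oligo (label x forward/reverse), normalized over the arrays long
#' enough to have that position, plus the histogram of unit counts.
#'
#' @param arrays A non-empty `barcode_arrays` object.
#' @param max_positions Number of leading positions to tabulate (default 5).
#' @return A `positional_frequencies` list: `freq`, a `2 * n_oligos` by
#'   `max_positions` matrix (rows like `"a:F"`) whose columns each sum to 1;
#'   columns with no eligible array are `NA` and listed in `empty_positions`;
#'   `k_counts`, the unit-count histogram; `n_eligible`, arrays per position.
#' @export
positional_frequencies <- function(arrays, max_positions = 5L) {
  stopifnot(inherits(arrays, "barcode_arrays"))
  if (arrays$n == 0L) stop("empty array collection", call. = FALSE)
  oriented <- as.vector(outer(arrays$oligo_labels, c("F", "R"), paste,
                              sep = ":"))
  freq <- matrix(NA_real_, nrow = length(oriented), ncol = max_positions,
                 dimnames = list(oriented, paste0("p", seq_len(max_positions))))
  n_eligible <- integer(max_positions)
  u <- arrays$units
  key <- paste(u$label, u$orientation, sep = ":")
  for (j in seq_len(max_positions)) {
    n_eligible[j] <- sum(arrays$k >= j)
    if (n_eligible[j] == 0L) next
    tab <- table(factor(key[u$position == j], levels = oriented))
    freq[, j] <- as.numeric(tab) / n_eligible[j]
  }
  structure(list(freq = freq,
                 k_counts = table(factor(arrays$k,
                                         levels = seq_len(max(arrays$k)))),
                 n_eligible = n_eligible,
                 empty_positions = which(n_eligible == 0L)),
            class = "positional_frequencies")
}

#' @export
print.positional_frequencies <- function(x, ...) {
  cat("<positional_frequencies>\n")
  cat("unit-count histogram:\n")
  print(x$k_counts)
  cat("oriented-oligo frequency matrix (first positions):\n")
  print(round(x$freq[, seq_len(min(3L, ncol(x$freq))), drop = FALSE], 3))
  invisible(x)
}
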
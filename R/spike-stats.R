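#' Per-neuron and layer-mean firing rates
#'
#' Spike counts divided by the window length, for every neuron of the layer
#' (silent neurons get 0 Hz).
#'
#' @param raster A `spike_raster`.
#' @param window Analysis window `c(start, end)` in seconds (typically after
#'   burn-in).
#' @return List with `rates` (Hz, length `raster$n`) and `mean` (layer mean).
#' @export
mean_rates <- function(raster, window = c(0, raster$duration)) {
  if (diff(window) <= 0) stop("zero-length window")
  sel <- raster$times >= window[1] & raster$times < window[2]
  rates <- tabulate(raster$ids[sel], raster$n) / diff(window)
  list(rates = rates, mean = mean(rates))
}

#' Pairwise correlation as a function of pairwise distance
#'
#' Pearson correlations of binned spike counts for all pairs of the supplied
#' neurons, averaged within equal-width periodic-distance bins over
#' `[0, sqrt(2)/2]`. Zero-variance columns are excluded. Empty distance bins
#' are reported as `NA`, not zero.
#'
#' @param counts T-by-K count matrix from [bin_counts()].
#' @param positions K-by-2 matrix of the neurons' positions (same column
#'   order).
#' @param n_bins Number of distance bins.
#' @return data.frame with `distance` (bin midpoint), `mean_corr`, `n_pairs`.
#' @export
correlations_vs_distance <- function(counts, positions, n_bins = 20L) {
  keep <- apply(counts, 2, sd) > 0
  counts <- counts[, keep, drop = FALSE]
  positions <- positions[keep, , drop = FALSE]
  k <- ncol(counts)
  if (k < 2) stop("need at least two neurons with count variance")
  cm <- cor(counts)
  ut <- upper.tri(cm)
  ij <- which(ut, arr.ind = TRUE)
  d <- periodic_distance(positions[ij[, 1], , drop = FALSE],
                         positions[ij[, 2], , drop = FALSE])
  brk <- seq(0, sqrt(2) / 2, length.out = n_bins + 1L)
  b <- pmin(findInterval(d, brk, rightmost.closed = TRUE), n_bins)
  mc <- rep(NA_real_, n_bins)
  np <- tabulate(b, n_bins)
  agg <- vapply(split(cm[ut], factor(b, levels = seq_len(n_bins))),
                function(v) if (length(v)) mean(v) else NA_real_, 0)
  mc[np > 0] <- agg[np > 0]
  data.frame(distance = (head(brk, -1) + tail(brk, -1)) / 2,
             mean_corr = mc, n_pairs = np)
}

#' Between-area spike-count correlations
#'
#' Pearson correlations of 50-ms spike counts for (sender, receiver) neuron
#' pairs and the mean of their distribution. When the full cross product
#' exceeds `max_pairs`, a seeded uniform random subsample of pairs is used.
#' Columns without count variance are excluded.
#'
#' @param counts_s,counts_r T-by-K count matrices with matched time bins.
#' @param max_pairs Cap on the number of pairs evaluated.
#' @param seed Seed for pair subsampling.
#' @return List with `mu` (distribution mean), `correlations` (vector) and
#'   `n_pairs`.
#' @export
between_area_correlations <- function(counts_s, counts_r, max_pairs = 1e6,
                                      seed = 1L) {
  if (nrow(counts_s) != nrow(counts_r))
    stop("mismatched number of time bins")
  zs <- scale(counts_s); zr <- scale(counts_r)
  zs <- zs[, apply(counts_s, 2, sd) > 0, drop = FALSE]
  zr <- zr[, apply(counts_r, 2, sd) > 0, drop = FALSE]
  t_ <- nrow(zs)
  ns <- ncol(zs); nr <- ncol(zr)
  n_all <- as.double(ns) * nr
  if (n_all <= max_pairs) {
    cc <- crossprod(zs, zr) / (t_ - 1)
    rho <- as.numeric(cc)
  } else {
    pair <- withr_seed(seed, {
      i <- sample.int(ns, max_pairs, replace = TRUE)
      j <- sample.int(nr, max_pairs, replace = TRUE)
      cbind(i, j)
    })
    rho <- numeric(max_pairs)
    chunk <- 2e5
    for (s0 in seq(1, max_pairs, by = chunk)) {
      s1 <- min(s0 + chunk - 1, max_pairs)
      rho[s0:s1] <- colSums(zs[, pair[s0:s1, 1], drop = FALSE] *
                              zr[, pair[s0:s1, 2], drop = FALSE]) / (t_ - 1)
    }
  }
  list(mu = mean(rho), correlations = rho, n_pairs = length(rho))
}
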
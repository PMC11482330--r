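#' Wrapped Gaussian density on the unit circle
#'
#' Density of a Gaussian with standard deviation `sigma` wrapped onto the
#' periodic unit interval: `g(u, sigma) = (1 / (sigma * sqrt(2 * pi))) *
#' sum_k exp(-(u + k)^2 / (2 sigma^2))`, truncated at `|k| <= k_max`. With the
#' default `k_max = 5` the truncation error is below 1e-12 for `sigma <= 0.3`.
#'
#' @param u Displacement(s); any real value, the density has period 1.
#' @param sigma Width of the underlying Gaussian, > 0.
#' @param k_max Truncation order of the wrapping sum, >= 1. The default grows
#'   with `sigma` (never below 5) so the truncation error stays below 1e-12
#'   even for very broad kernels.
#' @return Density value(s), same length as `u`.
#' @export
wrapped_gaussian <- function(u, sigma, k_max = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  if (is.null(k_max)) k_max <- max(5L, as.integer(ceiling(8 * sigma)) + 1L)
  if (k_max < 1L) stop("`k_max` must be >= 1")
  cpp_wrapped_gaussian(as.numeric(u), sigma, as.integer(k_max))
}

#' Periodic Euclidean distance on the unit square
#'
#' Distance with per-coordinate wrap-around: each coordinate difference is
#' reduced to `min(|d|, 1 - |d|)`. The maximum attainable distance is
#' `sqrt(2)/2`.
#'
#' @param x,y Positions: length-2 vectors or n-by-2 matrices in `[0, 1)^2`.
#' @return Distance(s).
#' @export
periodic_distance <- function(x, y) {
  x <- rbind(x); y <- rbind(y)
  d <- abs(x - y)
  d <- pmin(d, 1 - d)
  unname(sqrt(rowSums(d * d)))
}

#' Build a square lattice layer
#'
#' Places `n` neurons of one class at the cell centers of a `sqrt(n)` by
#' `sqrt(n)` lattice covering the periodic unit square: neuron `i` (1-based)
#' sits at `(((i-1) mod s) + 0.5) / s, (floor((i-1) / s) + 0.5) / s)`.
#' Cell-centered placement avoids coincident positions across layers of
#' different sizes.
#'
#' @param n Number of neurons; must be a perfect square.
#' @param class Neuron class label: `"E"`, `"I"` or `"input"`.
#' @return An object of class `grid_layer`: list with `n`, `side`, `positions`
#'   (n-by-2 matrix) and `class`.
#' @export
grid_layer <- function(n, class = c("E", "I", "input")) {
  class <- match.arg(class)
  s <- as.integer(round(sqrt(n)))
  if (s * s != n) stop("`n` must be a perfect square, got ", n)
  i <- seq_len(n) - 1L
  pos <- cbind(x1 = ((i %% s) + 0.5) / s, x2 = ((i %/% s) + 0.5) / s)
  structure(list(n = as.integer(n), side = s, positions = pos, class = class),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d %s neurons on a %dx%d lattice\n",
              x$n, x$class, x$side, x$side))
  invisible(x)
}

#' Distance-dependent connection probability
#'
#' Probability that a presynaptic neuron at `y` connects to a postsynaptic
#' neuron at `x`: `p = p_bar * g(x1 - y1, sigma) * g(x2 - y2, sigma)`, clipped
#' to `[0, 1]`, where `g` is the wrapped Gaussian and `p_bar` is the mean
#' connection probability (so the expected out-degree onto a layer of `N`
#' postsynaptic neurons is `K_out = p_bar * N`).
#'
#' @param x,y Postsynaptic / presynaptic positions (length-2 or n-by-2).
#' @param sigma Wrapped-Gaussian width.
#' @param p_bar Mean connection probability in `[0, 1]`.
#' @param k_max Wrapping truncation order.
#' @return Probability value(s) in `[0, 1]`.
#' @export
connection_probability <- function(x, y, sigma, p_bar, k_max = NULL) {
  if (p_bar < 0 || p_bar > 1) stop("`p_bar` must be in [0, 1]")
  x <- rbind(x); y <- rbind(y)
  p <- p_bar * wrapped_gaussian(x[, 1] - y[, 1], sigma, k_max) *
    wrapped_gaussian(x[, 2] - y[, 2], sigma, k_max)
  pmin(p, 1)
}

#' Subset of a layer acting as a presynaptic source
#'
#' A regular sublattice (or arbitrary subset) of a layer's neurons, used e.g.
#' when the receiver's feedforward sources are an input-layer-sized sample of
#' the sender's excitatory lattice.
#'
#' @param layer A `grid_layer`.
#' @param ids 1-based neuron ids to keep.
#' @return An object of class `layer_subset` with `n`, `positions`, `ids` and
#'   the parent `class`.
#' @export
layer_subset <- function(layer, ids) {
  stopifnot(inherits(layer, "grid_layer"), all(ids >= 1 & ids <= layer$n))
  structure(list(n = length(ids),
                 positions = layer$positions[ids, , drop = FALSE],
                 ids = as.integer(ids), class = layer$class),
            class = "layer_subset")
}

#' Regular sublattice ids
#'
#' Ids (1-based) of an approximately regular `side_sub` x `side_sub` sublattice
#' of a `side_full` x `side_full` layer lattice.
#'
#' @param side_full,side_sub Lattice sides, `side_sub <= side_full`.
#' @return Integer vector of `side_sub^2` ids.
#' @export
sublattice_ids <- function(side_full, side_sub) {
  stopifnot(side_sub <= side_full)
  line <- unique(floor((seq_len(side_sub) - 0.5) * side_full / side_sub)) # 0-based
  as.integer(outer(line * side_full, line, `+`) + 1L)
}

#' Sample a spatial synaptic projection
#'
#' Draws the directed wiring of one (presynaptic class, postsynaptic class)
#' projection under one of two schemes:
#'
#' * `"outdegree"` (default, used by the simulations): every presynaptic
#'   neuron makes exactly `K_out = round(p_bar * n_post)` contacts whose
#'   displacements are drawn from the isotropic wrapped Gaussian of width
#'   `sigma` and mapped to the enclosing postsynaptic lattice cell. Repeated
#'   draws of a target are kept as multiple contacts (multi-synapses), which
#'   preserves the total synaptic drive where the pairwise probability
#'   formula saturates at short distance; self-contacts are redrawn.
#' * `"bernoulli"`: every ordered pair is connected independently with the
#'   probability of [connection_probability()] (clipped at 1); no duplicate
#'   edges; degree distributions are binomial.
#'
#' Reproducible given `seed`; each projection should get its own stream, see
#' [seed_stream()].
#'
#' @param pre A `grid_layer` or [layer_subset()] (presynaptic sources).
#' @param post A `grid_layer` (postsynaptic lattice).
#' @param sigma Wrapped-Gaussian width of the projection.
#' @param p_bar Mean connection probability (`K_out / n_post`).
#' @param seed Integer seed for this projection's private RNG stream.
#' @param scheme `"outdegree"` or `"bernoulli"`.
#' @param exclude_self Drop `i -> i` contacts. Defaults to TRUE when pre and
#'   post are the same layer.
#' @return An object of class `synapse_matrix`: list with CSR fields `ptr`
#'   (length `n_pre + 1`) and `idx` (0-based postsynaptic indices; possibly
#'   repeated under `"outdegree"`), plus `n_pre`, `n_post`, `sigma`, `p_bar`,
#'   `scheme`.
#' @export
sample_synapses <- function(pre, post, sigma, p_bar, seed,
                            scheme = c("outdegree", "bernoulli"),
                            exclude_self = identical(pre, post)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(pre, c("grid_layer", "layer_subset")),
            inherits(post, "grid_layer"))
  if (p_bar < 0) stop("`p_bar` must be nonnegative")
  # under the multi-synapse out-degree scheme p_bar = K_out / n_post is a mean
  # contact count and may exceed 1 (scaled networks with preserved in-degrees)
  if (scheme == "bernoulli" && p_bar > 1)
    stop("`p_bar` must be in [0, 1] for the bernoulli scheme")
  if (sigma <= 0) stop("`sigma` must be positive")
  exp_edges <- p_bar * as.double(pre$n) * post$n
  if (exp_edges > 5e8) stop("expected edge count ", format(exp_edges),
                            " exceeds the memory budget")
  self_idx <- if (isTRUE(exclude_self) && inherits(pre, "grid_layer") &&
                  pre$n == post$n) seq_len(pre$n) - 1L
              else rep(-1L, pre$n)
  out <- cpp_sample_synapses(pre$positions[, 1], pre$positions[, 2],
                             post$side, sigma, p_bar, as.double(seed),
                             self_idx, match(scheme, c("outdegree", "bernoulli")) - 1L)
  structure(list(ptr = out$ptr, idx = out$idx,
                 n_pre = pre$n, n_post = post$n,
                 sigma = sigma, p_bar = p_bar, scheme = scheme),
            class = "synapse_matrix")
}

#' @export
print.synapse_matrix <- function(x, ...) {
  cat(sprintf(
    "<synapse_matrix> %d edges, %d -> %d neurons (density %.4g, nominal %.4g)\n",
    length(x$idx), x$n_pre, x$n_post,
    length(x$idx) / (as.double(x$n_pre) * x$n_post), x$p_bar))
  invisible(x)
}

#' Triplet representation of a projection
#'
#' @param x A `synapse_matrix`.
#' @param ... Unused.
#' @return data.frame with 1-based `pre` and `post` columns, one row per edge.
#' @export
as.data.frame.synapse_matrix <- function(x, ...) {
  data.frame(pre = rep.int(seq_len(x$n_pre), diff(x$ptr)),
             post = x$idx + 1L)
}

#' Empirical connection frequency versus distance
#'
#' Bins all ordered (pre, post) pairs of a sampled projection by periodic
#' distance and returns the fraction connected per bin, for comparison with
#' the wrapped-Gaussian profile.
#'
#' @param syn A `synapse_matrix`.
#' @param pre,post The `grid_layer`s it was sampled from.
#' @param n_bins Number of equal-width distance bins over `[0, sqrt(2)/2]`.
#' @param max_pre Cap on the number of presynaptic neurons scanned (they are
#'   subsampled deterministically by taking every k-th) to bound cost.
#' @return data.frame with `distance` (bin midpoint), `p_hat`, `n_pairs`.
#' @export
connection_vs_distance <- function(syn, pre, post, n_bins = 20L,
                                   max_pre = 400L) {
  keep <- unique(as.integer(round(seq(1L, pre$n,
                                      length.out = min(pre$n, max_pre)))))
  brk <- seq(0, sqrt(2) / 2, length.out = n_bins + 1L)
  tot <- con <- numeric(n_bins)
  for (i in keep) {
    d <- periodic_distance(
      matrix(pre$positions[i, ], post$n, 2, byrow = TRUE), post$positions)
    b <- pmin(findInterval(d, brk, rightmost.closed = TRUE), n_bins)
    tot_i <- tabulate(b, n_bins)
    tgt <- syn$idx[seq.int(syn$ptr[i] + 1L, length.out = syn$ptr[i + 1L] - syn$ptr[i])] + 1L
    con_i <- tabulate(b[tgt], n_bins)
    tot <- tot + tot_i; con <- con + con_i
  }
  data.frame(distance = (head(brk, -1) + tail(brk, -1)) / 2,
             p_hat = ifelse(tot > 0, con / tot, NA_real_),
             n_pairs = tot)
}
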
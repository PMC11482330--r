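#' Factor analysis by expectation-maximization
#'
#' Fits the Gaussian factor model `x ~ N(mu, L L' + Psi)` with `q` latent
#' variables to a T-by-K count matrix: `C_shared = L L'` is the shared (low
#' rank) covariance component and `Psi = C_private` the diagonal private
#' variances, which unlike probabilistic PCA are not constrained to be equal.
#' EM maximizes the data log-likelihood; the training log-likelihood is
#' nondecreasing across iterations and convergence is declared when its
#' relative improvement falls below `tol`.
#'
#' @param x T-by-K data matrix (rows = time bins).
#' @param q Number of latent factors, `0 <= q < K`. With `q = 0` the model
#'   reduces to a diagonal covariance.
#' @param tol Relative log-likelihood improvement for convergence.
#' @param max_iter Maximum EM iterations; non-convergence yields a warning and
#'   the final model.
#' @param seed Seed for the random initialization of `L`.
#' @return An object of class `fa_model`: `mu`, `L` (K-by-q), `psi` (diagonal
#'   of `C_private`), `c_shared`, `lambdas` (eigenvalues of `C_shared`,
#'   descending), `d_shared` (participation ratio), `loglik` (per-iteration
#'   trace), `converged`, `q`, `n_obs`.
#' @export
fit_fa <- function(x, q, tol = 1e-6, max_iter = 500L, seed = 1L) {
  x <- as.matrix(x)
  t_ <- nrow(x); k <- ncol(x)
  if (q < 0 || q >= k) stop("`q` must satisfy 0 <= q < K")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- crossprod(xc) / t_
  if (any(diag(s) <= 0))
    stop("zero-variance column in `x`; filter unresponsive neurons first")

  if (q == 0L) {
    psi <- diag(s)
    ll <- ll_gauss(s, diag(psi, k), t_)
    return(new_fa_model(mu, matrix(0, k, 0), psi, ll, TRUE, q, t_))
  }

  l <- withr_seed(seed, {
    a <- matrix(rnorm(k * q), k, q)
    a <- qr.Q(qr(a)) # random orthonormal directions
    a * sqrt(mean(diag(s)) / 2)
  })
  psi <- diag(s) / 2
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sigma <- tcrossprod(l) + diag(psi, k)
    inv <- chol2inv(chol(sigma))
    beta <- crossprod(l, inv)            # q x k
    sb <- s %*% t(beta)                  # k x q
    ezz <- diag(q) - beta %*% l + beta %*% sb
    l_new <- sb %*% solve(ezz)
    psi_new <- pmax(diag(s - l_new %*% t(sb)), 1e-8)
    ll <- ll_gauss(s, sigma, t_)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      l <- l_new; psi <- psi_new
      break
    }
    ll_old <- ll
    l <- l_new; psi <- psi_new
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  out <- new_fa_model(mu, l, psi, ll_trace, converged, q, t_)
  out
}

new_fa_model <- function(mu, l, psi, ll_trace, converged, q, t_) {
  c_shared <- tcrossprod(l)
  # eigenvalues of L L' are the squared singular values of L
  lambdas <- if (q > 0) sort(svd(l, nu = 0, nv = 0)$d^2, decreasing = TRUE)
             else numeric(0)
  d_shared <- if (length(lambdas) && any(lambdas > 0))
    participation_ratio(lambdas) else NA_real_
  structure(list(mu = mu, L = l, psi = psi, c_shared = c_shared,
                 lambdas = lambdas, d_shared = d_shared,
                 loglik = ll_trace, converged = converged, q = q,
                 n_obs = t_),
            class = "fa_model")
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("<fa_model> K = %d, q = %d, D_shared = %.3f, %s\n",
              length(x$mu), x$q,
              if (is.na(x$d_shared)) NA else x$d_shared,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Gaussian log-likelihood of T observations summarized by MLE covariance s
# under model covariance sigma (mean at the sample mean).
ll_gauss <- function(s, sigma, t_) {
  k <- ncol(s)
  ch <- chol(sigma)
  ld <- 2 * sum(log(diag(ch)))
  -t_ / 2 * (k * log(2 * pi) + ld + sum(chol2inv(ch) * s))
}

#' Log-likelihood of data under a fitted factor model
#'
#' @param model An `fa_model`.
#' @param x T-by-K data matrix (e.g. held-out time bins).
#' @return Total Gaussian log-likelihood of the rows of `x`.
#' @export
loglik_fa <- function(model, x) {
  x <- as.matrix(x)
  k <- length(model$mu)
  sigma <- model$c_shared + diag(model$psi, k)
  xc <- sweep(x, 2, model$mu)
  ch <- chol(sigma)
  z <- xc %*% chol2inv(ch) * xc
  -0.5 * (nrow(x) * (k * log(2 * pi) + 2 * sum(log(diag(ch)))) + sum(z))
}

# Drop columns whose counts are constant overall or within any contiguous
# training fold (they make the Gaussian factor likelihood degenerate).
drop_fold_constant <- function(x, folds) {
  fold_id <- cut(seq_len(nrow(x)), folds, labels = FALSE)
  ok <- rep(TRUE, ncol(x))
  for (f in seq_len(folds)) {
    tr <- x[fold_id != f, , drop = FALSE]
    ok <- ok & apply(tr, 2, function(col) any(col != col[1]))
  }
  ok & apply(x, 2, function(col) any(col != col[1]))
}

#' Cross-validated selection of the number of factors
#'
#' Picks the `q` maximizing the held-out data log-likelihood over contiguous
#' time-block folds (blocks respect the temporal autocorrelation of binned
#' spike counts). Ties break to the smallest `q`.
#'
#' @param x T-by-K data matrix.
#' @param q_grid Candidate factor counts.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for EM initializations.
#' @param ... Passed to [fit_fa()].
#' @return List with `q_star`, and `table` (data.frame of `q`, summed held-out
#'   log-likelihood).
#' @export
select_q <- function(x, q_grid = 1:15, folds = 5L, seed = 1L, ...) {
  if (!length(q_grid)) stop("`q_grid` is empty")
  x <- as.matrix(x)
  t_ <- nrow(x)
  if (t_ < 2 * folds) stop("too few time bins for ", folds, " folds")
  ok <- drop_fold_constant(x, folds)
  if (!all(ok)) {
    warning(sum(!ok), " fold-degenerate column(s) dropped before q selection")
    x <- x[, ok, drop = FALSE]
  }
  fold_id <- cut(seq_len(t_), folds, labels = FALSE)
  ll <- matrix(NA_real_, length(q_grid), folds)
  for (f in seq_len(folds)) {
    tr <- x[fold_id != f, , drop = FALSE]
    te <- x[fold_id == f, , drop = FALSE]
    for (qi in seq_along(q_grid)) {
      m <- suppressWarnings(
        fit_fa(tr, q_grid[qi], seed = seed_stream(seed, "fa_cv", f), ...))
      ll[qi, f] <- loglik_fa(m, te)
    }
  }
  tot <- rowSums(ll)
  q_star <- q_grid[which.max(tot)]
  list(q_star = q_star,
       table = data.frame(q = q_grid, heldout_loglik = tot))
}

#' Participation ratio of an eigenspectrum
#'
#' The threshold-free effective dimensionality `(sum(lambda))^2 /
#' sum(lambda^2)`: `n` for a uniform spectrum of `n` equal eigenvalues, 1 when
#' a single eigenvalue dominates. Invariant to uniform rescaling.
#'
#' @param lambdas Nonnegative eigenvalues, not all zero.
#' @return The participation ratio.
#' @export
participation_ratio <- function(lambdas) {
  if (any(lambdas < -1e-12 * max(abs(lambdas))))
    stop("eigenvalues must be nonnegative")
  lambdas <- pmax(lambdas, 0)
  if (!any(lambdas > 0)) stop("all-zero spectrum: dimensionality undefined")
  sum(lambdas)^2 / sum(lambdas^2)
}

#' Sample a disc of responsive neurons
#'
#' Draws `k` distinct neurons uniformly at random among those lying within
#' periodic distance `radius` of a disc center and firing above `threshold`.
#' A radius of 0.5 covers the full periodic unit square.
#'
#' @param positions n-by-2 matrix of neuron positions.
#' @param rates Per-neuron firing rates in Hz.
#' @param radius Disc radius in grid units.
#' @param k Neurons to sample (default 50).
#' @param threshold Rate filter in Hz (default 2; strictly above).
#' @param seed Seed (center draw + neuron sampling).
#' @param center Optional fixed disc center (length-2); random if NULL.
#' @return List with `ids` (row indices into `positions`), `center`, `radius`.
#' @export
sample_disc <- function(positions, rates, radius, k = 50L, threshold = 2,
                        seed = 1L, center = NULL) {
  stopifnot(nrow(positions) == length(rates))
  withr_seed(seed, {
    if (is.null(center)) center <- runif(2)
    d <- periodic_distance(matrix(center, nrow(positions), 2, byrow = TRUE),
                           positions)
    # a radius of 0.5 spans the whole periodic domain (half the domain width
    # in every direction), so no neuron is excluded by distance
    elig <- which((radius >= 0.5 | d <= radius) & rates > threshold)
    if (length(elig) < k)
      stop(sprintf(
        "only %d eligible neurons (need %d) in disc of radius %.3g",
        length(elig), k, radius))
    list(ids = sort(sample(elig, k)), center = center, radius = radius)
  })
}

#' Shared dimensionality as a function of sampling radius
#'
#' For each disc radius and repeat: sample 50 responsive neurons, bin their
#' spikes in 50-ms bins, select the factor count by cross-validated likelihood,
#' fit the factor model and record the participation-ratio dimensionality of
#' its shared covariance.
#'
#' @param raster A `spike_raster` for one layer.
#' @param positions Positions of the layer's neurons (E lattice, typically).
#' @param radii Disc radii to sweep.
#' @param n_repeats Random disc centers per radius.
#' @param window Analysis window (seconds).
#' @param bin Bin width (seconds).
#' @param k Neurons per disc.
#' @param threshold Rate filter (Hz).
#' @param q_grid,folds Passed to [select_q()].
#' @param seed Master seed.
#' @return data.frame with one row per (radius, repeat): `radius`, `rep`,
#'   `q_star`, `d_shared`.
#' @export
dimensionality_vs_radius <- function(raster, positions, radii,
                                     n_repeats = 10L,
                                     window = c(1, raster$duration),
                                     bin = 0.05, k = 50L, threshold = 2,
                                     q_grid = 1:15, folds = 5L, seed = 1L) {
  rates <- mean_rates(raster, window)$rates[seq_len(nrow(positions))]
  out <- list()
  for (r in radii) {
    for (rep_i in seq_len(n_repeats)) {
      disc <- sample_disc(positions, rates, r, k, threshold,
                          seed_stream(seed, paste0("disc", r), rep_i))
      counts <- bin_counts(raster, bin, window, neurons = disc$ids)
      counts <- counts[, drop_fold_constant(counts, folds), drop = FALSE]
      sq <- select_q(counts, q_grid, folds,
                     seed_stream(seed, "q_sel", rep_i))
      m <- suppressWarnings(
        fit_fa(counts, sq$q_star, seed = seed_stream(seed, "fa_fit", rep_i)))
      out[[length(out) + 1L]] <-
        data.frame(radius = r, rep = rep_i, q_star = sq$q_star,
                   d_shared = m$d_shared)
    }
  }
  do.call(rbind, out)
}
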
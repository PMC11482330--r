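#' Reduced-rank regression communication model
#'
#' Predicts receiver population activity from sender activity through a
#' rank-constrained linear map: `R_hat = S B_RRR` with
#' `B_RRR = B_OLS Gamma_m Gamma_m'`, where `B_OLS = (S'S)^{-1} S'R` is the
#' ordinary least-squares map and the columns of `Gamma_m` are the top `m`
#' eigenvectors of `(S B_OLS)'(S B_OLS)`. This is the optimal rank-`m`
#' least-squares solution; at `m = K` it equals `B_OLS`. Columns of `S` and
#' `R` are mean-centered before regression (consistent with the demeaned total
#' sum of squares of the performance measure); no variance normalization is
#' applied.
#'
#' @param s,r T-by-K count matrices (sender, receiver), matched time bins.
#' @param m Rank constraint, `0 <= m <= K`.
#' @param ridge Optional ridge regularization: `lambda = ridge * trace(S'S)/K`
#'   is added to the diagonal of `S'S` (default 0 = off; a singular `S'S`
#'   raises an error advising it).
#' @return An object of class `rrr_model` with `B_ols`, `B_rrr`, `Gamma_m`,
#'   `predictive_dims` (columns of `B_OLS Gamma_m`), `m`, and the column
#'   centers `s_center`, `r_center`.
#' @export
fit_rrr <- function(s, r, m, ridge = 0) {
  s <- as.matrix(s); r <- as.matrix(r)
  if (nrow(s) != nrow(r)) stop("mismatched number of time bins")
  k <- ncol(r)
  if (m < 0 || m > ncol(s)) stop("`m` must be in 0..K")
  s_center <- colMeans(s); r_center <- colMeans(r)
  sc <- sweep(s, 2, s_center); rc <- sweep(r, 2, r_center)
  g <- crossprod(sc)
  if (ridge > 0) g <- g + diag(ridge * sum(diag(g)) / ncol(g), ncol(g))
  b_ols <- tryCatch(solve(g, crossprod(sc, rc)),
                    error = function(e)
                      stop("S'S is singular; consider the `ridge` option ",
                           "(original error: ", conditionMessage(e), ")"))
  fitted <- sc %*% b_ols
  eg <- eigen(crossprod(fitted), symmetric = TRUE)
  gamma_m <- eg$vectors[, seq_len(m), drop = FALSE]
  b_rrr <- if (m == 0) matrix(0, ncol(s), k)
           else b_ols %*% tcrossprod(gamma_m)
  structure(list(B_ols = b_ols, B_rrr = b_rrr, Gamma_m = gamma_m,
                 predictive_dims = b_ols %*% gamma_m, m = m,
                 s_center = s_center, r_center = r_center,
                 eigenvalues = eg$values),
            class = "rrr_model")
}

#' Predict receiver activity from sender activity
#'
#' @param object An `rrr_model`.
#' @param s New sender activity (T-by-K).
#' @param ... Unused.
#' @return Predicted receiver matrix (the training receiver column means are
#'   added back).
#' @export
predict.rrr_model <- function(object, s, ...) {
  sc <- sweep(as.matrix(s), 2, object$s_center)
  sweep(sc %*% object$B_rrr, 2, object$r_center, `+`)
}

#' Prediction performance (R squared)
#'
#' `1 - RSS/TSS` with the total sum of squares demeaned per column of the
#' observed activity, pooled over all neurons and time bins. Columns with zero
#' total variance are excluded with a warning. The returned value is floored
#' at 0 (held-out predictions can otherwise be arbitrarily poor); multiply by
#' 100 for the percent scale used in reported results.
#'
#' @param r Observed receiver activity (T-by-K).
#' @param r_hat Predicted activity, same shape.
#' @return R squared in `[0, 1]`.
#' @export
prediction_performance <- function(r, r_hat) {
  r <- as.matrix(r); r_hat <- as.matrix(r_hat)
  if (!identical(dim(r), dim(r_hat))) stop("mismatched shapes")
  tss_col <- colSums(sweep(r, 2, colMeans(r))^2)
  keep <- tss_col > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance column(s) excluded from R^2")
    r <- r[, keep, drop = FALSE]; r_hat <- r_hat[, keep, drop = FALSE]
    tss_col <- tss_col[keep]
  }
  rss <- sum((r - r_hat)^2)
  max(0, 1 - rss / sum(tss_col))
}

#' Cross-validated optimal rank of the communication subspace
#'
#' Evaluates held-out prediction performance for every rank `m` in `0..K` over
#' contiguous time-block folds, and selects the optimal rank `m*` as the
#' smallest `m` whose mean performance is within one standard error of the
#' mean (SEM) of the peak performance. The reported performance is the mean
#' cross-validated performance at `m*`, in percent.
#'
#' @param s,r T-by-K count matrices.
#' @param folds Number of contiguous cross-validation folds (default 20).
#' @param ridge Passed to [fit_rrr()].
#' @return List with `m_star`, `performance` (percent, at `m*`), and `curve`
#'   (data.frame `m`, `mean_perf`, `sem_perf`, percent scale).
#' @export
optimal_rank <- function(s, r, folds = 20L, ridge = 0) {
  s <- as.matrix(s); r <- as.matrix(r)
  t_ <- nrow(s)
  if (t_ < 2 * folds) stop("too few time bins for ", folds, " folds")
  k <- ncol(s)
  ranks <- 0:k
  fold_id <- cut(seq_len(t_), folds, labels = FALSE)
  perf <- matrix(NA_real_, length(ranks), folds)
  for (f in seq_len(folds)) {
    tr_s <- s[fold_id != f, , drop = FALSE]
    tr_r <- r[fold_id != f, , drop = FALSE]
    te_s <- s[fold_id == f, , drop = FALSE]
    te_r <- r[fold_id == f, , drop = FALSE]
    full <- fit_rrr(tr_s, tr_r, k, ridge = ridge)
    sc <- sweep(te_s, 2, full$s_center)
    fitted_dirs <- sc %*% full$B_ols          # T_test x K, full-rank fit
    g <- full$Gamma_m                          # all K eigenvectors
    proj <- fitted_dirs %*% g                  # coordinates per eigenvector
    for (mi in seq_along(ranks)) {
      m <- ranks[mi]
      pred <- if (m == 0) matrix(0, nrow(te_s), k)
              else tcrossprod(proj[, seq_len(m), drop = FALSE],
                              g[, seq_len(m), drop = FALSE])
      r_hat <- sweep(pred, 2, full$r_center, `+`)
      perf[mi, f] <- suppressWarnings(prediction_performance(te_r, r_hat))
    }
  }
  mean_perf <- rowMeans(perf)
  sem_perf <- apply(perf, 1, sd) / sqrt(folds)
  peak <- which.max(mean_perf)
  ok <- mean_perf >= mean_perf[peak] - sem_perf[peak]
  m_star <- ranks[which(ok)[1]]
  list(m_star = m_star,
       performance = 100 * mean_perf[ranks == m_star],
       curve = data.frame(m = ranks, mean_perf = 100 * mean_perf,
                          sem_perf = 100 * sem_perf))
}

#' Communication analysis for one sender/receiver pair of discs
#'
#' Samples 50 responsive neurons from exactly overlapping discs (same center)
#' in the sender and receiver layers, computes each side's shared
#' dimensionality (cross-validated factor count, participation ratio) and the
#' cross-validated communication-subspace performance and optimal rank.
#'
#' @param raster_s,raster_r Sender / receiver `spike_raster`s.
#' @param positions Positions of the layers' E lattice (identical geometry in
#'   both layers).
#' @param radius Disc radius (default 0.2).
#' @param window,bin Analysis window and bin width (seconds).
#' @param k Neurons per disc.
#' @param threshold Rate filter (Hz).
#' @param q_grid,fa_folds Factor-count selection grid and folds.
#' @param cv_folds Folds for the rank cross-validation.
#' @param seed Master seed.
#' @return One-row data.frame: `d_shared_s`, `d_shared_r`, `performance`
#'   (percent), `m_star`.
#' @export
comm_analysis <- function(raster_s, raster_r, positions, radius = 0.2,
                          window = c(1, raster_s$duration), bin = 0.05,
                          k = 50L, threshold = 2, q_grid = 1:15,
                          fa_folds = 5L, cv_folds = 20L, seed = 1L) {
  center <- withr_seed(seed_stream(seed, "center"), runif(2))
  rates_s <- mean_rates(raster_s, window)$rates[seq_len(nrow(positions))]
  rates_r <- mean_rates(raster_r, window)$rates[seq_len(nrow(positions))]
  disc_s <- sample_disc(positions, rates_s, radius, k, threshold,
                        seed_stream(seed, "disc_s"), center = center)
  disc_r <- sample_disc(positions, rates_r, radius, k, threshold,
                        seed_stream(seed, "disc_r"), center = center)
  cs <- bin_counts(raster_s, bin, window, neurons = disc_s$ids)
  cr <- bin_counts(raster_r, bin, window, neurons = disc_r$ids)
  # guard against neurons whose counts are constant within a CV fold
  folds_chk <- max(fa_folds, cv_folds)
  cs <- cs[, drop_fold_constant(cs, folds_chk), drop = FALSE]
  cr <- cr[, drop_fold_constant(cr, folds_chk), drop = FALSE]

  d_of <- function(counts, tag) {
    sq <- select_q(counts, q_grid, fa_folds, seed_stream(seed, tag))
    m <- suppressWarnings(
      fit_fa(counts, sq$q_star, seed = seed_stream(seed, paste0(tag, "_fit"))))
    m$d_shared
  }
  d_s <- d_of(cs, "fa_s")
  d_r <- d_of(cr, "fa_r")
  comm <- optimal_rank(cs, cr, folds = cv_folds)
  data.frame(d_shared_s = d_s, d_shared_r = d_r,
             performance = comm$performance, m_star = comm$m_star)
}

#' Communication sweep across destabilization scenarios
#'
#' Simulates each scenario's three-layer network and joins the within-area
#' shared dimensionalities with the communication-subspace performance,
#' producing the scenario summary table (including the
#' `D_shared(S) - D_shared(R)` difference against which performance is
#' compared).
#'
#' @param scenarios Character vector of scenario names (see
#'   [scenario_params()]).
#' @param scale Network scale factor.
#' @param duration Trial length in seconds.
#' @param seed Master seed.
#' @param radius Disc radius.
#' @param ... Passed to [comm_analysis()].
#' @return data.frame with one row per scenario: scenario, rates, `d_shared_s`,
#'   `d_shared_r`, `d_diff`, `performance`, `m_star`.
#' @export
communication_sweep <- function(scenarios, scale, duration, seed,
                                radius = 0.2, ...) {
  out <- lapply(scenarios, function(sc) {
    net <- run_three_layer(scenario_params(sc, scale),
                           seed_stream(seed, sc), duration = duration)
    win <- c(net$cfg$simulation$burn_in, duration)
    res <- comm_analysis(net$sender, net$receiver, net$e_layer$positions,
                         radius = radius, window = win,
                         seed = seed_stream(seed, paste0(sc, "_comm")), ...)
    cbind(data.frame(scenario = sc,
                     rate_s = mean_rates(net$sender, win)$mean,
                     rate_r = mean_rates(net$receiver, win)$mean),
          res)
  })
  out <- do.call(rbind, out)
  out$d_diff <- out$d_shared_s - out$d_shared_r
  out
}
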
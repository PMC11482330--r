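test_that("reduced-rank regression equals brute-force rank-constrained LS", {
  withr::with_seed(14, {
    for (rep_i in 1:5) {
      t_ <- 200; k <- 8
      s <- matrix(rnorm(t_ * k), t_, k)
      b_true <- matrix(rnorm(k * k), k, k)
      r <- s %*% b_true + matrix(rnorm(t_ * k, sd = 0.5), t_, k)
      for (m in c(1, 3, k)) {
        fit <- fit_rrr(s, r, m)
        # compare fitted values against the Eckart-Young oracle
        sc <- sweep(s, 2, colMeans(s))
        expect_lt(max(abs(sc %*% fit$B_rrr - brute_force_rrr_fit(s, r, m))),
                  1e-8)
      }
      # full rank recovers OLS exactly
      fit_full <- fit_rrr(s, r, k)
      expect_lt(max(abs(fit_full$B_rrr - fit_full$B_ols)), 1e-10)
    }
  })
})

test_that("noiseless low-rank maps are recovered exactly", {
  withr::with_seed(15, {
    s <- matrix(rnorm(300 * 10), 300, 10)
    b1 <- outer(rnorm(10), rnorm(10)) # rank 1
    r <- s %*% b1
    fit <- fit_rrr(s, r, 1)
    expect_lt(max(abs(predict(fit, s) - r)), 1e-8)
    expect_equal(prediction_performance(r, predict(fit, s)), 1)
    # Gamma_m columns are orthonormal
    g <- fit_rrr(s, r + rnorm(3000, sd = 0.1), 4)$Gamma_m
    expect_equal(crossprod(g), diag(4), tolerance = 1e-10)
  })
})

test_that("prediction performance implements the pooled demeaned R^2", {
  r <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2)
  r_hat <- matrix(c(1.1, 2.2, 2.7, 2.2, 3.9, 5.6), 3, 2)
  rss <- sum((r - r_hat)^2)
  tss <- sum(sweep(r, 2, colMeans(r))^2)
  expect_equal(prediction_performance(r, r_hat), 1 - rss / tss)
  expect_equal(prediction_performance(r, r), 1)
  # predicting the column means gives exactly 0
  means <- matrix(colMeans(r), 3, 2, byrow = TRUE)
  expect_equal(prediction_performance(r, means), 0)
  # worse than the mean is floored at 0; zero-variance columns are dropped
  expect_equal(prediction_performance(r, -r), 0)
  r0 <- cbind(r, 5)
  expect_warning(p0 <- prediction_performance(r0, cbind(r_hat, 5)),
                 "zero-variance")
  expect_equal(p0, 1 - rss / tss)
  expect_error(prediction_performance(r, r_hat[, 1, drop = FALSE]), "shapes")
})

test_that("cross-validated optimal rank finds the true rank and nulls", {
  withr::with_seed(16, {
    t_ <- 400; k <- 12
    s <- matrix(rnorm(t_ * k), t_, k)
    b3 <- matrix(rnorm(k * 3), k, 3) %*% matrix(rnorm(3 * k), 3, k) # rank 3
    r <- s %*% b3
    res <- optimal_rank(s, r, folds = 10)
    expect_equal(res$m_star, 3L)
    expect_gt(res$performance, 99)
    # training-set performance is nondecreasing in m
    fitall <- lapply(0:k, function(m) {
      f <- fit_rrr(s, r, m); prediction_performance(r, predict(f, s))
    })
    expect_true(all(diff(unlist(fitall)) >= -1e-10))
    # independent sender and receiver: performance ~ 0, minimal rank
    r_null <- matrix(rnorm(t_ * k), t_, k)
    res0 <- optimal_rank(s, r_null, folds = 10)
    expect_lt(res0$performance, 5)
    expect_lte(res0$m_star, 1L)
    # the CV curve at m = K equals the cross-validated OLS performance
    expect_equal(res$curve$mean_perf[res$curve$m == k],
                 res$curve$mean_perf[nrow(res$curve)])
  })
})

test_that("time-bin permutation destroys communication but not dimensionality", {
  withr::with_seed(17, {
    t_ <- 500; k <- 20
    z <- matrix(rnorm(t_ * 2), t_, 2) # two shared latents
    ls <- matrix(rnorm(k * 2), k, 2); lr <- matrix(rnorm(k * 2), k, 2)
    s <- z %*% t(ls) + matrix(rnorm(t_ * k, sd = .5), t_, k)
    r <- z %*% t(lr) + matrix(rnorm(t_ * k, sd = .5), t_, k)
    perf <- optimal_rank(s, r, folds = 10)$performance
    expect_gt(perf, 20)
    perm <- sample(t_)
    perf_perm <- optimal_rank(s, r[perm, ], folds = 10)$performance
    expect_lt(perf_perm, 5)
    # within-area shared dimensionality is untouched by the permutation
    f1 <- suppressWarnings(fit_fa(r, 2, seed = 1))
    f2 <- suppressWarnings(fit_fa(r[perm, ], 2, seed = 1))
    expect_equal(f1$d_shared, f2$d_shared, tolerance = 1e-6)
  })
})

test_that("communication sweep joins simulation, dimensionality and RRR", {
  sw <- communication_sweep("standard", scale = 0.05, duration = 5,
                            seed = 99, radius = 0.4, q_grid = 1:3,
                            fa_folds = 3, cv_folds = 10)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$scenario, "standard")
  expect_gt(sw$rate_s, 2)
  expect_true(sw$m_star >= 0 && sw$m_star <= 50)
  expect_true(sw$performance >= 0 && sw$performance <= 100)
  expect_equal(sw$d_diff, sw$d_shared_s - sw$d_shared_r)
})
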
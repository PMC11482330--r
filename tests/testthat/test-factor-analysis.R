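test_that("participation ratio identities", {
  expect_equal(participation_ratio(rep(3.7, 12)), 12)
  expect_equal(participation_ratio(c(1, 0, 0, 0)), 1)
  expect_equal(participation_ratio(c(4, 1)), 25 / 17)
  # invariant to uniform rescaling; bounded by the number of nonzero values
  l <- c(5, 3, 2, 0.5, 0)
  expect_equal(participation_ratio(l), participation_ratio(10 * l))
  expect_lt(participation_ratio(l), sum(l > 0))
  expect_error(participation_ratio(c(0, 0)), "all-zero")
  expect_error(participation_ratio(c(-1, 2)), "nonnegative")
})

test_that("EM factor analysis recovers a known model", {
  dat <- make_fa_data(t_ = 5000, k = 30, q = 3, seed = 21)
  fit <- fit_fa(dat$x, q = 3, seed = 1)
  expect_true(fit$converged)
  # training log-likelihood is nondecreasing at every iteration
  expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[1])))
  # subspace of the loading matrix recovered within 5 degrees
  expect_lt(principal_angle(fit$L, dat$L), 5)
  # private variances within 10 percent (median relative error)
  expect_lt(median(abs(fit$psi - dat$psi) / dat$psi), 0.10)
  # total model covariance matches the sample covariance in trace at a
  # tight convergence tolerance (the MLE stationarity condition)
  fit_tight <- fit_fa(dat$x, q = 3, seed = 1, tol = 1e-10, max_iter = 5000)
  s <- cov(dat$x) * (nrow(dat$x) - 1) / nrow(dat$x)
  model_cov <- fit_tight$c_shared + diag(fit_tight$psi)
  expect_lt(abs(sum(diag(model_cov)) - sum(diag(s))) / sum(diag(s)), 0.01)
  # eigenvalues of LL' equal squared singular values of L
  ev <- eigen(fit$c_shared, symmetric = TRUE)$values[1:3]
  expect_equal(ev, fit$lambdas, tolerance = 1e-8)
})

test_that("q = 0 reduces to a diagonal model and zero-variance columns error", {
  dat <- make_fa_data(400, 8, 2, seed = 3)
  fit0 <- fit_fa(dat$x, q = 0)
  expect_equal(fit0$c_shared, matrix(0, 8, 8))
  expect_true(is.na(fit0$d_shared))
  x_bad <- cbind(dat$x, 0)
  expect_error(fit_fa(x_bad, 1), "zero-variance")
  expect_error(fit_fa(dat$x, q = 8), "q")
})

test_that("cross-validated factor count finds the true rank", {
  hits <- 0L
  for (s in 1:10) {
    dat <- make_fa_data(t_ = 800, k = 12, q = 2, seed = 100 + s, noise = 0.5)
    sq <- select_q(dat$x, q_grid = 0:5, folds = 4, seed = s)
    # held-out likelihood at q* is maximal over the grid by construction
    expect_equal(max(sq$table$heldout_loglik),
                 sq$table$heldout_loglik[sq$table$q == sq$q_star])
    if (sq$q_star == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # pure diagonal Gaussian data: no shared structure, smallest q wins
  x <- withr::with_seed(5, matrix(rnorm(600 * 10), 600, 10))
  expect_lte(select_q(x, q_grid = 0:4, folds = 4, seed = 1)$q_star, 1L)
})

test_that("disc sampling respects radius, rate filter and reproducibility", {
  gl <- grid_layer(40^2, "E")
  rates <- withr::with_seed(6, runif(1600, 0, 12))
  d1 <- sample_disc(gl$positions, rates, radius = 0.15, k = 50, seed = 4)
  expect_length(d1$ids, 50)
  expect_false(any(duplicated(d1$ids)))
  # every sampled neuron verified in-disc by the brute-force shift oracle
  for (i in d1$ids)
    expect_lte(shift_distance(gl$positions[i, ], d1$center), 0.15)
  expect_true(all(rates[d1$ids] > 2))
  # radius 0.5 spans the whole periodic domain: every responsive neuron is
  # eligible regardless of the center
  d2 <- sample_disc(gl$positions, rates, radius = 0.5, k = sum(rates > 2),
                    seed = 4)
  expect_length(d2$ids, sum(rates > 2))
  # a threshold above all rates must fail loudly, naming the radius
  expect_error(sample_disc(gl$positions, rates, 0.2, threshold = 20),
               "radius")
  expect_identical(sample_disc(gl$positions, rates, 0.2, seed = 9)$ids,
                   sample_disc(gl$positions, rates, 0.2, seed = 9)$ids)
  # too-small discs fail: the radius cannot hold 50 eligible neurons
  expect_error(sample_disc(gl$positions, rates, 0.05, seed = 1), "0.05")
})

test_that("dimensionality pipeline returns sane values on synthetic counts", {
  # factor data standing in for binned counts of a 60-neuron patch
  dat <- make_fa_data(t_ = 600, k = 60, q = 4, seed = 33, noise = 0.6)
  x <- round(pmax(dat$x, 0))
  sq <- select_q(x, q_grid = c(1, 2, 4, 6), folds = 4, seed = 2)
  fit <- suppressWarnings(fit_fa(x, sq$q_star, seed = 2))
  expect_gte(fit$d_shared, 1)
  expect_lte(fit$d_shared, sq$q_star)
})

test_that("dimensionality-vs-radius sweep has the expected structure", {
  gl <- grid_layer(900, "E")
  ras <- generate_poisson_layer(900, 10, 30, seed = 44)
  dv <- dimensionality_vs_radius(ras, gl$positions, radii = c(0.2, 0.5),
                                 n_repeats = 2, window = c(0, 30),
                                 q_grid = 1:2, folds = 3, seed = 5)
  expect_equal(nrow(dv), 4L)
  expect_true(all(dv$q_star %in% 1:2))
  # independent Poisson neurons carry no shared structure: the fitted shared
  # covariance is near-degenerate and its participation ratio stays small
  expect_true(all(dv$d_shared >= 1 - 1e-9 & dv$d_shared <= 10))
})
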
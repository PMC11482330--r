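test_that("wrapped Gaussian is periodic, normalized, and truncation-exact", {
  u <- seq(-0.5, 0.5, by = 0.01)
  for (sigma in c(0.05, 0.1, 0.3)) {
    expect_equal(wrapped_gaussian(u, sigma), wrapped_gaussian(u + 1, sigma))
    # integrates to 1 over one period
    int <- integrate(function(x) wrapped_gaussian(x, sigma), 0, 1,
                     rel.tol = 1e-9)$value
    expect_lt(abs(int - 1), 1e-6)
    # k_max = 5 equals a high-order truncation to machine precision
    expect_equal(wrapped_gaussian(u, sigma, k_max = 5),
                 wrapped_gaussian(u, sigma, k_max = 50), tolerance = 1e-12)
  }
  expect_error(wrapped_gaussian(0.1, -0.2), "positive")
})

test_that("periodic distance matches the 9-shift brute-force oracle", {
  expect_equal(periodic_distance(c(0.1, 0.1), c(0.9, 0.9)),
               sqrt(0.2^2 + 0.2^2))
  expect_equal(periodic_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- runif(2); y <- runif(2)
      expect_equal(periodic_distance(x, y), shift_distance(x, y),
                   tolerance = 1e-12)
    }
  })
  # vectorized form and the max possible value
  x <- matrix(runif(40), 20); y <- matrix(runif(40), 20)
  expect_true(all(periodic_distance(x, y) <= sqrt(2) / 2 + 1e-12))
})

test_that("connection probability follows the wrapped-Gaussian product", {
  # direct evaluation of the formula by an independent expression
  x <- c(0.15, 0.4); y <- c(0.8, 0.05); sigma <- 0.1; p_bar <- 0.04
  g1 <- sum(exp(-(x[1] - y[1] + (-5:5))^2 / (2 * sigma^2))) /
    (sigma * sqrt(2 * pi))
  g2 <- sum(exp(-(x[2] - y[2] + (-5:5))^2 / (2 * sigma^2))) /
    (sigma * sqrt(2 * pi))
  expect_equal(connection_probability(x, y, sigma, p_bar),
               min(1, p_bar * g1 * g2), tolerance = 1e-12)
  # flat-kernel limit: a very broad kernel gives p ~ p_bar everywhere
  expect_equal(connection_probability(x, y, sigma = 10, p_bar = 0.05), 0.05,
               tolerance = 1e-6)
  # averaging the pair probability over the whole postsynaptic lattice
  # recovers the mean connection probability
  post <- grid_layer(40^2, "E")
  p <- connection_probability(post$positions,
                              matrix(c(0.31, 0.62), 40^2, 2, byrow = TRUE),
                              sigma = 0.1, p_bar = 0.01)
  expect_lt(abs(mean(p) - 0.01), 1e-3)
})

test_that("grid layers are cell-centered lattices on [0,1)^2", {
  gl <- grid_layer(16, "E")
  expect_equal(gl$side, 4L)
  expect_equal(gl$positions[1, ], c(x1 = 0.125, x2 = 0.125))
  expect_equal(gl$positions[16, ], c(x1 = 0.875, x2 = 0.875))
  expect_true(all(gl$positions >= 0 & gl$positions < 1))
  expect_error(grid_layer(17), "perfect square")
})

test_that("bernoulli sampling matches binomial edge statistics", {
  pre <- grid_layer(30^2, "E"); post <- grid_layer(30^2, "E")
  p_bar <- 0.03
  syn <- sample_synapses(pre, post, sigma = 0.15, p_bar, seed = 5,
                         scheme = "bernoulli")
  n_pairs <- as.double(pre$n) * post$n - pre$n # self-edges excluded
  se <- sqrt(n_pairs * p_bar * (1 - p_bar))
  expect_lt(abs(length(syn$idx) - p_bar * n_pairs), 3 * se)
  # no self-edges, no duplicates
  df <- as.data.frame(syn)
  expect_false(any(df$pre == df$post))
  expect_false(any(duplicated(df)))
  # out-degrees are binomial(n_post - 1, p_bar): chi-square goodness of fit
  deg <- diff(syn$ptr)
  expect_lt(abs(mean(deg) - p_bar * (post$n - 1)), 3 * sd(deg) / sqrt(pre$n))
  edges <- qbinom(seq(0, 1, length.out = 7), post$n - 1L, p_bar)
  edges <- unique(c(-1L, edges[-c(1, 7)], post$n))
  obs <- table(cut(deg, edges))
  pr <- diff(pbinom(edges, post$n - 1L, p_bar))
  ct <- suppressWarnings(chisq.test(obs, p = pr / sum(pr)))
  expect_gt(ct$p.value, 0.01)
  # p_bar = 0 gives an empty matrix
  empty <- sample_synapses(pre, post, 0.1, 0, seed = 1, scheme = "bernoulli")
  expect_length(empty$idx, 0)
})

test_that("out-degree sampling has exact out-degrees and Gaussian profile", {
  pre <- grid_layer(20^2, "input"); post <- grid_layer(40^2, "E")
  p_bar <- 0.05
  syn <- sample_synapses(pre, post, sigma = 0.1, p_bar, seed = 7)
  k_out <- round(p_bar * post$n)
  expect_true(all(diff(syn$ptr) == k_out))
  # connection frequency vs distance follows the wrapped-Gaussian shape:
  # monotone decreasing over the first bins, near zero far away
  prof <- connection_vs_distance(syn, pre, post, n_bins = 10)
  expect_gt(prof$p_hat[1], prof$p_hat[3])
  expect_gt(prof$p_hat[2], prof$p_hat[5])
  expect_lt(prof$p_hat[8], prof$p_hat[1] / 20)
  # profile tracks the normalized kernel product: compare shape at bin centers
  g2 <- wrapped_gaussian(prof$distance, 0.1)^2 # isotropic radial proxy
  expect_gt(cor(prof$p_hat, g2 * exp(-(prof$distance)^2 * 0)), 0.95)
})

test_that("reproducibility and independence of projection seed streams", {
  pre <- grid_layer(15^2, "E"); post <- grid_layer(15^2, "E")
  a <- sample_synapses(pre, post, 0.1, 0.05, seed = 42)
  b <- sample_synapses(pre, post, 0.1, 0.05, seed = 42)
  expect_identical(a$idx, b$idx)
  # broadening the I kernel in one projection leaves another projection's
  # wiring untouched under its own seed stream
  i_layer <- grid_layer(8^2, "I")
  ee1 <- sample_synapses(pre, post, 0.1, 0.05, seed_stream(1, "EE"))
  ei_narrow <- sample_synapses(i_layer, post, 0.1, 0.04, seed_stream(1, "EI"))
  ei_broad <- sample_synapses(i_layer, post, 0.3, 0.04, seed_stream(1, "EI"))
  ee2 <- sample_synapses(pre, post, 0.1, 0.05, seed_stream(1, "EE"))
  expect_identical(ee1$idx, ee2$idx)
  expect_false(identical(ei_narrow$idx, ei_broad$idx))
})

test_that("sublattice ids form a regular subset", {
  ids <- sublattice_ids(63, 16)
  expect_length(ids, 256)
  expect_length(unique(ids), 256)
  gl <- grid_layer(63^2, "E")
  sub <- layer_subset(gl, ids)
  # spread over the full domain
  expect_lt(max(sub$positions[, 1]) - 1, 0)
  expect_gt(min(diff(sort(unique(sub$positions[, 1])))), 0.02)
})
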
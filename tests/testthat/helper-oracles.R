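# Independent oracles and shared fixtures for the test suite.

# Brute-force periodic distance: minimum Euclidean distance over the 9
# shifted copies of y on the torus.
shift_distance <- function(x, y) {
  shifts <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
  min(apply(shifts, 1, function(s) sqrt(sum((x - (y + s))^2))))
}

# Direct convolution of a spike train with the difference-of-exponentials
# kernel, sampled on the integration grid with the same alignment as the
# event-driven integrator (a spike at step s contributes eta(k*dt) at step
# s + k).
convolve_kernel <- function(spike_steps, weight, n_steps, dt, tau_r, tau_d) {
  out <- numeric(n_steps)
  tt <- seq_len(n_steps) - 1L
  for (s in spike_steps) {
    lag <- (tt - s) * dt
    eta <- ifelse(lag >= 0, (exp(-lag / tau_d) - exp(-lag / tau_r)) /
                    (tau_d - tau_r), 0)
    out <- out + weight * eta
  }
  out
}

# Eckart-Young oracle: the best rank-m approximation (in Frobenius norm) of
# the OLS fit, mapped back to a coefficient matrix via the pseudoinverse.
# Independent route to the reduced-rank regression solution.
brute_force_rrr_fit <- function(s, r, m) {
  sc <- sweep(s, 2, colMeans(s))
  rc <- sweep(r, 2, colMeans(r))
  fit <- sc %*% solve(crossprod(sc), crossprod(sc, rc))
  sv <- svd(fit)
  keep <- seq_len(m)
  sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], m) %*%
    t(sv$v[, keep, drop = FALSE])
}

# Draw T samples from a known factor model x ~ N(mu, LL' + Psi).
make_fa_data <- function(t_, k, q, seed, noise = 0.3) {
  withr::with_seed(seed, {
    l <- matrix(rnorm(k * q), k, q)
    psi <- runif(k, noise / 2, noise)
    mu <- rnorm(k, 5, 1)
    z <- matrix(rnorm(t_ * q), t_, q)
    eps <- matrix(rnorm(t_ * k), t_, k) %*% diag(sqrt(psi), k)
    list(x = sweep(z %*% t(l) + eps, 2, mu, `+`), L = l, psi = psi, mu = mu)
  })
}

# Largest principal angle (degrees) between the column spans of two matrices.
principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}

# Cached scaled-network simulations shared across tests: one three-layer run
# per scenario under fixed study conditions (scale 0.2, 15-s trials).
.sim_cache <- new.env(parent = emptyenv())

scenario_bundle <- function(scenario, scale = 0.2, duration = 15,
                            seed = 20240101) {
  key <- paste(scenario, scale, duration, seed, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  net <- run_three_layer(scenario_params(scenario, scale), seed,
                         duration = duration)
  win <- c(net$cfg$simulation$burn_in, duration)
  e_ids <- seq_len(net$sizes$n_e)
  bundle <- list(
    net = net, win = win, e_ids = e_ids,
    rate_s = mean(mean_rates(net$sender, win)$rates[e_ids]),
    rate_r = mean(mean_rates(net$receiver, win)$rates[e_ids]))
  .sim_cache[[key]] <- bundle
  bundle
}

bundle_between_mu <- function(b, max_pairs = 2e5) {
  cs <- bin_counts(b$net$sender, 0.05, b$win, neurons = b$e_ids)
  cr <- bin_counts(b$net$receiver, 0.05, b$win, neurons = b$e_ids)
  between_area_correlations(cs, cr, max_pairs = max_pairs, seed = 99)$mu
}

# A small uncoupled-layer helper: one neuron driven by a constant current.
isolated_neuron <- function(i_ext, duration = 2, dt = 0.05, v0 = -60,
                            nrn = standard_params()$neuron,
                            syn = standard_params()$synapse) {
  simulate_layer(1L, 0L, NULL, list(), nrn, syn, dt, duration, v0,
                 i_ext = i_ext, record = 1L)
}
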
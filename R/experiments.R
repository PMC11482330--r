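#' Superposition linearity test
#'
#' Tests whether the mapping from input to output spiking is linear in a
#' destabilized E/I layer. Per trial, three simulations are run with
#' independent Poisson input realizations: `I1` (7 Hz in the upper half of the
#' input grid, `x2 >= 0.5`; 3 Hz in the lower half), `I2` (rates swapped), and
#' `I_homo` (uniform 10 Hz, the sum of the two intensities). With output-rate
#' vectors `nu_1`, `nu_2`, `nu_homo` estimated after discarding the first
#' second, linearity predicts `nu_1 + nu_2 = nu_homo`; the per-trial statistic
#' is the mean over excitatory output neurons of
#' `|nu_sum,j - nu_homo,j|`.
#'
#' @param type `"spatial"` (output layer with `sigma_i = 0.3`) or `"temporal"`
#'   (`tau_i_decay = 24` ms).
#' @param scale Network scale factor.
#' @param n_trials Number of trials (30 in the full-scale protocol).
#' @param duration Trial length in seconds (20).
#' @param burn_in Seconds discarded at the start of each run (1).
#' @param seed Master seed. Wiring is fixed across trials; input realizations
#'   and initial voltages are redrawn per run.
#' @param rates Named vector `c(hi, lo, homo)` of input intensities in Hz.
#' @return List with `mu` and `sd` of the per-trial mean absolute rate
#'   difference (Hz), `per_trial` (vector), and the last trial's `nu_1`,
#'   `nu_2`, `nu_homo`, `abs_diff` vectors.
#' @export
linearity_test <- function(type = c("spatial", "temporal"), scale = 1,
                           n_trials = 30L, duration = 20, burn_in = 1,
                           seed = 1L, rates = c(hi = 7, lo = 3, homo = 10)) {
  type <- match.arg(type)
  cfg <- standard_params(scale)
  if (type == "spatial") cfg$sender$sigma_i <- 0.3
  else cfg$sender$tau_i_decay <- 24

  sz <- layer_sizes(cfg)
  input_layer <- grid_layer(sz$n_input, "input")
  e_layer <- grid_layer(sz$n_e, "E")
  i_layer <- grid_layer(sz$n_i, "I")
  n <- sz$n_e + sz$n_i
  upper <- input_layer$positions[, 2] >= 0.5

  bst <- scale_boosts(cfg, sz)
  rec <- build_recurrent_wiring(e_layer, i_layer, cfg$connectivity,
                                cfg$sender$sigma_i, seed_stream(seed, "wiring"),
                                bst$e, bst$i)
  ffwd <- build_ffwd_wiring(input_layer, e_layer, i_layer, cfg$connectivity,
                            seed_stream(seed, "wiring_in"), bst$ffwd)
  syn <- cfg$synapse; syn$tau_i_decay <- cfg$sender$tau_i_decay
  wsc <- weight_divisor(cfg, sz)
  win <- c(burn_in, duration)

  run_one <- function(rate_vec, trial, tag) {
    inp <- generate_poisson_layer(
      sz$n_input, rate_vec, duration,
      seed_stream(seed, paste0("input_", tag), trial))
    v0 <- withr_seed(seed_stream(seed, paste0("init_", tag), trial),
                     runif(n, cfg$neuron$v_reset, cfg$neuron$v_t))
    out <- simulate_layer(sz$n_e, sz$n_i, rec,
                          list(list(wiring = ffwd, raster = inp)),
                          cfg$neuron, syn, cfg$simulation$dt, duration, v0,
                          layer = "output", w_scale = wsc)
    mean_rates(out, win)$rates[seq_len(sz$n_e)]
  }

  r1 <- ifelse(upper, rates[["hi"]], rates[["lo"]])
  r2 <- ifelse(upper, rates[["lo"]], rates[["hi"]])
  per_trial <- numeric(n_trials)
  nu_1 <- nu_2 <- nu_homo <- NULL
  for (tr in seq_len(n_trials)) {
    nu_1 <- run_one(r1, tr, "I1")
    nu_2 <- run_one(r2, tr, "I2")
    nu_homo <- run_one(rep(rates[["homo"]], sz$n_input), tr, "Ihomo")
    per_trial[tr] <- mean(abs(nu_1 + nu_2 - nu_homo))
  }
  list(mu = mean(per_trial), sd = sd(per_trial), per_trial = per_trial,
       nu_1 = nu_1, nu_2 = nu_2, nu_homo = nu_homo,
       abs_diff = abs(nu_1 + nu_2 - nu_homo), type = type)
}

#' Frozen-input macroscopic-chaos test
#'
#' Generates a single realization of input-layer activity, propagates it once
#' through a standard sender layer, then simulates the receiver twice with
#' identical wiring, input and inhibitory-cell initial voltages -- the only
#' difference between the two trials is the initial membrane voltage of the
#' excitatory receiver neurons. Trial-to-trial unreliability at spatial scale
#' `r` is summarized by the normalized time-averaged absolute difference of
#' disc-averaged population rates:
#' `Delta(r) = mean_t |nu1_r(t) - nu2_r(t)| / nubar_r`, on 50-ms bins, where
#' `nubar_r` is the grand-mean rate over both trials. All excitatory neurons
#' within the disc contribute (no rate filter); radius 0.5 covers the whole
#' grid.
#'
#' @param type Receiver regime: `"standard"`, `"spatial"` (`sigma_i = 0.3`) or
#'   `"temporal"` (`tau_i_decay = 24` ms).
#' @param scale Network scale factor.
#' @param radii Disc radii to evaluate.
#' @param duration Trial length in seconds.
#' @param seed Master seed (input, wiring, shared I-cell voltages).
#' @param n_discs Random disc centers per radius (averaged).
#' @param init_seeds Length-2 integer vector: the E-cell initial-voltage seeds
#'   of the two trials. Equal seeds make the trials identical.
#' @param bin Bin width in seconds.
#' @return List with `table` (data.frame `radius`, `delta`), `grid_delta`
#'   (whole-grid value), `grid_traces` (two whole-grid E-rate time series,
#'   Hz), and the two receiver rasters.
#' @export
chaos_test <- function(type = c("standard", "spatial", "temporal"),
                       scale = 1, radii = c(0.025, 0.05, 0.1, 0.2, 0.5),
                       duration = 20, seed = 1L, n_discs = 5L,
                       init_seeds = c(1L, 2L), bin = 0.05) {
  type <- match.arg(type)
  cfg <- standard_params(scale)
  if (type == "spatial") cfg$receiver$sigma_i <- 0.3
  if (type == "temporal") cfg$receiver$tau_i_decay <- 24

  sz <- layer_sizes(cfg)
  input_layer <- grid_layer(sz$n_input, "input")
  e_layer <- grid_layer(sz$n_e, "E")
  i_layer <- grid_layer(sz$n_i, "I")
  n <- sz$n_e + sz$n_i
  dt <- cfg$simulation$dt
  wsc <- weight_divisor(cfg, sz)
  bst <- scale_boosts(cfg, sz)

  input <- generate_poisson_layer(sz$n_input, cfg$simulation$input_rate,
                                  duration, seed_stream(seed, "input"))
  sender <- local({
    rec <- build_recurrent_wiring(e_layer, i_layer, cfg$connectivity,
                                  cfg$sender$sigma_i,
                                  seed_stream(seed, "wiring_S"), bst$e, bst$i)
    ffwd <- build_ffwd_wiring(input_layer, e_layer, i_layer, cfg$connectivity,
                              seed_stream(seed, "wiring_inS"), bst$ffwd)
    v0 <- withr_seed(seed_stream(seed, "init_S"),
                     runif(n, cfg$neuron$v_reset, cfg$neuron$v_t))
    simulate_layer(sz$n_e, sz$n_i, rec,
                   list(list(wiring = ffwd, raster = input)),
                   cfg$neuron, cfg$synapse, dt, duration, v0, layer = "sender",
                   w_scale = wsc)
  })

  rec_r <- build_recurrent_wiring(e_layer, i_layer, cfg$connectivity,
                                  cfg$receiver$sigma_i,
                                  seed_stream(seed, "wiring_R"), bst$e, bst$i)
  sub_side <- min(e_layer$side, input_layer$side)
  src_ids <- sublattice_ids(e_layer$side, sub_side)
  rule <- cfg$layers$scale_rule %||% "preserve_indegree"
  boost_sr <- if (rule == "sqrtN") 1 else cfg$layers$n_input / length(src_ids)
  ffwd_r <- build_ffwd_wiring(layer_subset(e_layer, src_ids), e_layer, i_layer,
                              cfg$connectivity, seed_stream(seed, "wiring_SR"),
                              boost_sr)
  syn_r <- cfg$synapse; syn_r$tau_i_decay <- cfg$receiver$tau_i_decay
  v_i <- withr_seed(seed_stream(seed, "init_I"),
                    runif(sz$n_i, cfg$neuron$v_reset, cfg$neuron$v_t))
  run_receiver <- function(vseed) {
    v_e <- withr_seed(seed_stream(seed, "init_E", vseed),
                      runif(sz$n_e, cfg$neuron$v_reset, cfg$neuron$v_t))
    simulate_layer(sz$n_e, sz$n_i, rec_r,
                   list(list(wiring = ffwd_r, raster = sender,
                             keep_ids = src_ids)),
                   cfg$neuron, syn_r, dt, duration, c(v_e, v_i),
                   layer = "receiver", w_scale = wsc)
  }
  r1 <- run_receiver(init_seeds[1])
  r2 <- run_receiver(init_seeds[2])

  e_ids <- seq_len(sz$n_e)
  c1 <- bin_counts(r1, bin, c(0, duration), neurons = e_ids)
  c2 <- bin_counts(r2, bin, c(0, duration), neurons = e_ids)

  delta_of <- function(ids) {
    nu1 <- rowSums(c1[, ids, drop = FALSE]) / (length(ids) * bin)
    nu2 <- rowSums(c2[, ids, drop = FALSE]) / (length(ids) * bin)
    nubar <- mean(c(nu1, nu2))
    if (nubar == 0) return(0)
    mean(abs(nu1 - nu2)) / nubar
  }

  tab <- do.call(rbind, lapply(radii, function(r) {
    ds <- vapply(seq_len(n_discs), function(i) {
      center <- withr_seed(seed_stream(seed, paste0("disc", r), i), runif(2))
      d <- periodic_distance(matrix(center, sz$n_e, 2, byrow = TRUE),
                             e_layer$positions)
      ids <- which(d <= r)
      if (!length(ids)) return(NA_real_)
      delta_of(ids)
    }, 0)
    data.frame(radius = r, delta = mean(ds, na.rm = TRUE))
  }))

  nu1_grid <- rowSums(c1) / (sz$n_e * bin)
  nu2_grid <- rowSums(c2) / (sz$n_e * bin)
  list(table = tab, grid_delta = delta_of(e_ids),
       grid_traces = cbind(trial1 = nu1_grid, trial2 = nu2_grid),
       raster1 = r1, raster2 = r2, type = type)
}

#' Run one destabilization scenario end to end
#'
#' Simulates the three-layer network for the named scenario and computes the
#' standard analysis bundle: layer rates, between-area correlation summary,
#' and (optionally) the shared-dimensionality and communication-subspace
#' analyses.
#'
#' @param scenario Scenario name, see [scenario_params()].
#' @param scale Network scale factor.
#' @param seed Master seed.
#' @param duration Trial length in seconds.
#' @param analyses Subset of `c("rates", "correlations", "communication")`.
#' @param max_pairs Passed to [between_area_correlations()].
#' @param ... Passed to [comm_analysis()].
#' @return List with the simulation bundle (`net`) and the requested analysis
#'   results (`rates`, `between`, `comm`).
#' @export
scenario_driver <- function(scenario, scale, seed, duration = 20,
                            analyses = c("rates", "correlations",
                                         "communication"),
                            max_pairs = 1e6, ...) {
  net <- run_three_layer(scenario_params(scenario, scale), seed,
                         duration = duration)
  win <- c(net$cfg$simulation$burn_in, duration)
  out <- list(net = net, scenario = scenario)
  if ("rates" %in% analyses) {
    out$rates <- list(sender = mean_rates(net$sender, win),
                      receiver = mean_rates(net$receiver, win))
  }
  if ("correlations" %in% analyses) {
    e_ids <- seq_len(net$sizes$n_e)
    cs <- bin_counts(net$sender, 0.05, win, neurons = e_ids)
    cr <- bin_counts(net$receiver, 0.05, win, neurons = e_ids)
    out$between <- between_area_correlations(
      cs, cr, max_pairs = max_pairs, seed = seed_stream(seed, "pairs"))
  }
  if ("communication" %in% analyses) {
    out$comm <- comm_analysis(net$sender, net$receiver,
                              net$e_layer$positions, window = win,
                              seed = seed_stream(seed, "comm"), ...)
  }
  out
}
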
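#' Standard network parameters
#'
#' Returns the full parameter tree of the three-layer spiking network with its
#' standard values: a 2500-neuron Poisson input layer and two recurrent
#' excitatory/inhibitory layers (sender, receiver) of 40,000 E and 10,000 I
#' exponential integrate-and-fire neurons each, arranged on the periodic unit
#' square. Connectivity is distance dependent through a wrapped Gaussian
#' (widths `sigma_ffwd` = 0.05, `sigma_e` = `sigma_i` = 0.1). Synaptic
#' strengths `j` are in mV and are divided by `sqrt(N)` of the postsynaptic
#' layer at simulation time, so that postsynaptic potentials stay below ~1 mV.
#'
#' Membrane dynamics use `c_m` = 1 and leak conductances 1/15 (E) and 1/10 (I),
#' i.e. membrane time constants of 15 ms and 10 ms; voltages in mV, synaptic
#' time constants in ms. The simulation block fixes the forward-Euler step
#' (0.05 ms), the trial duration (20 s), the discarded burn-in (1 s) and the
#' uniform 10-Hz input rate.
#'
#' @param scale Linear scale factor `f` in (0, 1] applied to all layer sizes.
#'   Scaled sizes are rounded to the nearest perfect square so neurons remain
#'   on a square lattice; synaptic weights are rescaled automatically through
#'   the `1/sqrt(N)` rule.
#' @return A nested list with blocks `layers`, `connectivity`, `neuron`,
#'   `synapse`, `sender`, `receiver` and `simulation`.
#' @export
standard_params <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0, scale <= 1)
  list(
    layers = list(n_e = 40000L, n_i = 10000L, n_input = 2500L, scale = scale),
    connectivity = list(
      scheme = "outdegree",
      sigma_ffwd = 0.05, sigma_e = 0.1,
      p_e_ffwd = 0.1, p_i_ffwd = 0.05,
      j_e_ffwd = 240, j_i_ffwd = 400,
      p_ee = 0.01, p_ei = 0.04, p_ie = 0.03, p_ii = 0.04,
      j_ee = 80, j_ei = -240, j_ie = 40, j_ii = -300
    ),
    neuron = list(
      c_m = 1, g_l_e = 1 / 15, g_l_i = 1 / 10,
      v_l = -60, v_th = -10, v_reset = -65, v_t = -50,
      t_ref_e = 1.5, t_ref_i = 0.5,
      delta_t_e = 2, delta_t_i = 0.5
    ),
    synapse = list(tau_e_rise = 1, tau_e_decay = 5,
                   tau_i_rise = 1, tau_i_decay = 8),
    # per-layer overrides of the destabilizable parameters
    sender = list(sigma_i = 0.1, tau_i_decay = 8),
    receiver = list(sigma_i = 0.1, tau_i_decay = 8),
    simulation = list(dt = 0.05, duration = 20, burn_in = 1, input_rate = 10)
  )
}

#' Scenario parameter sets
#'
#' The five study conditions: the `standard` balanced network, and networks
#' whose E/I balance is destabilized in exactly one layer, either in space
#' (recurrent inhibition broadened to `sigma_i` = 0.3) or in time (inhibitory
#' synaptic decay slowed to `tau_i_decay` = 24 ms).
#'
#' @param scenario One of `"standard"`, `"spatialS"`, `"spatialR"`,
#'   `"temporalS"`, `"temporalR"` (S = sender destabilized, R = receiver).
#' @param scale Linear scale factor, see [standard_params()].
#' @return A parameter tree as returned by [standard_params()].
#' @export
scenario_params <- function(scenario = c("standard", "spatialS", "spatialR",
                                         "temporalS", "temporalR"),
                            scale = 1) {
  scenario <- match.arg(scenario)
  cfg <- standard_params(scale)
  switch(scenario,
    standard  = NULL,
    spatialS  = { cfg$sender$sigma_i <- 0.3 },
    spatialR  = { cfg$receiver$sigma_i <- 0.3 },
    temporalS = { cfg$sender$tau_i_decay <- 24 },
    temporalR = { cfg$receiver$tau_i_decay <- 24 }
  )
  cfg$scenario <- scenario
  cfg
}

#' Scaled lattice size
#'
#' Scales a layer size by `f` and rounds to the nearest perfect square, so that
#' the scaled layer still forms a square lattice on the unit domain.
#'
#' @param n Full-scale neuron count (a perfect square).
#' @param f Scale factor in (0, 1].
#' @return Integer perfect square.
#' @export
scaled_size <- function(n, f) {
  s <- max(1L, as.integer(round(sqrt(n * f))))
  s * s
}

# Resolved (scaled) layer sizes for a config tree. Under the default
# in-degree-preserving scale rule the Poisson input layer is kept at full
# size (it is computationally free, and full-size sourcing keeps the
# feedforward multi-synapse multiplicity at its full-scale value).
layer_sizes <- function(cfg) {
  f <- cfg$layers$scale
  rule <- cfg$layers$scale_rule %||% "preserve_indegree"
  list(n_e = scaled_size(cfg$layers$n_e, f),
       n_i = scaled_size(cfg$layers$n_i, f),
       n_input = if (rule == "sqrtN") scaled_size(cfg$layers$n_input, f)
                 else cfg$layers$n_input)
}

#' Derive a child seed from a master seed
#'
#' Deterministically fans a single master seed out to named substreams
#' (wiring, input, initial voltages, sampling, cross-validation, ...), so that
#' changing one stage's randomness never perturbs another stage under
#' parameter sweeps. Arithmetic stays below 2^31.
#'
#' @param master Integer master seed.
#' @param name Character stream label.
#' @param index Optional integer for indexed substreams (e.g. trials).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
seed_stream <- function(master, name, index = 0L) {
  stopifnot(length(master) == 1L, is.character(name), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  x <- (as.double(master) %% m)
  x <- (x * 48271 + h + 1) %% m
  x <- (x * 69621 + as.double(index) * 7919 + 1) %% m
  as.integer(x + 1)
}

#' Synaptic weight divisor of a (possibly scaled) layer
#'
#' At full scale, synaptic strengths enter the dynamics as `j / sqrt(N)` with
#' `N` the total (E + I) size of the postsynaptic layer. Downscaling a
#' balanced network while keeping its operating point is delicate: if both
#' in-degrees `K` and `N` shrink with the scale factor `f`, the mean drives
#' (each of order `K j / sqrt(N)`) fall by `sqrt(f)` and the layer rates
#' collapse away from their full-scale values. The default scaled-mode rule
#' (`"preserve_indegree"`) therefore holds every neuron's input statistics at
#' full scale: in-degrees stay at their full-scale values (repeated contacts
#' acting as multi-synapses) and weights stay `j / sqrt(N_full)`, so mean and
#' variance of the synaptic drive -- and hence the balance equations and rate
#' table -- are preserved; the cost is a larger shared-wiring overlap between
#' neighboring neurons. Set `cfg$layers$scale_rule <- "sqrtN"` for the literal
#' rule in which in-degrees scale with `f` and weights use `sqrt(N_scaled)`.
#'
#' @param cfg Parameter tree.
#' @param sz Resolved scaled sizes.
#' @return The divisor applied to `j`.
#' @export
weight_divisor <- function(cfg, sz = layer_sizes(cfg)) {
  rule <- cfg$layers$scale_rule %||% "preserve_indegree"
  if (rule == "sqrtN") sqrt(sz$n_e + sz$n_i)
  else sqrt(cfg$layers$n_e + cfg$layers$n_i)
}

# Per-projection factors multiplying the nominal mean connection probability
# so that realized in-degrees stay at their full-scale values (the factor is
# the pre-layer shrinkage); all 1 under the literal "sqrtN" rule.
scale_boosts <- function(cfg, sz = layer_sizes(cfg)) {
  rule <- cfg$layers$scale_rule %||% "preserve_indegree"
  if (rule == "sqrtN") return(list(e = 1, i = 1, ffwd = 1))
  list(e = cfg$layers$n_e / sz$n_e,
       i = cfg$layers$n_i / sz$n_i,
       ffwd = cfg$layers$n_input / sz$n_input)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
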
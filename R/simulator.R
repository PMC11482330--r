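#' Spike raster container
#'
#' Event store for one layer and one trial: spike times (seconds) and 1-based
#' neuron ids, sorted by time.
#'
#' @param times Spike times in seconds, in `[0, duration)`.
#' @param ids Integer neuron ids in `1..n`.
#' @param n Number of neurons in the layer.
#' @param duration Trial duration in seconds.
#' @param layer Layer label.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(times, ids, n, duration, layer = "layer") {
  stopifnot(length(times) == length(ids))
  if (length(times) && (min(times) < 0 || max(times) >= duration))
    stop("spike times must lie in [0, duration)")
  o <- order(times, ids)
  structure(list(times = as.numeric(times)[o], ids = as.integer(ids)[o],
                 n = as.integer(n), duration = as.numeric(duration),
                 layer = layer),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %s: %d spikes, %d neurons, %.3g s (%.2f Hz mean)\n",
              x$layer, length(x$times), x$n, x$duration,
              length(x$times) / x$n / x$duration))
  invisible(x)
}

#' Homogeneous Poisson input layer
#'
#' Independent homogeneous Poisson spike trains, one per neuron. `rate` may be
#' a vector (one rate per neuron) to build spatially heterogeneous inputs.
#'
#' @param n Number of neurons.
#' @param rate Firing rate(s) in Hz, >= 0; scalar or length `n`.
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @return A `spike_raster`.
#' @export
generate_poisson_layer <- function(n, rate, duration, seed) {
  if (any(rate < 0)) stop("`rate` must be nonnegative")
  rate <- rep_len(rate, n)
  counts <- withr_seed(seed, {
    k <- rpois(n, rate * duration)
    t_ <- runif(sum(k), 0, duration)
    list(k = k, t = t_)
  })
  spike_raster(counts$t, rep.int(seq_len(n), counts$k), n, duration, "input")
}

# Evaluate `expr` under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Merge an E-target and an I-target projection (same presynaptic layer) into
# one CSR over the post layer's combined E-then-I indexing.
merge_projections <- function(syn_e, syn_i, n_e) {
  n_pre <- syn_e$n_pre
  cnt <- diff(syn_e$ptr) + diff(syn_i$ptr)
  ptr <- c(0L, cumsum(cnt))
  idx <- integer(ptr[n_pre + 1L])
  for_pre <- rep.int(seq_len(n_pre), diff(syn_e$ptr))
  # place E targets then I targets per presynaptic neuron
  off_e <- ptr[seq_len(n_pre)]
  pos_e <- sequence(diff(syn_e$ptr)) + rep.int(off_e, diff(syn_e$ptr))
  idx[pos_e] <- syn_e$idx
  off_i <- ptr[seq_len(n_pre)] + diff(syn_e$ptr)
  pos_i <- sequence(diff(syn_i$ptr)) + rep.int(off_i, diff(syn_i$ptr))
  idx[pos_i] <- syn_i$idx + as.integer(n_e)
  list(ptr = ptr, idx = idx)
}

# Build the four recurrent projections of one E/I layer and combine them into
# a single CSR keyed by presynaptic neuron (E cells first, then I cells).
build_recurrent_wiring <- function(e_layer, i_layer, conn, sigma_i, seed,
                                   boost_e = 1, boost_i = 1) {
  sch <- conn$scheme %||% "outdegree"
  syn_ee <- sample_synapses(e_layer, e_layer, conn$sigma_e, conn$p_ee * boost_e,
                            seed_stream(seed, "EE"), sch, exclude_self = TRUE)
  syn_ie <- sample_synapses(e_layer, i_layer, conn$sigma_e, conn$p_ie * boost_e,
                            seed_stream(seed, "IE"), sch, exclude_self = FALSE)
  syn_ei <- sample_synapses(i_layer, e_layer, sigma_i, conn$p_ei * boost_i,
                            seed_stream(seed, "EI"), sch, exclude_self = FALSE)
  syn_ii <- sample_synapses(i_layer, i_layer, sigma_i, conn$p_ii * boost_i,
                            seed_stream(seed, "II"), sch, exclude_self = TRUE)
  from_e <- merge_projections(syn_ee, syn_ie, e_layer$n)
  from_i <- merge_projections(syn_ei, syn_ii, e_layer$n)
  list(ptr = c(from_e$ptr, from_e$ptr[e_layer$n + 1L] + from_i$ptr[-1L]),
       idx = c(from_e$idx, from_i$idx),
       # weights in C++ delivery order: preE->postE, preE->postI,
       # preI->postE, preI->postI
       j = c(conn$j_ee, conn$j_ie, conn$j_ei, conn$j_ii))
}

# Build a feedforward projection (excitatory kernel) from a source layer onto
# an E/I layer; returns CSR plus the class-specific weights (unscaled j).
build_ffwd_wiring <- function(src_layer, e_layer, i_layer, conn, seed,
                              boost = 1) {
  sch <- conn$scheme %||% "outdegree"
  syn_e <- sample_synapses(src_layer, e_layer, conn$sigma_ffwd,
                           conn$p_e_ffwd * boost,
                           seed_stream(seed, "ffwdE"), sch, exclude_self = FALSE)
  syn_i <- sample_synapses(src_layer, i_layer, conn$sigma_ffwd,
                           conn$p_i_ffwd * boost,
                           seed_stream(seed, "ffwdI"), sch, exclude_self = FALSE)
  c(merge_projections(syn_e, syn_i, e_layer$n),
    list(j_e = conn$j_e_ffwd, j_i = conn$j_i_ffwd))
}

# Raster -> (step, pre) event arrays for the C++ integrator, keeping only
# spikes from the id vector `keep_ids` (renumbered 0-based to the position in
# `keep_ids`).
raster_to_events <- function(raster, dt_ms, keep_ids = NULL) {
  t_ <- raster$times; id <- raster$ids
  if (!is.null(keep_ids)) {
    pre <- match(id, keep_ids)
    sel <- !is.na(pre)
    t_ <- t_[sel]; id <- pre[sel]
  }
  list(step = as.integer(floor(t_ * 1000 / dt_ms)), pre = as.integer(id) - 1L)
}

#' Integrate one recurrent E/I layer
#'
#' Forward-Euler integration (step `dt` ms) of exponential
#' integrate-and-fire dynamics: `c_m dV/dt = -g_l (V - v_l) + g_l delta_t
#' exp((V - v_t)/delta_t) + I(t)`, with spike threshold `v_th`, reset `v_reset`
#' held for the refractory period, and synaptic currents summed over
#' difference-of-exponentials kernels. Synaptic strengths are `j / sqrt(N)`
#' with `N` the total (E + I) size of this layer. The exponential term's
#' argument is capped at 20 to guard against overflow; any voltage at or above
#' `v_th` registers a spike at that step. Deterministic given wiring, inputs
#' and initial voltages.
#'
#' @param n_e,n_i Layer composition.
#' @param rec Recurrent CSR wiring (internal `build_recurrent_wiring()`; NULL
#'   for an uncoupled layer).
#' @param ffwd List of feedforward projections; each element is a list with
#'   `wiring` (CSR + `j_e`, `j_i`) and `raster` (the presynaptic
#'   `spike_raster`, E-kernel).
#' @param nrn,syn Neuron and synapse parameter blocks (see [standard_params()]);
#'   `syn$tau_i_decay` is this layer's (possibly destabilized) value.
#' @param dt Euler step in ms.
#' @param duration Seconds to integrate.
#' @param v_init Initial voltages, length `n_e + n_i`.
#' @param w_scale Divisor applied to the synaptic strengths `j` (defaults to
#'   `sqrt(n_e + n_i)`; scaled-down networks use [weight_divisor()] to keep
#'   every neuron's input statistics at full scale).
#' @param i_ext Constant external current (mV/ms), scalar or per neuron.
#' @param record Integer ids (1-based) whose voltage and synaptic-drive traces
#'   to record.
#' @param layer Label for the returned raster.
#' @return A `spike_raster`, with attributes `v_trace` and `i_trace`
#'   (step-by-neuron matrices) when `record` is nonempty, and `v_final`.
#' @export
simulate_layer <- function(n_e, n_i, rec, ffwd, nrn, syn, dt, duration,
                           v_init, i_ext = 0, record = integer(0),
                           layer = "layer", w_scale = sqrt(n_e + n_i)) {
  n <- n_e + n_i
  if (length(v_init) != n) stop("`v_init` must have length n_e + n_i")
  if (syn$tau_e_decay <= syn$tau_e_rise || syn$tau_i_decay <= syn$tau_i_rise)
    stop("tau_decay must exceed tau_rise")
  n_steps <- as.integer(round(duration * 1000 / dt))
  rootN <- w_scale
  if (is.null(rec))
    rec <- list(ptr = integer(n + 1L), idx = integer(0), j = numeric(4))
  ext <- lapply(ffwd, function(p) {
    ev <- raster_to_events(p$raster, dt, p$keep_ids)
    list(ptr = p$wiring$ptr, idx = p$wiring$idx,
         step = ev$step, pre = ev$pre,
         w_e = p$wiring$j_e / rootN, w_i = p$wiring$j_i / rootN)
  })
  out <- cpp_simulate_layer(
    n_e, n_i, dt, n_steps,
    gl = c(nrn$g_l_e, nrn$g_l_i) / nrn$c_m,
    delta_t = c(nrn$delta_t_e, nrn$delta_t_i),
    tref_steps = as.integer(round(c(nrn$t_ref_e, nrn$t_ref_i) / dt)),
    v_l = nrn$v_l, v_th = nrn$v_th, v_reset = nrn$v_reset, v_t = nrn$v_t,
    tau_er = syn$tau_e_rise, tau_ed = syn$tau_e_decay,
    tau_ir = syn$tau_i_rise, tau_id = syn$tau_i_decay,
    rec_ptr = rec$ptr, rec_idx = rec$idx,
    rec_w = rec$j / rootN,
    ext_projs = ext,
    v_init = v_init, i_ext = as.numeric(i_ext),
    record_idx = as.integer(record) - 1L)
  ras <- spike_raster(out$step * dt / 1000, out$id + 1L, n, duration, layer)
  if (length(record)) {
    attr(ras, "v_trace") <- out$v_trace
    attr(ras, "i_trace") <- out$i_trace
  }
  attr(ras, "v_final") <- out$v_final
  ras
}

#' Run the three-layer network
#'
#' Drives the sender layer with the Poisson input layer and the receiver layer
#' with the sender's excitatory spikes (purely feedforward between layers; no
#' receiver-to-sender projections). The two recurrent layers may differ in
#' their destabilizable parameters (`sigma_i`, `tau_i_decay`) per the
#' scenario. All randomness (wiring, input, initial voltages) is fanned out
#' from `seed` via named streams.
#'
#' @param cfg Parameter tree from [standard_params()] / [scenario_params()].
#' @param seed Master integer seed.
#' @param duration Override of `cfg$simulation$duration` (seconds).
#' @return List with `input`, `sender`, `receiver` rasters, the E/I layer
#'   geometries (`e_layer`, `i_layer`), resolved sizes and the config.
#' @export
run_three_layer <- function(cfg, seed, duration = cfg$simulation$duration) {
  sz <- layer_sizes(cfg)
  input_layer <- grid_layer(sz$n_input, "input")
  e_layer <- grid_layer(sz$n_e, "E")
  i_layer <- grid_layer(sz$n_i, "I")
  conn <- cfg$connectivity
  dt <- cfg$simulation$dt
  n <- sz$n_e + sz$n_i
  wsc <- weight_divisor(cfg, sz)
  bst <- scale_boosts(cfg, sz)

  input <- generate_poisson_layer(sz$n_input, cfg$simulation$input_rate,
                                  duration, seed_stream(seed, "input"))

  sender <- local({
    rec <- build_recurrent_wiring(e_layer, i_layer, conn, cfg$sender$sigma_i,
                                  seed_stream(seed, "wiring_S"),
                                  bst$e, bst$i)
    ffwd <- build_ffwd_wiring(input_layer, e_layer, i_layer, conn,
                              seed_stream(seed, "wiring_inS"), bst$ffwd)
    v0 <- withr_seed(seed_stream(seed, "init_S"),
                     runif(n, cfg$neuron$v_reset, cfg$neuron$v_t))
    syn_s <- cfg$synapse; syn_s$tau_i_decay <- cfg$sender$tau_i_decay
    simulate_layer(sz$n_e, sz$n_i, rec,
                   list(list(wiring = ffwd, raster = input)),
                   cfg$neuron, syn_s, dt, duration, v0, layer = "sender",
                   w_scale = wsc)
  })

  # the receiver's feedforward sources: an input-layer-sized regular
  # sublattice of the sender's E cells (keeps the feedforward in-degree of
  # both recurrent layers identical)
  sub_side <- min(e_layer$side, input_layer$side)
  src_ids <- sublattice_ids(e_layer$side, sub_side)
  rule <- cfg$layers$scale_rule %||% "preserve_indegree"
  boost_sr <- if (rule == "sqrtN") 1 else cfg$layers$n_input / length(src_ids)
  src <- layer_subset(e_layer, src_ids)
  receiver <- local({
    rec <- build_recurrent_wiring(e_layer, i_layer, conn, cfg$receiver$sigma_i,
                                  seed_stream(seed, "wiring_R"),
                                  bst$e, bst$i)
    ffwd <- build_ffwd_wiring(src, e_layer, i_layer, conn,
                              seed_stream(seed, "wiring_SR"), boost_sr)
    v0 <- withr_seed(seed_stream(seed, "init_R"),
                     runif(n, cfg$neuron$v_reset, cfg$neuron$v_t))
    syn_r <- cfg$synapse; syn_r$tau_i_decay <- cfg$receiver$tau_i_decay
    simulate_layer(sz$n_e, sz$n_i, rec,
                   list(list(wiring = ffwd, raster = sender,
                             keep_ids = src_ids)),
                   cfg$neuron, syn_r, dt, duration, v0, layer = "receiver",
                   w_scale = wsc)
  })

  list(input = input, sender = sender, receiver = receiver,
       e_layer = e_layer, i_layer = i_layer, sizes = sz, cfg = cfg,
       seed = seed)
}

#' Bin a raster into a spike-count matrix
#'
#' Nonoverlapping half-open bins `[t, t + bin)`; a trailing partial bin is
#' discarded, so the total count is conserved up to the dropped tail.
#'
#' @param raster A `spike_raster`.
#' @param bin Bin width in seconds (default 50 ms).
#' @param window Analysis window `c(start, end)` in seconds; defaults to the
#'   whole trial.
#' @param neurons Neuron ids to keep as columns (in the given order); default
#'   all.
#' @return Integer T-by-K count matrix with attributes `bin`, `window`,
#'   `neurons`.
#' @export
bin_counts <- function(raster, bin = 0.05, window = c(0, raster$duration),
                       neurons = NULL) {
  if (diff(window) <= 0) stop("empty analysis window")
  n_bins <- floor(diff(window) / bin + 1e-9)
  if (n_bins < 1) stop("window shorter than one bin")
  if (is.null(neurons)) neurons <- seq_len(raster$n)
  k <- length(neurons)
  sel <- raster$times >= window[1] & raster$times < window[1] + n_bins * bin
  t_idx <- floor((raster$times[sel] - window[1]) / bin)
  t_idx[t_idx >= n_bins] <- n_bins - 1 # guard exact-boundary roundoff
  col <- match(raster$ids[sel], neurons)
  keep <- !is.na(col)
  m <- matrix(tabulate((col[keep] - 1L) * n_bins + t_idx[keep] + 1L,
                       nbins = n_bins * k),
              nrow = n_bins, ncol = k)
  colnames(m) <- as.character(neurons)
  structure(m, bin = bin, window = c(window[1], window[1] + n_bins * bin),
            neurons = neurons)
}
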
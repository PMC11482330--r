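#' Load and validate a configuration file
#'
#' Reads a YAML configuration and merges it over the standard parameter
#' defaults. Only keys present in the default tree are accepted; unknown keys
#' are rejected with the path to the offending key. An empty (or absent) file
#' yields the full standard defaults. Basic consistency rules are enforced:
#' positive widths and time constants, `tau_decay > tau_rise`, probabilities
#' in `[0, 1]`, `dt > 0` and `burn_in < duration`.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @param scale Scale factor applied to the defaults before merging.
#' @return A validated parameter tree (see [standard_params()]).
#' @export
load_config <- function(path = NULL, scale = 1) {
  cfg <- standard_params(scale)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user, "")
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, where) {
  for (key in names(user)) {
    full <- paste0(where, "$", key)
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]])) {
      if (!is.list(user[[key]])) stop("expected a block at ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  cn <- cfg$connectivity; sy <- cfg$synapse; sim <- cfg$simulation
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  check(cfg$layers$scale > 0 && cfg$layers$scale <= 1, "scale must be in (0, 1]")
  check(cn$scheme %in% c("outdegree", "bernoulli"),
        "connectivity scheme must be 'outdegree' or 'bernoulli'")
  for (s in c(cn$sigma_ffwd, cn$sigma_e, cfg$sender$sigma_i,
              cfg$receiver$sigma_i))
    check(s > 0, "sigma must be positive")
  for (p in c(cn$p_e_ffwd, cn$p_i_ffwd, cn$p_ee, cn$p_ei, cn$p_ie, cn$p_ii))
    check(p >= 0 && p <= 1, "connection probabilities must be in [0, 1]")
  check(sy$tau_e_decay > sy$tau_e_rise, "tau_e_decay must exceed tau_e_rise")
  for (td in c(sy$tau_i_decay, cfg$sender$tau_i_decay,
               cfg$receiver$tau_i_decay))
    check(td > sy$tau_i_rise, "tau_i_decay must exceed tau_i_rise")
  check(cfg$neuron$v_reset < cfg$neuron$v_t,
        "v_reset must be below the soft threshold v_t")
  check(cfg$neuron$v_t < cfg$neuron$v_th, "v_t must be below v_th")
  check(cfg$neuron$delta_t_e > 0 && cfg$neuron$delta_t_i > 0,
        "delta_t must be positive")
  check(sim$dt > 0, "dt must be positive")
  check(sim$burn_in < sim$duration, "burn_in must be below duration")
  check(sim$input_rate >= 0, "input_rate must be nonnegative")
  invisible(cfg)
}

#' Save a spike raster (gzipped CSV + metadata sidecar)
#'
#' Events go to a gzipped CSV (`time`, `id`); layer metadata and simple
#' checksums go to a YAML sidecar (`<path>.meta.yml`) so that corruption is
#' detected on load.
#'
#' @param raster A `spike_raster`.
#' @param path Output path, conventionally ending in `.csv.gz`.
#' @return `path`, invisibly.
#' @export
save_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  data.table::fwrite(data.table::data.table(time = raster$times,
                                            id = raster$ids),
                     path, compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  meta <- list(n = raster$n, duration = raster$duration, layer = raster$layer,
               n_events = length(raster$times),
               sum_ids = sum(as.double(raster$ids)),
               sum_times = round(sum(raster$times), 6))
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' Load a spike raster saved by [save_raster()]
#'
#' @param path Path passed to [save_raster()].
#' @return A `spike_raster`.
#' @export
load_raster <- function(path) {
  meta_path <- paste0(path, ".meta.yml")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("raster file or metadata sidecar missing: ", path)
  meta <- yaml::read_yaml(meta_path)
  con <- gzfile(path) # plain files are passed through unchanged
  cols <- scan(con, what = list(time = numeric(), id = integer()),
               sep = ",", skip = 1, quiet = TRUE)
  close(con)
  ev <- data.frame(time = cols$time, id = cols$id)
  if (nrow(ev) != meta$n_events ||
      (nrow(ev) && (abs(sum(as.double(ev$id)) - meta$sum_ids) > 0.5 ||
                    abs(round(sum(ev$time), 6) - meta$sum_times) > 1e-3)))
    stop("integrity error: raster file does not match its metadata checksum")
  spike_raster(ev$time, ev$id, meta$n, meta$duration, meta$layer)
}

#' Run manifest
#'
#' Captures everything needed to bit-reproduce a pipeline stage: the scenario,
#' master seed, scale factor, package version and per-stage output paths.
#'
#' @param scenario Scenario name.
#' @param seed Master seed.
#' @param scale Scale factor.
#' @param outputs Named character vector/list of output paths.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(scenario, seed, scale, outputs = list()) {
  structure(list(scenario = scenario, seed = as.integer(seed), scale = scale,
                 package_version = as.character(utils::packageVersion("spikecomms")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 outputs = outputs),
            class = "run_manifest")
}
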
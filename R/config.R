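## Run configuration: a flat, human-editable YAML document whose field names
## mirror the model parameter tables, so defaults are auditable at a glance.

#' Default run configuration
#'
#' Returns the full configuration used by the command-line interface, with
#' every field at its reference value: the stimulus block (velocities,
#' extreme, hold, dt, trials), the afferent block (hair-row geometry and
#' filter/spike-generator parameters), the DIN block (preset label or
#' explicit parameters), the analysis block (analysis velocities, resampling
#' reps), a seed and an output directory.
#'
#' @param seed integer seed stored in the config.
#' @param out_dir output directory.
#' @return a named list (class `dinsim_config`).
#' @export
default_config <- function(seed = 1L, out_dir = ".") {
  structure(list(
    stimulus = list(velocity = 40, velocities = c(12, 50, 150, 400),
                    extreme = 50, hold = 1, dt = 0.001, n_trials = 4),
    afferent = list(N_hairs = 20, Range = 2.5, Deflect_slope = 1,
                    LPF_tau = 0.010, LPF_w = 2, HPF_tau = 0.030, HPF_w = 20,
                    Offset = 35, Norm = 100, Rmax = 300, dS = 0.001,
                    refractory = 0.003),
    din = list(preset = "ON"),
    analysis = list(velocities = c(12, 50, 150, 400), n_trials = 4,
                    resample_reps = 100, n_per_group = 15),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "dinsim_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param config a `dinsim_config` list.
#' @param path file path.
#' @return `read_config()` returns the config; `write_config()` the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  for (blk in names(cfg)) {
    if (is.list(base[[blk]]) && is.list(cfg[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else {
      base[[blk]] <- cfg[[blk]]
    }
  }
  structure(base, class = "dinsim_config")
}

## constructors from the config blocks
config_afferents <- function(config) {
  a <- config$afferent
  afferent_params(lpf_tau = a$LPF_tau, lpf_weight = a$LPF_w,
                  hpf_tau = a$HPF_tau, hpf_weight = a$HPF_w,
                  offset = a$Offset, norm = a$Norm, rmax = a$Rmax,
                  dt = a$dS, refractory = a$refractory)
}

config_rows <- function(config) {
  a <- config$afferent
  list(hair_row_config("dorsal", n_hairs = a$N_hairs,
                       onset_spacing = a$Range, slope = a$Deflect_slope),
       hair_row_config("ventral", n_hairs = a$N_hairs,
                       onset_spacing = a$Range, slope = a$Deflect_slope))
}

config_din <- function(config) {
  d <- config$din
  if (!is.null(d$preset)) return(din_preset(d$preset))
  do.call(din_params, d)
}
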
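## Descending interneuron (DIN) model variants. All variants share the first
## stage: afferent spike trains are low-pass filtered (unit impulse per spike,
## decay tau_LPF1), summed per hair row, weighted (Wd, Wv) and added. The
## simple position-sensitive variant feeds this input, divided by its
## normalization, straight into the spike generator. The band-pass variants
## (ON, OFF, dynamic position-sensitive, dynamic extreme position-sensitive)
## pass the input through a series band-pass (LPF tau 50 ms weight 2, then
## HPF tau 40 ms weight 20), rectify (none / abs / -abs), normalize, and add
## an offset before spiking.

#' DIN model parameters
#'
#' Parameter record for one descending-interneuron model variant. Use
#' [din_preset()] for the named reference variants.
#'
#' @param label variant label (free text; presets use `SP_d`, `SP_v`, `ON`,
#'   `OFF`, `DP_d`, `DP_v`, `Ex.DP`, `RANDOM`).
#' @param lpf1_tau time constant (s) of the per-spike low-pass in the common
#'   input stage.
#' @param wd,wv weights of the dorsal and ventral afferent input streams.
#' @param use_branch logical: pass the input through the band-pass branch
#'   (FALSE for simple position-sensitive variants).
#' @param lpf2_tau,lpf2_weight band-pass low-pass time constant (s) and weight.
#' @param hpf_tau,hpf_weight band-pass high-pass time constant (s) and weight.
#' @param offset constant added after normalization (band-pass branch only).
#' @param rectify `"none"`, `"abs"` (full-wave) or `"neg_abs"` (inverted
#'   full-wave, for OFF-type suppression).
#' @param norm normalization divisor.
#' @param rmax spike-generator rate scale (1/s). DIN spike generation has no
#'   refractory period.
#' @param const_act constant activation level for input-free (`RANDOM`)
#'   neurons; ignored otherwise.
#' @return an object of class `din_params`.
#' @export
din_params <- function(label = "custom", lpf1_tau = 0.005, wd = 1, wv = 1,
                       use_branch = TRUE, lpf2_tau = 0.050, lpf2_weight = 2,
                       hpf_tau = 0.040, hpf_weight = 20, offset = 0,
                       rectify = c("none", "abs", "neg_abs"), norm = 20,
                       rmax = 100, const_act = NA_real_) {
  rectify <- match.arg(rectify)
  stopifnot(norm > 0, rmax > 0, wd >= 0, wv >= 0, lpf1_tau > 0)
  structure(list(label = label, lpf1_tau = lpf1_tau, wd = wd, wv = wv,
                 use_branch = use_branch, lpf2_tau = lpf2_tau,
                 lpf2_weight = lpf2_weight, hpf_tau = hpf_tau,
                 hpf_weight = hpf_weight, offset = offset, rectify = rectify,
                 norm = norm, rmax = rmax, const_act = const_act),
            class = "din_params")
}

#' Named DIN model presets
#'
#' The reference parameterizations of the four modelled DIN types (plus the
#' dynamic extreme position-sensitive variant and an input-free random
#' spiker):
#'
#' | label  | Wd | Wv | branch | offset | rectify | norm | Rmax |
#' |--------|----|----|--------|--------|---------|------|------|
#' | SP_d   | 1  | 0  | no     |        |         | 4    | 10   |
#' | SP_v   | 0  | 1  | no     |        |         | 4    | 10   |
#' | Ex.DP  | 1  | 1  | yes    | -0.2   | none    | 20   | 100  |
#' | ON     | 1  | 1  | yes    | -0.2   | abs     | 20   | 120  |
#' | DP_d   | 1  | 0  | yes    | -0.2   | abs     | 20   | 100  |
#' | DP_v   | 0  | 1  | yes    | -0.2   | abs     | 20   | 100  |
#' | OFF    | 1  | 1  | yes    | +1     | neg_abs | 40   | 30   |
#'
#' All variants share `lpf1_tau` 5 ms and the band-pass (LPF 50 ms / weight 2,
#' HPF 40 ms / weight 20). The OFF variant thereby realizes
#' `act = 1 - |b|/40`: the ON-type drive inverted, scaled by 0.5, and
#' subtracted from a constant offset of 1, so its resting rate is
#' `rmax * 1 = 30` Hz. `RANDOM` is an input-free neuron with constant
#' activation 0.2 and `rmax` 100 (about 20 Hz).
#'
#' @param label one of `SP_d`, `SP_v`, `ON`, `OFF`, `DP_d`, `DP_v`, `Ex.DP`,
#'   `RANDOM`.
#' @return a [din_params()] object.
#' @export
din_preset <- function(label) {
  presets <- c("SP_d", "SP_v", "ON", "OFF", "DP_d", "DP_v", "Ex.DP", "RANDOM")
  if (!is.character(label) || length(label) != 1L || !(label %in% presets))
    stop("unknown DIN preset; valid labels: ",
         paste(presets, collapse = ", "), call. = FALSE)
  switch(label,
    SP_d  = din_params("SP_d", wd = 1, wv = 0, use_branch = FALSE,
                       norm = 4, rmax = 10),
    SP_v  = din_params("SP_v", wd = 0, wv = 1, use_branch = FALSE,
                       norm = 4, rmax = 10),
    ON    = din_params("ON", wd = 1, wv = 1, offset = -0.2, rectify = "abs",
                       norm = 20, rmax = 120),
    OFF   = din_params("OFF", wd = 1, wv = 1, offset = 1, rectify = "neg_abs",
                       norm = 40, rmax = 30),
    DP_d  = din_params("DP_d", wd = 1, wv = 0, offset = -0.2, rectify = "abs",
                       norm = 20, rmax = 100),
    DP_v  = din_params("DP_v", wd = 0, wv = 1, offset = -0.2, rectify = "abs",
                       norm = 20, rmax = 100),
    Ex.DP = din_params("Ex.DP", wd = 1, wv = 1, offset = -0.2,
                       rectify = "none", norm = 20, rmax = 100),
    RANDOM = din_params("RANDOM", use_branch = FALSE, norm = 1, rmax = 100,
                        const_act = 0.2)
  )
}

## internal: weighted, LPF1-integrated afferent input on the full (settled)
## grid of an afferent_population.
integrate_input_full <- function(pop, wd, wv, lpf1_tau) {
  dt <- pop$params$dt
  d_cols <- pop$side == "dorsal"
  cnt_d <- rowSums(pop$counts_full[, d_cols, drop = FALSE])
  cnt_v <- rowSums(pop$counts_full[, !d_cols, drop = FALSE])
  wd * lpf_first_order(cnt_d, lpf1_tau, dt, init = 0) +
    wv * lpf_first_order(cnt_v, lpf1_tau, dt, init = 0)
}

#' Integrate afferent spike trains into a DIN input function
#'
#' Common first stage of all DIN variants: the per-step spike counts of each
#' hair row are smoothed by the package's standard first-order low-pass
#' ([lpf_first_order()], time constant `lpf1_tau`), spreading each spike into
#' an exponentially decaying postsynaptic potential; row sums are weighted by
#' `wd`/`wv` and added. Each spike's PSP peaks at `1 - exp(-dt/lpf1_tau)`
#' and the filter has unit DC gain, so for afferents firing steadily at
#' total weighted rate R the input settles around `R * dt`, the expected
#' spike count per time step.
#'
#' @param pop an `afferent_population` from [simulate_hair_fields()].
#' @param wd,wv dorsal/ventral input weights.
#' @param lpf1_tau integration time constant (s), default 0.005.
#' @return an `activation_trace` on the stimulus grid.
#' @export
integrate_afferent_input <- function(pop, wd = 1, wv = 1, lpf1_tau = 0.005) {
  stopifnot(inherits(pop, "afferent_population"))
  full <- integrate_input_full(pop, wd, wv, lpf1_tau)
  if (pop$n_settle > 0L) full <- full[-seq_len(pop$n_settle)]
  new_activation_trace(full, dt = pop$params$dt)
}

#' DIN branch: band-pass, rectification, normalization, offset
#'
#' Variant-specific second stage. Simple position-sensitive variants
#' (`use_branch = FALSE`) return `input / norm`. Band-pass variants compute a
#' series band-pass `b = hpf_weight * HPF(lpf2_weight * LPF(input))`, apply
#' the rectification mode (`none`: b; `abs`: |b|; `neg_abs`: -|b|), divide by
#' `norm` and add `offset`. Because the series band-pass has zero DC gain,
#' constant input drives the output to `offset`, keeping ON-type variants
#' below spike threshold during stimulus hold phases, while the OFF variant
#' rests at `offset = 1`.
#'
#' @param input an `activation_trace` (from [integrate_afferent_input()]) or
#'   numeric vector.
#' @param params a [din_params()].
#' @param dt sample interval, taken from `input` when it is a trace.
#' @return an `activation_trace`.
#' @export
din_branch <- function(input, params, dt = NULL) {
  stopifnot(inherits(params, "din_params"))
  if (inherits(input, "activation_trace")) {
    if (is.null(dt)) dt <- input$dt
    input <- input$values
  }
  if (is.null(dt)) stop("`dt` must be supplied for numeric input", call. = FALSE)
  if (!params$use_branch)
    return(new_activation_trace(input / params$norm, dt = dt))
  b <- params$hpf_weight *
    hpf_first_order(params$lpf2_weight *
                      lpf_first_order(input, params$lpf2_tau, dt),
                    params$hpf_tau, dt)
  b <- switch(params$rectify,
              none = b,
              abs = abs(b),
              neg_abs = -abs(b))
  new_activation_trace(b / params$norm + params$offset, dt = dt)
}

#' Simulate one DIN on an afferent population response
#'
#' Composes [integrate_afferent_input()], [din_branch()] and
#' [generate_spike_train()] (no refractory period at the DIN stage). The
#' filter cascade runs on the settle-extended grid of the afferent population
#' and is cropped to the stimulus window before spike generation. `RANDOM`
#' neurons bypass the input entirely and spike on a constant activation
#' `const_act`.
#'
#' @param pop an `afferent_population`.
#' @param params a [din_params()] (see [din_preset()]).
#' @param seed integer seed for the DIN's spike generator.
#' @return an object of class `din_response`: `params`, `input`
#'   (`activation_trace`, pre-branch), `activation` (post-branch), `spikes`
#'   (`spike_train`), and the stimulus.
#' @export
simulate_din <- function(pop, params, seed = 1L) {
  stopifnot(inherits(pop, "afferent_population"),
            inherits(params, "din_params"))
  dt <- pop$params$dt
  n_keep <- nrow(pop$counts_full) - pop$n_settle
  crop <- function(v) if (pop$n_settle > 0L) v[-seq_len(pop$n_settle)] else v
  if (!is.na(params$const_act)) {
    input <- new_activation_trace(rep(0, n_keep), dt = dt)
    act <- new_activation_trace(rep(params$const_act, n_keep), dt = dt)
  } else {
    full_in <- integrate_input_full(pop, params$wd, params$wv, params$lpf1_tau)
    full_act <- din_branch(full_in, params, dt = dt)
    input <- new_activation_trace(crop(full_in), dt = dt)
    act <- new_activation_trace(crop(full_act$values), dt = dt)
  }
  st <- generate_spike_train(act, rmax = params$rmax, dt = dt,
                             refractory = 0, seed = seed)
  structure(list(params = params, input = input, activation = act,
                 spikes = st, stimulus = pop$stimulus),
            class = "din_response")
}

#' @export
print.din_response <- function(x, ...) {
  cat(sprintf("<din_response> %s: %d spikes over %g s (mean %.2f Hz)\n",
              x$params$label, length(x$spikes$times), x$spikes$duration,
              spike_rate(x$spikes)))
  invisible(x)
}

#' @export
plot.din_response <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- trace_times(x$stimulus)
  graphics::plot(tt, x$stimulus$angle, type = "l", xlab = "",
                 ylab = "angle (deg)", ...)
  graphics::plot(tt, x$activation$values, type = "l", xlab = "",
                 ylab = "activation")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$spikes$times, rep(1, length(x$spikes$times)), pch = "|",
                 ylim = c(0, 2), yaxt = "n", xlim = range(tt),
                 xlab = "time (s)", ylab = x$params$label)
  invisible(x)
}

#' Simulate the full pathway for one DIN on a staircase stimulus
#'
#' Convenience wrapper: builds the afferent population for `trace` and
#' simulates `params` on it, with afferent and DIN seeds split from `seed`.
#'
#' @param trace a `joint_angle_trace`.
#' @param params a [din_params()].
#' @param afferents an [afferent_params()].
#' @param seed master seed.
#' @return a `din_response`.
#' @export
simulate_pathway <- function(trace, params, afferents = afferent_params(),
                             seed = 1L) {
  pop <- simulate_hair_fields(trace, afferents, seed = derive_seed(seed, 1))
  simulate_din(pop, params, seed = derive_seed(seed, 2))
}

#' Velocity tuning of a DIN model
#'
#' Mean spike rate during the staircase ramps (the movement window) as a
#' function of ramp velocity, averaged over sweeps. The movement window is
#' used for every variant: movement-activated variants (ON, DP, Ex.DP) are
#' driven only there, and the OFF variant's defining property — baseline
#' firing increasingly suppressed by faster movement — is likewise a property
#' of the rate during movement (a whole-trial mean would rebound towards
#' baseline at high velocities simply because the ramps occupy ever less of
#' the trial).
#'
#' @param params a [din_params()].
#' @param velocities ramp velocities in degrees/s (within `[1, 800]`).
#' @param n_sweeps sweeps per velocity (default 4).
#' @param afferents an [afferent_params()].
#' @param hold_duration staircase hold duration (s).
#' @param extreme staircase amplitude (degrees).
#' @param seed master seed.
#' @return data frame with `velocity_deg_s`, `mean_rate_hz`, `window`.
#' @export
velocity_tuning <- function(params, velocities = c(12, 50, 150, 400),
                            n_sweeps = 4, afferents = afferent_params(),
                            hold_duration = 1, extreme = 50, seed = 1L) {
  stopifnot(all(velocities >= 1 & velocities <= 800))
  rate <- vapply(seq_along(velocities), function(vi) {
    v <- velocities[vi]
    tr <- build_staircase(v, hold_duration = hold_duration, extreme = extreme,
                          dt = afferents$dt)
    lab <- segment_intervals(tr)
    ramp_idx <- which(lab$label %in% c("ramp_up", "ramp_down"))
    mean(vapply(seq_len(n_sweeps), function(s) {
      resp <- simulate_pathway(tr, params, afferents,
                               seed = derive_seed(seed, vi, s))
      steps <- as.integer(round(resp$spikes$times / afferents$dt + 0.5))
      sum(steps %in% ramp_idx) / (length(ramp_idx) * afferents$dt)
    }, numeric(1)))
  }, numeric(1))
  data.frame(velocity_deg_s = velocities, mean_rate_hz = rate,
             window = "ramps")
}
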
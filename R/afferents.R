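## Hair-field afferent model: joint angle -> per-hair deflection -> lead-lag
## (LPF + HPF) activation -> noisy spike generation with absolute refractory
## period, for two rows (dorsal/ventral) of 20 sensilla each.

#' Hair-row configuration
#'
#' One row of proprioceptive hairs on one side of the Sc-Pd joint. Hair i has
#' deflection onset at `(i - 1) * onset_spacing` degrees of joint excursion on
#' the row's side; beyond its onset its deflection grows with `slope` up to
#' `max_deflection`. With 20 hairs spaced 2.5 degrees apart, onsets tile the
#' full 50-degree half-range, so the number of deflected hairs grows linearly
#' with joint excursion. Dorsal hairs deflect only for positive joint angles,
#' ventral hairs only for negative ones.
#'
#' @param side `"dorsal"` or `"ventral"`.
#' @param n_hairs number of hairs in the row (default 20).
#' @param onset_spacing degrees of joint excursion between successive hair
#'   onsets (default 2.5).
#' @param slope dimensionless gain from joint excursion beyond onset to hair
#'   deflection (default 1).
#' @param max_deflection saturation deflection in degrees; default
#'   `n_hairs * onset_spacing` (the full half-range), so only the most
#'   proximal hairs can reach full deflection.
#' @return an object of class `hair_row_config`.
#' @export
hair_row_config <- function(side = c("dorsal", "ventral"), n_hairs = 20,
                            onset_spacing = 2.5, slope = 1,
                            max_deflection = n_hairs * onset_spacing) {
  side <- match.arg(side)
  stopifnot(n_hairs >= 1, onset_spacing > 0, slope > 0, max_deflection > 0)
  structure(list(side = side, n_hairs = as.integer(n_hairs),
                 onset_spacing = onset_spacing, slope = slope,
                 max_deflection = max_deflection),
            class = "hair_row_config")
}

#' Afferent model parameters
#'
#' Filter, offset, normalization and spike-generator settings shared by all
#' hair-field afferents. Defaults are the reference parameterization of the
#' model: low-pass 10 ms with weight 2 (tonic, position-proportional
#' component), high-pass 30 ms with weight 20 (phasic, velocity-proportional
#' component), offset 35, normalization 100, maximal rate 300 Hz on a 1 ms
#' grid, absolute refractory period 3 ms.
#'
#' @param lpf_tau,lpf_weight low-pass time constant (s) and weight.
#' @param hpf_tau,hpf_weight high-pass time constant (s) and weight.
#' @param offset constant subtracted from the weighted filter sum.
#' @param norm divisor applied after the offset subtraction.
#' @param rmax spike-generator rate scale (1/s).
#' @param dt sample interval (s).
#' @param refractory absolute refractory period (s).
#' @return an object of class `afferent_params`.
#' @export
afferent_params <- function(lpf_tau = 0.010, lpf_weight = 2,
                            hpf_tau = 0.030, hpf_weight = 20,
                            offset = 35, norm = 100, rmax = 300,
                            dt = 0.001, refractory = 0.003) {
  stopifnot(lpf_tau > 0, hpf_tau > 0, norm > 0, rmax > 0, dt > 0,
            refractory >= 0)
  structure(list(lpf_tau = lpf_tau, lpf_weight = lpf_weight,
                 hpf_tau = hpf_tau, hpf_weight = hpf_weight,
                 offset = offset, norm = norm, rmax = rmax,
                 dt = dt, refractory = refractory),
            class = "afferent_params")
}

new_activation_trace <- function(values, dt, t0 = 0) {
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "activation_trace")
}

new_spike_train <- function(times, duration, dt) {
  structure(list(times = as.numeric(times), duration = duration, dt = dt),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (mean rate %.2f Hz)\n",
              length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Mean spike rate of a spike train
#' @param st a `spike_train`.
#' @return spikes per second over the train's duration.
#' @export
spike_rate <- function(st) length(st$times) / st$duration

#' Per-hair deflection traces for one hair row
#'
#' Maps a joint-angle trace to the deflection of every hair in a row:
#' `deflection_i = clip(slope * (excursion - onset_i), 0, max_deflection)`
#' where `excursion` is the joint angle on the row's side (positive part for
#' dorsal rows, negative part magnitude for ventral rows) and
#' `onset_i = (i - 1) * onset_spacing`.
#'
#' @param trace a `joint_angle_trace` (degrees, dorsal positive).
#' @param row a [hair_row_config()].
#' @return numeric matrix, samples x hairs, of deflections in degrees.
#' @export
deflect_hairs <- function(trace, row) {
  stopifnot(inherits(trace, "joint_angle_trace"),
            inherits(row, "hair_row_config"))
  exc <- if (row$side == "dorsal") pmax(trace$angle, 0) else pmax(-trace$angle, 0)
  onsets <- (seq_len(row$n_hairs) - 1) * row$onset_spacing
  defl <- outer(exc, onsets, function(e, o) row$slope * (e - o))
  defl[defl < 0] <- 0
  defl[defl > row$max_deflection] <- row$max_deflection
  colnames(defl) <- sprintf("%s_%02d", substr(row$side, 1, 1), seq_len(row$n_hairs))
  defl
}

#' Lead-lag activation of a hair-field afferent
#'
#' Converts a hair-deflection trace into the afferent's activation
#' (an abstraction of its membrane potential):
#' `act = (lpf_weight * LPF(x) + hpf_weight * HPF(x) - offset) / norm`.
#' The low-pass carries the tonic, position-proportional component and the
#' high-pass the phasic, velocity-proportional component; with the default
#' parameters a sustained deflection of 50 degrees settles at
#' `(2 * 50 - 35)/100 = 0.65` and zero deflection at `-0.35` (below the spike
#' threshold of zero).
#'
#' Filters are initialized at steady state for the first sample, so protocols
#' that start mid-hold begin transient-free.
#'
#' @param deflection numeric vector of hair deflections (degrees, >= 0), or a
#'   `joint_angle_trace` whose `dt` must match `params$dt`.
#' @param params an [afferent_params()].
#' @return an `activation_trace` (dimensionless).
#' @export
lead_lag_activation <- function(deflection, params = afferent_params()) {
  if (inherits(deflection, "joint_angle_trace")) {
    if (abs(deflection$dt - params$dt) > 1e-12)
      stop("grid mismatch: trace dt != params dt", call. = FALSE)
    deflection <- deflection$angle
  }
  x <- as.numeric(deflection)
  act <- (params$lpf_weight * lpf_first_order(x, params$lpf_tau, params$dt) +
          params$hpf_weight * hpf_first_order(x, params$hpf_tau, params$dt) -
          params$offset) / params$norm
  new_activation_trace(act, dt = params$dt)
}

#' Noisy spike generator
#'
#' Bernoulli spike generation per time step: a spike is emitted at step k
#' with probability `p = min(max(act[k], 0) * dt * rmax, 1)`; after a spike,
#' the following `round(refractory/dt)` steps are absolutely refractory, so
#' the minimum inter-spike interval is `refractory + dt` and the maximal
#' attainable rate is `1/(refractory + dt)`. For constant activation `a` in
#' (0, 1] the long-run mean rate is `1/(refractory + dt/p)` with
#' `p = min(1, a * dt * rmax)`.
#'
#' Negative activation yields no spikes. Identical seeds give identical
#' trains.
#'
#' @param act an `activation_trace` or numeric vector.
#' @param rmax rate scale (1/s).
#' @param dt sample interval (s); taken from `act` if it is a trace.
#' @param refractory absolute refractory period (s), >= 0.
#' @param seed integer seed for this train (NULL: use current RNG stream).
#' @return a `spike_train`; spike times are the midpoint times of the spiking
#'   steps, in `[0, duration)`.
#' @export
generate_spike_train <- function(act, rmax, dt = NULL, refractory = 0,
                                 seed = NULL) {
  if (inherits(act, "activation_trace")) {
    if (is.null(dt)) dt <- act$dt
    act <- act$values
  }
  if (is.null(dt)) stop("`dt` must be supplied for a bare numeric activation",
                        call. = FALSE)
  stopifnot(rmax > 0, dt > 0, refractory >= 0)
  n <- length(act)
  p <- pmin(pmax(act, 0) * dt * rmax, 1)
  u <- with_seed(seed, stats::runif(n))
  cand <- which(u <= p & p > 0)
  r_steps <- as.integer(round(refractory / dt))
  if (r_steps > 0L && length(cand) > 1L) {
    keep <- logical(length(cand))
    last <- -Inf
    for (j in seq_along(cand)) {
      if (cand[j] - last > r_steps) {
        keep[j] <- TRUE
        last <- cand[j]
      }
    }
    cand <- cand[keep]
  }
  new_spike_train((cand - 0.5) * dt, duration = n * dt, dt = dt)
}

#' Simulate both hair fields
#'
#' Full afferent-population simulation: per-hair deflection
#' ([deflect_hairs()]), lead-lag activation ([lead_lag_activation()]) and
#' noisy spike generation ([generate_spike_train()]), independently for every
#' hair of a dorsal and a ventral row. Per-afferent random streams are derived
#' deterministically from the master seed (rule: `derive_seed(seed, row, i)`
#' with row 1 = dorsal, 2 = ventral), or can be supplied explicitly.
#'
#' To avoid onset artefacts in downstream spike-driven filters, the stimulus
#' is internally extended backwards by `settle` seconds of its initial value;
#' the returned traces and spike trains are cropped to the stimulus window,
#' but the full spike-count matrix is retained (internally) for DIN
#' integration.
#'
#' @param trace a `joint_angle_trace` on the `params$dt` grid.
#' @param params an [afferent_params()].
#' @param rows list of two [hair_row_config()]s (dorsal and ventral).
#' @param seed master integer seed.
#' @param seeds optional integer matrix/vector of per-afferent seeds
#'   (length `sum(n_hairs)`, dorsal row first); overrides `seed` splitting.
#' @param settle pre-roll duration in s (default 0.5) simulated at the
#'   initial joint angle and discarded from the outputs.
#' @return an object of class `afferent_population`: per-afferent metadata
#'   (`side`, `hair`, `onset_deg`), `activation` matrix (samples x afferents),
#'   list of `spike_train`s, the stimulus, and internal fields used by the
#'   DIN stage.
#' @export
simulate_hair_fields <- function(trace, params = afferent_params(),
                                 rows = list(hair_row_config("dorsal"),
                                             hair_row_config("ventral")),
                                 seed = 1L, seeds = NULL, settle = 0.5) {
  stopifnot(inherits(trace, "joint_angle_trace"), length(rows) == 2L)
  if (abs(trace$dt - params$dt) > 1e-12)
    stop("grid mismatch: trace dt != params dt", call. = FALSE)
  n_settle <- as.integer(round(settle / params$dt))
  ext <- new_joint_angle_trace(c(rep(trace$angle[1], n_settle), trace$angle),
                               dt = trace$dt, extreme = trace$extreme)
  n_full <- length(ext$angle)
  n_hairs_total <- sum(vapply(rows, function(r) r$n_hairs, integer(1)))
  if (!is.null(seeds) && length(seeds) != n_hairs_total)
    stop("`seeds` must have one entry per afferent", call. = FALSE)

  side <- character(0); hair <- integer(0); onset <- numeric(0)
  act_full <- matrix(0, n_full, n_hairs_total)
  counts_full <- matrix(0L, n_full, n_hairs_total)
  col <- 0L
  for (ri in seq_along(rows)) {
    row <- rows[[ri]]
    defl <- deflect_hairs(ext, row)
    for (i in seq_len(row$n_hairs)) {
      col <- col + 1L
      a <- lead_lag_activation(defl[, i], params)
      s <- if (is.null(seeds)) derive_seed(seed, ri, i) else seeds[col]
      st <- generate_spike_train(a, rmax = params$rmax, dt = params$dt,
                                 refractory = params$refractory, seed = s)
      act_full[, col] <- a$values
      steps <- as.integer(round(st$times / params$dt + 0.5))
      counts_full[steps, col] <- 1L
      side <- c(side, row$side)
      hair <- c(hair, i)
      onset <- c(onset, (i - 1) * row$onset_spacing)
    }
  }
  keep <- seq.int(n_settle + 1L, n_full)
  spikes <- lapply(seq_len(n_hairs_total), function(j) {
    steps <- which(counts_full[keep, j] == 1L)
    new_spike_train((steps - 0.5) * params$dt,
                    duration = length(keep) * params$dt, dt = params$dt)
  })
  structure(list(
    side = side, hair = hair, onset_deg = onset,
    activation = act_full[keep, , drop = FALSE],
    spikes = spikes,
    stimulus = trace, params = params, rows = rows,
    counts_full = counts_full, n_settle = n_settle
  ), class = "afferent_population")
}

#' @export
print.afferent_population <- function(x, ...) {
  nsp <- vapply(x$spikes, function(s) length(s$times), integer(1))
  cat(sprintf("<afferent_population> %d afferents (%d dorsal, %d ventral)\n",
              length(x$spikes), sum(x$side == "dorsal"),
              sum(x$side == "ventral")))
  cat(sprintf("  stimulus: %g s, total spikes: %d\n",
              length(x$stimulus$angle) * x$stimulus$dt, sum(nsp)))
  invisible(x)
}

#' Export afferent spike trains as a long-format CSV
#'
#' Columns: `afferent_id`, `side`, `onset_deg`, `spike_time_s`.
#' @param pop an `afferent_population`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(pop, path) {
  rows <- lapply(seq_along(pop$spikes), function(j) {
    t <- pop$spikes[[j]]$times
    if (!length(t)) return(NULL)
    data.frame(afferent_id = j, side = pop$side[j],
               onset_deg = pop$onset_deg[j], spike_time_s = t)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(afferent_id = integer(0), side = character(0),
                     onset_deg = numeric(0), spike_time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Single-sensillum amplitude and velocity tuning
#'
#' Runs deflect-and-return protocols on one modelled sensillum and summarizes
#' its phasic-tonic response: the mean sustained rate during the hold phase
#' as a function of deflection amplitude, and the peak rate (PSTH maximum
#' across repetitions) during the upward ramp as a function of deflection
#' velocity.
#'
#' @param amplitudes degrees, for the sustained-rate sweep (constant
#'   `amp_velocity`).
#' @param velocities degrees/s, for the peak-rate sweep (constant
#'   `vel_amplitude`).
#' @param params an [afferent_params()].
#' @param n_reps repetitions per condition for the PSTH (default 10).
#' @param amp_velocity ramp speed used in the amplitude sweep (default 50).
#' @param vel_amplitude deflection amplitude used in the velocity sweep
#'   (default 25).
#' @param psth_bin PSTH bin width in s (default 0.02).
#' @param hold_duration hold duration in s.
#' @param seed master seed.
#' @return list with data frames `amplitude` (`amplitude_deg`,
#'   `sustained_rate_hz`) and `velocity` (`velocity_deg_s`, `peak_rate_hz`).
#' @export
single_sensillum_tuning <- function(amplitudes = seq(5, 50, by = 5),
                                    velocities = c(25, 50, 90, 150, 250),
                                    params = afferent_params(), n_reps = 10,
                                    amp_velocity = 50, vel_amplitude = 25,
                                    psth_bin = 0.02, hold_duration = 1,
                                    seed = 1L) {
  stopifnot(length(amplitudes) > 0, length(velocities) > 0)
  sustained <- vapply(seq_along(amplitudes), function(ai) {
    amp <- amplitudes[ai]
    tr <- build_single_hair_protocol(amp, velocity = amp_velocity,
                                     hold_duration = hold_duration,
                                     dt = params$dt)
    act <- lead_lag_activation(tr, params)
    m_h <- as.integer(round(hold_duration / params$dt))
    m_r <- as.integer(round(amp / amp_velocity / params$dt))
    hold_idx <- seq.int(m_h + m_r + 1L, m_h + m_r + m_h)
    # skip the first 200 ms of the hold so the phasic transient has decayed
    hold_idx <- hold_idx[hold_idx > m_h + m_r + as.integer(round(0.2 / params$dt))]
    mean(vapply(seq_len(n_reps), function(r) {
      st <- generate_spike_train(act, rmax = params$rmax, dt = params$dt,
                                 refractory = params$refractory,
                                 seed = derive_seed(seed, 1, ai, r))
      steps <- as.integer(round(st$times / params$dt + 0.5))
      sum(steps %in% hold_idx) / (length(hold_idx) * params$dt)
    }, numeric(1)))
  }, numeric(1))

  peak <- vapply(seq_along(velocities), function(vi) {
    v <- velocities[vi]
    tr <- build_single_hair_protocol(vel_amplitude, velocity = v,
                                     hold_duration = hold_duration,
                                     dt = params$dt)
    act <- lead_lag_activation(tr, params)
    n <- length(act$values)
    bins <- ceiling(n * params$dt / psth_bin)
    counts <- numeric(bins)
    for (r in seq_len(n_reps)) {
      st <- generate_spike_train(act, rmax = params$rmax, dt = params$dt,
                                 refractory = params$refractory,
                                 seed = derive_seed(seed, 2, vi, r))
      b <- pmin(bins, floor(st$times / psth_bin) + 1L)
      counts <- counts + tabulate(b, nbins = bins)
    }
    max(counts) / (n_reps * psth_bin)
  }, numeric(1))

  list(amplitude = data.frame(amplitude_deg = amplitudes,
                              sustained_rate_hz = sustained),
       velocity = data.frame(velocity_deg_s = velocities,
                             peak_rate_hz = peak))
}
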
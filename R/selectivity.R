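## Selectivity statistics: signed contrasts s = (A - B)/(A + B) of mean spike
## rates between two classes of stimulus intervals, computed for direction
## (up- vs down-ramps), position (dorsal vs ventral ramps-and-holds) and
## motion (ramps vs holds), at several staircase velocities.

#' Signed selectivity score
#'
#' `s = (A - B)/(A + B)` for two mean spike rates, ranging continuously from
#' 1 (activity only in A) to -1 (activity only in B). If both rates are zero
#' the score is undefined; 0 is returned with attribute `valid = FALSE`.
#'
#' @param rate_A,rate_B mean spike rates (Hz, >= 0).
#' @return numeric score in `[-1, 1]` with attribute `valid`.
#' @examples
#' selectivity_score(30, 10) # 0.5
#' @export
selectivity_score <- function(rate_A, rate_B) {
  if (rate_A < 0 || rate_B < 0)
    stop("spike rates must be non-negative", call. = FALSE)
  if (rate_A + rate_B == 0)
    return(structure(0, valid = FALSE))
  structure((rate_A - rate_B) / (rate_A + rate_B), valid = TRUE)
}

## mean rate of spike steps over a set of sample indices
.rate_in <- function(steps, idx, dt) {
  if (!length(idx)) return(NA_real_)
  sum(steps %in% idx) / (length(idx) * dt)
}

#' Score one spike response against interval labels
#'
#' Computes the three selectivity scores of a spike train for a labelled
#' staircase stimulus:
#' * **direction**: A = mean rate over up-ramps (levation), B = down-ramps
#'   (depression); holds excluded.
#' * **position**: A contrasts the upper (dorsal) against the lower
#'   (ventral) half of the working range: A = mean of (rate over upper
#'   ramps, rate over dorsal holds), B = mean of (rate over lower ramps,
#'   rate over ventral holds); rest holds excluded. The movement and hold
#'   components enter with equal weight on both sides because the staircase
#'   contains two ventral holds but only one dorsal hold — pooling by time
#'   would give any movement-driven neuron a spurious positive position
#'   score purely from the unequal hold exposure. Dorsal-selective is
#'   positive.
#' * **motion**: A = all ramps, B = all holds. Movement-selective is positive.
#'
#' Mean rates may also be supplied pre-averaged across trials via
#' `rates`; see [characterize_neuron()].
#'
#' @param spikes a `spike_train` sharing the stimulus grid with `labels`.
#' @param labels an `interval_labels` from [segment_intervals()].
#' @return named numeric vector `c(direction, position, motion)` with
#'   attribute `valid` (logical vector; FALSE where both rates were zero).
#' @export
score_response <- function(spikes, labels) {
  stopifnot(inherits(spikes, "spike_train"), inherits(labels, "interval_labels"))
  if (abs(spikes$dt - labels$dt) > 1e-12)
    stop("spike train and labels are on different grids", call. = FALSE)
  steps <- as.integer(round(spikes$times / spikes$dt + 0.5))
  r <- interval_rates(steps, labels, labels$dt)
  score_from_rates(r)
}

## Minimum number of spikes that must fall in the contrasted intervals for a
## selectivity score to count as estimable. A signed contrast of rates
## estimated from fewer spikes is dominated by Bernoulli sampling noise
## (SE >= ~0.35 at 8 spikes), so such scores are reported as the neutral
## value 0 with validity flag FALSE — the same treatment the A + B = 0
## (undefined) case receives.
.min_score_spikes <- 8

## mean rates per interval class needed by the three scores
interval_rates <- function(steps, labels, dt) {
  lab <- labels$label
  up <- which(lab == "ramp_up")
  down <- which(lab == "ramp_down")
  ramps <- which(lab %in% c("ramp_up", "ramp_down"))
  holds <- which(lab %in% c("hold_ventral", "hold_rest", "hold_dorsal"))
  upper_ramps <- which(lab %in% c("ramp_up", "ramp_down") &
                         labels$half == "upper")
  lower_ramps <- which(lab %in% c("ramp_up", "ramp_down") &
                         labels$half == "lower")
  dorsal_holds <- which(lab == "hold_dorsal")
  ventral_holds <- which(lab == "hold_ventral")
  need <- list(up = up, down = down,
               upper_ramps = upper_ramps, dorsal_holds = dorsal_holds,
               lower_ramps = lower_ramps, ventral_holds = ventral_holds,
               ramps = ramps, holds = holds)
  if (any(!vapply(need, length, integer(1))))
    stop("stimulus is missing an interval class needed for scoring",
         call. = FALSE)
  rates <- vapply(need, .rate_in, numeric(1), steps = steps, dt = dt)
  counts <- vapply(need, function(idx) sum(steps %in% idx), numeric(1))
  names(counts) <- paste0("n_", names(need))
  c(rates, counts)
}

## scores from the per-class summaries (rates trial-averaged, counts summed)
score_from_rates <- function(r) {
  gated <- function(s, n) {
    if (n < .min_score_spikes) structure(0, valid = FALSE) else s
  }
  d <- gated(selectivity_score(r[["up"]], r[["down"]]),
             r[["n_up"]] + r[["n_down"]])
  p <- gated(selectivity_score((r[["upper_ramps"]] + r[["dorsal_holds"]]) / 2,
                               (r[["lower_ramps"]] + r[["ventral_holds"]]) / 2),
             r[["n_upper_ramps"]] + r[["n_dorsal_holds"]] +
               r[["n_lower_ramps"]] + r[["n_ventral_holds"]])
  m <- gated(selectivity_score(r[["ramps"]], r[["holds"]]),
             r[["n_ramps"]] + r[["n_holds"]])
  structure(c(direction = as.numeric(d), position = as.numeric(p),
              motion = as.numeric(m)),
            valid = c(direction = attr(d, "valid"),
                      position = attr(p, "valid"),
                      motion = attr(m, "valid")))
}

#' Characterize a neuron by 12 selectivity scores
#'
#' Runs a staircase at each of four velocities for `n_trials` trials,
#' averages the interval mean rates across trials, and scores each velocity,
#' yielding the neuron's 12-dimensional selectivity vector
#' (direction, position, motion at each velocity).
#'
#' @param simulate function `(trace, trial_seed) -> spike_train` running the
#'   neuron on a stimulus; see [din_simulator()] for the standard pathway
#'   simulator.
#' @param velocities four staircase velocities in degrees/s, each within
#'   `[12, 400]` (the analysis range; default `c(12, 50, 150, 400)`).
#' @param n_trials trials per velocity (default 4).
#' @param hold_duration,extreme,dt staircase parameters.
#' @param seed master seed; trial seeds are `derive_seed(seed, vi, trial)`.
#' @return an object of class `selectivity_vector`: named numeric vector of
#'   12 scores (`direction_v1..v4`, `position_v1..v4`, `motion_v1..v4`) with
#'   attributes `velocities` and `valid`.
#' @export
characterize_neuron <- function(simulate, velocities = c(12, 50, 150, 400),
                                n_trials = 4, hold_duration = 1, extreme = 50,
                                dt = 0.001, seed = 1L) {
  if (length(velocities) != 4L)
    stop("exactly four analysis velocities are required", call. = FALSE)
  if (any(velocities < 12 | velocities > 400))
    stop("analysis velocities must lie within [12, 400] degrees/s",
         call. = FALSE)
  per_v <- lapply(seq_along(velocities), function(vi) {
    tr <- build_staircase(velocities[vi], hold_duration = hold_duration,
                          extreme = extreme, dt = dt)
    lab <- segment_intervals(tr)
    rates <- vapply(seq_len(n_trials), function(trial) {
      st <- simulate(tr, derive_seed(seed, vi, trial))
      steps <- as.integer(round(st$times / st$dt + 0.5))
      interval_rates(steps, lab, dt)
    }, numeric(16))
    summ <- rowMeans(rates)
    # counts accumulate across trials; rates stay trial-averaged
    summ[9:16] <- summ[9:16] * n_trials
    score_from_rates(summ)
  })
  scores <- c(
    vapply(per_v, function(s) s[["direction"]], numeric(1)),
    vapply(per_v, function(s) s[["position"]], numeric(1)),
    vapply(per_v, function(s) s[["motion"]], numeric(1))
  )
  names(scores) <- c(paste0("direction_v", 1:4), paste0("position_v", 1:4),
                     paste0("motion_v", 1:4))
  valid <- unlist(lapply(per_v, attr, "valid"))
  structure(scores, velocities = velocities,
            valid = valid, class = "selectivity_vector")
}

#' Standard pathway simulator callback for [characterize_neuron()]
#'
#' Returns a closure `(trace, trial_seed) -> spike_train` that simulates the
#' full hair-field-to-DIN pathway for the given DIN parameters, with fresh
#' afferent noise per trial.
#'
#' @param params a [din_params()].
#' @param afferents an [afferent_params()].
#' @return a function usable as the `simulate` argument of
#'   [characterize_neuron()].
#' @export
din_simulator <- function(params, afferents = afferent_params()) {
  force(params); force(afferents)
  function(trace, trial_seed) {
    simulate_pathway(trace, params, afferents, seed = trial_seed)$spikes
  }
}
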
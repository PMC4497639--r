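## Stimulus protocols: ramp-and-hold staircases of the Sc-Pd joint angle and
## single-sensillum deflect-and-return protocols, plus exact interval
## segmentation.
##
## Sampling convention: a trace of n samples covers [t0, t0 + n*dt); sample k
## sits at the segment midpoint t0 + (k - 1/2)*dt. Midpoint sampling makes a
## spatio-temporally symmetric staircase trial exactly reversible
## sample-for-sample, and keeps every sample strictly inside one piecewise
## linear segment so segmentation is exact.

new_joint_angle_trace <- function(angle, dt, t0 = 0, extreme = NA_real_,
                                  velocity = NA_real_, protocol = "custom") {
  structure(
    list(angle = as.numeric(angle), dt = dt, t0 = t0, extreme = extreme,
         velocity = velocity, protocol = protocol),
    class = "joint_angle_trace"
  )
}

#' Sample times of a trace
#'
#' Midpoint sample times `t0 + (k - 1/2) dt` for a [joint_angle_trace] or any
#' object with `dt`, `t0` and a length.
#' @param x a `joint_angle_trace` or `activation_trace`.
#' @return numeric vector of times (s).
#' @export
trace_times <- function(x) {
  n <- length(x$angle %||% x$values)
  x$t0 + (seq_len(n) - 0.5) * x$dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## midpoint-sampled linear ramp from `from` to `to` over m samples
ramp_samples <- function(from, to, m) {
  if (m == 0L) return(numeric(0))
  from + (to - from) * (seq_len(m) - 0.5) / m
}

#' Build a ramp-and-hold staircase stimulus
#'
#' One trial holds the joint at the ventral extreme (-extreme), ramps to rest
#' (0), on to the dorsal extreme (+extreme), and back in the reverse sequence:
#' plateau sequence `[-extreme, 0, +extreme, 0, -extreme]` with two upward and
#' two downward constant-velocity ramps. The trial is symmetric in space and
#' time, so reversing the sample sequence reproduces it exactly. Trials are
#' concatenated back to back.
#'
#' Ramp and hold durations are rounded to an integer number of samples; the
#' realized slope is `extreme / (round(extreme/velocity/dt) * dt)`, which
#' equals the nominal velocity whenever the ramp duration is a multiple of
#' `dt`.
#'
#' @param velocity ramp speed in degrees/s (> 0).
#' @param hold_duration duration of each hold phase in s (default 1).
#' @param extreme amplitude of the excursion in degrees (default 50).
#' @param dt sample interval in s (default 0.001).
#' @param n_trials number of concatenated trials (default 1).
#' @return a `joint_angle_trace`: list with `angle` (degrees, dorsal
#'   positive), `dt`, `t0`, `extreme`, `velocity`.
#' @examples
#' tr <- build_staircase(100)
#' length(tr$angle) # 4 * 0.5 s ramps + 5 * 1 s holds = 7000 samples
#' @export
build_staircase <- function(velocity, hold_duration = 1, extreme = 50,
                            dt = 0.001, n_trials = 1) {
  if (!is.numeric(velocity) || velocity <= 0)
    stop("`velocity` must be a positive number (degrees/s)", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (extreme <= 0) stop("`extreme` must be positive", call. = FALSE)
  if (hold_duration <= 0) stop("`hold_duration` must be positive", call. = FALSE)
  m_r <- max(1L, as.integer(round(extreme / velocity / dt)))
  m_h <- max(1L, as.integer(round(hold_duration / dt)))
  e <- extreme
  trial <- c(
    rep(-e, m_h), ramp_samples(-e, 0, m_r),
    rep(0, m_h),  ramp_samples(0, e, m_r),
    rep(e, m_h),  ramp_samples(e, 0, m_r),
    rep(0, m_h),  ramp_samples(0, -e, m_r),
    rep(-e, m_h)
  )
  # enforce bit-exact spatio-temporal symmetry (construction is symmetric up
  # to floating-point rounding of the two ramp directions)
  trial <- (trial + rev(trial)) / 2
  new_joint_angle_trace(rep(trial, n_trials), dt = dt, extreme = extreme,
                        velocity = velocity, protocol = "staircase")
}

#' Build a single-hair deflect-and-return protocol
#'
#' Deflection protocol for one sensillum: zero, ramp up at `velocity` to
#' `amplitude`, hold, ramp down, zero. Used for amplitude and velocity tuning
#' of a single afferent.
#'
#' @param amplitude deflection amplitude in degrees (>= 0); 0 gives a
#'   constant-zero trace.
#' @param velocity ramp speed in degrees/s (> 0).
#' @param hold_duration duration of the hold at `amplitude` and of the
#'   leading/trailing zero segments, in s.
#' @param dt sample interval in s.
#' @return a `joint_angle_trace` (interpreted as hair deflection, degrees).
#' @export
build_single_hair_protocol <- function(amplitude, velocity = 50,
                                       hold_duration = 1, dt = 0.001) {
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("`amplitude` must be >= 0 degrees", call. = FALSE)
  if (velocity <= 0) stop("`velocity` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  m_h <- max(1L, as.integer(round(hold_duration / dt)))
  m_r <- as.integer(round(amplitude / velocity / dt))
  ang <- c(
    rep(0, m_h), ramp_samples(0, amplitude, m_r),
    rep(amplitude, m_h), ramp_samples(amplitude, 0, m_r),
    rep(0, m_h)
  )
  new_joint_angle_trace(ang, dt = dt, extreme = amplitude, velocity = velocity,
                        protocol = "single_hair")
}

#' Segment a piecewise-linear trace into labelled intervals
#'
#' Labels every sample of a staircase-type trace as one of `ramp_up`,
#' `ramp_down`, `hold_ventral`, `hold_rest`, `hold_dorsal`, and tags ramps
#' with the half-range they span (`lower` for `[-extreme, 0]`, `upper` for
#' `[0, +extreme]`).
#'
#' Segmentation works on per-gap slopes. Interior gaps of a ramp carry the
#' full slope; the two gaps straddling a segment boundary carry half of it
#' (midpoint sampling). A sample is a ramp sample iff it touches at least one
#' full-slope gap, which recovers the generating segments exactly.
#'
#' @param trace a `joint_angle_trace` produced by [build_staircase()] (or any
#'   piecewise-linear trace alternating ramps and holds).
#' @param slope_tolerance gaps with |slope| below this (degrees/s) count as
#'   stationary; default 0.5, below the slowest velocity in use.
#' @return an object of class `interval_labels`: list with `label` (factor,
#'   one per sample), `half` (`"lower"`/`"upper"`/`NA`), `interval_id`
#'   (integer run id), and the trace's `dt`.
#' @examples
#' lab <- segment_intervals(build_staircase(100))
#' table(lab$label)
#' @export
segment_intervals <- function(trace, slope_tolerance = 0.5) {
  stopifnot(inherits(trace, "joint_angle_trace"))
  ang <- trace$angle
  n <- length(ang)
  if (n < 2L) {
    lab <- factor(rep("hold_rest", n),
                  levels = c("ramp_up", "ramp_down", "hold_ventral",
                             "hold_rest", "hold_dorsal"))
    return(structure(list(label = lab, half = rep(NA_character_, n),
                          interval_id = rep(1L, n), dt = trace$dt),
                     class = "interval_labels"))
  }
  slopes <- diff(ang) / trace$dt
  moving <- abs(slopes) > slope_tolerance
  if (any(moving)) {
    vmax <- max(abs(slopes))
    full <- abs(slopes) > 0.75 * vmax  # interior ramp gaps (boundary gaps ~ vmax/2)
    if (!any(full))
      stop("trace is not piecewise linear with distinct ramps and holds",
           call. = FALSE)
  } else {
    full <- moving
  }
  is_ramp <- c(full, FALSE) | c(FALSE, full)  # touches a full-slope gap
  # sign of each ramp sample's local slope
  up <- logical(n)
  pos_gap <- c(full & slopes > 0, FALSE) | c(FALSE, full & slopes > 0)
  up[is_ramp] <- pos_gap[is_ramp]

  extreme <- trace$extreme
  if (is.na(extreme)) extreme <- max(abs(ang))
  label <- character(n)
  label[is_ramp & up] <- "ramp_up"
  label[is_ramp & !up] <- "ramp_down"
  hold_idx <- which(!is_ramp)
  label[hold_idx] <- ifelse(ang[hold_idx] > extreme / 2, "hold_dorsal",
                     ifelse(ang[hold_idx] < -extreme / 2, "hold_ventral",
                            "hold_rest"))
  # consistency: hold samples must sit on (near-)constant plateaus
  if (length(hold_idx)) {
    runs <- split(hold_idx, cumsum(c(1L, diff(hold_idx) != 1L)))
    for (r in runs) {
      if (diff(range(ang[r])) > max(1e-9, slope_tolerance * trace$dt * 2))
        stop("trace is not piecewise linear: non-constant hold plateau",
             call. = FALSE)
    }
  }
  interval_id <- cumsum(c(1L, as.integer(label[-1] != label[-n])))
  half <- rep(NA_character_, n)
  for (id in unique(interval_id[is_ramp])) {
    idx <- which(interval_id == id)
    half[idx] <- if (mean(ang[idx]) < 0) "lower" else "upper"
  }
  structure(list(label = factor(label,
                                levels = c("ramp_up", "ramp_down",
                                           "hold_ventral", "hold_rest",
                                           "hold_dorsal")),
                 half = half, interval_id = interval_id, dt = trace$dt),
            class = "interval_labels")
}

#' @export
print.joint_angle_trace <- function(x, ...) {
  cat(sprintf(
    "<joint_angle_trace> %s protocol: %d samples, dt = %g s, duration = %g s\n",
    x$protocol, length(x$angle), x$dt, length(x$angle) * x$dt))
  cat(sprintf("  angle range [%g, %g] deg, nominal velocity %g deg/s\n",
              min(x$angle), max(x$angle), x$velocity))
  invisible(x)
}

#' @export
plot.joint_angle_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$angle, type = "l",
                 xlab = "time (s)", ylab = "Sc-Pd joint angle (deg)", ...)
  invisible(x)
}

#' Export a joint-angle trace as a two-column CSV
#'
#' Writes `time_s, angle_deg`.
#' @param trace a `joint_angle_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace_times(trace), angle_deg = trace$angle),
    path, row.names = FALSE)
  invisible(path)
}
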
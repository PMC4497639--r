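#' First-order low-pass filter (exponential update)
#'
#' Discrete first-order low-pass on a uniform grid, using the exact
#' exponential-integrator update
#' `y[k] = y[k-1] + (1 - exp(-dt/tau)) * (x[k] - y[k-1])`,
#' which matches the continuous first-order response at the sample points
#' for piecewise-constant input and is unconditionally stable.
#'
#' @param x numeric input signal.
#' @param tau time constant (s), > 0.
#' @param dt sample interval (s), > 0.
#' @param init initial filter state `y[0]`; defaults to `x[1]`, i.e. steady
#'   state for the initial input value, so a protocol that starts mid-hold
#'   produces no spurious onset transient.
#' @return numeric vector, same length as `x`.
#' @seealso [hpf_first_order()]
#' @export
lpf_first_order <- function(x, tau, dt, init = x[1]) {
  stopifnot(tau > 0, dt > 0)
  if (length(x) == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive", init = init))
}

#' First-order high-pass filter
#'
#' Complement of the first-order low-pass on the same grid:
#' `y = x - lpf(x, tau)`. DC gain is zero; for a long constant-velocity ramp
#' of slope v the output settles at `v * dt * a / (1 - a)` with
#' `a = exp(-dt/tau)` (the discrete analogue of the continuous `tau * v`).
#'
#' @inheritParams lpf_first_order
#' @return numeric vector, same length as `x`.
#' @export
hpf_first_order <- function(x, tau, dt, init = x[1]) {
  x - lpf_first_order(x, tau, dt, init = init)
}

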
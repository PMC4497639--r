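# Closed-form oracles used across tests, derived independently of the
# package's filter implementation (plain difference-equation algebra).

# steady-state lag of the discrete first-order low-pass behind a ramp of
# slope v: L = v * dt * (1 - alpha)/alpha with alpha = 1 - exp(-dt/tau)
ramp_lag <- function(v, tau, dt) {
  a <- 1 - exp(-dt / tau)
  v * dt * (1 - a) / a
}

# expected mean rate of the Bernoulli spike generator at constant activation
# a: p = min(1, a*dt*rmax) per step, refractory blocks r = round(refr/dt)
# steps after each spike, so E[ISI] = r*dt + dt/p
expected_rate <- function(a, rmax, dt, refractory = 0) {
  p <- min(1, max(0, a) * dt * rmax)
  if (p == 0) return(0)
  1 / (round(refractory / dt) * dt + dt / p)
}

# binomial-ish standard error of a rate estimated from a duration T
rate_se <- function(rate, T) sqrt(rate / T)

# interval sample indices by label
label_idx <- function(labels, what) {
  switch(what,
    ramps = which(labels$label %in% c("ramp_up", "ramp_down")),
    holds = which(!(labels$label %in% c("ramp_up", "ramp_down"))),
    which(labels$label == what)
  )
}

# rate of a spike train over a set of sample indices
rate_over <- function(st, idx) {
  steps <- round(st$times / st$dt + 0.5)
  sum(steps %in% idx) / (length(idx) * st$dt)
}

# steady-state hold indices: drop the first `drop_s` seconds of every hold
steady_hold_idx <- function(labels, drop_s = 0.3) {
  hold <- which(!(labels$label %in% c("ramp_up", "ramp_down")))
  runs <- split(hold, cumsum(c(1, diff(hold) != 1)))
  drop_n <- round(drop_s / labels$dt)
  unlist(lapply(runs, function(r) r[-seq_len(min(drop_n, length(r)))]),
         use.names = FALSE)
}
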
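test_that("hair deflection maps joint angle per hair geometry", {
  dor <- hair_row_config("dorsal")
  ven <- hair_row_config("ventral")
  # at rest every hair of both rows is undeflected
  rest <- dinsim:::new_joint_angle_trace(rep(0, 10), dt = 0.001, extreme = 50)
  expect_true(all(deflect_hairs(rest, dor) == 0))
  expect_true(all(deflect_hairs(rest, ven) == 0))
  # ventral hairs stay undeflected in the dorsal range and vice versa
  up <- dinsim:::new_joint_angle_trace(rep(50, 5), dt = 0.001, extreme = 50)
  expect_true(all(deflect_hairs(up, ven) == 0))
  d <- deflect_hairs(up, dor)
  # onset 47.5 deg hair deflected by 2.5 deg; onset-0 hair at the ceiling
  expect_equal(unname(d[1, 20]), 2.5)
  expect_equal(unname(d[1, 1]), 50)
  # deflection grows linearly past onset with slope 1
  mid <- dinsim:::new_joint_angle_trace(rep(20, 5), dt = 0.001, extreme = 50)
  dm <- deflect_hairs(mid, dor)
  expect_equal(unname(dm[1, ]), pmax(20 - (0:19) * 2.5, 0))
  # saturation ceiling is respected
  row2 <- hair_row_config("dorsal", max_deflection = 10)
  expect_equal(max(deflect_hairs(up, row2)), 10)
})

test_that("lead-lag activation matches first-order closed forms", {
  ap <- afferent_params()
  # zero deflection pins activation at -offset/norm = -0.35 (below threshold)
  a0 <- lead_lag_activation(rep(0, 100), ap)
  expect_equal(a0$values, rep(-0.35, 100))
  # sustained deflection: LPF -> steady value, HPF -> 0
  a1 <- lead_lag_activation(rep(50, 4000), ap)
  expect_equal(tail(a1$values, 1), (2 * 50 - 35) / 100, tolerance = 1e-9)
  # constant-velocity ramp: HPF settles at its discrete ramp-lag closed form
  v <- 100
  x <- c(rep(0, 10), v * 0.001 * seq_len(5000))
  ar <- lead_lag_activation(x, ap)
  expected <- (2 * (tail(x, 1) - ramp_lag(v, 0.01, 0.001)) +
                 20 * ramp_lag(v, 0.03, 0.001) - 35) / 100
  expect_equal(tail(ar$values, 1), expected, tolerance = 1e-6)
  # dt mismatch between trace and params is refused
  tr <- build_staircase(100, dt = 0.002)
  expect_error(lead_lag_activation(tr, ap), "grid mismatch")
})

test_that("spike generator obeys its Bernoulli-with-refractoriness law", {
  # no spikes at non-positive activation
  expect_length(generate_spike_train(rep(-0.2, 5000), rmax = 300, dt = 0.001,
                                     seed = 1)$times, 0L)
  expect_length(generate_spike_train(rep(0, 5000), rmax = 300, dt = 0.001,
                                     seed = 1)$times, 0L)
  # rate oracle without refractoriness: act 1, Rmax 300 -> 300 Hz over 60 s
  st <- generate_spike_train(rep(1, 60000), rmax = 300, dt = 0.001,
                             refractory = 0, seed = 42)
  expect_lt(abs(spike_rate(st) - 300), 3 * rate_se(300, 60))
  # with the 3 ms refractory period: 1/(0.003 + dt/0.3) ~ 158 Hz
  st2 <- generate_spike_train(rep(1, 60000), rmax = 300, dt = 0.001,
                              refractory = 0.003, seed = 42)
  r_exp <- expected_rate(1, 300, 0.001, 0.003)
  expect_lt(abs(spike_rate(st2) - r_exp), 3 * rate_se(r_exp, 60))
  # minimum ISI = refractory + dt; max rate capped at 1/(refractory + dt)
  expect_gte(min(diff(st2$times)), 0.003)
  st3 <- generate_spike_train(rep(10, 60000), rmax = 300, dt = 0.001,
                              refractory = 0.003, seed = 7)
  expect_lte(spike_rate(st3), 1 / 0.004 + 1e-9)
  # partial activations follow the same law (3 SE over 60 s)
  for (a in c(0.25, 0.6)) {
    sta <- generate_spike_train(rep(a, 60000), rmax = 300, dt = 0.001,
                                refractory = 0.003, seed = 100 + a * 100)
    re <- expected_rate(a, 300, 0.001, 0.003)
    expect_lt(abs(spike_rate(sta) - re), 3 * rate_se(re, 60))
  }
  # per-step probability is clipped at 1: enormous activation fires every step
  st4 <- generate_spike_train(rep(100, 1000), rmax = 300, dt = 0.001,
                              refractory = 0, seed = 3)
  expect_length(st4$times, 1000L)
  # identical seeds give identical trains
  expect_identical(
    generate_spike_train(rep(0.5, 5000), 300, dt = 0.001, seed = 11)$times,
    generate_spike_train(rep(0.5, 5000), 300, dt = 0.001, seed = 11)$times)
})

test_that("hair-field population: geometry, rest silence, cascaded onsets", {
  tr <- build_staircase(100)
  pop <- simulate_hair_fields(tr, seed = 5)
  expect_length(pop$spikes, 40L)
  expect_equal(sum(pop$side == "dorsal"), 20L)
  lab <- segment_intervals(tr)
  rest <- label_idx(lab, "hold_rest")
  # no afferent fires while the joint rests at 0 degrees
  for (st in pop$spikes) expect_equal(rate_over(st, rest), 0)
  # every train respects the afferent refractory period
  for (st in pop$spikes) {
    if (length(st$times) > 1) expect_gte(min(diff(st$times)), 0.003)
  }
  # cascaded onsets: during the rest->dorsal ramp, proximal dorsal hairs
  # start firing before distal ones
  up_upper <- which(lab$label == "ramp_up" & lab$half == "upper")
  t0 <- min(up_upper) * 0.001
  first_spike <- vapply(which(pop$side == "dorsal"), function(j) {
    t <- pop$spikes[[j]]$times
    t <- t[t >= t0]
    if (length(t)) t[1] else NA_real_
  }, numeric(1))
  ok <- !is.na(first_spike)
  expect_gt(cor(pop$onset_deg[pop$side == "dorsal"][ok], first_spike[ok]), 0.9)
  # distal hairs never reach the proximal activation ceiling
  expect_lt(max(pop$activation[, 20]), max(pop$activation[, 1]))
})

test_that("phasic-tonic structure: deflection transients exceed tonic activation", {
  # while a hair is being deflected, the high-pass (phasic) component adds
  # to the low-pass (tonic) one, so the activation at the end of the rising
  # ramp exceeds the sustained activation reached later during the hold --
  # for every deflection velocity of interest (the release transient is the
  # mirror image and suppresses the afferent below its tonic rate)
  ap <- afferent_params()
  for (v in c(25, 100, 400)) {
    tr <- build_single_hair_protocol(25, velocity = v)
    lab <- segment_intervals(tr)
    act <- lead_lag_activation(tr, ap)
    up <- which(lab$label == "ramp_up")
    hold_late <- tail(which(lab$label == "hold_dorsal" |
                              (lab$label == "hold_rest" &
                                 tr$angle == max(tr$angle))), 100)
    hold_late <- seq(max(up) + 500, max(up) + 600)
    expect_gt(max(act$values[up]), mean(act$values[hold_late]))
    expect_lt(min(act$values[which(lab$label == "ramp_down")]),
              mean(act$values[hold_late]))
  }
})

test_that("mirror symmetry: negated stimulus with swapped rows and seeds", {
  tr <- build_staircase(200)
  neg <- dinsim:::new_joint_angle_trace(-tr$angle, dt = tr$dt,
                                        extreme = tr$extreme)
  seeds <- vapply(seq_len(40), function(i) derive_seed(9, i), integer(1))
  pop <- simulate_hair_fields(tr, seeds = seeds, seed = 9)
  # swapped rows + swapped per-hair seeds on the negated stimulus
  pop2 <- simulate_hair_fields(neg, seeds = c(seeds[21:40], seeds[1:20]),
                               seed = 9)
  for (j in 1:20) {
    expect_identical(pop$spikes[[j]]$times, pop2$spikes[[j + 20]]$times)
    expect_identical(pop$spikes[[j + 20]]$times, pop2$spikes[[j]]$times)
  }
})

test_that("full population simulation is deterministic under a fixed seed", {
  tr <- build_staircase(300)
  p1 <- simulate_hair_fields(tr, seed = 123)
  p2 <- simulate_hair_fields(tr, seed = 123)
  expect_identical(lapply(p1$spikes, `[[`, "times"),
                   lapply(p2$spikes, `[[`, "times"))
  expect_identical(p1$activation, p2$activation)
})

test_that("single-sensillum tuning: sustained rate monotone, peak linear in velocity", {
  tun <- single_sensillum_tuning(amplitudes = c(10, 20, 30, 40, 50),
                                 velocities = c(25, 50, 90, 150, 250),
                                 n_reps = 8, seed = 21)
  expect_true(all(diff(tun$amplitude$sustained_rate_hz) >= 0))
  fit <- lm(peak_rate_hz ~ velocity_deg_s, data = tun$velocity)
  expect_gt(summary(fit)$r.squared, 0.9)
  # zero-amplitude protocol never spikes
  tun0 <- single_sensillum_tuning(amplitudes = 0, velocities = 50,
                                  n_reps = 2, seed = 1)
  expect_equal(tun0$amplitude$sustained_rate_hz, 0)
})
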
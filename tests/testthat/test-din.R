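# build a minimal synthetic afferent population with prescribed per-step
# spike counts, for closed-form checks of the DIN input stage
fake_population <- function(counts_d, counts_v, dt = 0.001, settle_n = 0L) {
  n <- length(counts_d)
  counts <- cbind(matrix(counts_d, n, 1), matrix(counts_v, n, 1))
  structure(list(
    side = c("dorsal", "ventral"), hair = c(1L, 1L), onset_deg = c(0, 0),
    activation = matrix(0, n - settle_n, 2),
    spikes = list(), stimulus = dinsim:::new_joint_angle_trace(
      rep(0, n - settle_n), dt = dt, extreme = 50),
    params = afferent_params(dt = dt),
    counts_full = counts, n_settle = settle_n
  ), class = "afferent_population")
}

test_that("afferent integration follows the unit-DC-gain low-pass law", {
  # silence integrates to zero
  z <- integrate_afferent_input(fake_population(rep(0L, 1000), rep(0L, 1000)))
  expect_equal(z$values, rep(0, 1000))
  # wd = 0 silences dorsal-only drive
  d <- integrate_afferent_input(fake_population(rep(1L, 1000), rep(0L, 1000)),
                                wd = 0, wv = 1)
  expect_equal(d$values, rep(0, 1000))
  # steady drive at total rate R settles at R*dt (here a deterministic
  # 1-spike-per-step train: mean input -> 1); weights scale linearly
  s <- integrate_afferent_input(fake_population(rep(1L, 3000), rep(1L, 3000)),
                                wd = 2, wv = 1)
  expect_equal(tail(s$values, 1), 3, tolerance = 1e-6)
  # stochastic oracle: k afferents at rate r -> mean ~ k*r*dt over a long run
  k <- 10; r <- 100; nsteps <- 60000
  cnt <- dinsim:::with_seed(31, rbinom(nsteps, k, r * 0.001))
  inp <- integrate_afferent_input(fake_population(cnt, rep(0L, nsteps)))
  expect_equal(mean(inp$values[-(1:100)]), k * r * 0.001, tolerance = 0.02)
})

test_that("DIN branch realizes the documented variant algebra", {
  dt <- 0.001
  # constant input + ON params: band-pass kills DC, activation -> offset
  on <- din_preset("ON")
  b <- din_branch(rep(5, 4000), on, dt = dt)
  expect_equal(tail(b$values, 1), -0.2, tolerance = 1e-6)
  # zero input + OFF params: activation identically 1 -> 30 Hz baseline
  off <- din_preset("OFF")
  b0 <- din_branch(rep(0, 1000), off, dt = dt)
  expect_equal(b0$values, rep(1, 1000))
  # falling input: unrectified branch goes negative, abs flips it to equal
  # magnitude, neg_abs to equal negative magnitude
  x <- c(rep(4, 1000), rep(0, 1000))
  ex <- din_preset("Ex.DP"); ex$offset <- 0
  on0 <- din_preset("ON"); on0$offset <- 0
  off0 <- din_preset("OFF"); off0$offset <- 0; off0$norm <- 20
  raw <- din_branch(x, ex, dt = dt)$values
  expect_lt(min(raw[1001:1200]), -0.05)
  expect_equal(din_branch(x, on0, dt = dt)$values, abs(raw))
  expect_equal(din_branch(x, off0, dt = dt)$values, -abs(raw))
  # OFF's effective drive is half of ON's for identical input (norm 40 vs 20)
  y <- c(rep(0, 500), rep(6, 1500))
  drive_on <- din_branch(y, on, dt = dt)$values - on$offset
  drive_off <- din_branch(y, off, dt = dt)$values - off$offset
  expect_equal(drive_off, -drive_on / 2, tolerance = 1e-9)
  # SP variant bypasses the branch entirely: input / norm
  sp <- din_preset("SP_d")
  expect_equal(din_branch(y, sp, dt = dt)$values, y / 4)
})

test_that("DIN presets carry the reference parameter table", {
  on <- din_preset("ON")
  expect_equal(c(on$lpf1_tau, on$lpf2_tau, on$hpf_tau), c(0.005, 0.05, 0.04))
  expect_equal(c(on$offset, on$norm, on$rmax), c(-0.2, 20, 120))
  expect_equal(on$rectify, "abs")
  off <- din_preset("OFF")
  expect_equal(c(off$offset, off$norm, off$rmax), c(1, 40, 30))
  expect_equal(off$rectify, "neg_abs")
  sp <- din_preset("SP_v")
  expect_false(sp$use_branch)
  expect_equal(c(sp$wd, sp$wv, sp$norm, sp$rmax), c(0, 1, 4, 10))
  expect_equal(din_preset("Ex.DP")$rectify, "none")
  expect_error(din_preset("XX"), "SP_d.*Ex.DP")
})

test_that("DIN phenotypes on the staircase match their defining patterns", {
  tr <- build_staircase(150)
  lab <- segment_intervals(tr)
  pop <- simulate_hair_fields(tr, seed = 41)
  ramps <- label_idx(lab, "ramps")
  steady <- steady_hold_idx(lab)
  # ON fires on every ramp and is silent in steady holds
  on <- simulate_din(pop, din_preset("ON"), seed = 42)
  per_ramp <- tapply(seq_along(ramps) > 0, lab$interval_id[ramps], sum)
  steps_on <- round(on$spikes$times / 0.001 + 0.5)
  ramp_ids <- unique(lab$interval_id[ramps])
  for (id in ramp_ids)
    expect_gt(sum(steps_on %in% which(lab$interval_id == id)), 0)
  expect_lt(rate_over(on$spikes, steady), 0.05 * rate_over(on$spikes, ramps))
  # simple position-sensitive: fires in its half-range only
  spd <- simulate_din(pop, din_preset("SP_d"), seed = 43)
  sp_steps <- round(spd$spikes$times / 0.001 + 0.5)
  expect_gte(mean(tr$angle[sp_steps] >= 0), 0.95)
  # dynamic position-sensitive: movement-only, dorsal-range only
  dpd <- simulate_din(pop, din_preset("DP_d"), seed = 44)
  dp_steps <- round(dpd$spikes$times / 0.001 + 0.5)
  expect_gte(mean(tr$angle[dp_steps] >= 0), 0.95)
  expect_lt(rate_over(dpd$spikes, steady), 0.05 * rate_over(dpd$spikes, ramps))
  # Ex.DP fires on away-from-rest ramps, not on return ramps
  ex <- simulate_din(pop, din_preset("Ex.DP"), seed = 45)
  away <- which((lab$label == "ramp_up" & lab$half == "upper") |
                  (lab$label == "ramp_down" & lab$half == "lower"))
  toward <- setdiff(ramps, away)
  expect_gt(rate_over(ex$spikes, away), 10)
  expect_lt(rate_over(ex$spikes, toward), 0.05 * rate_over(ex$spikes, away))
  # RANDOM bypasses the pathway at its constant activation (~20 Hz)
  rnd <- simulate_din(pop, din_preset("RANDOM"), seed = 46)
  expect_lt(abs(spike_rate(rnd$spikes) - 20), 3 * rate_se(20, rnd$spikes$duration))
})

test_that("mirrored stimulus with swapped weights mirrors the DIN response", {
  tr <- build_staircase(200)
  neg <- dinsim:::new_joint_angle_trace(-tr$angle, dt = tr$dt, extreme = 50)
  seeds <- vapply(seq_len(40), function(i) derive_seed(77, i), integer(1))
  pop <- simulate_hair_fields(tr, seeds = seeds, seed = 77)
  pop_m <- simulate_hair_fields(neg, seeds = c(seeds[21:40], seeds[1:20]),
                                seed = 77)
  p <- din_preset("DP_d")
  p_sw <- din_preset("DP_d"); p_sw$wd <- 0; p_sw$wv <- 1
  r1 <- simulate_din(pop, p, seed = 88)
  r2 <- simulate_din(pop_m, p_sw, seed = 88)
  expect_identical(r1$spikes$times, r2$spikes$times)
})

test_that("velocity tuning trends: ON increases, OFF is suppressed with velocity", {
  vt_on <- velocity_tuning(din_preset("ON"), seed = 1)
  expect_true(all(diff(vt_on$mean_rate_hz) > 0))
  vt_off <- velocity_tuning(din_preset("OFF"), seed = 1)
  # declining movement-window rate: negative trend in log velocity and a
  # clear endpoint contrast (see the vignette on why strict adjacent
  # ordering is not resolvable at n = 4 sweeps)
  slope <- coef(lm(vt_off$mean_rate_hz ~ log(vt_off$velocity_deg_s)))[2]
  expect_lt(slope, 0)
  expect_lt(vt_off$mean_rate_hz[4], vt_off$mean_rate_hz[1])
  expect_true(all(vt_off$window == "ramps"))
})
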
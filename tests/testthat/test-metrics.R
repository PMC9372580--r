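test_that("per-leg RMS means honour the edge-phase mask", {
  mask <- edge_phase_mask()
  expect_equal(turn_rms_pct(rep(40, 200), mask), c(IL = 40, OL = 40))
  # masked points do not contribute
  env <- numeric(200); env[mask] <- 60
  expect_equal(turn_rms_pct(env, mask), c(IL = 60, OL = 60))
  # fully masked half flags an undefined value
  expect_true(all(is.na(turn_rms_pct(rep(1, 200), rep(FALSE, 200)))))
  expect_error(turn_rms_pct(rep(1, 200), mask[1:100]), "length")
})

test_that("mean power frequency matches spectral-line closed forms", {
  rate <- 1926
  t <- seq(0, 1, by = 1 / rate)
  expect_lt(abs(turn_mpf(sin(2 * pi * 80 * t), rate) - 80), 1)
  two <- sin(2 * pi * 60 * t) + sin(2 * pi * 100 * t)
  expect_lt(abs(turn_mpf(two, rate) - 80), 1)
  expect_true(is.na(turn_mpf(numeric(64), rate)))   # too short
  expect_true(is.na(turn_mpf(numeric(500), rate)))  # zero power
  # MPF of any band-passed signal stays in the analysis band
  set.seed(3)
  for (i in 1:5) {
    x <- bandpass_emg(rnorm(4000), rate)
    m <- turn_mpf(x, rate)
    expect_gte(m, 20); expect_lte(m, 500)
  }
})

test_that("activation time sums supra-threshold periods", {
  rate <- 1000
  # constant 30 %MVC across a 800-ms turn: fully active
  env <- rep(30, 1000)
  expect_equal(activation_time(env, rate, 0.1, 0.9),
               c(burst_ms = 800, burst_pct = 100), tolerance = 1e-6)
  # everywhere below threshold
  expect_equal(activation_time(rep(10, 1000), rate, 0.1, 0.9),
               c(burst_ms = 0, burst_pct = 0))
  # square burst at 25 %MVC covering 400 of 800 ms
  env <- rep(0, 1000); env[301:700] <- 25
  bt <- activation_time(env, rate, 0.1, 0.9)
  expect_equal(unname(bt["burst_ms"]), 400, tolerance = 2)
  expect_equal(unname(bt["burst_pct"]), 50, tolerance = 0.5)
  # two supra-threshold intervals are summed
  env <- rep(0, 1000); env[201:300] <- 30; env[601:700] <- 30
  expect_equal(unname(activation_time(env, rate, 0.1, 0.9)["burst_ms"]),
               200, tolerance = 2)
})

test_that("turn and run timing are exact interval arithmetic", {
  expect_equal(turn_times(c(1.0, 1.8, 2.7)), c(800, 900))
  expect_error(turn_times(1.0), "2 switches")
  expect_equal(run_time(10.0, 44.9), 34.9)
})

test_that("kinematic scalars match the sinusoid closed form", {
  rate <- 148
  t <- seq(0, 10, by = 1 / rate)
  ang <- 120 + 15 * sin(2 * pi * 0.6 * t)
  vel <- angular_velocity(ang, rate)
  ks <- kinematic_scalars(ang, vel, rate, 1, 9)
  expect_equal(unname(ks["min_angle_deg"]), 105, tolerance = 0.05)
  expect_equal(unname(ks["max_angle_deg"]), 135, tolerance = 0.05)
  aw <- 15 * 2 * pi * 0.6
  expect_lt(abs(ks[["peak_ext_vel_dps"]] - aw) / aw, 0.02)
  expect_lt(abs(ks[["peak_flex_vel_dps"]] + aw) / aw, 0.02)
  # constant angle: zero amplitude and velocities
  ks0 <- kinematic_scalars(rep(120, 1481), numeric(1481), rate, 1, 9)
  expect_identical(unname(ks0["max_angle_deg"] - ks0["min_angle_deg"]), 0)
  expect_identical(unname(ks0[c("peak_flex_vel_dps", "peak_ext_vel_dps")]),
                   c(0, 0))
  # monotone extension ramp has no flexion phase
  ramp <- 100 + 5 * t
  ksr <- kinematic_scalars(ramp, angular_velocity(ramp, rate), rate, 1, 9)
  expect_identical(unname(ksr["peak_flex_vel_dps"]), 0)
  expect_gt(ksr[["peak_ext_vel_dps"]], 4.9)
})

test_that("burst cut-off table and run selection follow the rules", {
  expect_identical(c(burst_cutoff_hz("DH"), burst_cutoff_hz("SG"),
                     burst_cutoff_hz("GS"), burst_cutoff_hz("SL")),
                   c(1, 2, 4, 7))
  mk <- function(idx, complete) data.frame(run_index = idx,
                                           start_s = idx * 100,
                                           end_s = idx * 100 + 40,
                                           complete = complete)
  # all four runs complete: First = 1, Last = 4
  sel <- select_runs(mk(1:4, TRUE))
  expect_identical(sel$runs, c(1L, 4L))
  expect_identical(sel$labels, c("First", "Last"))
  # incomplete first run: fall over to runs 2 and 5
  sel2 <- select_runs(mk(1:5, c(FALSE, TRUE, TRUE, TRUE, TRUE)))
  expect_identical(sel2$runs, c(2L, 5L))
  # incomplete fourth run, no run 5: first/last complete fallback
  sel3 <- select_runs(mk(1:4, c(TRUE, TRUE, TRUE, FALSE)))
  expect_identical(sel3$runs, c(1L, 3L))
  expect_error(select_runs(mk(1:2, c(TRUE, FALSE))), "fewer than 2")
})

test_that("the extracted table satisfies the metric invariants", {
  res <- clean_gs_metrics()
  m <- res$metrics
  validate_metrics_table(m)
  expect_identical(sort(unique(m$run_label)), c("First", "Last"))
  expect_identical(sort(unique(m$run_index)), c(1L, 4L))
  # burst never exceeds its turn
  wide <- merge(
    m[m$metric == "burst_ms", c("run_index", "cycle_index", "leg", "channel", "value")],
    m[m$metric == "turn_time_ms", c("run_index", "cycle_index", "leg", "value")],
    by = c("run_index", "cycle_index", "leg"))
  expect_true(all(wide$value.x <= wide$value.y + 1e-9))
  expect_true(all(m$value[m$metric == "burst_pct"] >= 0 &
                    m$value[m$metric == "burst_pct"] <= 100))
  expect_true(all(m$value[m$metric == "rms_pct_mvc"] >= 0))
  mpf <- m$value[m$metric == "mpf_hz"]
  expect_true(all(mpf >= 20 & mpf <= 500))
  # amplitude equals max - min over the same cycle
  amp <- m[m$metric == "amplitude_deg", ]
  mm <- m[m$metric %in% c("min_angle_deg", "max_angle_deg"), ]
  for (i in seq_len(min(nrow(amp), 20))) {
    sub <- mm[mm$run_index == amp$run_index[i] &
                mm$cycle_index == amp$cycle_index[i] &
                mm$channel == amp$channel[i], ]
    expect_gte(amp$value[i] + 1e-9,
               max(sub$value[sub$metric == "max_angle_deg"]) -
                 min(sub$value[sub$metric == "min_angle_deg"]) - 0.5)
  }
  # row count: one rms row per usable cycle, muscle and leg
  usable <- sum(!res$cycles$excluded & res$cycles$run_index %in% c(1L, 4L))
  expect_identical(sum(m$metric == "rms_pct_mvc"), usable * 5L * 2L)
})

test_that("per-turn estimates recover the generator's truth", {
  out <- clean_gs()
  res <- clean_gs_metrics()
  m <- res$metrics
  tr <- out$truth
  # RMS %MVC: per-leg means match the true drive within 10% (>= 50 turns)
  for (mus in c("VM", "RF")) {
    for (lg in c("IL", "OL")) {
      est <- m$value[m$metric == "rms_pct_mvc" & m$channel == mus & m$leg == lg]
      truth <- mean(tr$drive_pct_mvc[tr$turns$leg == lg, mus])
      expect_gt(length(est), 20)
      expect_lt(abs(mean(est) - truth) / truth, 0.10)
    }
  }
  # MPF per muscle within 5 Hz of the configured spectral centre
  for (mus in c("VM", "SMST")) {
    est <- m$value[m$metric == "mpf_hz" & m$channel == mus]
    centre <- c(VM = 95, SMST = 80)[[mus]]
    expect_lt(abs(mean(est) - centre), 5)
  }
  # mean detected turn time within 5% of the configured 1.47 s
  tt <- m$value[m$metric == "turn_time_ms"]
  expect_lt(abs(mean(tt) - 1470) / 1470, 0.05)
})

test_that("metrics are invariant to the absolute EMG scale", {
  out <- clean_gs()
  s2 <- out$session
  for (mus in c("VM", "RF", "VL", "BF", "SMST"))
    s2$channels[[mus]]$data <- 2 * s2$channels[[mus]]$data
  s2$mvc_references <- 2 * s2$mvc_references
  res2 <- build_metrics_table(s2)
  res1 <- clean_gs_metrics()
  expect_equal(res2$metrics$value, res1$metrics$value, tolerance = 1e-9)
})
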
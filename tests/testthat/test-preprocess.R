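test_that("EMG band-pass rejects DC and passes the mid band", {
  rate <- 1926
  t <- seq(0, 3, by = 1 / rate)
  # constant input is annihilated
  out <- bandpass_emg(rep(2.5, length(t)), rate)
  expect_lt(max(abs(out)), 1e-6 * 2.5)
  # 100 Hz unit sine passes within 5% of unity
  a100 <- sine_amplitude(bandpass_emg(sin(2 * pi * 100 * t), rate), rate, 100)
  expect_lt(abs(a100 - 1), 0.05)
  # 5 Hz unit sine is strongly attenuated
  a5 <- max(abs(bandpass_emg(sin(2 * pi * 5 * t), rate)[2000:3000]))
  expect_lt(a5, 0.1)
  # cutoff at/above Nyquist is refused
  expect_error(bandpass_emg(sin(t), rate = 900), "Nyquist")
})

test_that("zero-phase magnitude matches the squared Butterworth gain", {
  rate <- 1926
  t <- seq(0, 4, by = 1 / rate)
  for (f in c(60, 100, 250)) {
    meas <- sine_amplitude(bandpass_emg(sin(2 * pi * f * t), rate), rate, f)
    expect_lt(abs(meas - butter_gain_bandpass(f, 20, 500, 2, rate)^2), 0.02)
  }
  rate <- 148
  t <- seq(0, 30, by = 1 / rate)
  for (f in c(0.4, 1)) {
    meas <- sine_amplitude(lowpass_angles(sin(2 * pi * f * t), "SL"),
                           rate, f, trim_s = 4)
    expect_lt(abs(meas - butter_gain_lowpass(f, 2.5, 4, rate)^2), 0.02)
  }
})

test_that("baseline removal kills drift and preserves the EMG band", {
  rate <- 1926
  t <- seq(0, 5, by = 1 / rate)
  # moving average of a line is the line: interior residual ~ 0
  ramp <- 3 + 0.5 * t
  out <- remove_baseline(ramp, rate)
  interior <- seq(rate, length(t) - rate)
  expect_lt(max(abs(out[interior])), 1e-9)
  # 50 Hz preserved within 5%, 0.2 Hz drift reduced by > 80%
  x <- sin(2 * pi * 50 * t) + 2 * sin(2 * pi * 0.2 * t)
  out <- remove_baseline(x, rate)
  expect_lt(abs(sine_amplitude(out, rate, 50) - 1), 0.05)
  expect_lt(sine_amplitude(out, rate, 0.2), 0.2 * 2)
  expect_identical(remove_baseline(numeric(2 * rate), rate),
                   numeric(2 * rate))
  expect_error(remove_baseline(numeric(100), rate), "shorter")
})

test_that("sliding RMS matches closed forms and its invariants", {
  rate <- 1926
  t <- seq(0, 2, by = 1 / rate)
  expect_equal(rms_envelope(rep(3, length(t)), rate), rep(3, length(t)),
               tolerance = 1e-12)
  env <- rms_envelope(sin(2 * pi * 100 * t), rate)
  interior <- seq(rate %/% 2, length(t) - rate %/% 2)
  expect_lt(max(abs(env[interior] - 1 / sqrt(2))), 0.01 / sqrt(2))
  expect_identical(rms_envelope(numeric(1000), rate), numeric(1000))
  # non-negative and sign-flip invariant
  x <- rnorm(5000)
  expect_true(all(rms_envelope(x, rate) >= 0))
  expect_equal(rms_envelope(-x, rate), rms_envelope(x, rate))
  expect_error(rms_envelope(x, rate, epoch_ms = 0), "positive")
})

test_that("artifact flags follow the mean +/- 6 SD rule", {
  set.seed(1)
  env <- abs(rnorm(5000, 10, 1))
  spike_at <- 2500
  env[spike_at] <- mean(env) + 10 * sd(env)
  am <- artifact_mask(env)
  expect_true(am$mask[spike_at])
  expect_lt(mean(am$mask), 0.01)
  expect_true(any(am$intervals$start <= spike_at & am$intervals$end >= spike_at))
  # constant envelope: zero variance, no artifacts, no error
  am0 <- artifact_mask(rep(4, 100))
  expect_false(any(am0$mask))
  expect_identical(nrow(am0$intervals), 0L)
  expect_error(artifact_mask(numeric(0)), "empty")
})

test_that("MVC reference applies the plateau and 10% force rules", {
  mk_trial <- function(force_peak, rms) {
    t_f <- seq(0, 4, by = 1 / 148)
    f <- numeric(length(t_f)); f[t_f >= 1 & t_f < 3] <- force_peak
    t_e <- seq(0, 4, by = 1 / 1926)
    x <- sqrt(2) * sin(2 * pi * 80 * t_e) * rms * (t_e >= 1 & t_e < 3)
    list(group = "extension", force = list(data = f, rate = 148),
         emg = list(VM = list(data = x, rate = 1926)))
  }
  # forces {100, 95, 85}, trial maxima {0.20, 0.18, 0.30}:
  # the strongest-EMG trial is excluded by force, reference = 0.19
  tri <- structure(list(mk_trial(100, 0.20), mk_trial(95, 0.18),
                        mk_trial(85, 0.30)), class = "ski_mvc_trials")
  ref <- mvc_reference(tri)
  expect_equal(unname(ref$reference["VM"]), 0.19, tolerance = 1e-3)
  expect_identical(ref$retained$extension, c(1L, 2L))
  # single trial: reference is its own maximum
  ref1 <- mvc_reference(structure(list(mk_trial(90, 0.25)),
                                  class = "ski_mvc_trials"))
  expect_equal(unname(ref1$reference["VM"]), 0.25, tolerance = 1e-3)
  expect_error(mvc_reference(structure(list(), class = "ski_mvc_trials")),
               "no MVC trials")
})

test_that("MVC normalization is linear and guarded", {
  env <- c(0, 0.1, 0.2)
  expect_equal(normalize_to_mvc(env, 0.2), c(0, 50, 100))
  expect_equal(normalize_to_mvc(3 * env, 0.2), 3 * normalize_to_mvc(env, 0.2))
  expect_error(normalize_to_mvc(env, 0), "positive")
  expect_error(normalize_to_mvc(env, -1), "positive")
})

test_that("discipline cut-off tables are correct and filters behave at DC", {
  expect_identical(c(accr_cutoff_hz("DH"), accr_cutoff_hz("SG"),
                     accr_cutoff_hz("GS"), accr_cutoff_hz("SL")),
                   c(0.8, 1, 2, 3))
  expect_identical(c(angle_cutoff_hz("DH"), angle_cutoff_hz("SG"),
                     angle_cutoff_hz("GS"), angle_cutoff_hz("SL")),
                   c(0.5, 1, 2, 2.5))
  expect_error(angle_cutoff_hz("biathlon"), "unknown discipline")
  # low-pass is the identity on DC for every discipline, including the
  # near-DC DH cutoff
  x <- rep(3.3, 30 * 148)
  for (d in c("SL", "GS", "SG", "DH")) {
    expect_lt(max(abs(lowpass_angles(x, d) - 3.3)), 1e-8)
    expect_lt(max(abs(lowpass_accr(x, d) - 3.3)), 1e-8)
  }
  # SL angles: 10 Hz crushed to < 5%, 0.3 Hz preserved within 5%
  t <- seq(0, 30, by = 1 / 148)
  expect_lt(sine_amplitude(lowpass_angles(sin(2 * pi * 10 * t), "SL"),
                           148, 10, trim_s = 3), 0.05)
  expect_lt(abs(sine_amplitude(lowpass_angles(sin(2 * pi * 0.3 * t), "SL"),
                               148, 0.3, trim_s = 3) - 1), 0.05)
})

test_that("angular velocity is a signed central difference", {
  rate <- 148
  t <- seq(0, 10, by = 1 / rate)
  # A sin(wt): peak speed A*w in both directions
  v <- angular_velocity(90 + 10 * sin(2 * pi * 0.5 * t), rate)
  expect_lt(abs(max(v) - 10 * 2 * pi * 0.5) / (10 * pi), 0.02)
  expect_lt(abs(min(v) + 10 * 2 * pi * 0.5) / (10 * pi), 0.02)
  expect_identical(angular_velocity(rep(95, 100), rate), numeric(100))
  v_ramp <- angular_velocity(100 + 5 * t, rate)
  expect_equal(v_ramp[2:(length(t) - 1)], rep(5, length(t) - 2),
               tolerance = 1e-9)
  expect_error(angular_velocity(c(1, 2), rate), "3 samples")
})
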
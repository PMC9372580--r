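## Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## Clean (noise- and artifact-free) GS session: 4 runs x 30 turns, used by
## segmentation/metrics recovery tests.
clean_gs <- function() {
  if (is.null(.fixtures$clean_gs))
    .fixtures$clean_gs <- generate_session(
      synth_config("GS", seed = 42, vibration_noise_sd = 0,
                   artifact_rate = 0))
  .fixtures$clean_gs
}

clean_gs_metrics <- function() {
  if (is.null(.fixtures$clean_gs_metrics))
    .fixtures$clean_gs_metrics <- build_metrics_table(clean_gs()$session)
  .fixtures$clean_gs_metrics
}

## Small hand-built session (valid structure, short signals) for IO tests.
tiny_session <- function(duration_s = 12) {
  n_e <- ceiling(duration_s * 1926)
  n_l <- ceiling(duration_s * 148)
  t_e <- (seq_len(n_e) - 1) / 1926
  t_l <- (seq_len(n_l) - 1) / 148
  ch <- list()
  for (m in c("VM", "RF", "VL", "BF", "SMST"))
    ch[[m]] <- list(data = 0.1 * sin(2 * pi * 80 * t_e), rate = 1926)
  ch$acc_x <- list(data = 0.01 * cos(2 * pi * 0.7 * t_l), rate = 148)
  ch$acc_y <- list(data = 0.02 * sin(2 * pi * 0.7 * t_l), rate = 148)
  ch$acc_z <- list(data = 1 + 0.4 * sin(2 * pi * 0.7 * t_l), rate = 148)
  ch$knee_angle <- list(data = 130 + 20 * sin(2 * pi * 0.35 * t_l), rate = 148)
  ch$hip_angle <- list(data = 120 + 15 * sin(2 * pi * 0.35 * t_l), rate = 148)
  mk <- data.frame(run_index = 1:2, start_s = c(0.5, 6.5),
                   end_s = c(5.5, 11.5), complete = c(TRUE, TRUE))
  ski_session("T01", "GS", ch, mk,
              mvc_references = c(VM = 0.2, RF = 0.2, VL = 0.2,
                                 BF = 0.2, SMST = 0.2))
}

## Single-pass Butterworth magnitude response, closed form on the bilinear
## (tan-warped) frequency axis so it is exact for the digital design; the
## zero-phase implementation squares it.
butter_gain_lowpass <- function(f, fc, order, rate) {
  w <- function(g) tan(pi * g / rate)
  1 / sqrt(1 + (w(f) / w(fc))^(2 * order))
}
butter_gain_bandpass <- function(f, flo, fhi, order, rate) {
  w <- function(g) tan(pi * g / rate)
  1 / sqrt(1 + ((w(f)^2 - w(flo) * w(fhi)) /
                  (w(f) * (w(fhi) - w(flo))))^(2 * order))
}

## Amplitude of a sinusoidal component in a signal at frequency f_hz,
## estimated over an interior window to avoid edge effects.
sine_amplitude <- function(x, rate, f_hz, trim_s = 1) {
  i <- seq(round(trim_s * rate), length(x) - round(trim_s * rate))
  t <- (i - 1) / rate
  2 * sqrt(mean(x[i] * sin(2 * pi * f_hz * t))^2 +
             mean(x[i] * cos(2 * pi * f_hz * t))^2)
}
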
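#' Configuration for the synthetic skier-session generator
#'
#' Builds a validated parameter set describing one simulated on-snow training
#' session: discipline, number of runs, turn-duration distribution, per-muscle
#' EMG drive in %MVC with leg (outside minus inside) and run (later minus
#' first) offsets, spectral centre of each EMG carrier, trunk-accelerometer
#' vibration noise, artifact frequency and goniometer ranges of motion.
#'
#' Discipline defaults reflect typical race-training courses: mean turn
#' durations of 0.80, 1.47, 2.15 and 2.30 s and 45, 30, 25 and 20 turns per
#' run for SL, GS, SG and DH respectively, within the regulation ranges of
#' SL 40-60, GS 25-50, SG 15-40 and DH 15-35 turns per run.
#'
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param n_runs number of runs in the session (>= 2; runs 1 and 4 are the
#'   standard comparison pair, so 4 is the default).
#' @param turns_per_run turns in every run; default is discipline-specific
#'   and must stay within the discipline's plausible range.
#' @param mean_turn_duration_s mean single-turn duration in seconds.
#' @param turn_duration_cv coefficient of variation of turn durations.
#' @param emg_burst_amplitude_pct_mvc named per-muscle inside-leg burst drive
#'   in %MVC.
#' @param run_effect_pct_mvc named per-muscle additive drive shift (in %MVC)
#'   applied to all runs after the first.
#' @param leg_effect_pct_mvc named per-muscle outside-minus-inside leg drive
#'   offset in %MVC.
#' @param mpf_center_hz named per-muscle spectral centre of the EMG carrier,
#'   inside the 20-500 Hz analysis band.
#' @param vibration_noise_sd accelerometer vibration noise SD in g.
#' @param artifact_rate expected number of injected EMG artifacts per run.
#' @param angle_range_deg list with `knee` and `hip` elements, each
#'   `c(min, max)` degrees with 180 = full extension.
#' @param burst_duty fraction of each turn occupied by the flat top of the
#'   burst envelope (cosine ramps of 10% of the turn on each side).
#' @param baseline_drive_pct_mvc tonic drive outside bursts, %MVC.
#' @param session_effect_sd_pct_mvc SD of the per-session random intercept of
#'   the true drive (between skier-session variability), %MVC.
#' @param turn_noise_sd_pct_mvc SD of the turn-to-turn drive variability
#'   (within-session residual), %MVC.
#' @param mvc_max_rms_mv named per-muscle true maximal RMS during the MVC, mV.
#' @param mvc_force_fractions peak-force fractions of the repeated MVC trials
#'   (relative to the best trial); defaults exercise the 10% retention rule.
#' @param mvc_noise_sd relative SD of additive noise in MVC EMG traces.
#' @param incomplete_runs integer run indices flagged as not finished.
#' @param inter_run_gap_s quiet gap between consecutive runs, seconds.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical sessions.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config("GS", seed = 42)
#' cfg$mean_turn_duration_s
synth_config <- function(discipline = c("GS", "SL", "SG", "DH"),
                         n_runs = 4L,
                         turns_per_run = NULL,
                         mean_turn_duration_s = NULL,
                         turn_duration_cv = 0.08,
                         emg_burst_amplitude_pct_mvc = NULL,
                         run_effect_pct_mvc = NULL,
                         leg_effect_pct_mvc = NULL,
                         mpf_center_hz = NULL,
                         vibration_noise_sd = 0.05,
                         artifact_rate = 1,
                         angle_range_deg = list(knee = c(100, 155),
                                                hip = c(95, 140)),
                         burst_duty = 0.6,
                         baseline_drive_pct_mvc = 5,
                         session_effect_sd_pct_mvc = 5,
                         turn_noise_sd_pct_mvc = 3,
                         mvc_max_rms_mv = NULL,
                         mvc_force_fractions = c(1.00, 0.96, 0.88),
                         mvc_noise_sd = 0.02,
                         incomplete_runs = integer(0),
                         inter_run_gap_s = 4,
                         seed = 1L) {
  discipline <- match_discipline(match.arg(discipline))

  defaults <- list(SL = list(dur = 0.80, turns = 45L),
                   GS = list(dur = 1.47, turns = 30L),
                   SG = list(dur = 2.15, turns = 25L),
                   DH = list(dur = 2.30, turns = 20L))[[discipline]]
  if (is.null(turns_per_run)) turns_per_run <- defaults$turns
  if (is.null(mean_turn_duration_s)) mean_turn_duration_s <- defaults$dur

  per_muscle <- function(x, fallback, what) {
    if (is.null(x)) x <- fallback
    if (length(x) == 1L && is.null(names(x)))
      x <- setNames(rep(x, length(SKI_MUSCLES)), SKI_MUSCLES)
    if (!all(SKI_MUSCLES %in% names(x)))
      stop(what, " must be named for all muscles: ",
           paste(SKI_MUSCLES, collapse = ", "))
    x <- x[SKI_MUSCLES]
    storage.mode(x) <- "double"
    x
  }
  emg_burst_amplitude_pct_mvc <- per_muscle(
    emg_burst_amplitude_pct_mvc,
    c(VM = 35, RF = 40, VL = 35, BF = 26, SMST = 24),
    "emg_burst_amplitude_pct_mvc")
  run_effect_pct_mvc <- per_muscle(run_effect_pct_mvc, 0, "run_effect_pct_mvc")
  leg_effect_pct_mvc <- per_muscle(
    leg_effect_pct_mvc, c(VM = 10, RF = -10, VL = 10, BF = 5, SMST = 5),
    "leg_effect_pct_mvc")
  mpf_center_hz <- per_muscle(
    mpf_center_hz, c(VM = 95, RF = 90, VL = 100, BF = 85, SMST = 80),
    "mpf_center_hz")
  mvc_max_rms_mv <- per_muscle(mvc_max_rms_mv, 0.2, "mvc_max_rms_mv")

  cfg <- structure(list(
    discipline = discipline,
    n_runs = as.integer(n_runs),
    turns_per_run = as.integer(turns_per_run),
    mean_turn_duration_s = mean_turn_duration_s,
    turn_duration_cv = turn_duration_cv,
    emg_burst_amplitude_pct_mvc = emg_burst_amplitude_pct_mvc,
    run_effect_pct_mvc = run_effect_pct_mvc,
    leg_effect_pct_mvc = leg_effect_pct_mvc,
    mpf_center_hz = mpf_center_hz,
    vibration_noise_sd = vibration_noise_sd,
    artifact_rate = artifact_rate,
    angle_range_deg = angle_range_deg,
    burst_duty = burst_duty,
    baseline_drive_pct_mvc = baseline_drive_pct_mvc,
    session_effect_sd_pct_mvc = session_effect_sd_pct_mvc,
    turn_noise_sd_pct_mvc = turn_noise_sd_pct_mvc,
    mvc_max_rms_mv = mvc_max_rms_mv,
    mvc_force_fractions = mvc_force_fractions,
    mvc_noise_sd = mvc_noise_sd,
    incomplete_runs = as.integer(incomplete_runs),
    inter_run_gap_s = inter_run_gap_s,
    emg_rate = SKI_EMG_RATE,
    lf_rate = SKI_LF_RATE,
    seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_runs < 2L) stop("configuration error: n_runs must be >= 2")
  if (cfg$turns_per_run < 1L) stop("configuration error: empty runs")
  if (cfg$mean_turn_duration_s <= 0)
    stop("configuration error: mean_turn_duration_s must be positive")
  rng <- SKI_TURN_RANGE[[cfg$discipline]]
  if (cfg$turns_per_run < rng[1] || cfg$turns_per_run > rng[2])
    stop("configuration error: turns_per_run ", cfg$turns_per_run,
         " outside the plausible ", cfg$discipline, " range [",
         rng[1], ", ", rng[2], "]")
  if (any(cfg$emg_burst_amplitude_pct_mvc < 0) || any(cfg$mvc_max_rms_mv <= 0))
    stop("configuration error: amplitude parameters must be non-negative")
  if (any(cfg$mpf_center_hz <= 20) || any(cfg$mpf_center_hz >= 500))
    stop("configuration error: mpf_center_hz must lie inside (20, 500) Hz")
  if (cfg$burst_duty <= 0 || cfg$burst_duty > 0.8)
    stop("configuration error: burst_duty must lie in (0, 0.8]")
  if (cfg$turn_duration_cv < 0 || cfg$vibration_noise_sd < 0 ||
      cfg$artifact_rate < 0)
    stop("configuration error: negative dispersion parameter")
  invisible(cfg)
}

## Burst envelope profile on the normalized turn coordinate u in [0, 1]:
## zero outside [0.1, 0.9], cosine ramps over [0.1, 0.2] and [0.8, 0.9],
## flat top over the central region. The flat top covers `duty` of the turn
## when duty = 0.6 (the default); wider duties stretch the flat region.
burst_profile <- function(u, duty = 0.6) {
  half_flat <- duty / 2
  ramp <- max(1e-6, 0.4 - half_flat)          # ramp width on each side
  on0 <- 0.5 - half_flat - ramp
  p <- numeric(length(u))
  lo <- u >= on0 & u < on0 + ramp
  p[lo] <- 0.5 * (1 - cos(pi * (u[lo] - on0) / ramp))
  p[u >= on0 + ramp & u <= 1 - on0 - ramp] <- 1
  hi <- u > 1 - on0 - ramp & u <= 1 - on0
  p[hi] <- 0.5 * (1 - cos(pi * (1 - on0 - u[hi]) / ramp))
  p
}

## Threshold-crossing times of the burst envelope for one turn (ground truth).
burst_truth_times <- function(start, dur, drive, baseline, duty, thr = 20) {
  if (drive <= thr) return(c(NA_real_, NA_real_))
  if (baseline >= thr) return(c(start, start + dur))
  half_flat <- duty / 2
  ramp <- max(1e-6, 0.4 - half_flat)
  on0 <- 0.5 - half_flat - ramp
  v <- acos(1 - 2 * (thr - baseline) / (drive - baseline)) / pi
  c(start + (on0 + ramp * v) * dur, start + (1 - on0 - ramp * v) * dur)
}

#' Generate one synthetic skier-session with ground truth
#'
#' Simulates the full multi-channel recording of one training session: five
#' surface EMG channels at 1926 Hz built as band-limited stochastic carriers
#' (centred per muscle on its configured spectral centre) amplitude-modulated
#' by per-turn burst envelopes in %MVC; a tri-axial trunk accelerometer at
#' 148 Hz whose low-passed resultant reaches a local minimum at every turn
#' switch; and knee/hip goniometer channels oscillating at turn frequency
#' between the configured extrema (180 degrees = full extension). Optional
#' high-amplitude transients emulate the vibration artifacts of on-snow EMG.
#'
#' @param config a [synth_config()] object.
#' @param session_id identifier of the skier-session (the random-effect
#'   grouping unit of the downstream models).
#' @return a list with elements `session` (a [ski_session()] recording) and
#'   `truth` (a `ski_ground_truth` list holding switch times, per-turn leg
#'   labels, true per-turn drives per muscle, burst on/off times, injected
#'   artifact intervals and the generating variance components).
#' @export
#' @examples
#' out <- generate_session(synth_config("SL", seed = 7))
#' nrow(out$truth$turns) == 4 * 45
generate_session <- function(config, session_id = "S01") {
  validate_synth_config(config)
  with_seed(config$seed, generate_session_impl(config, session_id))
}

generate_session_impl <- function(cfg, session_id) {
  lead <- 0.6                 # quiet lead-in/out inside each run, seconds
  s_log <- sqrt(log(1 + cfg$turn_duration_cv^2))

  ## --- timeline: run markers and switch times -------------------------------
  cursor <- 1.0
  turns <- NULL
  markers <- NULL
  switch_times <- list()
  for (r in seq_len(cfg$n_runs)) {
    dur <- cfg$mean_turn_duration_s *
      exp(rnorm(cfg$turns_per_run, -s_log^2 / 2, s_log))
    sw <- cursor + lead + cumsum(c(0, dur))
    run_end <- sw[length(sw)] + lead
    markers <- rbind(markers, data.frame(
      run_index = r, start_s = cursor, end_s = run_end,
      complete = !(r %in% cfg$incomplete_runs)))
    turns <- rbind(turns, data.frame(
      run_index = r, turn_in_run = seq_len(cfg$turns_per_run),
      start_s = sw[-length(sw)], end_s = sw[-1],
      leg = rep_len(c("IL", "OL"), cfg$turns_per_run)))
    switch_times[[r]] <- sw
    cursor <- run_end + cfg$inter_run_gap_s
  }
  total_s <- cursor - cfg$inter_run_gap_s + 1.0
  n_turn <- nrow(turns)

  ## --- true per-turn drive (%MVC) -------------------------------------------
  sess_int <- rnorm(length(SKI_MUSCLES), 0, cfg$session_effect_sd_pct_mvc)
  names(sess_int) <- SKI_MUSCLES
  drive <- matrix(NA_real_, n_turn, length(SKI_MUSCLES),
                  dimnames = list(NULL, SKI_MUSCLES))
  for (m in SKI_MUSCLES) {
    eps <- rnorm(n_turn, 0, cfg$turn_noise_sd_pct_mvc)
    # centre the turn-to-turn noise within each leg so the configured
    # outside-minus-inside offset is exactly recoverable from the truth
    for (lg in c("IL", "OL")) {
      idx <- turns$leg == lg
      eps[idx] <- eps[idx] - mean(eps[idx])
    }
    drive[, m] <- cfg$emg_burst_amplitude_pct_mvc[m] +
      cfg$leg_effect_pct_mvc[m] * (turns$leg == "OL") +
      cfg$run_effect_pct_mvc[m] * (turns$run_index > 1) +
      sess_int[m] + eps
    drive[, m] <- pmax(drive[, m], cfg$baseline_drive_pct_mvc + 0.5)
  }

  ## --- EMG channels ----------------------------------------------------------
  n_emg <- ceiling(total_s * cfg$emg_rate)
  t_emg <- (seq_len(n_emg) - 1) / cfg$emg_rate
  channels <- list()
  burst_on <- burst_off <- matrix(NA_real_, n_turn, length(SKI_MUSCLES),
                                  dimnames = list(NULL, SKI_MUSCLES))
  for (m in SKI_MUSCLES) {
    centre <- cfg$mpf_center_hz[m]
    band <- c(max(20.5, centre - 40), min(499.5, centre + 40))
    carrier <- butter_zerophase(rnorm(n_emg), cfg$emg_rate, band,
                                type = "pass", order = 4L)
    carrier <- carrier / sqrt(mean(carrier^2))
    env <- rep(cfg$baseline_drive_pct_mvc, n_emg)
    for (k in seq_len(n_turn)) {
      i0 <- floor(turns$start_s[k] * cfg$emg_rate) + 1L
      i1 <- min(n_emg, ceiling(turns$end_s[k] * cfg$emg_rate))
      u <- (t_emg[i0:i1] - turns$start_s[k]) /
        (turns$end_s[k] - turns$start_s[k])
      env[i0:i1] <- cfg$baseline_drive_pct_mvc +
        (drive[k, m] - cfg$baseline_drive_pct_mvc) *
        burst_profile(u, cfg$burst_duty)
      bt <- burst_truth_times(turns$start_s[k],
                              turns$end_s[k] - turns$start_s[k],
                              drive[k, m], cfg$baseline_drive_pct_mvc,
                              cfg$burst_duty)
      burst_on[k, m] <- bt[1]; burst_off[k, m] <- bt[2]
    }
    channels[[m]] <- list(data = carrier * env / 100 * cfg$mvc_max_rms_mv[m],
                          rate = cfg$emg_rate)
  }

  ## --- artifacts --------------------------------------------------------------
  artifacts <- data.frame(channel = character(0), start_s = numeric(0),
                          end_s = numeric(0))
  if (cfg$artifact_rate > 0) {
    for (r in seq_len(cfg$n_runs)) {
      n_art <- rpois(1, cfg$artifact_rate)
      if (n_art == 0) next
      for (a in seq_len(n_art)) {
        m <- sample(SKI_MUSCLES, 1)
        mk <- markers[markers$run_index == r, ]
        art_dur <- 0.05
        t0 <- runif(1, mk$start_s + lead, mk$end_s - lead - art_dur)
        i0 <- floor(t0 * cfg$emg_rate) + 1L
        i1 <- i0 + ceiling(art_dur * cfg$emg_rate)
        seg <- channels[[m]]$data
        run_idx <- seq(floor(mk$start_s * cfg$emg_rate) + 1L,
                       min(length(seg), ceiling(mk$end_s * cfg$emg_rate)))
        # oscillatory in-band transient (a DC pulse would be removed by the
        # 20-500 Hz band-pass); >= 10 SD of the run signal so the +/- 6 SD
        # envelope rule fires
        amp <- 30 * sd(seg[run_idx])
        tt <- (seq(i0, i1) - i0) / cfg$emg_rate
        channels[[m]]$data[i0:i1] <- channels[[m]]$data[i0:i1] +
          amp * sin(2 * pi * 150 * tt)
        artifacts <- rbind(artifacts, data.frame(
          channel = m, start_s = t0, end_s = t0 + art_dur))
      }
    }
  }

  ## --- accelerometer and goniometers (148 Hz) --------------------------------
  n_lf <- ceiling(total_s * cfg$lf_rate)
  t_lf <- (seq_len(n_lf) - 1) / cfg$lf_rate
  ## AccR rests at the arch maximum between runs; each run enters and leaves
  ## through a smooth half-arch so the only local minima are turn switches.
  accr_min <- 0.8; accr_swing <- 0.8; accr_rest <- accr_min + accr_swing
  lat_amp <- 0.3
  accr_clean <- rep(accr_rest, n_lf)
  for (r in seq_len(cfg$n_runs)) {
    sw <- switch_times[[r]]
    first_sw <- sw[1]; last_sw <- sw[length(sw)]
    iin <- which(t_lf >= first_sw - lead & t_lf < first_sw)
    accr_clean[iin] <- accr_min +
      accr_swing * sin(pi / 2 * (first_sw - t_lf[iin]) / lead)
    iout <- which(t_lf > last_sw & t_lf <= last_sw + lead)
    accr_clean[iout] <- accr_min +
      accr_swing * sin(pi / 2 * (t_lf[iout] - last_sw) / lead)
  }
  lateral <- numeric(n_lf)
  angle <- list(knee = rep(cfg$angle_range_deg$knee[2], n_lf),
                hip = rep(cfg$angle_range_deg$hip[2], n_lf))
  for (k in seq_len(n_turn)) {
    i0 <- floor(turns$start_s[k] * cfg$lf_rate) + 1L
    i1 <- min(n_lf, ceiling(turns$end_s[k] * cfg$lf_rate))
    u <- (t_lf[i0:i1] - turns$start_s[k]) /
      (turns$end_s[k] - turns$start_s[k])
    u <- pmin(pmax(u, 0), 1)
    accr_clean[i0:i1] <- accr_min + accr_swing * sin(pi * u)
    lateral[i0:i1] <- lat_amp * ifelse(turns$leg[k] == "IL", 1, -1) *
      sin(pi * u)
    for (j in SKI_JOINTS) {
      rng <- cfg$angle_range_deg[[j]]
      angle[[j]][i0:i1] <- rng[2] - (rng[2] - rng[1]) * sin(pi * u)^2
    }
  }
  noise <- function() rnorm(n_lf, 0, cfg$vibration_noise_sd)
  channels$acc_x <- list(data = noise(), rate = cfg$lf_rate)
  channels$acc_y <- list(data = lateral + noise(), rate = cfg$lf_rate)
  channels$acc_z <- list(data = accr_clean + noise(), rate = cfg$lf_rate)
  channels$knee_angle <- list(data = angle$knee, rate = cfg$lf_rate)
  channels$hip_angle <- list(data = angle$hip, rate = cfg$lf_rate)

  session <- ski_session(session_id = session_id,
                         discipline = cfg$discipline,
                         channels = channels,
                         run_markers = markers,
                         mvc_references = cfg$mvc_max_rms_mv)
  truth <- structure(list(
    turns = turns,
    switch_times = switch_times,
    drive_pct_mvc = drive,
    burst_on_s = burst_on,
    burst_off_s = burst_off,
    artifacts = artifacts,
    session_intercepts = sess_int,
    run_effect_pct_mvc = cfg$run_effect_pct_mvc,
    leg_effect_pct_mvc = cfg$leg_effect_pct_mvc,
    var_between_session = cfg$session_effect_sd_pct_mvc^2,
    var_residual = cfg$turn_noise_sd_pct_mvc^2),
    class = "ski_ground_truth")
  list(session = session, truth = truth)
}

#' Generate a set of synthetic MVC trials
#'
#' Simulates the maximal voluntary contraction normalization procedure: at
#' least three isometric knee extensions (for VM, RF, VL) and three knee
#' flexions (for BF, SMST), each with a force trace (ramp, plateau, release)
#' and synchronized EMG whose plateau RMS equals the configured per-muscle
#' maximum. Peak forces vary across trials (per `mvc_force_fractions`) so
#' that the 10% force retention rule of [mvc_reference()] is exercised while
#' the EMG reference itself stays at the configured maximum.
#'
#' @param config a [synth_config()] object.
#' @param noise_sd relative SD of additive EMG noise; defaults to the
#'   config's `mvc_noise_sd`. Use 0 for the closed-loop noise-free case.
#' @return a `ski_mvc_trials` list of trials, each with `group`
#'   (`"extension"` or `"flexion"`), a `force` trace (N, 148 Hz) and named
#'   `emg` traces (mV, 1926 Hz).
#' @export
generate_mvc_trials <- function(config, noise_sd = config$mvc_noise_sd) {
  validate_synth_config(config)
  with_seed(config$seed + 9973L, {
    trials <- list()
    for (grp in c("extension", "flexion")) {
      muscles <- if (grp == "extension") SKI_EXTENSORS else SKI_FLEXORS
      base_force <- if (grp == "extension") 1800 else 800
      for (fr in config$mvc_force_fractions) {
        peak <- base_force * fr
        # force profile: rest, 1 s ramp up, 3 s plateau, 1 s release, rest
        t_f <- seq(0, 6, by = 1 / config$lf_rate)
        force <- numeric(length(t_f))
        force[t_f >= 0.5 & t_f < 1.5] <- peak * (t_f[t_f >= 0.5 & t_f < 1.5] - 0.5)
        force[t_f >= 1.5 & t_f < 4.5] <- peak
        force[t_f >= 4.5 & t_f < 5.5] <- peak * (5.5 - t_f[t_f >= 4.5 & t_f < 5.5])
        t_e <- seq(0, 6, by = 1 / config$emg_rate)
        rel <- approx(t_f, force / peak, xout = t_e, rule = 2)$y
        emg <- list()
        for (m in muscles) {
          target_rms <- config$mvc_max_rms_mv[m] * rel
          x <- sqrt(2) * sin(2 * pi * config$mpf_center_hz[m] * t_e) * target_rms
          if (noise_sd > 0)
            x <- x + rnorm(length(x), 0, noise_sd * config$mvc_max_rms_mv[m])
          emg[[m]] <- list(data = x, rate = config$emg_rate)
        }
        trials[[length(trials) + 1L]] <-
          list(group = grp, force = list(data = force, rate = config$lf_rate),
               emg = emg)
      }
    }
    structure(trials, class = "ski_mvc_trials")
  })
}
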
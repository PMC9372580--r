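## Burst-envelope low-pass cut-offs (Hz) by discipline: the linear envelope
## used for activation-time detection tracks slower bursts in speed events.
BURST_CUTOFF_HZ <- c(DH = 1, SG = 2, GS = 4, SL = 7)

#' Burst-envelope cut-off lookup
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @return low-pass cut-off in Hz (1 / 2 / 4 / 7 for DH / SG / GS / SL).
#' @export
burst_cutoff_hz <- function(discipline) {
  BURST_CUTOFF_HZ[[match_discipline(discipline)]]
}

#' Linear envelope for burst detection
#'
#' Rectifies the band-passed EMG and low-passes it (fourth-order zero-phase
#' Butterworth) at the discipline cut-off. Rectification before the low-pass
#' is required: smoothing a zero-mean EMG at a few hertz would annihilate
#' it. By default the rectified-mean envelope is rescaled by `sqrt(pi / 2)`
#' so that, for a Gaussian interference-pattern EMG, the envelope estimates
#' the local RMS amplitude — the same scale as the MVC reference against
#' which the 20%-MVC activation threshold is applied.
#'
#' @param emg_bandpassed band-passed EMG samples.
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param rate sampling rate, Hz.
#' @param calibrate `"rms"` (Gaussian RMS calibration) or `"none"` (plain
#'   rectified mean).
#' @return the non-negative linear envelope.
#' @export
burst_envelope <- function(emg_bandpassed, discipline, rate = SKI_EMG_RATE,
                           calibrate = c("rms", "none")) {
  calibrate <- match.arg(calibrate)
  env <- butter_zerophase(abs(emg_bandpassed), rate,
                          burst_cutoff_hz(discipline), "low", 4L)
  if (calibrate == "rms") env <- env * sqrt(pi / 2)
  pmax(env, 0)
}

#' Mean EMG amplitude per leg over one normalized cycle
#'
#' Mean of the %MVC envelope over the retained (loaded-phase) grid points of
#' each leg half, after removal of the edge-change phases.
#'
#' @param grid_env %MVC envelope on the 200-point cycle grid
#'   (see [time_normalize()]).
#' @param mask edge-phase mask from [edge_phase_mask()].
#' @return named vector `c(IL = ..., OL = ...)`; `NA` for a half whose points
#'   are all masked.
#' @export
turn_rms_pct <- function(grid_env, mask = edge_phase_mask()) {
  n <- length(grid_env)
  if (length(mask) != n) stop("mask length must match the grid")
  half <- n %/% 2L
  il <- grid_env[seq_len(half)][mask[seq_len(half)]]
  ol <- grid_env[seq(half + 1L, n)][mask[seq(half + 1L, n)]]
  c(IL = if (length(il)) mean(il) else NA_real_,
    OL = if (length(ol)) mean(ol) else NA_real_)
}

#' Mean power frequency of an EMG segment
#'
#' Power-weighted mean frequency of the single (untapered) periodogram of
#' the band-passed EMG, restricted to the 20-500 Hz analysis band:
#' `sum(f * P(f)) / sum(P(f))`.
#'
#' @param x band-passed EMG samples for one leg of one turn (edge phases
#'   removed), at least 128 samples.
#' @param rate sampling rate, Hz.
#' @param fmin,fmax analysis band, Hz.
#' @return the MPF in Hz, or `NA` if the segment is too short or carries no
#'   power in the band.
#' @export
turn_mpf <- function(x, rate = SKI_EMG_RATE, fmin = 20, fmax = 500) {
  n <- length(x)
  if (n < 128L) return(NA_real_)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * rate / n
  keep <- f >= fmin & f <= fmax & f <= rate / 2
  if (!any(keep) || sum(p[keep]) == 0) return(NA_real_)
  sum(f[keep] * p[keep]) / sum(p[keep])
}

#' EMG activation time within one turn
#'
#' Total duration for which the linear envelope exceeds the activation
#' threshold (default 20% of the MVC maximal RMS) inside the turn; multiple
#' supra-threshold intervals are summed. Reported in absolute milliseconds
#' and as a percentage of the turn duration.
#'
#' @param env_pct linear envelope in %MVC on the native time base (time 0 at
#'   the first sample).
#' @param rate sampling rate, Hz.
#' @param t_start,t_end turn boundaries, seconds.
#' @param threshold_pct activation threshold, %MVC.
#' @return named vector `c(burst_ms = ..., burst_pct = ...)`.
#' @export
activation_time <- function(env_pct, rate, t_start, t_end,
                            threshold_pct = 20) {
  i0 <- max(1L, floor(t_start * rate) + 1L)
  i1 <- min(length(env_pct), ceiling(t_end * rate))
  if (i1 < i0) return(c(burst_ms = 0, burst_pct = 0))
  turn_ms <- (t_end - t_start) * 1000
  burst_ms <- min(sum(env_pct[i0:i1] > threshold_pct) / rate * 1000, turn_ms)
  c(burst_ms = burst_ms, burst_pct = 100 * burst_ms / turn_ms)
}

#' Per-turn and per-run timing
#'
#' `turn_times` converts consecutive switch times into single-turn durations
#' in milliseconds; `run_time` is the elapsed time between a run's start and
#' end markers in seconds.
#'
#' @param switches increasing switch times, seconds.
#' @return `turn_times`: durations in ms, one per turn.
#' @export
turn_times <- function(switches) {
  if (length(switches) < 2L) stop("need at least 2 switches")
  diff(switches) * 1000
}

#' @rdname turn_times
#' @param start_s,end_s run markers, seconds.
#' @return `run_time`: the run duration in seconds.
#' @export
run_time <- function(start_s, end_s) {
  end_s - start_s
}

#' Kinematic scalars for one turn
#'
#' Minimal and maximal joint angle, and the peak angular velocities of the
#' flexion (most negative) and extension (most positive) phases within the
#' turn window. A window without a flexion (or extension) phase yields 0 for
#' the corresponding peak.
#'
#' @param angle_deg filtered joint angle, degrees (time 0 at first sample).
#' @param vel_dps angular velocity, degrees per second (same time base).
#' @param rate sampling rate, Hz.
#' @param t_start,t_end window boundaries, seconds.
#' @return named vector with `min_angle_deg`, `max_angle_deg`,
#'   `peak_flex_vel_dps`, `peak_ext_vel_dps`.
#' @export
kinematic_scalars <- function(angle_deg, vel_dps, rate, t_start, t_end) {
  i0 <- max(1L, floor(t_start * rate) + 1L)
  i1 <- min(length(angle_deg), ceiling(t_end * rate))
  a <- angle_deg[i0:i1]; v <- vel_dps[i0:i1]
  c(min_angle_deg = min(a), max_angle_deg = max(a),
    peak_flex_vel_dps = min(0, min(v)), peak_ext_vel_dps = max(0, max(v)))
}

#' Select the comparison runs of a session
#'
#' The standardized comparison pairs the first and fourth runs of the
#' session, or runs 2 and 5 when run 1 or 4 is incomplete. When neither pair
#' is available (short or partly incomplete sessions) the first and last
#' complete runs are compared instead.
#'
#' @param run_markers run-marker data.frame.
#' @return list with integer `runs` (the two run indices) and `labels`
#'   (`c("First", "Last")`). Errors if fewer than 2 complete runs exist.
#' @export
select_runs <- function(run_markers) {
  ok <- function(r) {
    i <- match(r, run_markers$run_index)
    !is.na(i) && run_markers$complete[i]
  }
  pair <- if (ok(1L) && ok(4L)) c(1L, 4L)
          else if (ok(2L) && ok(5L)) c(2L, 5L)
          else {
    compl <- run_markers$run_index[run_markers$complete]
    if (length(compl) < 2L)
      stop("fewer than 2 eligible runs in the session")
    c(min(compl), max(compl))
  }
  list(runs = pair, labels = c("First", "Last"))
}

#' Extract the tidy per-turn metrics table of one session
#'
#' Runs the full per-session chain: EMG conditioning (band-pass, baseline
#' removal, sliding RMS, MVC normalization, artifact flagging per run),
#' turn-switch detection on the low-passed accelerometer resultant, cycle
#' construction, and reduction of every usable cycle of the two comparison
#' runs to scalar outcomes — EMG amplitude (%MVC), mean power frequency,
#' burst duration (ms and % of turn), turn time, joint angle extrema,
#' movement amplitude, peak angular velocities and run time.
#'
#' First/last cycles of each run are excluded, and a muscle's rows for a
#' cycle are dropped when more than `drop_artifact_frac` of its EMG samples
#' in that cycle are artifact-flagged (automatic surrogate for visual
#' artifact screening).
#'
#' @param session a validated [ski_session()].
#' @param mvc_reference optional named per-muscle reference RMS; defaults to
#'   the references stored in the session.
#' @param drop_artifact_frac artifact-sample fraction above which a
#'   (cycle, muscle) pair is dropped.
#' @param polarity turn polarity passed to [build_cycles()].
#' @param burst_threshold_pct activation threshold, %MVC.
#' @return list with `metrics` (tidy table, see [validate_metrics_table()]),
#'   `cycles` (cycle boundaries incl. exclusion flags), `counts` (per-run
#'   retained/dropped cycle bookkeeping) and `selected_runs`.
#' @export
build_metrics_table <- function(session, mvc_reference = NULL,
                                drop_artifact_frac = 0.05,
                                polarity = "right_first",
                                burst_threshold_pct = 20) {
  validate_session(session)
  disc <- session$discipline
  ref <- if (!is.null(mvc_reference)) mvc_reference else session$mvc_references
  if (is.null(ref))
    stop("no MVC reference available: supply mvc_reference or attach ",
         "mvc_references to the session")
  emg_rate <- SKI_EMG_RATE; lf_rate <- SKI_LF_RATE
  mk <- session$run_markers
  sel <- select_runs(mk)

  ## EMG conditioning per muscle
  env_pct <- benv_pct <- bp <- art <- list()
  for (m in SKI_MUSCLES) {
    raw <- session$channels[[m]]$data
    b <- bandpass_emg(raw, emg_rate)
    bl <- remove_baseline(b, emg_rate)
    env <- rms_envelope(bl, emg_rate)
    env_pct[[m]] <- normalize_to_mvc(env, ref[[m]])
    benv_pct[[m]] <- 100 * burst_envelope(b, disc, emg_rate) / ref[[m]]
    bp[[m]] <- b
    # artifact statistics per run segment (run-level nonstationarity)
    mask <- rep(FALSE, length(env))
    for (r in seq_len(nrow(mk))) {
      i0 <- max(1L, floor(mk$start_s[r] * emg_rate) + 1L)
      i1 <- min(length(env), ceiling(mk$end_s[r] * emg_rate))
      mask[i0:i1] <- artifact_mask(env[i0:i1])$mask
    }
    art[[m]] <- mask
  }

  ## Segmentation from the trunk accelerometer
  accr <- compute_accr(session$channels$acc_x$data,
                       session$channels$acc_y$data,
                       session$channels$acc_z$data)
  accr_f <- lowpass_accr(accr, disc, lf_rate)
  switches <- detect_turn_switches(accr_f, disc, lf_rate)
  cycles <- build_cycles(switches, mk, polarity)

  ## Kinematics
  ang <- vel <- list()
  for (j in SKI_JOINTS) {
    a <- lowpass_angles(session$channels[[paste0(j, "_angle")]]$data,
                        disc, lf_rate)
    ang[[j]] <- a
    vel[[j]] <- angular_velocity(a, lf_rate)
  }

  rows <- list()
  add <- function(run_index, run_label, cycle_index, leg, channel, metric,
                  value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session_id = session$session_id, run_index = run_index,
      run_label = run_label, cycle_index = cycle_index,
      leg = leg, channel = channel, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }

  counts <- NULL
  for (ri in seq_along(sel$runs)) {
    r <- sel$runs[ri]; lab <- sel$labels[ri]
    mrow <- mk[mk$run_index == r, ]
    add(r, lab, NA_integer_, NA_character_, NA_character_, "run_time_s",
        run_time(mrow$start_s, mrow$end_s))
    cyc <- cycles[cycles$run_index == r & !cycles$excluded, ]
    n_dropped_art <- 0L
    for (ci in seq_len(nrow(cyc))) {
      cy <- cyc[ci, ]
      halves <- list(IL = c(cy$start_s, cy$mid_s), OL = c(cy$mid_s, cy$end_s))
      # turn time and kinematics per leg
      for (lg in names(halves)) {
        h <- halves[[lg]]
        add(r, lab, cy$cycle_index, lg, NA_character_, "turn_time_ms",
            (h[2] - h[1]) * 1000)
        for (j in SKI_JOINTS) {
          ks <- kinematic_scalars(ang[[j]], vel[[j]], lf_rate, h[1], h[2])
          for (met in names(ks))
            add(r, lab, cy$cycle_index, lg, j, met, ks[[met]])
        }
      }
      # amplitude of movement over the full cycle (both legs together)
      for (j in SKI_JOINTS) {
        i0 <- max(1L, floor(cy$start_s * lf_rate) + 1L)
        i1 <- min(length(ang[[j]]), ceiling(cy$end_s * lf_rate))
        add(r, lab, cy$cycle_index, NA_character_, j, "amplitude_deg",
            max(ang[[j]][i0:i1]) - min(ang[[j]][i0:i1]))
      }
      # EMG metrics per muscle
      e0 <- max(1L, floor(cy$start_s * emg_rate) + 1L)
      e1 <- min(length(env_pct[[1]]), ceiling(cy$end_s * emg_rate))
      for (m in SKI_MUSCLES) {
        if (mean(art[[m]][e0:e1]) > drop_artifact_frac) {
          n_dropped_art <- n_dropped_art + 1L
          next
        }
        grid_env <- time_normalize(env_pct[[m]], emg_rate,
                                   cy$start_s, cy$mid_s, cy$end_s)
        rms <- turn_rms_pct(grid_env)
        for (lg in names(halves)) {
          h <- halves[[lg]]
          if (!is.na(rms[[lg]]))
            add(r, lab, cy$cycle_index, lg, m, "rms_pct_mvc", rms[[lg]])
          # MPF on the retained central window of the half, native rate
          hd <- h[2] - h[1]
          s0 <- max(1L, floor((h[1] + 0.2 * hd) * emg_rate) + 1L)
          s1 <- min(length(bp[[m]]), ceiling((h[2] - 0.2 * hd) * emg_rate))
          mpf <- turn_mpf(bp[[m]][s0:s1], emg_rate)
          if (!is.na(mpf)) add(r, lab, cy$cycle_index, lg, m, "mpf_hz", mpf)
          bt <- activation_time(benv_pct[[m]], emg_rate, h[1], h[2],
                                burst_threshold_pct)
          add(r, lab, cy$cycle_index, lg, m, "burst_ms", bt[["burst_ms"]])
          add(r, lab, cy$cycle_index, lg, m, "burst_pct", bt[["burst_pct"]])
        }
      }
    }
    counts <- rbind(counts, data.frame(
      run_index = r, run_label = lab,
      cycles_total = sum(cycles$run_index == r),
      cycles_excluded_ends = sum(cycles$run_index == r & cycles$excluded),
      cycle_muscle_dropped_artifact = n_dropped_art))
  }
  metrics <- do.call(rbind, rows)
  validate_metrics_table(metrics)
  list(metrics = metrics, cycles = cycles, counts = counts,
       selected_runs = sel)
}
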
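## Discipline-specific Butterworth cut-off tables (Hz). Goniometer angles and
## the accelerometer resultant are smoothed harder in the speed disciplines,
## whose turns are slower.
ANGLE_CUTOFF_HZ <- c(DH = 0.5, SG = 1, GS = 2, SL = 2.5)
ACCR_CUTOFF_HZ <- c(DH = 0.8, SG = 1, GS = 2, SL = 3)

#' Discipline cut-off lookups
#'
#' Low-pass cut-off frequencies of the fourth-order Butterworth stages:
#' 0.5 / 1 / 2 / 2.5 Hz (DH / SG / GS / SL) for the goniometer angles and
#' 0.8 / 1 / 2 / 3 Hz for the accelerometer resultant.
#'
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @return the cut-off in Hz.
#' @export
angle_cutoff_hz <- function(discipline) {
  ANGLE_CUTOFF_HZ[[match_discipline(discipline)]]
}

#' @rdname angle_cutoff_hz
#' @export
accr_cutoff_hz <- function(discipline) {
  ACCR_CUTOFF_HZ[[match_discipline(discipline)]]
}

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward (zero phase lag, so
#' segmentation and EMG-kinematics alignment are unaffected; the effective
#' magnitude response is the squared single-pass response). The signal is
#' extended on both sides by odd reflection before filtering, long enough for
#' near-DC cut-offs to settle, then trimmed; this keeps constants exactly
#' constant under low-pass filtering.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param cutoff_hz one (low/high) or two (pass) corner frequencies, Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param order filter order (2 or 4 in this pipeline).
#' @return the filtered signal, same length as `x`.
#' @export
butter_zerophase <- function(x, rate, cutoff_hz, type = "low", order = 4L) {
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= rate / 2))
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz)")
  n <- length(x)
  if (n < 8L) stop("signal too short to filter")
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = type)
  pad <- min(n - 1L, max(12L * order, ceiling(3 * rate / min(cutoff_hz))))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xe <- c(pre, x, post)
  # filter relative to the leading value so a constant carries no start-up
  # transient (the steady-state gain at DC is 1 for low-pass, 0 otherwise)
  one_pass <- function(z) {
    off <- z[1]
    y <- signal::filter(bf, z - off)
    if (type == "low") y + off else as.numeric(y)
  }
  y <- rev(one_pass(rev(one_pass(xe))))
  y[seq(pad + 1L, pad + n)]
}

#' Band-pass filter raw EMG
#'
#' Second-order Butterworth band-pass (default 20-500 Hz) applied zero-phase;
#' removes DC, movement artifact below 20 Hz and content above 500 Hz.
#'
#' @param x raw EMG samples.
#' @param rate sampling rate, Hz (must exceed 1000 so that the 500 Hz edge is
#'   below Nyquist).
#' @param low,high band edges, Hz.
#' @param order single-pass filter order.
#' @return filtered EMG, same length.
#' @export
bandpass_emg <- function(x, rate = SKI_EMG_RATE, low = 20, high = 500,
                         order = 2L) {
  butter_zerophase(x, rate, c(low, high), type = "pass", order = order)
}

#' Remove baseline drift with a 1-s moving average
#'
#' Subtracts a centred moving average (default width 1 s, reflection padding
#' at the edges) from the signal, suppressing slow baseline fluctuation while
#' leaving the EMG band essentially untouched.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param width_s moving-average width, seconds.
#' @return the detrended signal.
#' @export
remove_baseline <- function(x, rate, width_s = 1) {
  w <- round(width_s * rate)
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  if (n < w) stop("signal shorter than the baseline window (", width_s, " s)")
  half <- (w - 1L) %/% 2L
  xe <- c(x[seq(half + 1L, 2L)], x, x[seq(n - 1L, n - half)])  # reflection
  cs <- cumsum(c(0, xe))
  ma <- (cs[seq(w + 1L, length(cs))] - cs[seq_len(length(cs) - w)]) / w
  x - ma
}

#' Sliding RMS envelope
#'
#' Root-mean-square amplitude over a centred sliding window (default 125 ms),
#' one value per input sample; edge samples use a truncated window. The
#' envelope is non-negative and invariant to a sign flip of the input.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param epoch_ms window length, milliseconds.
#' @return numeric envelope, same length as `x`.
#' @export
rms_envelope <- function(x, rate, epoch_ms = 125) {
  if (epoch_ms <= 0) stop("epoch_ms must be positive")
  w <- round(epoch_ms / 1000 * rate)
  if (w %% 2 == 0) w <- w + 1L
  n <- length(x)
  if (n <= w) stop("signal shorter than the RMS epoch")
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Flag artifact samples on an RMS envelope
#'
#' Samples whose envelope exceeds mean +/- `n_sd` standard deviations
#' (default 6, with mean and SD computed over the supplied segment, normally
#' one run) are flagged as artifacts, emulating the automatic rejection of
#' transient vibration spikes. A zero-variance envelope yields an empty mask.
#'
#' @param env RMS envelope (non-negative numeric).
#' @param n_sd threshold width in standard deviations.
#' @param rate optional sampling rate; when given, flagged intervals are
#'   reported in seconds.
#' @return list with `mask` (logical, `TRUE` = artifact) and `intervals`
#'   (data.frame of flagged sample ranges, with times if `rate` is given).
#' @export
artifact_mask <- function(env, n_sd = 6, rate = NULL) {
  if (!length(env)) stop("empty envelope")
  m <- mean(env); s <- sd(env)
  mask <- if (is.na(s) || s == 0) rep(FALSE, length(env))
          else env > m + n_sd * s | env < m - n_sd * s
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!is.null(rate) && nrow(iv)) {
    iv$start_s <- (iv$start - 1) / rate
    iv$end_s <- (iv$end - 1) / rate
  }
  list(mask = mask, intervals = iv)
}

#' Extract the MVC reference from repeated trials
#'
#' For every trial the peak force and the maximal 500-ms sliding RMS of each
#' EMG trace during the force plateau are computed. The plateau is the
#' longest interval where force stays at or above 90% of the trial's peak.
#' Trials whose peak force is within 10% of the best trial of the same muscle
#' group are retained, and the per-muscle reference is the mean of the
#' retained trials' maxima — the maximal neural drive used to express
#' on-snow EMG in %MVC.
#'
#' @param trials a `ski_mvc_trials` list (see [generate_mvc_trials()]).
#' @param window_ms RMS window, milliseconds.
#' @param force_tol retention tolerance on peak force (fraction of maximum).
#' @param plateau_frac force threshold defining the plateau, fraction of the
#'   trial peak.
#' @return list with `reference` (named per-muscle RMS), `retained`
#'   (per-group indices of retained trials) and `peak_force` per trial.
#' @export
mvc_reference <- function(trials, window_ms = 500, force_tol = 0.10,
                          plateau_frac = 0.9) {
  if (!length(trials)) stop("no MVC trials supplied")
  groups <- vapply(trials, `[[`, character(1), "group")
  peak_force <- vapply(trials, function(tr) max(tr$force$data), numeric(1))
  per_trial_rms <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    f <- tr$force$data
    plateau <- f >= plateau_frac * max(f)
    r <- rle(plateau)
    if (!any(r$values)) stop("no detectable force plateau in trial ", i)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- which(r$values)[which.max(r$lengths[r$values])]
    p0 <- (starts[k] - 1) / tr$force$rate
    p1 <- (ends[k] - 1) / tr$force$rate
    vals <- c()
    for (m in names(tr$emg)) {
      e <- tr$emg[[m]]
      env <- rms_envelope(e$data, e$rate, epoch_ms = window_ms)
      w_half <- (window_ms / 1000) / 2   # the full window must sit in the plateau
      idx <- which((seq_along(env) - 1) / e$rate >= p0 + w_half &
                   (seq_along(env) - 1) / e$rate <= p1 - w_half)
      if (!length(idx)) stop("plateau shorter than the RMS window in trial ", i)
      vals[m] <- max(env[idx])
    }
    per_trial_rms[[i]] <- vals
  }
  reference <- c()
  retained <- list()
  for (grp in unique(groups)) {
    g <- which(groups == grp)
    keep <- g[peak_force[g] >= (1 - force_tol) * max(peak_force[g])]
    retained[[grp]] <- keep
    muscles <- names(per_trial_rms[[keep[1]]])
    for (m in muscles)
      reference[m] <- mean(vapply(per_trial_rms[keep], `[[`, numeric(1), m))
  }
  list(reference = reference, retained = retained, peak_force = peak_force,
       trial_rms = per_trial_rms)
}

#' Normalize an RMS envelope to %MVC
#'
#' @param env RMS envelope in raw units.
#' @param ref positive per-muscle MVC reference RMS in the same units.
#' @return envelope expressed in percent of the MVC reference.
#' @export
normalize_to_mvc <- function(env, ref) {
  if (!is.numeric(ref) || length(ref) != 1L || is.na(ref) || ref <= 0)
    stop("MVC reference must be a single positive number")
  100 * env / ref
}

#' Discipline-specific low-pass filtering of angles and AccR
#'
#' Fourth-order zero-phase Butterworth low-pass at the discipline cut-off
#' (see [angle_cutoff_hz()] and [accr_cutoff_hz()]), removing vibration while
#' preserving the turn-frequency content.
#'
#' @param x angle (degrees) or accelerometer-resultant (g) samples.
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param rate sampling rate, Hz.
#' @param order single-pass filter order.
#' @return the filtered series.
#' @export
lowpass_angles <- function(x, discipline, rate = SKI_LF_RATE, order = 4L) {
  butter_zerophase(x, rate, angle_cutoff_hz(discipline), "low", order)
}

#' @rdname lowpass_angles
#' @export
lowpass_accr <- function(x, discipline, rate = SKI_LF_RATE, order = 4L) {
  butter_zerophase(x, rate, accr_cutoff_hz(discipline), "low", order)
}

#' Joint angular velocity
#'
#' Central-difference derivative of the (filtered) joint angle. Negative
#' values indicate flexion (decreasing angle, with 180 degrees = full
#' extension), positive values extension.
#'
#' @param angle_deg filtered joint angle, degrees.
#' @param rate sampling rate, Hz.
#' @return angular velocity in degrees per second, same length (one-sided
#'   differences at the ends).
#' @export
angular_velocity <- function(angle_deg, rate) {
  n <- length(angle_deg)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  v <- numeric(n)
  v[2:(n - 1)] <- (angle_deg[3:n] - angle_deg[1:(n - 2)]) * rate / 2
  v[1] <- (angle_deg[2] - angle_deg[1]) * rate
  v[n] <- (angle_deg[n] - angle_deg[n - 1]) * rate
  v
}
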
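#' Resultant acceleration
#'
#' Elementwise vector norm of the tri-axial trunk accelerometer,
#' `sqrt(x^2 + y^2 + z^2)`, in g.
#'
#' @param acc_x,acc_y,acc_z equal-length axis samples, g.
#' @return the resultant acceleration series.
#' @export
compute_accr <- function(acc_x, acc_y, acc_z) {
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z))
    stop("accelerometer axes must have equal length")
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Detect turn switches from the filtered AccR
#'
#' A turn switch — the instant separating consecutive turns — is detected at
#' each local minimum of the low-passed resultant acceleration (the skier is
#' unloaded between edge sets, so AccR dips at every edge change). Noise-
#' induced double minima are suppressed by a minimum separation between
#' accepted minima, tied to the discipline cut-off (default
#' `0.5 / accr_cutoff_hz(discipline)` seconds); when two minima fall closer
#' than that, the deeper one wins.
#'
#' @param accr_filtered AccR already low-passed at the discipline cut-off
#'   (see [lowpass_accr()]).
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param rate sampling rate, Hz.
#' @param min_separation_s override for the minimum separation, seconds.
#' @return increasing switch times in seconds. Detection is invariant to a
#'   uniform rescaling of AccR. An error is raised if fewer than 3 switches
#'   are found (no complete cycle).
#' @export
detect_turn_switches <- function(accr_filtered, discipline,
                                 rate = SKI_LF_RATE, min_separation_s = NULL) {
  match_discipline(discipline)
  if (is.null(min_separation_s))
    min_separation_s <- 0.5 / accr_cutoff_hz(discipline)
  n <- length(accr_filtered)
  if (n < 3L) stop("no switches: signal too short")
  x <- accr_filtered
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  if (length(cand) >= 2L) {
    # greedy pruning: accept minima from deepest upward, enforce separation
    ord <- cand[order(x[cand])]
    min_gap <- min_separation_s * rate
    accepted <- integer(0)
    for (i in ord)
      if (!length(accepted) || all(abs(accepted - i) >= min_gap))
        accepted <- c(accepted, i)
    cand <- sort(accepted)
  }
  if (length(cand) < 3L)
    stop("no switches: fewer than 3 AccR minima detected")
  (cand - 1L) / rate
}

#' Build double-turn cycles from switch times
#'
#' Consecutive switches delimit single turns; with right-leg instrumentation
#' a cycle is one right turn (inside-leg role) followed by one left turn
#' (outside-leg role). Turns are labelled alternately from the first switch
#' of each run (polarity `"right_first"` by default; use `"left_first"` when
#' the run starts mid left turn, in which case the leading partial turn is
#' dropped). Cycles never cross run boundaries, and the first and last cycle
#' of every run are flagged `excluded` (unrepresentative entry/exit turns).
#'
#' @param switches switch times, seconds.
#' @param run_markers run-marker data.frame (`run_index`, `start_s`, `end_s`,
#'   `complete`).
#' @param polarity `"right_first"` or `"left_first"`.
#' @return data.frame of cycles: `run_index`, `cycle_index` (within run),
#'   `start_s`, `mid_s`, `end_s`, `excluded`.
#' @export
build_cycles <- function(switches, run_markers,
                         polarity = c("right_first", "left_first")) {
  polarity <- match.arg(polarity)
  out <- NULL
  for (r in seq_len(nrow(run_markers))) {
    mk <- run_markers[r, ]
    sw <- switches[switches >= mk$start_s & switches <= mk$end_s]
    if (polarity == "left_first" && length(sw) > 1L) sw <- sw[-1]
    if (length(sw) < 4L) next   # fewer than 3 turns: no usable pairing
    n_cycle <- (length(sw) - 1L) %/% 2L
    if (n_cycle < 1L) next
    idx <- seq_len(n_cycle)
    cyc <- data.frame(run_index = mk$run_index, cycle_index = idx,
                      start_s = sw[2L * idx - 1L], mid_s = sw[2L * idx],
                      end_s = sw[2L * idx + 1L],
                      excluded = idx == 1L | idx == n_cycle)
    out <- rbind(out, cyc)
  }
  if (is.null(out))
    stop("no run contains at least 4 switches; cannot build cycles")
  out
}

#' Time-normalize one cycle to the 200-point grid
#'
#' Each half of the cycle (right turn from `start` to `mid`, left turn from
#' `mid` to `end`) is resampled to 100 points by linear interpolation on its
#' own time base and the halves are concatenated, so each leg occupies
#' exactly 50% of the grid regardless of its duration and cycle percentages
#' are integral. Endpoint values are preserved.
#'
#' @param x channel samples (uniform rate, time 0 at the first sample).
#' @param rate sampling rate of `x`, Hz.
#' @param start_s,mid_s,end_s cycle boundaries, seconds
#'   (`start_s < mid_s < end_s`).
#' @param n_per_leg grid points per leg half.
#' @return numeric vector of length `2 * n_per_leg`.
#' @export
time_normalize <- function(x, rate, start_s, mid_s, end_s, n_per_leg = 100L) {
  if (!(start_s < mid_s && mid_s < end_s))
    stop("cycle boundaries must satisfy start < mid < end")
  n <- length(x)
  if (start_s < 0 || end_s > (n - 1) / rate)
    stop("cycle lies outside the sampled signal (empty half)")
  i0 <- max(1L, floor(start_s * rate))          # subset around the cycle
  i1 <- min(n, ceiling(end_s * rate) + 2L)
  t <- (seq(i0, i1) - 1) / rate
  xs <- x[i0:i1]
  g1 <- seq(start_s, mid_s, length.out = n_per_leg)
  g2 <- seq(mid_s, end_s, length.out = n_per_leg)
  c(approx(t, xs, xout = g1)$y, approx(t, xs, xout = g2)$y)
}

#' Edge-change phase mask over the normalized cycle grid
#'
#' The edge-change ("unloading") phases span 0-10%, 40-60% and 90-100% of
#' the double-turn cycle and are excluded from EMG averaging. On the default
#' 200-point grid the mask retains exactly 120 points (60%); interior range
#' boundaries are half-open so no point is double-counted.
#'
#' @param n_per_leg grid points per leg half (grid length is twice this).
#' @return logical vector, `TRUE` = retained (loaded phase).
#' @export
edge_phase_mask <- function(n_per_leg = 100L) {
  n <- 2L * n_per_leg
  pct <- (seq_len(n) - 1) * 100 / n
  !(pct < 10 | (pct >= 40 & pct < 60) | pct >= 90)
}
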
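#' Construct and validate a session recording
#'
#' A session recording bundles the raw multi-channel signals and metadata of
#' one skier-session (one athlete, one day, one discipline): five EMG
#' channels at 1926 Hz (`VM`, `RF`, `VL`, `BF`, `SMST`), the tri-axial trunk
#' accelerometer and two goniometer channels at 148 Hz (`acc_x`, `acc_y`,
#' `acc_z`, `knee_angle`, `hip_angle`), ordered non-overlapping run markers,
#' and optional per-muscle MVC reference RMS values.
#'
#' @param session_id opaque identifier; the grouping unit of the mixed models.
#' @param discipline one of `"SL"`, `"GS"`, `"SG"`, `"DH"`.
#' @param channels named list; each element a list with numeric `data` and a
#'   positive `rate` in Hz. All channels in [SKI_CHANNELS] are required.
#' @param run_markers data.frame with columns `run_index`, `start_s`,
#'   `end_s`, `complete`.
#' @param mvc_references optional named per-muscle maximal RMS (same units as
#'   the EMG channels).
#' @return a validated object of class `ski_session`.
#' @export
ski_session <- function(session_id, discipline, channels, run_markers,
                        mvc_references = NULL) {
  rec <- structure(list(session_id = as.character(session_id),
                        discipline = discipline,
                        channels = channels,
                        run_markers = run_markers,
                        mvc_references = mvc_references),
                   class = "ski_session")
  validate_session(rec)
  rec
}

#' Validate the structure of a session recording
#'
#' Checks channel completeness, sampling rates, absence of missing samples
#' inside run intervals, marker ordering, angle bounds (angles must lie in
#' (0, 180] degrees, 180 = full extension) and the presence of at least one
#' complete run. Every violation raises an error naming the offending field.
#'
#' @param rec a `ski_session`.
#' @return the recording, invisibly, if valid.
#' @export
validate_session <- function(rec) {
  if (!inherits(rec, "ski_session")) stop("not a ski_session object")
  match_discipline(rec$discipline)
  missing_ch <- setdiff(SKI_CHANNELS, names(rec$channels))
  if (length(missing_ch))
    stop("validation error: missing channel ", paste(missing_ch, collapse = ", "))
  for (ch in SKI_CHANNELS) {
    x <- rec$channels[[ch]]
    if (!is.list(x) || is.null(x$data) || is.null(x$rate))
      stop("validation error: channel ", ch, " must have data and rate")
    if (!is.numeric(x$rate) || length(x$rate) != 1L || x$rate <= 0)
      stop("validation error: channel ", ch, " has non-positive rate")
    expected <- if (ch %in% SKI_MUSCLES) SKI_EMG_RATE else SKI_LF_RATE
    if (x$rate != expected)
      stop("validation error: channel ", ch, " rate mismatch (", x$rate,
           " != ", expected, ")")
  }
  mk <- rec$run_markers
  need <- c("run_index", "start_s", "end_s", "complete")
  if (!is.data.frame(mk) || !all(need %in% names(mk)))
    stop("validation error: run_markers must have columns ",
         paste(need, collapse = ", "))
  if (nrow(mk) == 0L) stop("validation error: run_markers empty")
  if (is.unsorted(mk$run_index, strictly = TRUE))
    stop("validation error: run_markers not ordered by run_index")
  if (any(mk$end_s <= mk$start_s))
    stop("validation error: run marker with end_s <= start_s")
  if (nrow(mk) > 1L && any(mk$start_s[-1] < mk$end_s[-nrow(mk)]))
    stop("validation error: run_markers overlap")
  if (!any(mk$complete)) stop("validation error: no complete run exists")
  for (ch in SKI_CHANNELS) {
    x <- rec$channels[[ch]]
    t_end <- (length(x$data) - 1) / x$rate
    for (r in seq_len(nrow(mk))) {
      i0 <- max(1L, floor(mk$start_s[r] * x$rate) + 1L)
      i1 <- min(length(x$data), ceiling(mk$end_s[r] * x$rate))
      if (mk$end_s[r] > t_end + 1 / x$rate || anyNA(x$data[i0:i1]))
        stop("validation error: channel ", ch,
             " has missing samples inside run ", mk$run_index[r])
    }
  }
  for (ch in c("knee_angle", "hip_angle")) {
    a <- rec$channels[[ch]]$data
    if (any(a <= 0 | a > 180, na.rm = TRUE))
      stop("validation error: channel ", ch,
           " outside (0, 180] degrees (180 = full extension)")
  }
  if (!is.null(rec$mvc_references)) {
    if (!all(SKI_MUSCLES %in% names(rec$mvc_references)))
      stop("validation error: mvc_references must name all muscles")
    if (any(rec$mvc_references <= 0))
      stop("validation error: mvc_references must be positive")
  }
  invisible(rec)
}

## Full-precision numeric CSV helpers: values are printed with %.17g so that
## a write/read round trip reproduces every double bit-exactly.
write_numeric_csv <- function(df, path) {
  cols <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(cols, 1L, paste, collapse = ","))
  writeLines(lines, path)
}

#' Write / read a session recording
#'
#' The on-disk container is one directory holding a `metadata.json` file
#' (identifier, discipline, rates, run markers, MVC references) and one
#' two-column CSV (`time`, `value`) per channel under `channels/`. Values are
#' written at full precision so the round trip is lossless.
#'
#' @param rec a validated `ski_session`.
#' @param path directory to create (overwritten if it exists).
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed, validated `ski_session`.
#' @export
write_session <- function(rec, path) {
  validate_session(rec)
  dir.create(file.path(path, "channels"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(session_id = rec$session_id,
               discipline = rec$discipline,
               rates = lapply(rec$channels, `[[`, "rate"),
               run_markers = rec$run_markers,
               mvc_references = if (!is.null(rec$mvc_references))
                 as.list(rec$mvc_references))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (ch in names(rec$channels)) {
    x <- rec$channels[[ch]]
    df <- data.frame(time = (seq_along(x$data) - 1) / x$rate, value = x$data)
    write_numeric_csv(df, file.path(path, "channels", paste0(ch, ".csv")))
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("validation error: metadata.json not found in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- list()
  for (ch in SKI_CHANNELS) {
    f <- file.path(path, "channels", paste0(ch, ".csv"))
    if (!file.exists(f))
      stop("validation error: missing channel ", ch)
    d <- data.table::fread(f, colClasses = "numeric", showProgress = FALSE)
    rate <- meta$rates[[ch]]
    if (is.null(rate)) stop("validation error: no rate recorded for ", ch)
    channels[[ch]] <- list(data = d$value, rate = as.numeric(rate))
  }
  mk <- as.data.frame(meta$run_markers)
  mk$complete <- as.logical(mk$complete)
  refs <- meta$mvc_references
  if (!is.null(refs)) refs <- unlist(refs)[SKI_MUSCLES]
  ski_session(session_id = meta$session_id, discipline = meta$discipline,
              channels = channels, run_markers = mk, mvc_references = refs)
}

SKI_METRIC_NAMES <- c("rms_pct_mvc", "mpf_hz", "burst_ms", "burst_pct",
                      "turn_time_ms", "min_angle_deg", "max_angle_deg",
                      "amplitude_deg", "peak_flex_vel_dps",
                      "peak_ext_vel_dps", "run_time_s")
SKI_METRIC_COLS <- c("session_id", "run_index", "run_label", "cycle_index",
                     "leg", "channel", "metric", "value")

#' Validate a tidy per-turn metrics table
#'
#' One row per scalar outcome, keyed by skier-session, run, cycle, leg and
#' muscle/joint. Cycle-level outcomes (`amplitude_deg`, `run_time_s`,
#' `turn_time_ms` rows describing the whole cycle) may carry `NA` legs or
#' cycle indices. Enforced invariants: `burst_pct` in \[0, 100\],
#' `rms_pct_mvc` >= 0, `burst_ms` >= 0, legs in \{IL, OL\}, metric names in
#' the documented vocabulary.
#'
#' @param rows data.frame with columns `session_id`, `run_index`,
#'   `run_label`, `cycle_index`, `leg`, `channel`, `metric`, `value`.
#' @return the table, invisibly, if valid.
#' @export
validate_metrics_table <- function(rows) {
  if (!is.data.frame(rows)) stop("validation error: metrics table must be a data.frame")
  missing_col <- setdiff(SKI_METRIC_COLS, names(rows))
  if (length(missing_col))
    stop("validation error: missing column ", paste(missing_col, collapse = ", "))
  if (nrow(rows) == 0L) return(invisible(rows))
  bad <- setdiff(unique(rows$metric), SKI_METRIC_NAMES)
  if (length(bad))
    stop("validation error: unknown metric ", paste(bad, collapse = ", "))
  if (any(!is.na(rows$leg) & !rows$leg %in% c("IL", "OL")))
    stop("validation error: leg must be IL or OL")
  chk <- function(metric, test, msg) {
    v <- rows$value[rows$metric == metric]
    if (any(!test(v[!is.na(v)]))) stop("validation error: ", msg)
  }
  chk("burst_pct", function(v) v >= 0 & v <= 100, "burst_pct outside [0, 100]")
  chk("rms_pct_mvc", function(v) v >= 0, "negative rms_pct_mvc")
  chk("burst_ms", function(v) v >= 0, "negative burst_ms")
  chk("amplitude_deg", function(v) v >= 0, "negative amplitude_deg")
  invisible(rows)
}

#' Write / read the tidy metrics table
#'
#' Long-format CSV with a stable column order and full numeric precision;
#' invariant violations are rejected on write.
#'
#' @param rows a metrics table (see [validate_metrics_table()]).
#' @param path CSV file path.
#' @return `write_metrics_table` returns `path` invisibly;
#'   `read_metrics_table` returns the table as a data.frame.
#' @export
write_metrics_table <- function(rows, path) {
  validate_metrics_table(rows)
  if (nrow(rows) == 0L) {
    writeLines(paste(SKI_METRIC_COLS, collapse = ","), path)
    return(invisible(path))
  }
  write_numeric_csv(rows[, SKI_METRIC_COLS], path)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  d <- data.table::fread(path, showProgress = FALSE, na.strings = c("NA", ""),
                         colClasses = list(character = c("session_id", "run_label",
                                                         "leg", "channel", "metric")))
  d <- as.data.frame(d)
  if (nrow(d)) validate_metrics_table(d)
  d
}
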
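bandpass_zero_phase <- function(raw, fs, f_hp, f_lp, order = 4L) {
  if (fs <= 2 * f_lp)
    stop("sampling rate ", fs, " Hz too low for a ", f_lp,
         " Hz low-pass cutoff", call. = FALSE)
  hp <- signal::butter(order, f_hp / (fs / 2), type = "high")
  lp <- signal::butter(order, f_lp / (fs / 2), type = "low")
  out <- signal::filtfilt(hp, raw)
  out <- signal::filtfilt(lp, out)
  as.numeric(out)
}

#' Band-pass filter an ECG or PPG record (zero phase)
#'
#' Fourth-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero group delay, squared magnitude response).
#' ECG band: 1--40 Hz; PPG band: 0.5--20 Hz.
#'
#' @param raw Numeric sample vector.
#' @param fs Sampling rate (Hz); must exceed twice the low-pass cutoff.
#' @return Filtered vector, same length as the input.
#' @export
filter_ecg <- function(raw, fs) {
  stopifnot(fs > 80)
  bandpass_zero_phase(raw, fs, 1, 40)
}

#' @rdname filter_ecg
#' @export
filter_ppg <- function(raw, fs) {
  stopifnot(fs > 40)
  bandpass_zero_phase(raw, fs, 0.5, 20)
}

#' Detect R-peaks in a (filtered) ECG record
#'
#' Local maxima above an adaptive threshold (midway between the signal
#' median and maximum), thinned with a 250 ms refractory period that
#' keeps the taller peak of any conflicting pair.
#'
#' @param ecg Filtered ECG sample vector.
#' @param fs Sampling rate (Hz).
#' @param refractory Minimum peak separation (s), default 0.25.
#' @return Numeric vector of R-peak times (s, relative to the first
#'   sample).  Zero detections on a nonempty record raise a warning.
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25) {
  n <- length(ecg)
  if (n < 3L) {
    warning("record too short for peak detection", call. = FALSE)
    return(numeric(0))
  }
  thr <- stats::median(ecg) + 0.5 * (max(ecg) - stats::median(ecg))
  core <- ecg[2:(n - 1L)]
  is_peak <- core > ecg[1:(n - 2L)] & core >= ecg[3:n] & core > thr
  cand <- which(is_peak) + 1L
  if (length(cand) == 0L || max(ecg) <= min(ecg)) {
    warning("no R-peaks detected", call. = FALSE)
    return(numeric(0))
  }
  keep <- logical(length(cand))
  taken <- numeric(0)
  for (i in order(ecg[cand], decreasing = TRUE)) {
    tc <- (cand[i] - 1L) / fs
    if (!length(taken) || all(abs(taken - tc) >= refractory)) {
      keep[i] <- TRUE
      taken <- c(taken, tc)
    }
  }
  idx <- sort(cand[keep])
  (idx - 1L + parabolic_offset(ecg, idx)) / fs
}

# Sub-sample refinement: vertex of the parabola through the sample
# triple around each extremum (offset in samples, clamped to +/- 0.5).
parabolic_offset <- function(x, idx) {
  vapply(idx, function(i) {
    if (i <= 1L || i >= length(x)) return(0)
    denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (abs(denom) < .Machine$double.eps * 8) return(0)
    max(-0.5, min(0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / denom))
  }, numeric(1))
}

#' Locate the maximum-upslope point of the PPG in each cardiac cycle
#'
#' For each cycle \eqn{[r_i, r_{i+1})} (the last cycle runs to the end
#' of the record) the PPG rising edge is delimited by the pulse foot
#' (cycle minimum) and the subsequent cycle maximum, and the time of
#' the maximum first difference within that edge is returned.  Cycles
#' with no admissible point (e.g. flat PPG) yield \code{NA}.
#'
#' @param ppg Filtered PPG sample vector.
#' @param fs Sampling rate (Hz).
#' @param r_times R-peak times (s) from [detect_r_peaks()].
#' @return Numeric vector, one time (s) or \code{NA} per R-peak.
#' @export
detect_max_slope_points <- function(ppg, fs, r_times) {
  if (length(r_times) == 0L)
    stop("'r_times' must be nonempty", call. = FALSE)
  n <- length(ppg)
  bounds <- c(r_times, (n - 1L) / fs)
  vapply(seq_along(r_times), function(i) {
    i0 <- floor(r_times[i] * fs) + 1L
    i1 <- min(n, ceiling(bounds[i + 1L] * fs))
    if (i1 - i0 < 3L) return(NA_real_)
    seg <- ppg[i0:i1]
    if (max(seg) - min(seg) < 1e-9) return(NA_real_)
    peak_rel <- which.max(seg)            # pulse peak of this cycle
    foot <- which.min(seg[1:peak_rel])    # foot precedes the peak
    if (peak_rel - foot < 3L) return(NA_real_)
    # centred first difference on the rising edge, with sub-sample
    # parabolic refinement of its maximum
    edge <- foot:peak_rel
    d <- (seg[pmin(edge + 1L, length(seg))] -
            seg[pmax(edge - 1L, 1L)]) / 2
    jm <- which.max(d)
    j_abs <- i0 - 1L + edge[jm]
    (j_abs - 1L + parabolic_offset_vec(d, jm)) / fs
  }, numeric(1))
}

parabolic_offset_vec <- function(d, j) {
  if (j <= 1L || j >= length(d)) return(0)
  denom <- d[j - 1L] - 2 * d[j] + d[j + 1L]
  if (abs(denom) < .Machine$double.eps * 8) return(0)
  max(-0.5, min(0.5, 0.5 * (d[j - 1L] - d[j + 1L]) / denom))
}

#' Compute a per-beat pulse arrival time series
#'
#' PAT is the interval from each R-peak to the maximum-upslope point
#' of the PPG in the same cardiac cycle.  Beats with a missing slope
#' point are dropped; beats with a non-positive PAT are rejected with
#' a warning.
#'
#' @param r_times R-peak times (s).
#' @param slope_times Per-beat maximum-upslope times (s), \code{NA} for
#'   missing beats (same length as \code{r_times}).
#' @return data.frame with columns \code{beat_time} (the R-peak time)
#'   and \code{pat} (s).
#' @export
compute_pat_series <- function(r_times, slope_times) {
  stopifnot(length(r_times) == length(slope_times))
  pat <- slope_times - r_times
  keep <- !is.na(pat)
  if (any(pat[keep] <= 0)) {
    warning(sum(pat[keep] <= 0),
            " beat(s) rejected: non-positive PAT", call. = FALSE)
    keep <- keep & (is.na(pat) | pat > 0)
  }
  data.frame(beat_time = r_times[keep], pat = pat[keep])
}

#' Average a PAT series over analysis windows
#'
#' Computes the windowed mean PAT paired with each cuff measurement
#' window.  A window's mean uses beats whose R-time lies in
#' \code{[t_start, t_end)}; windows with fewer than \code{min_beats}
#' cardiac cycles (default 8, guarding against respiratory modulation)
#' are excluded and counted in the \code{n_excluded} attribute.
#'
#' @param series data.frame from [compute_pat_series()].
#' @param windows data.frame with columns \code{t_start}, \code{t_end}
#'   (non-overlapping, ascending).
#' @param min_beats Minimum cycles per admissible window, default 8.
#' @return data.frame with columns \code{t_start}, \code{t_end},
#'   \code{pat_bar}, \code{n_beats}; attribute \code{n_excluded}.
#' @export
average_pat_windows <- function(series, windows, min_beats = 8L) {
  windows <- as.data.frame(windows)
  stopifnot(all(c("t_start", "t_end") %in% names(windows)))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- series$beat_time >= windows$t_start[i] &
      series$beat_time < windows$t_end[i]
    data.frame(t_start = windows$t_start[i], t_end = windows$t_end[i],
               pat_bar = if (any(sel)) mean(series$pat[sel]) else NA_real_,
               n_beats = sum(sel))
  })
  out <- do.call(rbind, rows)
  keep <- out$n_beats >= min_beats
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!keep)
  res
}

#' Extract a PAT series from a raw two-channel waveform record
#'
#' Convenience wrapper: filter both channels, detect R-peaks, locate
#' per-cycle PPG maximum-upslope points, and assemble the PAT series.
#'
#' @param wave A \code{patbp_waveform} (or list with \code{ecg},
#'   \code{ppg}, \code{fs}).
#' @return data.frame from [compute_pat_series()].
#' @export
extract_pat <- function(wave) {
  ecg_f <- filter_ecg(wave$ecg, wave$fs)
  ppg_f <- filter_ppg(wave$ppg, wave$fs)
  r <- detect_r_peaks(ecg_f, wave$fs)
  s <- detect_max_slope_points(ppg_f, wave$fs, r)
  out <- compute_pat_series(r, s)
  t0 <- if (is.null(wave$t0)) 0 else wave$t0
  out$beat_time <- out$beat_time + t0   # back to record time
  out
}
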
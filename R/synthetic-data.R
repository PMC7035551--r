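#' Default distributions for synthetic subject profiles
#'
#' Means/SDs for each profile field.  Resting SBP/DBP follow the study
#' population (young healthy adults: SBP 118.37 +/- 12.95, DBP
#' 69.40 +/- 8.79 mmHg).  The remaining fields describe post-exercise
#' recovery during a seated recording: heart rate and PAT relax
#' exponentially back to rest with a shared time constant, PAT is
#' shortened immediately after exercise (higher BP, faster pulse
#' wave) and carries beat-to-beat jitter.
#'
#' @param ... Named overrides; each field is a c(mean, sd) pair except
#'   \code{generating_model}.
#' @return A list of c(mean, sd) pairs plus \code{generating_model}.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    sbp0 = c(118.37, 12.95),       # mmHg
    dbp0 = c(69.40, 8.79),         # mmHg
    pat0 = c(0.25, 0.02),          # s
    gamma = c(0.031, 0),           # mmHg^-1, healthy-adult constant
    heart_rate_rest = c(70, 7),    # bpm
    heart_rate_peak = c(100, 10),  # bpm, just after stair climbing
    pat_drop_exercise = c(0.080, 0.015), # s (~20 mmHg SBP elevation)
    decay_tau = c(180, 30),        # s
    pat_jitter_sd = c(0.005, 0),   # s
    pat_rest_fluct = c(0.030, 0),  # s, slow resting PAT wander amplitude
    generating_model = "dMK-BH")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown cohort_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

profile_ok <- function(p) {
  p$sbp0 > p$dbp0 && p$dbp0 > 0 && p$pat0 > 0 && p$gamma > 0 &&
    p$pat_drop_exercise >= 0 && p$pat0 - p$pat_drop_exercise > 0 &&
    p$heart_rate_rest > 0 && p$heart_rate_peak >= p$heart_rate_rest
}

#' Draw a synthetic cohort of subject profiles
#'
#' Each profile field is drawn independently from a Gaussian with the
#' configured mean/SD; draws violating the physiological constraints
#' (SBP0 > DBP0 > 0, PAT0 minus the exercise drop positive, peak HR at
#' least resting HR) are re-drawn, up to a bounded retry count.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [cohort_config()] list.
#' @param seed Optional integer seed; identical seeds give identical
#'   cohorts.
#' @param max_retries Retries per subject before the config is declared
#'   invalid.
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{sbp0}, \code{dbp0}, \code{pat0}, \code{gamma},
#'   \code{heart_rate_rest}, \code{heart_rate_peak},
#'   \code{pat_drop_exercise}, \code{decay_tau}, \code{pat_jitter_sd},
#'   \code{generating_model}.
#' @export
make_cohort <- function(n_subjects, config = cohort_config(),
                        seed = NULL, max_retries = 100L) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  fields <- setdiff(names(config), "generating_model")
  draw_one <- function(id) {
    for (try in seq_len(max_retries)) {
      p <- lapply(config[fields], function(ms) stats::rnorm(1L, ms[1L], ms[2L]))
      p$generating_model <- config$generating_model
      if (profile_ok(p)) {
        p$subject_id <- id
        return(as.data.frame(p))
      }
    }
    stop("could not draw a valid profile after ", max_retries,
         " retries; check cohort_config distributions", call. = FALSE)
  }
  out <- do.call(rbind, lapply(sprintf("S%02d", seq_len(n_subjects)),
                               draw_one))
  out <- out[c("subject_id", fields, "generating_model")]
  rownames(out) <- NULL
  out
}

as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- as.list(profile)
  }
  profile
}

#' Simulate a per-beat PAT trajectory for one subject
#'
#' In the post-exercise state, heart rate recovers exponentially from
#' \code{heart_rate_peak} to \code{heart_rate_rest} with time constant
#' \code{decay_tau}; beat times follow the instantaneous rate.  True
#' PAT recovers from its post-exercise shortened value back to
#' \code{pat0}:
#' \deqn{PAT(t) = PAT_0 - \Delta \exp(-t/\tau) + \epsilon_t,}
#' with Gaussian per-beat jitter of SD \code{pat_jitter_sd}.  At a
#' 15-minute duration and study-like heart rates this yields on the
#' order of a thousand or more beats per subject.
#'
#' In the rest state, heart rate is constant and mean PAT wanders
#' slowly about \code{pat0} (two incommensurate low-frequency
#' sinusoids with random phases, amplitude \code{pat_rest_fluct}),
#' emulating the natural resting blood-pressure variability that makes
#' repeated quiet-state cuff readings differ from one another; jitter
#' applies on top.  Setting \code{pat_rest_fluct = 0} gives a
#' strictly stationary PAT at \code{pat0}.
#'
#' @param profile One cohort row (data.frame row or list).
#' @param duration Record length (s), > 0; default 900.
#' @param seed Optional integer seed.
#' @param state \code{"post_exercise"} (default): HR and PAT recover
#'   exponentially, the segment clock starting at the end of exercise.
#'   \code{"rest"}: constant resting HR and PAT mean \code{pat0}
#'   (jitter still applies) -- the quiet state in which baseline
#'   calibration is performed.
#' @param t_offset Shift added to all beat times (s), for placing a
#'   segment inside a longer session.
#' @return data.frame with columns \code{beat_time} (s, strictly
#'   increasing) and \code{pat_true} (s, positive).
#' @export
simulate_pat_trajectory <- function(profile, duration = 900,
                                    seed = NULL,
                                    state = c("post_exercise", "rest"),
                                    t_offset = 0) {
  p <- as_profile(profile)
  state <- match.arg(state)
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  beat_times <- numeric(0)
  t <- 0
  while (t < duration) {
    beat_times <- c(beat_times, t)
    hr <- if (state == "rest") p$heart_rate_rest else
      p$heart_rate_rest +
        (p$heart_rate_peak - p$heart_rate_rest) * exp(-t / p$decay_tau)
    t <- t + 60 / hr
  }
  if (state == "rest") {
    fluct <- if (is.null(p$pat_rest_fluct)) 0 else p$pat_rest_fluct
    pat <- rep(p$pat0, length(beat_times))
    if (fluct > 0) {
      phases <- stats::runif(2, 0, 2 * pi)
      # Mayer-wave-scale wander: periods of ~110 s and ~40 s
      pat <- pat + fluct *
        (0.8 * sin(2 * pi * beat_times / 110 + phases[1L]) +
           0.45 * sin(2 * pi * beat_times / 40 + phases[2L]))
    }
  } else {
    pat <- p$pat0 - p$pat_drop_exercise * exp(-beat_times / p$decay_tau)
  }
  if (p$pat_jitter_sd > 0)
    pat <- pat + stats::rnorm(length(pat), 0, p$pat_jitter_sd)
  if (any(pat <= 0))
    stop("simulated PAT non-positive; jitter too large for this profile",
         call. = FALSE)
  data.frame(beat_time = beat_times + t_offset, pat_true = pat)
}

#' Generating model parameters implied by a subject profile
#'
#' A profile's baseline (SBP0, DBP0, PAT0, gamma) defines a reference
#' dMK-BH pressure-PAT curve.  For baseline-anchored generating models
#' (MK-BH, dMK-BH) the parameters are the baseline itself.  For the
#' coefficient models (MK-EE, L-MK, M-M) parameters are obtained by
#' exact calibration to the reference curve at k anchor PATs spanning
#' the subject's simulated PAT range, so that ground-truth BP derived
#' from them is exactly consistent with the declared generating model.
#'
#' @param profile One cohort row.
#' @return A \code{patbp_model} for \code{profile$generating_model}.
#' @export
generating_params <- function(profile) {
  p <- as_profile(profile)
  model <- match_model_id(p$generating_model)
  bl <- baseline_state(p$sbp0, p$dbp0, p$pat0, gamma = p$gamma)
  if (model %in% c("MK-BH", "dMK-BH"))
    return(new_patbp_model(model, baseline = bl))
  ref <- new_patbp_model("dMK-BH", baseline = bl)
  fluct <- if (is.null(p$pat_rest_fluct)) 0 else p$pat_rest_fluct
  margin <- 8 * p$pat_jitter_sd + 2 * fluct + 0.005
  lo <- p$pat0 - p$pat_drop_exercise - margin
  hi <- p$pat0 + margin
  if (lo <= 0) stop("profile PAT range reaches zero", call. = FALSE)
  k <- required_calibration_points(model)
  # The reference curve's DBP channel is non-monotone at very short
  # PAT, which the monotone M-M form cannot interpolate; shrink the
  # anchor range from below until the exact fit succeeds.
  for (shrink in seq(0, 0.75, by = 0.15)) {
    anchors <- seq(lo + (hi - lo) * shrink, hi, length.out = k)
    refbp <- estimate_bp(ref, anchors, warn_crossed = FALSE)
    fit <- tryCatch(
      calibrate_bp_model(model,
                         data.frame(pat = anchors, sbp = refbp$sbp,
                                    dbp = refbp$dbp),
                         gamma = p$gamma),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stop("could not construct ", model,
       " generating parameters for this profile", call. = FALSE)
}

#' Derive per-beat ground-truth BP from a PAT trajectory
#'
#' Evaluates the generating model at each beat's true PAT, so the
#' ground truth is exactly model-consistent (noiseless round trips
#' recover the generating parameters exactly).
#'
#' @param pat_traj data.frame from [simulate_pat_trajectory()].
#' @param params A \code{patbp_model} (e.g. [generating_params()]).
#' @return data.frame with columns \code{beat_time}, \code{sbp_true},
#'   \code{dbp_true} (mmHg).
#' @export
derive_true_bp <- function(pat_traj, params) {
  est <- estimate_bp(params, pat_traj$pat_true, warn_crossed = FALSE)
  data.frame(beat_time = pat_traj$beat_time, sbp_true = est$sbp,
             dbp_true = est$dbp)
}

# PPG pulse: difference of Gaussian CDFs -- a sharp rise whose maximum
# slope sits at the PAT fiducial, then a slow decay well separated in
# time so it does not move the upslope maximum.
ppg_pulse_rise_sd <- 0.012   # s
ppg_pulse_decay_sd <- 0.080  # s
ppg_pulse_decay_lag <- 0.25  # s

#' Render synthetic ECG/PPG waveforms from a PAT trajectory
#'
#' ECG is a train of narrow Gaussian R-like spikes, one at each beat
#' time; PPG is one pulse per beat built so the maximum of its first
#' derivative falls at \code{beat_time + pat_true} to within one
#' sample.  Morphology is deliberately minimal: only the R-peak and
#' maximum-upslope timing matter downstream.
#'
#' @param pat_traj data.frame from [simulate_pat_trajectory()].
#' @param fs Sampling rate (Hz), >= 200; default 1000.
#' @param noise_sd Additive Gaussian noise SD on both channels
#'   (amplitude units; spike amplitude is 1).
#' @param seed Optional integer seed.
#' @return A list of class \code{patbp_waveform} with elements
#'   \code{fs}, \code{t0}, \code{t}, \code{ecg}, \code{ppg}.
#' @export
render_waveforms <- function(pat_traj, fs = 1000, noise_sd = 0,
                             seed = NULL) {
  stopifnot(fs >= 200)
  bt <- pat_traj$beat_time
  pat <- pat_traj$pat_true
  if (length(bt) > 1L && min(diff(bt)) <= max(pat) + 0.05)
    stop("invalid trajectory: beats closer together than the ",
         "synthesized pulse width", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t0 <- min(bt) - 0.5           # pre-roll so the first beat is intact
  t_end <- max(bt) + max(pat) + 0.6
  n <- floor((t_end - t0) * fs) + 1L
  tt <- t0 + (seq_len(n) - 1L) / fs
  ecg <- numeric(n); ppg <- numeric(n)
  ecg_sd <- 0.008
  add_local <- function(sig, center, halfwidth, fun) {
    i0 <- max(1L, floor((center - halfwidth - t0) * fs) + 1L)
    i1 <- min(n, ceiling((center + halfwidth - t0) * fs) + 1L)
    idx <- i0:i1
    sig[idx] <- sig[idx] + fun(tt[idx])
    sig
  }
  for (b in seq_along(bt)) {
    ecg <- add_local(ecg, bt[b], 6 * ecg_sd, function(x)
      exp(-(x - bt[b])^2 / (2 * ecg_sd^2)))
    rise_c <- bt[b] + pat[b]
    decay_c <- rise_c + ppg_pulse_decay_lag
    ppg <- add_local(ppg, rise_c + ppg_pulse_decay_lag / 2,
                     ppg_pulse_decay_lag / 2 + 5 * ppg_pulse_decay_sd +
                       5 * ppg_pulse_rise_sd,
                     function(x)
                       stats::pnorm((x - rise_c) / ppg_pulse_rise_sd) -
                       stats::pnorm((x - decay_c) / ppg_pulse_decay_sd))
  }
  if (noise_sd > 0) {
    ecg <- ecg + stats::rnorm(n, 0, noise_sd)
    ppg <- ppg + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(fs = fs, t0 = t0, t = tt, ecg = ecg, ppg = ppg),
            class = "patbp_waveform")
}

#' @export
print.patbp_waveform <- function(x, ...) {
  cat(sprintf("Synthetic ECG/PPG record: %.1f s at %g Hz (%d samples)\n",
              length(x$t) / x$fs, x$fs, length(x$t)))
  invisible(x)
}

#' Simulate periodic cuff blood-pressure readings
#'
#' Each reading occupies a measurement window (a cuff cycle takes
#' about 30 s); the reported SBP/DBP is the mean of the true per-beat
#' values inside the window plus independent Gaussian device error
#' (default SD 2.5 mmHg, emulating a consumer oscillometric monitor of
#' roughly 3 mmHg accuracy).
#'
#' @param bp_traj data.frame from [derive_true_bp()].
#' @param interval Start-to-start spacing of readings (s), default 30.
#' @param meas_duration Window length of one reading (s), default 30;
#'   must not exceed \code{interval}.
#' @param device_sd Device error SD (mmHg), default 2.5.
#' @param t_start First window start (s); defaults to the trajectory
#'   start.
#' @param t_end No window may extend past this time; defaults to the
#'   trajectory end.
#' @param seed Optional integer seed.
#' @return data.frame with columns \code{t_start}, \code{t_end},
#'   \code{sbp}, \code{dbp}.
#' @export
simulate_cuff_readings <- function(bp_traj, interval = 30,
                                   meas_duration = 30, device_sd = 2.5,
                                   t_start = NULL, t_end = NULL,
                                   seed = NULL) {
  stopifnot(interval >= meas_duration, meas_duration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_start)) t_start <- min(bp_traj$beat_time)
  if (is.null(t_end)) t_end <- ceiling(max(bp_traj$beat_time))
  if (t_end - meas_duration < t_start)
    stop("cuff schedule does not fit inside the BP trajectory",
         call. = FALSE)
  starts <- seq(t_start, t_end - meas_duration, by = interval)
  out <- lapply(starts, function(s) {
    sel <- bp_traj$beat_time >= s & bp_traj$beat_time < s + meas_duration
    if (!any(sel))
      stop("cuff window [", s, ", ", s + meas_duration,
           "] overlaps no beats: schedule/trajectory mismatch",
           call. = FALSE)
    data.frame(t_start = s, t_end = s + meas_duration,
               sbp = mean(bp_traj$sbp_true[sel]),
               dbp = mean(bp_traj$dbp_true[sel]))
  })
  out <- do.call(rbind, out)
  if (device_sd > 0) {
    out$sbp <- out$sbp + stats::rnorm(nrow(out), 0, device_sd)
    out$dbp <- out$dbp + stats::rnorm(nrow(out), 0, device_sd)
  }
  out
}
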
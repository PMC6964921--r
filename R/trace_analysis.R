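# Per-trial analysis chain: zero-phase low-pass filtering,
# central-difference kinematics, acceleration-threshold saccade detection,
# exclusion rules, and the predicted-error / crossing-time metrics.
#
# All bin edges downstream are half-open [lo, hi); time is ms from trial
# start; degrees rightward positive.

#' Zero-phase low-pass filter
#'
#' Butterworth filter applied forward and backward (zero phase lag).
#' NaN gaps (blinks, dropouts) split the series into finite runs; each run
#' long enough for the filter is processed independently and gaps are
#' preserved.
#'
#' @param x Uniformly sampled numeric series.
#' @param cutoff Cutoff frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @param order Butterworth order (the forward-backward pass doubles the
#'   effective order).
#' @return Filtered series, same length.
#' @export
lowpass_zero_phase <- function(x, cutoff = 50, rate = 1000, order = 2) {
  min_len <- 3 * (order * 3 + 1)
  if (length(x) < min_len)
    stop("lowpass_zero_phase: series shorter than 3x the filter order")
  bf <- signal::butter(order, cutoff / (rate / 2))
  # odd-reflection padding at both ends so the forward-backward pass sees
  # continuous data (filtfilt assumes zero initial state)
  ff <- function(z) {
    np <- min(length(z) - 1, max(3 * round(rate / cutoff), 9))
    head_pad <- 2 * z[1] - z[(np + 1):2]
    tail_pad <- 2 * z[length(z)] - z[(length(z) - 1):(length(z) - np)]
    zf <- signal::filtfilt(bf, c(head_pad, z, tail_pad))
    zf[(np + 1):(np + length(z))]
  }
  out <- x
  ok <- is.finite(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_len) next
    idx <- starts[k]:ends[k]
    out[idx] <- ff(x[idx])
  }
  out
}

#' Central-difference derivative
#'
#' Interior: v[i] = (x[i+1] - x[i-1]) * rate / 2 (exact for linear series;
#' applied twice it is exact for quadratics). Endpoints use one-sided
#' differences. NaN at sample i propagates to i-1 and i+1.
#'
#' @param x Numeric series (length >= 3).
#' @param rate Sampling rate, Hz.
#' @return Derivative series, same length.
#' @export
differentiate_central <- function(x, rate = 1000) {
  n <- length(x)
  stopifnot(n >= 3)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v
}

#' Detect saccades by acceleration threshold
#'
#' Samples where |acceleration| exceeds `threshold` are grouped into events;
#' events separated by less than `merge_gap_ms` are merged; onsets and
#' offsets are refined outward to the nearest local extremum of velocity in
#' the saccade direction; events shorter than `min_dur_ms` are dropped.
#' Amplitude is the eye displacement from onset to offset.
#'
#' @param pos,vel,acc Filtered eye position and its derivatives.
#' @param time_ms Sample times.
#' @param threshold Acceleration threshold, deg/s^2 (default 750).
#' @param merge_gap_ms Merge gap, ms.
#' @param min_dur_ms Minimum event duration, ms.
#' @param refine_max_ms Farthest the onset/offset refinement may walk
#'   beyond the threshold crossing, ms.
#' @return Data frame with onset_ms, offset_ms, amplitude.
#' @export
detect_saccades <- function(pos, vel, acc, time_ms, threshold = 750,
                            merge_gap_ms = 20, min_dur_ms = 6,
                            refine_max_ms = 15) {
  dt_ms <- time_ms[2] - time_ms[1]
  over <- abs(acc) > threshold
  over[!is.finite(acc)] <- FALSE
  if (!any(over))
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude = numeric(0)))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  spans <- cbind(starts[r$values], ends[r$values])
  # merge spans separated by less than the gap
  merged <- list(spans[1, ])
  if (nrow(spans) > 1) {
    for (k in 2:nrow(spans)) {
      last <- merged[[length(merged)]]
      if ((spans[k, 1] - last[2]) * dt_ms < merge_gap_ms) {
        merged[[length(merged)]] <- c(last[1], spans[k, 2])
      } else {
        merged[[length(merged) + 1]] <- spans[k, ]
      }
    }
  }
  n <- length(pos)
  ev <- lapply(merged, function(sp) {
    i0 <- sp[1]; i1 <- sp[2]
    kmax <- round(refine_max_ms / dt_ms)
    lo <- max(1, sp[1] - kmax)
    hi <- min(n, sp[2] + kmax)
    # saccade direction from the velocity deviation against the local
    # pursuit baseline (net displacement misleads for small saccades
    # against fast pursuit)
    base_idx <- c(lo:sp[1], sp[2]:hi)
    base <- stats::median(vel[base_idx], na.rm = TRUE)
    dev <- vel[i0:i1] - base
    ipk <- (i0:i1)[which.max(abs(dev))]
    dirn <- sign(vel[ipk] - base)
    if (dirn == 0 || is.na(dirn)) dirn <- 1
    # onset/offset at the local minima of directed velocity on either
    # side of the velocity peak (the threshold crossing sits well down
    # the filtered flank); the walk is capped beyond the raw span
    i0 <- ipk
    while (i0 > lo && is.finite(vel[i0 - 1]) &&
           dirn * vel[i0 - 1] < dirn * vel[i0]) i0 <- i0 - 1
    i1 <- ipk
    while (i1 < hi && is.finite(vel[i1 + 1]) &&
           dirn * vel[i1 + 1] < dirn * vel[i1]) i1 <- i1 + 1
    # the filtered flank leaves the velocity minimum well before the
    # movement proper: take the first rise above 5% of the peak-to-
    # baseline excursion on each side
    v0 <- dirn * vel[i0]; v1 <- dirn * vel[i1]; vp <- dirn * vel[ipk]
    while (i0 < ipk && dirn * vel[i0 + 1] - v0 < 0.05 * (vp - v0))
      i0 <- i0 + 1
    while (i1 > ipk && dirn * vel[i1 - 1] - v1 < 0.05 * (vp - v1))
      i1 <- i1 - 1
    c(i0, i1)
  })
  out <- data.frame(
    onset_ms = vapply(ev, function(e) time_ms[e[1]], numeric(1)),
    offset_ms = vapply(ev, function(e) time_ms[e[2]], numeric(1)),
    amplitude = vapply(ev, function(e) pos[e[2]] - pos[e[1]], numeric(1)))
  out <- out[out$offset_ms - out$onset_ms >= min_dur_ms, , drop = FALSE]
  # refinement can make neighbours touch; enforce ordering
  out <- out[order(out$onset_ms), , drop = FALSE]
  if (nrow(out) > 1) {
    keep <- c(TRUE, out$onset_ms[-1] > out$offset_ms[-nrow(out)])
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Position error and retinal slip series
#'
#' PE = target - eye (deg); RS = target velocity - eye velocity (deg/s).
#'
#' @param target,eye Position series (eye already filtered).
#' @param target_vel,eye_vel Velocity series.
#' @return List with `pe`, `rs`.
#' @export
compute_errors <- function(target, eye, target_vel, eye_vel) {
  list(pe = target - eye, rs = target_vel - eye_vel)
}

#' Predicted position error
#'
#' PE_pred = PE + dt * RS.
#'
#' @param pe Position error, deg.
#' @param rs Retinal slip, deg/s.
#' @param dt Extrapolation horizon, seconds (default 0.15).
#' @return PE_pred in degrees (vectorised).
#' @export
compute_pe_pred <- function(pe, rs, dt = 0.15) {
  pe + dt * rs
}

#' Eye-crossing time
#'
#' T_xe = -PE / RS, in ms: the time until the eye's current trajectory
#' intersects the target. Undefined (NA) when |RS| is below `eps` --
#' crossing time is unstable as slip approaches zero.
#'
#' @param pe Position error, deg.
#' @param rs Retinal slip, deg/s.
#' @param eps Slip magnitude below which the ratio is undefined.
#' @return T_xe in ms (vectorised; NA marks undefined).
#' @export
compute_txe <- function(pe, rs, eps = 1e-9) {
  out <- -pe / rs * 1000
  out[abs(rs) < eps] <- NA_real_
  out
}

#' Target-crossing time
#'
#' T_xt = -PS / VS, in ms: the time for the stepped target to re-cross its
#' pre-step trajectory. Undefined (NA) for VS = 0.
#'
#' @param ps2 Position step, deg.
#' @param vs2 Velocity step, deg/s.
#' @return T_xt in ms (vectorised; NA marks undefined).
#' @export
compute_txt <- function(ps2, vs2) {
  out <- -ps2 / vs2 * 1000
  out[vs2 == 0] <- NA_real_
  out
}

#' Predicted position error averaged over a window after the target step
#'
#' @param pe_pred PE_pred series.
#' @param time_ms Sample times.
#' @param step2_ms Second-step time.
#' @param window Averaging window, ms (default 50).
#' @return Mean PE_pred over [step2, step2 + window).
#' @export
pe_pred_at_step <- function(pe_pred, time_ms, step2_ms, window = 50) {
  idx <- time_ms >= step2_ms & time_ms < step2_ms + window
  mean(pe_pred[idx], na.rm = TRUE)
}

#' Sample the pre-saccadic sensory state
#'
#' Instantaneous PE and RS `lead` ms before the saccade onset (the last
#' moment sensory input can influence the trigger), with PE_pred and T_xe
#' derived from them. If onset - lead falls before the target step, the
#' sample is taken at the step and flagged.
#'
#' @param pe,rs Error series.
#' @param time_ms Sample times.
#' @param onset_ms Saccade onset.
#' @param step2_ms Second-step time.
#' @param lead Sampling lead, ms (default 100).
#' @param dt Extrapolation horizon, s.
#' @return List with pe, rs, pe_pred, txe, t_sample_ms, clamped.
#' @export
sample_presaccadic <- function(pe, rs, time_ms, onset_ms, step2_ms,
                               lead = 100, dt = 0.15) {
  t_s <- onset_ms - lead
  clamped <- t_s < step2_ms
  if (clamped) t_s <- step2_ms
  i <- which.min(abs(time_ms - t_s))
  list(pe = pe[i], rs = rs[i],
       pe_pred = compute_pe_pred(pe[i], rs[i], dt),
       txe = compute_txe(pe[i], rs[i]),
       t_sample_ms = time_ms[i], clamped = clamped)
}

#' Classify a trial as early, late or smooth
#'
#' Smooth: no saccade onset within `window` ms of the second step. Early:
#' trigger time below `early_cutoff`; late otherwise.
#'
#' @param trigger_time Trigger time (onset - step2), ms, or NA.
#' @param window Classification window, ms (default 400).
#' @param early_cutoff Early/late boundary, ms (default 175).
#' @return "early", "late" or "smooth".
#' @export
classify_trial <- function(trigger_time, window = 400, early_cutoff = 175) {
  if (is.na(trigger_time) || trigger_time >= window) return("smooth")
  if (trigger_time < early_cutoff) "early" else "late"
}

#' Apply the trial exclusion rules
#'
#' A trial is excluded when (in order of precedence): eye samples are
#' missing (blink/dropout NaN) at or after the second step within the
#' critical window; a saccade is in flight at the second step; two
#' post-step saccades follow each other within `double_isi_ms` (double
#' saccade); or the first post-step saccade was made to the first ramp's
#' trajectory rather than to the stepped target -- it lands closer to the
#' extrapolated pre-step trajectory than to the actual target, or moves
#' opposite to the position error at its onset.
#'
#' @param eye Eye position series (unfiltered is fine; only NaNs matter).
#' @param time_ms Sample times.
#' @param events Detected saccades (data frame from [detect_saccades()]).
#' @param step2_ms Second-step time.
#' @param pe PE series (for the direction rule).
#' @param target Target position series (for the first-ramp landing rule).
#' @param ps2,vs2 Second step parameters; when supplied, the pre-step
#'   trajectory target(t) - ps2 - vs2 (t - step2) is reconstructed for the
#'   first-ramp rule.
#' @param window Classification window, ms.
#' @param critical_pad Extra time after the window still considered
#'   critical, ms.
#' @param double_isi_ms Inter-saccadic interval defining a double saccade.
#' @return List with `keep` (logical) and `reason` ("ok", "blink",
#'   "saccade_at_step", "double_saccade", "first_ramp",
#'   "wrong_direction").
#' @export
apply_exclusions <- function(eye, time_ms, events, step2_ms, pe,
                             target = NULL, ps2 = NA, vs2 = NA,
                             window = 400, critical_pad = 200,
                             double_isi_ms = 100) {
  crit <- time_ms >= step2_ms & time_ms <= step2_ms + window + critical_pad
  if (any(!is.finite(eye[crit])))
    return(list(keep = FALSE, reason = "blink"))
  if (nrow(events) > 0 &&
      any(events$onset_ms <= step2_ms & events$offset_ms >= step2_ms))
    return(list(keep = FALSE, reason = "saccade_at_step"))
  post <- events[events$onset_ms > step2_ms, , drop = FALSE]
  if (nrow(post) >= 2) {
    isi <- post$onset_ms[-1] - post$offset_ms[-nrow(post)]
    first_in_window <- post$onset_ms[1] - step2_ms < window
    if (first_in_window && isi[1] < double_isi_ms)
      return(list(keep = FALSE, reason = "double_saccade"))
  }
  if (nrow(post) > 0 && post$onset_ms[1] - step2_ms < window) {
    i_off <- which.min(abs(time_ms - post$offset_ms[1]))
    if (!is.null(target) && !is.na(ps2) && !is.na(vs2)) {
      # landing position against actual target vs extrapolated first ramp
      t_off <- time_ms[i_off]
      tgt_new <- target[i_off]
      tgt_old <- tgt_new - ps2 - vs2 * (t_off - step2_ms) / 1000
      eye_off <- eye[i_off]
      if (is.finite(eye_off) &&
          abs(eye_off - tgt_old) < abs(eye_off - tgt_new))
        return(list(keep = FALSE, reason = "first_ramp"))
    }
    i_on <- which.min(abs(time_ms - post$onset_ms[1]))
    pe_on <- pe[i_on]
    if (is.finite(pe_on) && abs(pe_on) > 0.25 &&
        sign(post$amplitude[1]) != sign(pe_on))
      return(list(keep = FALSE, reason = "wrong_direction"))
  }
  list(keep = TRUE, reason = "ok")
}

#' Analyse a single eye trace
#'
#' Runs the full per-trial chain: filtering, kinematics, saccade detection,
#' exclusions, classification and the PE_pred / T_xe / T_xt metrics.
#'
#' Sampled metrics: `pe_pred_step` averages PE_pred over the 50-ms window
#' after the step (trigger-time analyses); `pe_sample` / `rs_sample` /
#' `pe_pred_sample` / `txe_sample` hold the pre-saccadic sample (100 ms
#' before onset) for saccade trials and the 400-ms post-step average for
#' smooth trials (occurrence analyses).
#'
#' @param trace An `eye_trace`.
#' @param dt Extrapolation horizon, s.
#' @param lp_cutoff,acc_threshold,merge_gap_ms,window,early_cutoff,
#'   presacc_lead,step_window,double_isi_ms Analysis constants (defaults:
#'   50 Hz, 750 deg/s^2, 20 ms, 400 ms, 175 ms, 100 ms, 50 ms, 100 ms).
#' @return One-row data frame of trial metrics.
#' @export
analyze_trial <- function(trace, dt = 0.15, lp_cutoff = 50,
                          acc_threshold = 750, merge_gap_ms = 20,
                          window = 400, early_cutoff = 175,
                          presacc_lead = 100, step_window = 50,
                          double_isi_ms = 100) {
  stopifnot(inherits(trace, "eye_trace"))
  t <- trace$time_ms
  rate <- 1000 / (t[2] - t[1])
  step2 <- trace$events[["step2"]]
  meta <- trace$meta
  gv <- function(x, d = NA) if (is.null(x)) d else x

  eye_f <- lowpass_zero_phase(trace$eye_x_deg, lp_cutoff, rate)
  eye_v <- differentiate_central(eye_f, rate)
  eye_a <- differentiate_central(eye_v, rate)
  # target velocity from the trace, one-sided around the step so the step
  # discontinuity does not leak a spurious velocity spike
  tgt_v <- differentiate_central(trace$target_x_deg, rate)
  i2 <- which.min(abs(t - step2))
  if (i2 > 1) tgt_v[i2 - 1] <- tgt_v[max(1, i2 - 2)]
  tgt_v[i2] <- if (i2 < length(t))
    (trace$target_x_deg[i2 + 1] - trace$target_x_deg[i2]) * rate else
      tgt_v[i2 - 1]

  events <- detect_saccades(eye_f, eye_v, eye_a, t, acc_threshold,
                            merge_gap_ms)
  err <- compute_errors(trace$target_x_deg, eye_f, tgt_v, eye_v)
  ps2 <- gv(meta$ps2); vs2 <- gv(meta$vs2)
  excl <- apply_exclusions(trace$eye_x_deg, t, events, step2, err$pe,
                           target = trace$target_x_deg, ps2 = ps2,
                           vs2 = vs2, window = window,
                           double_isi_ms = double_isi_ms)
  txt <- if (is.na(ps2) || is.na(vs2)) NA_real_ else compute_txt(ps2, vs2)
  pe_pred <- compute_pe_pred(err$pe, err$rs, dt)
  pp_step <- pe_pred_at_step(pe_pred, t, step2, step_window)
  stepw <- t >= step2 & t < step2 + step_window
  pe_step <- mean(err$pe[stepw], na.rm = TRUE)
  rs_step <- mean(err$rs[stepw], na.rm = TRUE)

  post <- events[events$onset_ms > step2, , drop = FALSE]
  first_on <- if (nrow(post) > 0) post$onset_ms[1] else NA_real_
  trig <- if (!is.na(first_on) && first_on - step2 < window)
    first_on - step2 else NA_real_
  klass <- classify_trial(trig, window, early_cutoff)

  pe_s <- rs_s <- pp_s <- txe_s <- pe_pre <- rs_pre <- pp_pre <- txe_pre <-
    NA_real_
  clamped <- NA
  if (!is.na(trig)) {
    smp <- sample_presaccadic(err$pe, err$rs, t, first_on, step2,
                              presacc_lead, dt)
    pe_pre <- smp$pe; rs_pre <- smp$rs
    pp_pre <- smp$pe_pred; txe_pre <- smp$txe
    clamped <- smp$clamped
    pe_s <- pe_pre; rs_s <- rs_pre; pp_s <- pp_pre; txe_s <- txe_pre
  } else {
    win <- t >= step2 & t < step2 + window
    pe_s <- mean(err$pe[win], na.rm = TRUE)
    rs_s <- mean(err$rs[win], na.rm = TRUE)
    pp_s <- compute_pe_pred(pe_s, rs_s, dt)
    txe_s <- compute_txe(pe_s, rs_s)
  }

  data.frame(
    trial_uid = gv(meta$trial_uid, NA_character_),
    participant = gv(meta$participant),
    session = gv(meta$session), block = gv(meta$block),
    trial_id = gv(meta$trial_id),
    condition = trace$condition,
    ps2 = ps2, vs2 = vs2, txt = txt, step2_ms = step2,
    excluded = !excl$keep, reason = excl$reason,
    n_saccades_post = nrow(post),
    trigger_time = trig, klass = klass,
    pe_pred_step = pp_step, pe_step = pe_step, rs_step = rs_step,
    pe_presacc = pe_pre, rs_presacc = rs_pre,
    pe_pred_presacc = pp_pre, txe_presacc = txe_pre,
    presacc_clamped = clamped,
    pe_sample = pe_s, rs_sample = rs_s,
    pe_pred_sample = pp_s, txe_sample = txe_s,
    stringsAsFactors = FALSE)
}

#' Read a single tabular eye trace
#'
#' Adapter for externally recorded trials stored as delimited text with
#' columns `time_ms`, `target_x_deg`, `eye_x_deg` (NaN marking missing
#' samples). Stimulus metadata is not part of the tabular format and must
#' be supplied by the caller; deposited datasets ship it in their own
#' layout, so mapping that layout onto these arguments is left to the
#' user.
#'
#' @param path File path (anything [utils::read.csv()] accepts).
#' @param step2_ms Second-step time, ms.
#' @param condition "clear" or "blur".
#' @param ps2,vs2 Second step parameters, if known.
#' @param meta Additional identifier fields.
#' @return An `eye_trace` ready for [analyze_trial()].
#' @export
read_tabular_trial <- function(path, step2_ms, condition = "clear",
                               ps2 = NA, vs2 = NA, meta = list()) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "target_x_deg", "eye_x_deg") %in% names(d)))
  new_eye_trace(d$time_ms, d$target_x_deg, d$eye_x_deg,
                c(trial_start = d$time_ms[1], step2 = step2_ms),
                condition = condition,
                meta = utils::modifyList(list(ps2 = ps2, vs2 = vs2), meta))
}

# all-NA metrics row with the analyze_trial column layout, for trials
# that could not be processed at all
.empty_metrics_row <- function() {
  data.frame(
    trial_uid = NA_character_, participant = NA_real_, session = NA_real_,
    block = NA_real_, trial_id = NA_real_, condition = NA_character_,
    ps2 = NA_real_, vs2 = NA_real_, txt = NA_real_, step2_ms = NA_real_,
    excluded = TRUE, reason = "unreadable", n_saccades_post = NA_integer_,
    trigger_time = NA_real_, klass = "smooth", pe_pred_step = NA_real_,
    pe_step = NA_real_, rs_step = NA_real_,
    pe_presacc = NA_real_, rs_presacc = NA_real_,
    pe_pred_presacc = NA_real_, txe_presacc = NA_real_,
    presacc_clamped = NA, pe_sample = NA_real_, rs_sample = NA_real_,
    pe_pred_sample = NA_real_, txe_sample = NA_real_,
    stringsAsFactors = FALSE)
}

#' Analyse every trial of a dataset
#'
#' @param ds A `synthetic_dataset` (or any list of `eye_trace` in
#'   `$traces`).
#' @param ... Analysis constants passed to [analyze_trial()].
#' @return Metrics data frame, one row per trial.
#' @export
analyze_dataset <- function(ds, ...) {
  rows <- lapply(ds$traces, analyze_trial, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count exclusions by reason
#'
#' @param metrics Metrics data frame from [analyze_dataset()].
#' @return Data frame with reason, n, fraction of all trials.
#' @export
exclusion_report <- function(metrics) {
  tab <- table(metrics$reason[metrics$excluded])
  data.frame(reason = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(metrics),
             stringsAsFactors = FALSE)
}
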
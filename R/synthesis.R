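# Synthetic eye traces with known ground truth.
#
# Two modes: "model" traces come from the closed-loop trigger model
# (simulate_trial); "scripted" traces place saccades by a deterministic rule
# with optional jitter so the analysis chain can be validated against exact
# ground truth. Blink and dropout faults can be injected to exercise the
# exclusion rules.

#' Construct an eye-trace object
#'
#' @param time_ms,target_x_deg,eye_x_deg Equal-length numeric vectors.
#' @param events Named numeric vector with at least `step2` (ms).
#' @param condition "clear" or "blur".
#' @param meta Named list of identifiers and stimulus parameters
#'   (participant, trial_uid, ps2, vs2, ...).
#' @return Object of class `eye_trace`.
#' @export
new_eye_trace <- function(time_ms, target_x_deg, eye_x_deg, events,
                          condition = "clear", meta = list()) {
  stopifnot(length(time_ms) == length(target_x_deg),
            length(time_ms) == length(eye_x_deg),
            "step2" %in% names(events))
  structure(list(time_ms = time_ms, target_x_deg = target_x_deg,
                 eye_x_deg = eye_x_deg, events = events,
                 condition = condition, meta = meta,
                 truth_saccades = data.frame(onset_ms = numeric(0),
                                             offset_ms = numeric(0),
                                             amplitude = numeric(0))),
            class = "eye_trace")
}

#' Synthesise a smooth-pursuit response to a target trajectory
#'
#' Eye velocity is a first-order low-pass response (time constant `tau`) to
#' the latency-delayed target velocity scaled by `gain`, with the
#' acceleration saturated at `accel_max` (pursuit cannot jump-start after
#' large velocity steps), plus white Gaussian motor noise; eye position is
#' its integral from the fixation point.
#'
#' @param traj A `target_trajectory`.
#' @param latency Pursuit latency, ms.
#' @param gain Steady-state pursuit gain (0-1].
#' @param tau Velocity time constant, ms.
#' @param motor_sd Motor velocity noise SD, deg/s (white, per sample).
#' @param accel_max Pursuit acceleration cap, deg/s^2.
#' @param condition,meta Passed to [new_eye_trace()].
#' @return An `eye_trace`; the pursuit-only eye velocity is attached as
#'   attribute `pursuit_vel`.
#' @export
synthesize_pursuit <- function(traj, latency = 100, gain = 0.9, tau = 40,
                               motor_sd = 0.5, accel_max = 450,
                               condition = "clear", meta = list()) {
  stopifnot(inherits(traj, "target_trajectory"), latency >= 0,
            gain > 0, gain <= 1, tau > 0, accel_max > 0)
  t <- traj$time_ms
  n <- length(t)
  dt_ms <- t[2] - t[1]
  dt_s <- dt_ms / 1000
  tv <- target_velocity(traj)
  lag <- round(latency / dt_ms)
  tv_del <- c(rep(0, lag), tv)[seq_len(n)]
  a <- min(dt_s / (tau / 1000), 1)
  dv_max <- accel_max * dt_s
  v <- numeric(n)
  for (i in seq_len(n - 1)) {
    dv <- a * (gain * tv_del[i] - v[i])
    v[i + 1] <- v[i] + max(-dv_max, min(dv_max, dv))
  }
  if (motor_sd > 0) v <- v + stats::rnorm(n, 0, motor_sd)
  x <- traj$x[1] + cumsum(c(0, v[-n])) * dt_s
  tr <- new_eye_trace(t, traj$x, x, traj$events, condition, meta)
  attr(tr, "pursuit_vel") <- v
  tr
}

#' Inject a minimum-jerk saccade into an eye trace
#'
#' Adds the minimum-jerk displacement profile at `onset_ms`; all later
#' samples are shifted by the full amplitude. Errors if the saccade would
#' overlap a previously injected one or run past the end of the trace.
#'
#' @param trace An `eye_trace`.
#' @param onset_ms Saccade onset, ms.
#' @param amplitude Degrees (0 leaves the trace unchanged).
#' @param duration_ms Optional duration; default from the main sequence.
#' @return The modified `eye_trace` with the event appended to
#'   `truth_saccades`.
#' @export
inject_saccade <- function(trace, onset_ms, amplitude, duration_ms = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  if (amplitude == 0) return(trace)
  if (is.null(duration_ms)) duration_ms <- main_sequence_duration(amplitude)
  t <- trace$time_ms
  dt_ms <- t[2] - t[1]
  i0 <- which.min(abs(t - onset_ms))
  len <- round(duration_ms / dt_ms)
  if (i0 + len > length(t))
    stop("inject_saccade: saccade runs past the end of the trace")
  prev <- trace$truth_saccades
  if (nrow(prev) > 0 &&
      any(onset_ms <= prev$offset_ms & onset_ms + duration_ms >= prev$onset_ms))
    stop("inject_saccade: overlaps an existing injected saccade")
  prof <- min_jerk_profile(amplitude, len * dt_ms, dt_ms)
  idx <- i0:(i0 + len)
  trace$eye_x_deg[idx] <- trace$eye_x_deg[idx] + prof
  if (i0 + len < length(t))
    trace$eye_x_deg[(i0 + len + 1):length(t)] <-
      trace$eye_x_deg[(i0 + len + 1):length(t)] + amplitude
  trace$truth_saccades <- rbind(prev,
    data.frame(onset_ms = t[i0], offset_ms = t[i0 + len],
               amplitude = amplitude))
  trace
}

# Scripted trigger rule. Not a scientific claim: a deterministic rule with
# known output so the analysis chain can be validated round-trip. Trials
# with |PE_pred| below `smooth_below` stay smooth; otherwise the trigger
# time shrinks with |PE_pred|.
.scripted_trigger <- function(pe_pred, base = 180, k = 600,
                              smooth_below = 2.5, jitter_sd = 0) {
  if (abs(pe_pred) < smooth_below) return(NA_real_)
  tt <- base + k / abs(pe_pred)
  if (jitter_sd > 0) tt <- tt + stats::rnorm(1, 0, jitter_sd)
  max(tt, 80)
}

#' Generate a labelled synthetic dataset
#'
#' Builds one trace per schedule row. In `"model"` mode traces come from the
#' closed-loop trigger model; in `"scripted"` mode a pursuit trace is
#' synthesised and saccades are placed by a deterministic rule (trigger time
#' `180 + 600 / |PE_pred|` ms with optional jitter, amplitude from the
#' noiseless pre-saccadic error), giving exact ground truth. Blink faults
#' (100-300 ms NaN gaps overlapping the critical window) and dropout faults
#' (isolated NaN samples) are injected per-trial at the configured rates.
#'
#' @param schedule Data frame from [build_session_schedule()].
#' @param mode `"model"` or `"scripted"`.
#' @param params A [model_params()] (model mode).
#' @param pursuit List of scripted-pursuit settings: latency, gain, tau,
#'   motor_sd.
#' @param trigger_rule List overriding the scripted rule constants: base, k,
#'   smooth_below, jitter_sd.
#' @param blink_rate,dropout_rate Per-trial fault probabilities.
#' @param analysis_dt Extrapolation horizon used by the scripted rule, s.
#' @param fix_dur,post_dur,task Trial-construction settings; `task` is a
#'   list passed to [draw_trial_spec()] (e.g. `ps2_mode`, `max_ttf`).
#' @param seed Optional integer; when given, regeneration is bit-identical.
#' @return Object of class `synthetic_dataset`: list with `schedule`,
#'   `traces` (list of `eye_trace`), `truth` (one row per trial), `mode`,
#'   `seed`.
#' @export
generate_dataset <- function(schedule, mode = c("model", "scripted"),
                             params = model_params(),
                             pursuit = list(), trigger_rule = list(),
                             blink_rate = 0, dropout_rate = 0,
                             analysis_dt = 0.15,
                             fix_dur = 200, post_dur = 1200,
                             task = list(), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pu <- utils::modifyList(list(latency = 100, gain = 0.9, tau = 40,
                               motor_sd = 0.5, accel_max = 450), pursuit)
  tg <- utils::modifyList(list(base = 180, k = 600, smooth_below = 2.5,
                               jitter_sd = 0), trigger_rule)
  n <- nrow(schedule)
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    row <- schedule[i, ]
    spec <- do.call(draw_trial_spec,
                    c(list(blur = row$condition == "blur",
                           trial_id = row$trial_id, block = row$block,
                           session = row$session,
                           participant = row$participant), task))
    traj <- build_trial(spec, fix_dur = fix_dur, post_dur = post_dur)
    uid <- sprintf("p%02d_t%04d", row$participant, row$trial_id)
    meta <- list(participant = row$participant, session = row$session,
                 block = row$block, trial_id = row$trial_id,
                 trial_uid = uid, ps2 = spec$ps2, vs2 = spec$vs2)
    if (mode == "model") {
      sim <- simulate_trial(traj, params)
      tr <- new_eye_trace(sim$trace$time_ms, sim$trace$target_x_deg,
                          sim$trace$eye_x_deg, traj$events,
                          sim$condition, meta)
      tr$truth_saccades <- sim$events[c("onset_ms", "offset_ms", "amplitude")]
      first <- sim$events$onset_ms[sim$events$onset_ms >
                                     traj$events[["step2"]]][1]
      tt <- if (is.na(first)) NA_real_ else first - traj$events[["step2"]]
    } else {
      tr <- synthesize_pursuit(traj, pu$latency, pu$gain, pu$tau,
                               pu$motor_sd, pu$accel_max,
                               condition = row$condition, meta = meta)
      pv <- attr(tr, "pursuit_vel")
      s2 <- traj$events[["step2"]]
      i2 <- which.min(abs(tr$time_ms - s2))
      win <- i2:min(length(tr$time_ms), i2 + 50)
      tv <- target_velocity(traj)
      pe_pred <- mean((tr$target_x_deg[win] - tr$eye_x_deg[win]) +
                        analysis_dt * (tv[win] - pv[win]))
      tt <- .scripted_trigger(pe_pred, tg$base, tg$k, tg$smooth_below,
                              tg$jitter_sd)
      if (!is.na(tt)) {
        io <- which.min(abs(tr$time_ms - (s2 + tt)))
        amp <- (tr$target_x_deg[io] - tr$eye_x_deg[io]) +
          0.1 * (tv[io] - pv[io])
        tr <- inject_saccade(tr, tr$time_ms[io], amp)
        tt <- tr$time_ms[io] - s2
      }
    }
    fault <- "none"
    if (blink_rate > 0 && stats::runif(1) < blink_rate) {
      fault <- "blink"
      s2 <- tr$events[["step2"]]
      dur <- stats::runif(1, 100, 300)
      start <- stats::runif(1, s2 - 50, s2 + 300)
      gap <- tr$time_ms >= start & tr$time_ms <= start + dur
      tr$eye_x_deg[gap] <- NA_real_
    } else if (dropout_rate > 0 && stats::runif(1) < dropout_rate) {
      fault <- "dropout"
      s2 <- tr$events[["step2"]]
      cand <- which(tr$time_ms >= s2 & tr$time_ms <= s2 + 400)
      tr$eye_x_deg[sample(cand, 3)] <- NA_real_
    }
    traces[[i]] <- tr
    truth[[i]] <- data.frame(
      trial_uid = uid, participant = row$participant,
      session = row$session, block = row$block, trial_id = row$trial_id,
      condition = row$condition, ps2 = spec$ps2, vs2 = spec$vs2,
      step2_ms = traj$events[["step2"]],
      trigger_ms = tt, n_saccades = nrow(tr$truth_saccades),
      fault = fault, stringsAsFactors = FALSE)
  }
  structure(list(schedule = schedule, traces = traces,
                 truth = do.call(rbind, truth), mode = mode, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' One CSV per trial (columns time_ms, target_x_deg, eye_x_deg; NaN marks
#' missing samples), a `truth.csv` ground-truth log, and a `manifest.json`
#' listing trials, conditions, events and the generating seed.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tdir <- file.path(dir, "traces")
  if (!dir.exists(tdir)) dir.create(tdir)
  files <- character(length(ds$traces))
  for (i in seq_along(ds$traces)) {
    tr <- ds$traces[[i]]
    files[i] <- paste0(tr$meta$trial_uid, ".csv")
    utils::write.csv(data.frame(time_ms = tr$time_ms,
                                target_x_deg = tr$target_x_deg,
                                eye_x_deg = tr$eye_x_deg),
                     file.path(tdir, files[i]), row.names = FALSE)
  }
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  man <- list(mode = ds$mode, seed = ds$seed, n_trials = length(ds$traces),
              trials = data.frame(
                file = file.path("traces", files),
                trial_uid = ds$truth$trial_uid,
                participant = ds$truth$participant,
                session = ds$truth$session,
                condition = ds$truth$condition,
                ps2 = ds$truth$ps2, vs2 = ds$truth$vs2,
                step2_ms = ds$truth$step2_ms))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `synthetic_dataset` (schedule reduced to the manifest fields).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  traces <- lapply(seq_len(nrow(man$trials)), function(i) {
    m <- man$trials[i, ]
    d <- utils::read.csv(file.path(dir, m$file))
    new_eye_trace(d$time_ms, d$target_x_deg, d$eye_x_deg,
                  c(trial_start = 0, step2 = m$step2_ms),
                  condition = m$condition,
                  meta = list(participant = m$participant,
                              session = m$session,
                              trial_uid = m$trial_uid,
                              ps2 = m$ps2, vs2 = m$vs2))
  })
  structure(list(schedule = man$trials, traces = traces, truth = truth,
                 mode = man$mode, seed = man$seed),
            class = "synthetic_dataset")
}
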
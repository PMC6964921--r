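# Stochastic trigger model: noisy observation of position error (PE) and
# retinal slip (RS), Kalman estimation, linear extrapolation to a predicted
# position error (PE_pred = PE + dt * RS), confidence that the target lies
# outside the fovea, accumulation of that confidence to a decision
# threshold, and closed-loop pursuit + saccade simulation.

#' Sensory and process noise model
#'
#' Position observations carry Gaussian noise whose SD depends on the target
#' condition (clear vs blurred). Velocity observations carry
#' signal-dependent noise (SDN): SD = `vel_sd_base + sdn_coef * |RS|`.
#' Process noise is a per-state diffusion (deg or deg/s per sqrt(s)) that
#' keeps the filter adaptive.
#'
#' @param pos_sd_clear,pos_sd_blur Position observation SD, degrees
#'   (per-sample noise, averaged away by the filter).
#' @param pos_amb_clear,pos_amb_blur Sustained localization ambiguity,
#'   degrees: the correlated part of position uncertainty (where inside a
#'   blurred blob the target "is") that repeated samples cannot average
#'   out; enters the predicted-error variance directly.
#' @param vel_sd_base Velocity observation SD at zero slip, deg/s.
#' @param sdn_coef Dimensionless SDN slope on |RS|.
#' @param process_pos_sd,process_vel_sd Process diffusion scales.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(pos_sd_clear = 0.5, pos_sd_blur = 2.5,
                        pos_amb_clear = 0, pos_amb_blur = 0.8,
                        vel_sd_base = 1, sdn_coef = 0.2,
                        process_pos_sd = 0.1, process_vel_sd = 3) {
  vals <- c(pos_sd_clear, pos_sd_blur, pos_amb_clear, pos_amb_blur,
            vel_sd_base, sdn_coef, process_pos_sd, process_vel_sd)
  stopifnot(all(vals >= 0), pos_sd_blur >= pos_sd_clear,
            pos_amb_blur >= pos_amb_clear)
  structure(list(pos_sd_clear = pos_sd_clear, pos_sd_blur = pos_sd_blur,
                 pos_amb_clear = pos_amb_clear,
                 pos_amb_blur = pos_amb_blur,
                 vel_sd_base = vel_sd_base, sdn_coef = sdn_coef,
                 process_pos_sd = process_pos_sd,
                 process_vel_sd = process_vel_sd),
            class = "noise_model")
}

#' Trigger-model parameters
#'
#' @param dt Extrapolation horizon for the predicted position error,
#'   seconds (0.09-0.29 plausible; default 0.15).
#' @param foveal_radius Radius of the foveal zone, degrees.
#' @param threshold Accumulated-confidence threshold for saccade triggering,
#'   log-probability-ratio units; calibrated so clear-condition median
#'   trigger times at large |PE_pred| fall around 150-200 ms.
#' @param sensory_delay,motor_delay Afferent and efferent delays, ms.
#' @param pursuit_gain Steady-state pursuit gain (0-1].
#' @param pursuit_accel_gain Rate constant (1/s) of the pursuit velocity
#'   drive on estimated retinal slip.
#' @param pursuit_pos_gain Weight (1/s) of estimated position error in the
#'   pursuit drive; keeps steady-state position error bounded during
#'   sustained pursuit.
#' @param conf_form Accumulated confidence signal: `"direction"` (default)
#'   accumulates |log(p_right / p_left)|, the log probability ratio that
#'   the predicted error lies right versus left of the fovea;
#'   `"foveal"` accumulates log(max(p_right, p_left) / p_foveal), the
#'   extrafoveal-to-foveal mass ratio.
#' @param noise A [noise_model()].
#' @return Object of class `model_params`.
#' @export
model_params <- function(dt = 0.15, foveal_radius = 2, threshold = 8,
                         sensory_delay = 60, motor_delay = 100,
                         pursuit_gain = 0.9, pursuit_accel_gain = 9,
                         pursuit_pos_gain = 0.3,
                         conf_form = c("direction", "foveal"),
                         noise = noise_model()) {
  conf_form <- match.arg(conf_form)
  stopifnot(dt >= 0, sensory_delay >= 0, motor_delay >= 0,
            pursuit_gain > 0, pursuit_gain <= 1, foveal_radius > 0,
            threshold > 0, pursuit_pos_gain >= 0,
            inherits(noise, "noise_model"))
  structure(list(dt = dt, foveal_radius = foveal_radius,
                 threshold = threshold, sensory_delay = sensory_delay,
                 motor_delay = motor_delay, pursuit_gain = pursuit_gain,
                 pursuit_accel_gain = pursuit_accel_gain,
                 pursuit_pos_gain = pursuit_pos_gain,
                 conf_form = conf_form, noise = noise),
            class = "model_params")
}

#' Sensory estimate of (PE, RS)
#'
#' @param pe,rs Mean position error (deg) and retinal slip (deg/s).
#' @param cov 2x2 symmetric positive semidefinite covariance of (PE, RS).
#' @return Object of class `sensory_estimate`.
#' @export
new_sensory_estimate <- function(pe = 0, rs = 0,
                                 cov = diag(c(25, 100))) {
  cov <- (cov + t(cov)) / 2
  if (any(diag(cov) < 0) || det(cov) < -1e-9)
    stop("new_sensory_estimate: covariance is not positive semidefinite")
  structure(list(pe = pe, rs = rs, cov = cov), class = "sensory_estimate")
}

#' Draw a noisy observation of the true retinal error state
#'
#' @param pe_true,rs_true True position error (deg) and retinal slip
#'   (deg/s); vectorised.
#' @param noise A [noise_model()].
#' @param blur Logical; use the blurred-condition position SD.
#' @return List with `pe_obs`, `rs_obs`.
#' @export
observe <- function(pe_true, rs_true, noise, blur = FALSE) {
  pos_sd <- if (isTRUE(blur)) noise$pos_sd_blur else noise$pos_sd_clear
  vel_sd <- noise$vel_sd_base + noise$sdn_coef * abs(rs_true)
  list(pe_obs = pe_true + stats::rnorm(length(pe_true), 0, pos_sd),
       rs_obs = rs_true + stats::rnorm(length(rs_true), 0, vel_sd))
}

# Scalar-unrolled Kalman predict + update for the 2-state (PE, RS) filter
# with constant-velocity dynamics (PE integrates RS, RS a random walk),
# known control inputs u_p, u_v (efference copy of the observer's own eye
# movement), identity observation and diagonal observation noise. Returns
# the updated state, covariance entries, raw innovations and innovation
# covariance.
.kf_step <- function(p, v, s11, s12, s22, zp, zv, rp, rv, q11, q22, dt,
                     u_p = 0, u_v = 0) {
  # predict
  p <- p + dt * v + u_p
  v <- v + u_v
  s11 <- s11 + dt * (2 * s12 + dt * s22) + q11
  s12 <- s12 + dt * s22
  s22 <- s22 + q22
  # update (H = I)
  ip <- zp - p
  iv <- zv - v
  a <- s11 + rp
  b <- s12
  cc <- s22 + rv
  det <- a * cc - b * b
  k11 <- (s11 * cc - s12 * b) / det
  k12 <- (-s11 * b + s12 * a) / det
  k21 <- (s12 * cc - s22 * b) / det
  k22 <- (-s12 * b + s22 * a) / det
  pn <- p + k11 * ip + k12 * iv
  vn <- v + k21 * ip + k22 * iv
  n11 <- (1 - k11) * s11 - k12 * s12
  n12 <- (1 - k11) * s12 - k12 * s22
  n21 <- -k21 * s11 + (1 - k22) * s12
  n22 <- -k21 * s12 + (1 - k22) * s22
  # order: p, v, s11, s12, s22, innov_p, innov_v, S11, S12, S22
  c(pn, vn, n11, (n12 + n21) / 2, n22, ip, iv, a, b, cc)
}

#' One Kalman predict/update step on a sensory estimate
#'
#' State (PE, RS) with constant-velocity dynamics: PE evolves by RS, RS is a
#' random walk. Observations are direct noisy readings of both states.
#'
#' @param est A `sensory_estimate`.
#' @param obs List with `pe_obs`, `rs_obs` (scalar observation).
#' @param obs_sd Length-2 observation SDs `c(pos, vel)`.
#' @param dt_step Time step, seconds.
#' @param process_sd Length-2 process diffusion scales (per sqrt(s)).
#' @return Updated `sensory_estimate`; innovation and its covariance are
#'   attached as attributes `innovation` and `innovation_cov`.
#' @export
kalman_update <- function(est, obs, obs_sd, dt_step,
                          process_sd = c(0.1, 3)) {
  stopifnot(inherits(est, "sensory_estimate"), dt_step > 0,
            length(obs_sd) == 2, all(obs_sd > 0))
  r <- .kf_step(est$pe, est$rs,
                est$cov[1, 1], est$cov[1, 2], est$cov[2, 2],
                obs$pe_obs, obs$rs_obs, obs_sd[1]^2, obs_sd[2]^2,
                process_sd[1]^2 * dt_step, process_sd[2]^2 * dt_step,
                dt_step)
  cov <- matrix(c(r[3], r[4], r[4], r[5]), 2, 2)
  out <- new_sensory_estimate(r[1], r[2], cov)
  attr(out, "innovation") <- c(r[6], r[7])
  attr(out, "innovation_cov") <- matrix(c(r[8], r[9], r[9], r[10]), 2, 2)
  out
}

#' Extrapolate a sensory estimate to a predicted position error
#'
#' PE_pred = PE + dt * RS, with variance propagated through the linear map:
#' var = cov_pp + 2 dt cov_pr + dt^2 cov_rr.
#'
#' @param est A `sensory_estimate`.
#' @param dt Extrapolation horizon, seconds (>= 0).
#' @return List with `mean` (deg), `var` (deg^2) and `dt`.
#' @export
predict_error <- function(est, dt) {
  stopifnot(inherits(est, "sensory_estimate"), dt >= 0)
  list(mean = est$pe + dt * est$rs,
       var = est$cov[1, 1] + 2 * dt * est$cov[1, 2] + dt^2 * est$cov[2, 2],
       dt = dt)
}

#' Confidence that the predicted target position lies outside the fovea
#'
#' For PE_pred ~ N(mean, var), returns the tail masses beyond the foveal
#' radius on either side and the log ratio of the larger extrafoveal mass to
#' the foveal mass -- the instantaneous decision signal.
#'
#' @param pred List with `mean` and `var` (as from [predict_error()]).
#' @param foveal_radius Foveal radius, degrees.
#' @return List with `p_right`, `p_left`, `log_ratio` (extrafoveal over
#'   foveal mass) and `log_dir_ratio` (right over left of the fovea,
#'   signed; its magnitude is the directional decision signal).
#' @export
confidence_outside_fovea <- function(pred, foveal_radius) {
  m <- pred$mean
  r <- foveal_radius
  stopifnot(r > 0, pred$var >= 0)
  if (pred$var == 0) {            # point mass
    out <- abs(m) > r
    return(list(p_right = as.numeric(m > r), p_left = as.numeric(m < -r),
                log_ratio = if (out) Inf else -Inf,
                log_dir_ratio = if (!out) 0 else if (m > r) Inf else -Inf))
  }
  s <- sqrt(pred$var)
  lpr <- stats::pnorm(r, m, s, lower.tail = FALSE, log.p = TRUE)
  lpl <- stats::pnorm(-r, m, s, log.p = TRUE)
  p_fov <- stats::pnorm(r, m, s) - stats::pnorm(-r, m, s)
  lfov <- if (p_fov > 0) {
    log(p_fov)
  } else if (m > 0) {   # foveal mass underflow: nearer-edge tail dominates
    stats::pnorm(r, m, s, log.p = TRUE)
  } else {
    stats::pnorm(-r, m, s, lower.tail = FALSE, log.p = TRUE)
  }
  list(p_right = exp(lpr), p_left = exp(lpl),
       log_ratio = max(lpr, lpl) - lfov,
       log_dir_ratio = lpr - lpl)
}

#' Initialise a decision state
#'
#' @param threshold Accumulated-evidence threshold, log-probability-ratio
#'   units.
#' @return Object of class `decision_state`.
#' @export
new_decision_state <- function(threshold) {
  stopifnot(threshold > 0)
  structure(list(evidence = 0, threshold = threshold,
                 triggered_at = NA_real_),
            class = "decision_state")
}

#' Accumulate decision evidence toward threshold
#'
#' Evidence rises at a rate proportional to the instantaneous log confidence
#' ratio; negative increments are floored at zero (rise-to-threshold, no
#' decay). The first threshold crossing sets `triggered_at`.
#'
#' @param state A `decision_state`.
#' @param log_ratio Instantaneous log confidence ratio.
#' @param dt_step Time step, seconds.
#' @param now Current time, ms (recorded at the crossing).
#' @return Updated `decision_state`.
#' @export
accumulate_decision <- function(state, log_ratio, dt_step, now = NA_real_) {
  state$evidence <- state$evidence + max(log_ratio, 0) * dt_step
  if (is.na(state$triggered_at) && state$evidence >= state$threshold)
    state$triggered_at <- now
  state
}

#' Main-sequence saccade duration
#'
#' Linear main-sequence rule: duration = 2.2 ms/deg * |amplitude| + 21 ms.
#'
#' @param amplitude Saccade amplitude, degrees.
#' @return Duration in ms.
#' @export
main_sequence_duration <- function(amplitude) {
  2.2 * abs(amplitude) + 21
}

#' Minimum-jerk saccade displacement profile
#'
#' Symmetric minimum-jerk displacement from 0 to `amplitude` over
#' `duration_ms`, sampled every `dt` ms (first sample at onset, displacement
#' 0; last at offset, displacement = amplitude).
#'
#' @param amplitude Degrees.
#' @param duration_ms Saccade duration, ms.
#' @param dt Sample period, ms.
#' @return Numeric displacement vector.
#' @export
min_jerk_profile <- function(amplitude, duration_ms, dt = 1) {
  tau <- seq(0, duration_ms, by = dt) / duration_ms
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Plan a catch-up saccade from the current sensory estimate
#'
#' The saccade lands on the position the target is expected to occupy at
#' landing: amplitude = PE + horizon * RS. The sensory estimate describes
#' the world one sensory delay ago, so the default horizon spans the
#' sensory delay, the motor delay and half the saccade duration (itself
#' set by the main sequence).
#'
#' @param est A `sensory_estimate` (or any list with `pe`, `rs`).
#' @param params A [model_params()].
#' @param now Decision time, ms.
#' @param horizon Optional explicit landing horizon in seconds, overriding
#'   the delay + half-duration rule.
#' @return List with `onset`, `offset` (ms), `duration` (ms), `amplitude`
#'   (deg).
#' @export
plan_saccade <- function(est, params, now, horizon = NULL) {
  md_s <- params$motor_delay / 1000
  if (is.null(horizon)) {
    lag_s <- (params$sensory_delay + params$motor_delay) / 1000
    amp0 <- est$pe + lag_s * est$rs
    horizon <- lag_s + main_sequence_duration(amp0) / 2000
  }
  amplitude <- est$pe + horizon * est$rs
  duration <- main_sequence_duration(amplitude)
  list(onset = now + params$motor_delay, duration = duration,
       amplitude = amplitude,
       offset = now + params$motor_delay + duration)
}

#' Closed-loop simulation of one tracking trial
#'
#' At every sample: the delayed true retinal error is observed with noise,
#' the Kalman estimate updated, the predicted position error extrapolated,
#' its extrafoveal confidence accumulated, and a saccade planned and
#' executed when the accumulated confidence crosses threshold. The pursuit
#' command accelerates the eye in proportion to estimated retinal slip with
#' a leak that sets the steady-state gain. Observations are suppressed in
#' flight (saccadic suppression); the accumulator resets at each perceived
#' target step and after each executed saccade, and the filter covariance is
#' inflated at perceived steps.
#'
#' @param traj A `target_trajectory`.
#' @param params A [model_params()].
#' @param keep_decision Keep the per-sample decision trace (estimates,
#'   prediction mean/variance, evidence, innovations)?
#' @return List with `trace` (data frame time_ms / target_x_deg /
#'   eye_x_deg), `events` (data frame of executed saccades: trigger_ms,
#'   onset_ms, offset_ms, amplitude), `decision` (data frame or NULL),
#'   `spec`, `condition`.
#' @export
simulate_trial <- function(traj, params, keep_decision = FALSE) {
  stopifnot(inherits(traj, "target_trajectory"),
            inherits(params, "model_params"))
  t <- traj$time_ms
  n <- length(t)
  dt_ms <- t[2] - t[1]
  dt_s <- dt_ms / 1000
  tx <- traj$x
  tv <- target_velocity(traj)
  nm <- params$noise
  blur <- isTRUE(traj$spec$blur)
  pos_sd <- if (blur) nm$pos_sd_blur else nm$pos_sd_clear
  amb2 <- (if (blur) nm$pos_amb_blur else nm$pos_amb_clear)^2
  rp <- pos_sd^2
  q11 <- nm$process_pos_sd^2 * dt_s
  q22 <- nm$process_vel_sd^2 * dt_s
  d_samp <- round(params$sensory_delay / dt_ms)
  md_samp <- round(params$motor_delay / dt_ms)
  dtp <- params$dt
  fov <- params$foveal_radius
  thr <- params$threshold

  # perceived step times (sample indices)
  step_flag <- logical(n)
  step_flag[pmin(n, round((traj$events[c("step1", "step2")] +
                             params$sensory_delay) / dt_ms) + 1)] <- TRUE

  ex <- numeric(n); ex[1] <- tx[1]
  ev <- numeric(n)
  kp <- params$pursuit_accel_gain
  kl <- kp * (1 - params$pursuit_gain) / params$pursuit_gain
  kq <- params$pursuit_pos_gain
  del_s <- params$sensory_delay / 1000
  zpn <- stats::rnorm(n)        # pre-drawn standard normals
  zvn <- stats::rnorm(n)
  vb <- nm$vel_sd_base
  sc <- nm$sdn_coef
  dir_conf <- identical(params$conf_form, "direction")

  # filter state: broad prior centred on zero error
  p <- 0; v <- 0; s11 <- 25; s12 <- 0; s22 <- 100
  evid <- 0
  pending_i <- NA_integer_     # saccade onset sample, once triggered
  sac_end <- 0L                # last flight sample of the current saccade
  supp_from <- 0L              # retinal suppression: observations taken
  supp_until <- -1L            # mid-flight arrive d_samp later
  sac_prof <- NULL
  sac_k <- 0L
  trigger_t <- NA_real_
  events <- list()

  if (keep_decision) {
    pe_est <- rs_est <- pm_tr <- pv_tr <- ev_tr <- rep(NA_real_, n)
    inn_p <- inn_v <- ia <- ib <- ic <- rep(NA_real_, n)
  }

  for (i in seq_len(n - 1)) {
    in_flight <- sac_k > 0L && i <= sac_end
    j <- i - d_samp
    if (j >= 2) {
      # efference copy: the observer knows its own (delayed) eye movement
      # exactly, so self-generated changes in PE and RS enter the filter
      # as control inputs rather than surprises
      u_p <- ev[j - 1] * dt_s - (ex[j] - ex[j - 1])
      u_v <- -(ev[j] - ev[j - 1])
      if (i < supp_from || i > supp_until) {
        pe_t <- tx[j] - ex[j]
        rs_t <- tv[j] - ev[j]
        zp <- pe_t + pos_sd * zpn[i]
        zv <- rs_t + (vb + sc * abs(rs_t)) * zvn[i]
        rv <- (vb + sc * abs(zv))^2
        r <- .kf_step(p, v, s11, s12, s22, zp, zv, rp, rv, q11, q22, dt_s,
                      u_p, u_v)
        p <- r[1]; v <- r[2]
        s11 <- r[3]; s12 <- r[4]; s22 <- r[5]
        if (keep_decision) {
          inn_p[i] <- r[6]; inn_v[i] <- r[7]
          ia[i] <- r[8]; ib[i] <- r[9]; ic[i] <- r[10]
        }
      } else {
        # saccadic suppression: predict with efference only
        p <- p + dt_s * v + u_p
        v <- v + u_v
        s11 <- s11 + dt_s * (2 * s12 + dt_s * s22) + q11
        s12 <- s12 + dt_s * s22
        s22 <- s22 + q22
      }
    }
    if (step_flag[i]) {           # perceived perturbation: new evidence
      s11 <- s11 + 25
      s22 <- s22 + 400
      evid <- 0
    }

    # forward model: the filter estimates the retinal state one sensory
    # delay ago; extrapolate to now with the known motor history (which
    # includes any saccade just executed)
    if (j >= 1) {
      pe_now <- p + (v + ev[j]) * del_s - (ex[i] - ex[j])
      rs_now <- v - (ev[i] - ev[j])
    } else {
      pe_now <- p
      rs_now <- v
    }

    pm <- pe_now + dtp * rs_now
    # predicted-error variance: filter covariance propagated through the
    # extrapolation, plus signal-dependent uncertainty about the slip
    # carrying the extrapolation (SDN does not average away into the
    # future)
    pv <- s11 + 2 * dtp * s12 + dtp^2 * s22 + (dtp * sc * rs_now)^2 +
      amb2
    if (is.na(pending_i) && !in_flight) {
      ssd <- sqrt(pv)
      zr <- (fov - pm) / ssd
      zl <- (-fov - pm) / ssd
      lpr <- stats::pnorm(zr, lower.tail = FALSE, log.p = TRUE)
      lpl <- stats::pnorm(zl, log.p = TRUE)
      pf <- stats::pnorm(zr) - stats::pnorm(zl)
      lr <- if (dir_conf) {
        # directional confidence |log p_right / p_left|, gated on the
        # target being more likely outside the fovea than inside;
        # capped so degenerate zero-variance estimates stay finite
        if (exp(lpr) + exp(lpl) > pf) min(abs(lpr - lpl), 1e5) else 0
      } else {
        # log extrafoveal / foveal mass
        lf <- if (pf > 0) log(pf)
          else if (pm > 0) stats::pnorm(zr, log.p = TRUE)
          else stats::pnorm(zl, lower.tail = FALSE, log.p = TRUE)
        max(lpr, lpl) - lf
      }
      if (lr > 0) evid <- evid + lr * dt_s
      if (evid >= thr) {
        # estimates are already delay-compensated: extrapolate over the
        # motor delay plus half the saccade duration only
        amp0 <- pe_now + (params$motor_delay / 1000) * rs_now
        plan <- plan_saccade(list(pe = pe_now, rs = rs_now), params, t[i],
                             horizon = params$motor_delay / 1000 +
                               main_sequence_duration(amp0) / 2000)
        pending_i <- i + md_samp
        trigger_t <- t[i]
        sac_prof <- diff(min_jerk_profile(plan$amplitude, plan$duration,
                                          dt_ms))
        attr(sac_prof, "plan") <- plan
      }
    }

    if (keep_decision) {
      pe_est[i] <- pe_now; rs_est[i] <- rs_now
      pm_tr[i] <- pm; pv_tr[i] <- pv; ev_tr[i] <- evid
    }

    # motor update: pursuit drive on the delay-compensated slip estimate
    # plus an optional weak position channel, leaky toward gain < 1
    ev[i + 1] <- ev[i] + (kp * (rs_now + kq * pe_now) -
                            kl * ev[i]) * dt_s
    ex[i + 1] <- ex[i] + ev[i] * dt_s

    if (!is.na(pending_i) && i + 1 == pending_i) {
      plan <- attr(sac_prof, "plan")
      sac_end <- min(n, i + length(sac_prof))
      supp_from <- i + 1 + d_samp
      supp_until <- sac_end + d_samp
      sac_k <- 0L
      events[[length(events) + 1]] <-
        list(trigger_ms = trigger_t, onset_ms = t[i + 1],
             offset_ms = t[i + 1] + plan$duration,
             amplitude = plan$amplitude)
      pending_i <- NA_integer_
      evid <- 0
    }
    if (!is.null(sac_prof) && sac_end > 0L && i + 1 <= sac_end) {
      sac_k <- sac_k + 1L
      ex[i + 1] <- ex[i + 1] + sac_prof[sac_k]
    }
    if (i + 1 > sac_end && sac_k > 0L) {
      sac_prof <- NULL
      sac_k <- 0L
      evid <- 0
    }
  }
  if (any(!is.finite(ex)))
    stop("simulate_trial: eye trace became non-finite")

  ev_df <- if (length(events)) {
    do.call(rbind, lapply(events, as.data.frame))
  } else {
    data.frame(trigger_ms = numeric(0), onset_ms = numeric(0),
               offset_ms = numeric(0), amplitude = numeric(0))
  }
  dec <- NULL
  if (keep_decision) {
    dec <- data.frame(time_ms = t, pe_est = pe_est, rs_est = rs_est,
                      pe_pred_mean = pm_tr, pe_pred_var = pv_tr,
                      evidence = ev_tr, innov_pe = inn_p, innov_rs = inn_v,
                      innov_var_pe = ia, innov_cov = ib, innov_var_rs = ic)
  }
  list(trace = data.frame(time_ms = t, target_x_deg = tx, eye_x_deg = ex),
       events = ev_df, decision = dec, spec = traj$spec,
       events_ms = traj$events,
       condition = if (blur) "blur" else "clear")
}
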
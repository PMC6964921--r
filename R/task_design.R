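# Double step-ramp stimulus design.
#
# A trial starts with fixation 20 deg left or right of screen center. The
# first step-ramp displaces the target further from center (2/4/6 deg) and
# ramps it back toward center (10/20/30 deg/s), inducing steady-state
# pursuit. After a variable steady period (500-700 ms) a second step-ramp
# perturbs position (within +/-20 deg) and velocity (uniform on
# [-50, 50] deg/s); this second perturbation is the event under study.

PS1_MAGNITUDES <- c(2, 4, 6)
VS1_MAGNITUDES <- c(10, 20, 30)

#' Create a double step-ramp trial specification
#'
#' @param fixation_x Fixation position, degrees (the task uses +/-20).
#' @param ps1 Signed first position step, degrees; magnitude must be 2, 4 or
#'   6 and the sign points away from screen center.
#' @param vs1 Signed first ramp velocity, deg/s; magnitude 10, 20 or 30,
#'   directed toward screen center.
#' @param steady_dur Steady pursuit duration before the second step, ms
#'   (500-700).
#' @param ps2,vs2 Signed second position step (deg, within +/-20) and
#'   velocity step (deg/s, within +/-50). The velocity step is relative to
#'   the ongoing first ramp -- it is the change that creates retinal slip
#'   in a tracking eye -- so the post-step ramp velocity is `vs1 + vs2`.
#'   `vs2 = 0` is admitted here (the ramp simply continues) although the
#'   sampler never draws it.
#' @param blur Logical; blurred-target (high position uncertainty) condition.
#' @param trial_id,block,session,participant Identifiers.
#' @return An object of class `step_ramp_spec`.
#' @export
new_step_ramp_spec <- function(fixation_x, ps1, vs1, steady_dur, ps2, vs2,
                               blur = FALSE, trial_id = 1L, block = 1L,
                               session = 1L, participant = 1L) {
  stopifnot(
    abs(ps1) %in% PS1_MAGNITUDES,
    abs(vs1) %in% VS1_MAGNITUDES,
    steady_dur >= 500, steady_dur <= 700,
    abs(ps2) <= 20, abs(vs2) <= 50
  )
  structure(
    list(fixation_x = fixation_x, ps1 = ps1, vs1 = vs1,
         steady_dur = steady_dur, ps2 = ps2, vs2 = vs2, blur = isTRUE(blur),
         trial_id = as.integer(trial_id), block = as.integer(block),
         session = as.integer(session), participant = as.integer(participant)),
    class = "step_ramp_spec"
  )
}

#' Admissible second-step position range for a given ramp velocity
#'
#' The second position step is constrained so the target would re-cross its
#' pre-step trajectory within `max_ttf` seconds (|ps2 / vs2| <= max_ttf) and
#' never exceeds +/-20 deg.
#'
#' @param vs2 Second ramp velocity, deg/s.
#' @param max_ttf Maximum absolute time-to-foveate, seconds.
#' @return `c(lo, hi)` bounds for ps2 in degrees.
#' @export
admissible_ps2 <- function(vs2, max_ttf = 1.0) {
  stopifnot(max_ttf > 0)
  lim <- min(20, max_ttf * abs(vs2))
  c(-lim, lim)
}

#' Draw a second step-ramp (position and velocity step)
#'
#' Velocity steps are uniform on [-50, 50] deg/s; position steps are then
#' drawn over the admissible interval (see [admissible_ps2()]), either
#' continuously (default) or from a 1-degree discrete grid.
#'
#' @param max_ttf Maximum absolute time-to-foveate |ps2/vs2|, seconds.
#' @param mode `"continuous"` (uniform over the admissible interval) or
#'   `"discrete"` (uniform over the whole-degree grid within it).
#' @param max_tries Rejection-sampling guard; exceeded only under
#'   misconfiguration.
#' @return Named numeric vector `c(ps2, vs2)`.
#' @export
draw_second_step <- function(max_ttf = 1.0, mode = c("continuous", "discrete"),
                             max_tries = 1e4) {
  mode <- match.arg(mode)
  stopifnot(max_ttf > 0)
  for (i in seq_len(max_tries)) {
    vs2 <- stats::runif(1, -50, 50)
    rng <- admissible_ps2(vs2, max_ttf)
    if (mode == "continuous") {
      return(c(ps2 = stats::runif(1, rng[1], rng[2]), vs2 = vs2))
    }
    grid <- seq(-20L, 20L, by = 1L)
    grid <- grid[grid >= rng[1] & grid <= rng[2]]
    if (length(grid) > 0)
      return(c(ps2 = grid[sample.int(length(grid), 1)], vs2 = vs2))
  }
  stop("draw_second_step: rejection sampling failed; check max_ttf")
}

#' Draw a complete random trial specification
#'
#' Applies the task's direction conventions (first step away from center,
#' first ramp toward center) and resamples the second step-ramp until the
#' target stays within the screen bound through the end of the
#' classification window after the second step.
#'
#' @param blur Logical condition flag.
#' @param fixation_x Fixation position (defaults to a random side at 20 deg).
#' @param max_ttf,ps2_mode Passed to [draw_second_step()].
#' @param screen_bound Half-width of the usable screen, degrees.
#' @param bound_window Window after the second step over which the on-screen
#'   bound is enforced, ms.
#' @param trial_id,block,session,participant Identifiers.
#' @param max_tries Resampling guard.
#' @return A `step_ramp_spec`.
#' @export
draw_trial_spec <- function(blur = FALSE,
                            fixation_x = sample(c(-20, 20), 1),
                            max_ttf = 1.0, ps2_mode = "continuous",
                            screen_bound = 30, bound_window = 400,
                            trial_id = 1L, block = 1L, session = 1L,
                            participant = 1L, max_tries = 1e4) {
  away <- sign(fixation_x)                  # away from center
  ps1 <- away * PS1_MAGNITUDES[sample.int(3, 1)]
  vs1 <- -away * VS1_MAGNITUDES[sample.int(3, 1)]
  steady_dur <- stats::runif(1, 500, 700)
  x_pre2 <- fixation_x + ps1 + vs1 * steady_dur / 1000
  for (i in seq_len(max_tries)) {
    ss <- draw_second_step(max_ttf, ps2_mode)
    x_post <- x_pre2 + ss[["ps2"]]
    x_end <- x_post + (vs1 + ss[["vs2"]]) * bound_window / 1000
    if (max(abs(c(x_post, x_end))) <= screen_bound) {
      return(new_step_ramp_spec(fixation_x, ps1, vs1, steady_dur,
                                ss[["ps2"]], ss[["vs2"]], blur = blur,
                                trial_id = trial_id, block = block,
                                session = session,
                                participant = participant))
    }
  }
  stop("draw_trial_spec: could not place second step on screen")
}

#' Build the target trajectory for one trial
#'
#' Piecewise-linear target position on the analysis grid: fixation, then
#' step 1 + ramp 1, then step 2 + ramp 2. The on-screen bound is enforced
#' from trial start through `bound_window` ms after the second step (the
#' window scored by the analysis); the simulated ramp continues linearly
#' afterwards.
#'
#' @param spec A `step_ramp_spec`.
#' @param sample_rate Samples per second (default 1000 Hz).
#' @param fix_dur Fixation duration before the first step, ms.
#' @param post_dur Simulated duration after the second step, ms (>= 800).
#' @param screen_bound,bound_window On-screen constraint (deg, ms).
#' @return An object of class `target_trajectory`: list with `time_ms`, `x`,
#'   `events` (named times of trial_start/step1/step2) and the `spec`.
#' @export
build_trial <- function(spec, sample_rate = 1000, fix_dur = 200,
                        post_dur = 1200, screen_bound = 30,
                        bound_window = 400) {
  stopifnot(inherits(spec, "step_ramp_spec"), post_dur >= 800)
  dt <- 1000 / sample_rate
  step1 <- round(fix_dur / dt) * dt
  step2 <- step1 + round(spec$steady_dur / dt) * dt
  total <- step2 + post_dur
  t <- seq(0, total, by = dt)
  x <- numeric(length(t))
  pre <- t < step1
  seg1 <- t >= step1 & t < step2
  seg2 <- t >= step2
  x[pre] <- spec$fixation_x
  x[seg1] <- spec$fixation_x + spec$ps1 + spec$vs1 * (t[seg1] - step1) / 1000
  x_pre2 <- spec$fixation_x + spec$ps1 + spec$vs1 * (step2 - step1) / 1000
  x[seg2] <- x_pre2 + spec$ps2 +
    (spec$vs1 + spec$vs2) * (t[seg2] - step2) / 1000
  chk <- t <= step2 + bound_window
  if (any(abs(x[chk]) > screen_bound + 1e-9))
    stop("build_trial: target leaves the +/-", screen_bound,
         " deg screen bound before the end of the classification window")
  structure(
    list(time_ms = t, x = x,
         events = c(trial_start = 0, step1 = step1, step2 = step2),
         spec = spec),
    class = "target_trajectory"
  )
}

#' Exact target velocity series for a trajectory
#'
#' Piecewise-constant velocity (0, vs1, vs1 + vs2); the sample at each
#' step time takes the post-step velocity.
#'
#' @param traj A `target_trajectory`.
#' @return Numeric vector of target velocities, deg/s.
#' @export
target_velocity <- function(traj) {
  stopifnot(inherits(traj, "target_trajectory"))
  t <- traj$time_ms
  v <- numeric(length(t))
  v[t >= traj$events[["step1"]]] <- traj$spec$vs1
  v[t >= traj$events[["step2"]]] <- traj$spec$vs1 + traj$spec$vs2
  v
}

#' Build a session schedule
#'
#' One row per trial: participants complete `sessions` sessions of `blocks`
#' blocks of `trials_per_block` trials. Conditions alternate between clear
#' and blurred targets across sessions; with counterbalancing, every second
#' participant starts with the blurred condition.
#'
#' @param n_participants,sessions,blocks,trials_per_block Positive counts
#'   (defaults: 15, 10, 10, 50).
#' @param counterbalance Logical; alternate the starting condition across
#'   participants.
#' @return A data frame with columns participant, session, block, trial,
#'   trial_id (within participant), condition.
#' @export
build_session_schedule <- function(n_participants = 15, sessions = 10,
                                   blocks = 10, trials_per_block = 50,
                                   counterbalance = TRUE) {
  stopifnot(n_participants >= 1, sessions >= 1, blocks >= 1,
            trials_per_block >= 1)
  g <- expand.grid(trial = seq_len(trials_per_block),
                   block = seq_len(blocks),
                   session = seq_len(sessions),
                   participant = seq_len(n_participants))
  start_blur <- if (counterbalance) g$participant %% 2L == 0L else FALSE
  blur <- xor(start_blur, g$session %% 2L == 0L)
  g$trial_id <- stats::ave(g$trial, g$participant, FUN = seq_along)
  g$condition <- ifelse(blur, "blur", "clear")
  g[c("participant", "session", "block", "trial", "trial_id", "condition")]
}

#' Draw trial specifications for every row of a schedule
#'
#' @param schedule Data frame from [build_session_schedule()].
#' @param ... Passed to [draw_trial_spec()] (e.g. `ps2_mode`, `max_ttf`).
#' @return List of `step_ramp_spec`, one per schedule row.
#' @export
generate_trial_specs <- function(schedule, ...) {
  lapply(seq_len(nrow(schedule)), function(i) {
    r <- schedule[i, ]
    draw_trial_spec(blur = r$condition == "blur",
                    trial_id = r$trial_id, block = r$block,
                    session = r$session, participant = r$participant, ...)
  })
}
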
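# Trigger-model components: observation noise, Kalman filter, predicted
# error, confidence, accumulation, saccade planning, closed-loop trials.

test_that("observations reduce to truth when noise is zero", {
  nm <- noise_model(pos_sd_clear = 0, pos_sd_blur = 0, vel_sd_base = 0,
                    sdn_coef = 0)
  obs <- observe(3.2, -14, nm)
  expect_equal(obs$pe_obs, 3.2)
  expect_equal(obs$rs_obs, -14)
})

test_that("observation noise matches its specification", {
  set.seed(10)
  nm <- noise_model()
  obs <- observe(rep(2, 1e4), rep(25, 1e4), nm, blur = FALSE)
  expect_lt(abs(sd(obs$pe_obs) / nm$pos_sd_clear - 1), 0.05)
  expect_lt(abs(sd(obs$rs_obs) /
                  (nm$vel_sd_base + nm$sdn_coef * 25) - 1), 0.05)
  # signal-dependent noise: variance grows with slip magnitude
  slow <- observe(rep(0, 5e3), rep(10, 5e3), nm)
  fast <- observe(rep(0, 5e3), rep(40, 5e3), nm)
  expect_gt(var(fast$rs_obs), var(slow$rs_obs))
})

test_that("the Kalman update obeys the classic noise limits", {
  est <- new_sensory_estimate(0, 0, diag(c(4, 25)))
  obs <- list(pe_obs = 3, rs_obs = -8)
  # near-zero observation noise: posterior mean goes to the observation
  up <- kalman_update(est, obs, obs_sd = c(1e-6, 1e-6), dt_step = 0.001)
  expect_equal(up$pe, 3, tolerance = 1e-4)
  expect_equal(up$rs, -8, tolerance = 1e-4)
  # huge observation noise: posterior equals the prediction
  up2 <- kalman_update(est, obs, obs_sd = c(1e6, 1e6), dt_step = 0.001)
  expect_equal(up2$pe, est$pe + 0.001 * est$rs, tolerance = 1e-4)
  expect_equal(up2$rs, est$rs, tolerance = 1e-4)
})

test_that("posterior uncertainty contracts over repeated updates", {
  set.seed(11)
  est <- new_sensory_estimate(0, 0, diag(c(25, 100)))
  traces <- numeric(50)
  for (k in 1:50) {
    obs <- list(pe_obs = 2 + rnorm(1, 0, 0.5),
                rs_obs = 5 + rnorm(1, 0, 1))
    est <- kalman_update(est, obs, obs_sd = c(0.5, 1), dt_step = 0.001,
                         process_sd = c(0.1, 3))
    traces[k] <- sum(diag(est$cov))
  }
  expect_true(all(diff(traces) < 1e-9))
})

test_that("non-positive-semidefinite covariances are rejected", {
  expect_error(new_sensory_estimate(0, 0, matrix(c(1, 5, 5, 1), 2)),
               "positive semidefinite")
})

test_that("standardized innovations have unit variance on matched data", {
  # truth follows the filter's own generative model, so whitened
  # innovations must be standard normal -- a correctness check on the
  # filter algebra
  set.seed(12)
  qs <- c(0.3, 5); rs <- c(0.5, 1.5); dt <- 0.001
  z <- c()
  for (trial in 1:1000) {
    pe <- rnorm(1, 0, 1); rsl <- rnorm(1, 0, 3)
    est <- new_sensory_estimate(0, 0, diag(c(1, 9)))
    for (k in 1:100) {
      pe <- pe + dt * rsl + rnorm(1, 0, qs[1] * sqrt(dt))
      rsl <- rsl + rnorm(1, 0, qs[2] * sqrt(dt))
      obs <- list(pe_obs = pe + rnorm(1, 0, rs[1]),
                  rs_obs = rsl + rnorm(1, 0, rs[2]))
      est <- kalman_update(est, obs, rs, dt, qs)
      if (k > 20) {   # skip the prior transient
        inn <- attr(est, "innovation")
        S <- attr(est, "innovation_cov")
        z <- c(z, backsolve(chol(S), inn, transpose = TRUE))
      }
    }
    if (length(z) > 4e4) break
  }
  expect_lt(abs(var(z) - 1), 0.1)
})

test_that("predicted error extrapolates mean and variance linearly", {
  est <- new_sensory_estimate(5, 10, matrix(c(1, 0.2, 0.2, 4), 2))
  pr <- predict_error(est, 0.15)
  expect_equal(pr$mean, 6.5)           # 5 + 0.15 * 10
  expect_equal(pr$var, 1 + 2 * 0.15 * 0.2 + 0.15^2 * 4)
  est2 <- new_sensory_estimate(5, -10, diag(c(1, 4)))
  expect_equal(predict_error(est2, 0.15)$mean, 3.5)
  pr0 <- predict_error(est, 0)
  expect_equal(pr0$mean, 5)
  expect_equal(pr0$var, 1)
})

test_that("extrafoveal confidence behaves at its symmetry points", {
  # zero mean: equal tails
  c0 <- confidence_outside_fovea(list(mean = 0, var = 2), 1)
  expect_equal(c0$p_right, c0$p_left)
  expect_equal(c0$log_dir_ratio, 0)
  # mean on the foveal edge with unit variance: right tail is exactly 1/2
  c1 <- confidence_outside_fovea(list(mean = 1, var = 1), 1)
  expect_equal(c1$p_right, 0.5)
  # far outside: certainty
  c2 <- confidence_outside_fovea(list(mean = 50, var = 1), 1)
  expect_gt(c2$p_right, 1 - 1e-12)
  expect_gt(c2$log_ratio, 100)
  # point mass inside the fovea
  c3 <- confidence_outside_fovea(list(mean = 0.5, var = 0), 1)
  expect_equal(c3$p_right, 0)
  expect_equal(c3$log_ratio, -Inf)
})

test_that("evidence accumulates linearly and triggers once", {
  st <- new_decision_state(threshold = 2)
  # constant positive rate c: crossing after threshold / c seconds
  for (k in 1:250) st <- accumulate_decision(st, 10, 0.001, now = k)
  expect_equal(st$triggered_at, 200)
  # non-positive rates never trigger
  st2 <- new_decision_state(2)
  for (k in 1:500) st2 <- accumulate_decision(st2, -5, 0.001, now = k)
  expect_true(is.na(st2$triggered_at))
  expect_equal(st2$evidence, 0)
})

test_that("saccade plans extrapolate to the landing point", {
  params <- model_params()
  # zero slip: amplitude equals the position error
  p0 <- plan_saccade(list(pe = 4, rs = 0), params, now = 1000)
  expect_equal(p0$amplitude, 4)
  expect_equal(p0$onset, 1000 + params$motor_delay)
  # explicit landing horizon: amplitude = pe + horizon * rs
  p1 <- plan_saccade(list(pe = 2, rs = 10), params, now = 0,
                     horizon = 0.125)
  expect_equal(p1$amplitude, 3.25)
  # main sequence keeps a 10-degree saccade within plausible duration
  expect_gt(main_sequence_duration(10), 20)
  expect_lt(main_sequence_duration(10), 100)
})

test_that("minimum-jerk profiles land exactly on the amplitude", {
  prof <- min_jerk_profile(5, 40)
  expect_equal(prof[1], 0)
  expect_equal(prof[length(prof)], 5, tolerance = 1e-9)
  expect_true(all(diff(prof) >= 0))
  # peak acceleration exceeds the detector threshold for 1-deg saccades
  prof1 <- min_jerk_profile(1, main_sequence_duration(1))
  acc <- diff(diff(prof1)) * 1e6
  expect_gt(max(abs(acc)), 750)
})

test_that("noise-free tracking with an unreachable threshold stays smooth", {
  p <- model_params(threshold = 1e9,
                    noise = noise_model(pos_sd_clear = 0, pos_sd_blur = 0,
                                        vel_sd_base = 0, sdn_coef = 0,
                                        process_pos_sd = 0.1,
                                        process_vel_sd = 3))
  traj <- build_trial(fixture_spec())
  sim <- simulate_trial(traj, p)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(is.finite(sim$trace$eye_x_deg)))
})

test_that("large perturbations trigger prompt saccades, small ones do not", {
  set.seed(13)
  p <- model_params()
  big <- fixture_spec(ps2 = 15, vs2 = 25)      # moving away, large error
  small <- fixture_spec(ps2 = 1, vs2 = -6)     # stays near the fovea
  frac_within <- function(spec, n = 60) {
    traj <- build_trial(spec)
    hits <- vapply(seq_len(n), function(i) {
      sim <- simulate_trial(traj, p)
      s2 <- traj$events[["step2"]]
      any(sim$events$onset_ms > s2 & sim$events$onset_ms <= s2 + 400)
    }, logical(1))
    mean(hits)
  }
  expect_gte(frac_within(big), 0.95)
  expect_lt(frac_within(small), 0.5)
})

test_that("simulated trials are reproducible under a seed", {
  traj <- build_trial(fixture_spec())
  p <- model_params()
  set.seed(77); a <- simulate_trial(traj, p)
  set.seed(77); b <- simulate_trial(traj, p)
  expect_identical(a$trace, b$trace)
  expect_identical(a$events, b$events)
})
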
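# Per-trial analysis chain: filtering, differentiation, detection,
# exclusions, metrics.

test_that("the zero-phase filter passes DC and the pursuit band", {
  t <- seq(0, 1, by = 0.001)
  expect_equal(lowpass_zero_phase(rep(3, 500)), rep(3, 500),
               tolerance = 1e-6)
  # 10-Hz component barely attenuated, 100-Hz strongly attenuated
  s10 <- sin(2 * pi * 10 * t)
  s100 <- sin(2 * pi * 100 * t)
  mid <- 300:700
  a10 <- max(abs(lowpass_zero_phase(s10)[mid]))
  a100 <- max(abs(lowpass_zero_phase(s100)[mid]))
  expect_gt(a10, 0.95)
  expect_lt(a100, 0.10)
  # zero phase: a symmetric pulse keeps its peak location
  pulse <- exp(-((seq_len(1001) - 501) / 30)^2)
  expect_equal(which.max(lowpass_zero_phase(pulse)), 501)
  expect_error(lowpass_zero_phase(1:5), "shorter")
})

test_that("NaN gaps are preserved and filtered around", {
  x <- sin(2 * pi * 5 * seq(0, 1, 0.001))
  x[400:450] <- NA
  xf <- lowpass_zero_phase(x)
  expect_true(all(is.na(xf[400:450])))
  expect_true(all(is.finite(xf[-(400:450)])))
})

test_that("central differences are exact for polynomials", {
  t <- seq(0, 0.5, by = 0.001)
  x <- 1000 * t                      # 1 deg/ms ramp
  v <- differentiate_central(x, 1000)
  expect_true(all(abs(v[2:(length(v) - 1)] - 1000) < 1e-6))
  xq <- 3 * t^2
  a <- differentiate_central(differentiate_central(xq, 1000), 1000)
  inner <- 3:(length(a) - 2)
  expect_true(all(abs(a[inner] - 6) < 1e-6))
  # NaN propagates to the two neighbours through the stencil
  x[100] <- NA
  vn <- differentiate_central(x, 1000)
  expect_true(all(is.na(vn[c(99, 101)])))
  expect_false(is.na(vn[97]))
})

test_that("pure pursuit traces yield no detections", {
  tr <- fixture_scripted_trace(amplitude = 0)
  eye_f <- lowpass_zero_phase(tr$eye_x_deg)
  v <- differentiate_central(eye_f)
  a <- differentiate_central(v)
  det <- detect_saccades(eye_f, v, a, tr$time_ms)
  expect_equal(nrow(det), 0)
})

test_that("injected saccades are recovered with onset error <= 5 ms", {
  tr <- fixture_scripted_trace(onset_ms = 1100, amplitude = 5)
  eye_f <- lowpass_zero_phase(tr$eye_x_deg)
  v <- differentiate_central(eye_f)
  a <- differentiate_central(v)
  det <- detect_saccades(eye_f, v, a, tr$time_ms)
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$onset_ms - 1100), 5)
  expect_equal(det$amplitude, 5, tolerance = 0.5)
})

test_that("two saccades 50 ms apart stay separate events", {
  tr <- fixture_scripted_trace(onset_ms = 1100, amplitude = 4)
  tr <- inject_saccade(tr, 1100 + main_sequence_duration(4) + 50, -3)
  eye_f <- lowpass_zero_phase(tr$eye_x_deg)
  v <- differentiate_central(eye_f)
  a <- differentiate_central(v)
  det <- detect_saccades(eye_f, v, a, tr$time_ms)
  expect_equal(nrow(det), 2)
})

test_that("detection is translation-equivariant", {
  tr <- fixture_scripted_trace(onset_ms = 1100, amplitude = 5)
  eye_f <- lowpass_zero_phase(tr$eye_x_deg)
  v <- differentiate_central(eye_f)
  a <- differentiate_central(v)
  d0 <- detect_saccades(eye_f, v, a, tr$time_ms)
  k <- 37
  n <- length(eye_f)
  d1 <- detect_saccades(eye_f[-(1:k)], v[-(1:k)], a[-(1:k)],
                        tr$time_ms[-(1:k)] - k)
  expect_equal(d1$onset_ms + k, d0$onset_ms)
  expect_equal(d1$offset_ms + k, d0$offset_ms)
})

test_that("error series follow the target-minus-eye convention", {
  err <- compute_errors(target = c(2, 3), eye = c(1, 1),
                        target_vel = c(10, 10), eye_vel = c(4, 4))
  expect_equal(err$pe, c(1, 2))       # target right of eye: positive
  expect_equal(err$rs, c(6, 6))
  # steady-state lag: eye 100 ms behind a 10 deg/s ramp leaves ~1 deg PE
  spec <- fixture_spec(ps2 = 0.01, vs2 = -10)
  traj <- build_trial(spec)
  tr <- synthesize_pursuit(traj, latency = 100, gain = 1, tau = 30,
                           motor_sd = 0)
  i <- which(tr$time_ms == 700)       # steady pursuit of the first ramp
  pe <- tr$target_x_deg[i] - tr$eye_x_deg[i]
  # the never-recovered first step plus the distance covered during the
  # response lag: ps1 + vs1 * (latency + tau)
  expect_equal(pe, spec$ps1 + spec$vs1 * (100 + 30) / 1000,
               tolerance = 0.5)
})

test_that("predicted error and crossing times match their formulas", {
  expect_equal(compute_pe_pred(5, 10, 0.15), 6.5)
  expect_equal(compute_pe_pred(5, -10, 0.15), 3.5)
  expect_equal(compute_pe_pred(0, 0), 0)
  expect_equal(compute_txt(5, 10), -500)
  expect_equal(compute_txt(5, -10), 500)
  expect_equal(compute_txe(-1, 10), 100)
  expect_true(is.na(compute_txe(2, 0)))
  expect_true(is.na(compute_txt(3, 0)))
})

test_that("step-window averaging matches an independent trapezoid", {
  t <- 0:2000
  pe_pred <- 6.5 + 0 * t
  expect_equal(pe_pred_at_step(pe_pred, t, 800, 50), 6.5)
  lin <- (t - 800) / 50               # 0 to 1 over the window
  expect_equal(pe_pred_at_step(lin, t, 800, 50), mean(lin[t >= 800 & t < 850]))
  set.seed(20)
  noisy <- rnorm(length(t))
  idx <- t >= 800 & t < 850
  oracle <- mean(noisy[idx])
  expect_equal(pe_pred_at_step(noisy, t, 800, 50), oracle)
})

test_that("pre-saccadic sampling hits the right instant", {
  t <- 0:2000
  pe <- 0.01 * t                      # known analytic series
  rs <- rep(4, length(t))
  s <- sample_presaccadic(pe, rs, t, onset_ms = 1200, step2_ms = 800)
  expect_equal(s$pe, 0.01 * 1100)
  expect_false(s$clamped)
  s0 <- sample_presaccadic(pe, rs, t, onset_ms = 1200, step2_ms = 800,
                           lead = 0)
  expect_equal(s0$pe, 0.01 * 1200)
  sc <- sample_presaccadic(pe, rs, t, onset_ms = 850, step2_ms = 800)
  expect_true(sc$clamped)
  expect_equal(sc$t_sample_ms, 800)
})

test_that("trial classification follows the window and cutoff", {
  expect_equal(classify_trial(120), "early")
  expect_equal(classify_trial(300), "late")
  expect_equal(classify_trial(450), "smooth")
  expect_equal(classify_trial(NA), "smooth")
  expect_equal(classify_trial(174.9), "early")
})

test_that("exclusion rules fire on their targeted faults", {
  t <- 0:2000
  eye <- rep(0, length(t)); pe <- rep(1, length(t))
  no_ev <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude = numeric(0))
  expect_true(apply_exclusions(eye, t, no_ev, 800, pe)$keep)
  # blink overlapping the critical window
  eye_b <- eye; eye_b[900:1000] <- NA
  ex <- apply_exclusions(eye_b, t, no_ev, 800, pe)
  expect_false(ex$keep); expect_equal(ex$reason, "blink")
  # saccade in flight at the step
  ev <- data.frame(onset_ms = 790, offset_ms = 820, amplitude = 2)
  ex2 <- apply_exclusions(eye, t, ev, 800, pe)
  expect_equal(ex2$reason, "saccade_at_step")
  # double saccade: second onset < 100 ms after first offset
  ev3 <- data.frame(onset_ms = c(900, 990), offset_ms = c(930, 1020),
                    amplitude = c(2, 2))
  ex3 <- apply_exclusions(eye, t, ev3, 800, pe)
  expect_equal(ex3$reason, "double_saccade")
  # saccade against the sign of the position error
  ev4 <- data.frame(onset_ms = 950, offset_ms = 980, amplitude = -3)
  ex4 <- apply_exclusions(eye, t, ev4, 800, pe)
  expect_equal(ex4$reason, "wrong_direction")
})

test_that("injected fault rates are reflected in the exclusion report", {
  set.seed(30)
  sched <- build_session_schedule(1, 1, 1, 120)
  ds <- generate_dataset(sched, mode = "scripted", blink_rate = 0.23,
                         seed = 30)
  m <- analyze_dataset(ds)
  frac <- mean(m$excluded & m$reason == "blink")
  injected <- mean(ds$truth$fault == "blink")
  expect_equal(frac, injected, tolerance = 1e-9)
  expect_lt(abs(injected - 0.23), 0.12)   # binomial fluctuation at n=120
})

test_that("metrics tables are byte-identical across repeat analyses", {
  set.seed(31)
  sched <- build_session_schedule(1, 1, 1, 5)
  ds <- generate_dataset(sched, mode = "scripted", seed = 31)
  m1 <- analyze_dataset(ds)
  m2 <- analyze_dataset(ds)
  expect_identical(m1, m2)
})

test_that("external tabular trials load and analyse like native ones", {
  tr <- fixture_scripted_trace(onset_ms = 1100, amplitude = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(data.frame(time_ms = tr$time_ms,
                       target_x_deg = tr$target_x_deg,
                       eye_x_deg = tr$eye_x_deg), path, row.names = FALSE)
  back <- read_tabular_trial(path, step2_ms = tr$events[["step2"]],
                             ps2 = tr$meta$ps2, vs2 = tr$meta$vs2)
  m_native <- analyze_trial(tr)
  m_ext <- analyze_trial(back)
  expect_equal(m_ext$trigger_time, m_native$trigger_time)
  expect_equal(m_ext$pe_pred_step, m_native$pe_pred_step)
})

test_that("phase-plot sign law holds on synthetic error series", {
  # pe and rs with the same sign: |pe| increasing; opposite: decreasing
  t <- seq(0, 1, 0.001)
  for (case in list(c(pe0 = 2, rs = 5), c(pe0 = -2, rs = -5),
                    c(pe0 = 2, rs = -5), c(pe0 = -2, rs = 5))) {
    pe <- case["pe0"] + case["rs"] * t
    d_abs <- diff(abs(pe))[1]
    same_sign <- unname(sign(case["pe0"]) == sign(case["rs"]))
    expect_equal(unname(d_abs > 0), same_sign)
  }
})

test_that("noiseless identity: predicted error is zero exactly when the
           eye-crossing time equals the horizon", {
  dt <- 0.15
  rs <- seq(-40, 40, by = 5); rs <- rs[rs != 0]
  pe <- -dt * rs                       # constructed on the identity locus
  expect_true(all(abs(compute_pe_pred(pe, rs, dt)) < 1e-12))
  expect_true(all(abs(compute_txe(pe, rs) - dt * 1000) < 1e-9))
  # and off the locus both deviate together
  pe2 <- pe + 1
  expect_true(all(compute_pe_pred(pe2, rs, dt) != 0))
  expect_true(all(abs(compute_txe(pe2, rs) - dt * 1000) > 1e-9))
})
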
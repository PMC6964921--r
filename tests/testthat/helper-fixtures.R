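# Shared fixtures, generated in code at test time.

# A fixed mid-size step-ramp spec used across tests.
fixture_spec <- function(ps2 = 8, vs2 = -20, blur = FALSE) {
  new_step_ramp_spec(fixation_x = -20, ps1 = -4, vs1 = 20,
                     steady_dur = 600, ps2 = ps2, vs2 = vs2, blur = blur)
}

# Noiseless scripted pursuit trace with a single injected saccade.
fixture_scripted_trace <- function(onset_ms = 1100, amplitude = 5,
                                   motor_sd = 0, spec = fixture_spec()) {
  traj <- build_trial(spec)
  tr <- synthesize_pursuit(traj, latency = 100, gain = 0.9, tau = 40,
                           motor_sd = motor_sd,
                           meta = list(ps2 = spec$ps2, vs2 = spec$vs2,
                                       participant = 1, trial_id = 1,
                                       trial_uid = "p01_t0001"))
  inject_saccade(tr, onset_ms, amplitude)
}

# Model-mode dataset at the scale used by the qualitative acceptance
# checks; generated once per test run and cached.
acceptance_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- build_session_schedule(n_participants = 5, sessions = 2,
                                      blocks = 4, trials_per_block = 50)
      ds <- generate_dataset(sched, mode = "model", seed = 20240915)
      cache <<- list(dataset = ds, metrics = run_analyze(ds))
    }
    cache
  }
})
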
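# Configuration and end-to-end pipeline stages: simulate -> analyze ->
# stats. Configs are nested lists with layered overrides; every analysis
# constant defaults to the task's stated value.

#' Default run configuration
#'
#' Nested list of every tunable constant: task geometry, schedule sizes,
#' model parameters, synthesis settings, analysis constants (extrapolation
#' horizon 150 ms, 50-Hz zero-phase filter, 750 deg/s^2 detector, 400-ms
#' classification window, 175-ms early cutoff, 100-ms pre-saccadic lead,
#' 50-ms step-averaging window) and statistics settings.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    schedule = list(n_participants = 15, sessions = 10, blocks = 10,
                    trials_per_block = 50, counterbalance = TRUE),
    task = list(max_ttf = 1.0, ps2_mode = "continuous", screen_bound = 30,
                fix_dur = 200, post_dur = 1200),
    model = list(dt = 0.15, foveal_radius = 2, threshold = 8,
                 sensory_delay = 60, motor_delay = 100, pursuit_gain = 0.9,
                 pursuit_accel_gain = 9, pursuit_pos_gain = 0.3,
                 conf_form = "direction",
                 noise = list(pos_sd_clear = 0.5, pos_sd_blur = 2.5,
                              pos_amb_clear = 0, pos_amb_blur = 0.8,
                              vel_sd_base = 1, sdn_coef = 0.2,
                              process_pos_sd = 0.1, process_vel_sd = 3)),
    synthesis = list(latency = 100, gain = 0.9, tau = 40, motor_sd = 0.5,
                     accel_max = 450,
                     blink_rate = 0, dropout_rate = 0,
                     trigger_rule = list(base = 180, k = 600,
                                         smooth_below = 2.5,
                                         jitter_sd = 0)),
    analysis = list(dt = 0.15, lp_cutoff = 50, acc_threshold = 750,
                    merge_gap_ms = 20, window = 400, early_cutoff = 175,
                    presacc_lead = 100, step_window = 50,
                    double_isi_ms = 100),
    stats = list(min_bin_n = 5)
  )
}

#' Merge configuration overrides onto defaults
#'
#' Recursive merge: values in `override` replace those in `base`; nested
#' lists merge element-wise.
#'
#' @param base Base configuration list.
#' @param override Partial configuration.
#' @return Merged list.
#' @export
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}

#' Load a JSON configuration file over the defaults
#'
#' @param path JSON file of (partial) configuration.
#' @return Full configuration list.
#' @export
load_config <- function(path) {
  merge_config(default_config(),
               jsonlite::read_json(path, simplifyVector = TRUE))
}

.model_params_from_config <- function(config) {
  m <- config$model
  model_params(dt = m$dt, foveal_radius = m$foveal_radius,
               threshold = m$threshold, sensory_delay = m$sensory_delay,
               motor_delay = m$motor_delay, pursuit_gain = m$pursuit_gain,
               pursuit_accel_gain = m$pursuit_accel_gain,
               pursuit_pos_gain = if (is.null(m$pursuit_pos_gain)) 0.3
                 else m$pursuit_pos_gain,
               conf_form = if (is.null(m$conf_form)) "direction"
                 else m$conf_form,
               noise = do.call(noise_model, m$noise))
}

#' Simulate a dataset from a configuration
#'
#' Builds the session schedule, draws trial specifications and generates
#' traces (model or scripted mode). With `out_dir`, the dataset, the
#' resolved configuration and a manifest are written to disk.
#'
#' @param config Configuration list (see [default_config()]).
#' @param mode "model" or "scripted".
#' @param out_dir Optional output directory.
#' @return The `synthetic_dataset`, invisibly when written.
#' @export
run_simulate <- function(config = default_config(), mode = "model",
                         out_dir = NULL) {
  sched <- do.call(build_session_schedule, config$schedule)
  syn <- config$synthesis
  ds <- generate_dataset(
    sched, mode = mode,
    params = .model_params_from_config(config),
    pursuit = syn[c("latency", "gain", "tau", "motor_sd", "accel_max")],
    trigger_rule = syn$trigger_rule,
    blink_rate = syn$blink_rate, dropout_rate = syn$dropout_rate,
    analysis_dt = config$analysis$dt,
    fix_dur = config$task$fix_dur, post_dur = config$task$post_dur,
    task = config$task[c("max_ttf", "ps2_mode", "screen_bound")],
    seed = config$seed)
  if (!is.null(out_dir)) {
    write_dataset(ds, out_dir)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(ds))
  }
  ds
}

#' Analyse a dataset directory or object
#'
#' Runs the trace-analysis chain on every trial. Unreadable trial files
#' are logged and marked excluded (reason "unreadable"); the run
#' continues.
#'
#' @param x A `synthetic_dataset` or a dataset directory path.
#' @param config Configuration list.
#' @param out_file Optional CSV path for the metrics table.
#' @return Metrics data frame.
#' @export
run_analyze <- function(x, config = default_config(), out_file = NULL) {
  an <- config$analysis
  if (is.character(x)) x <- read_dataset(x)
  rows <- lapply(seq_along(x$traces), function(i) {
    tr <- x$traces[[i]]
    out <- tryCatch(
      analyze_trial(tr, dt = an$dt, lp_cutoff = an$lp_cutoff,
                    acc_threshold = an$acc_threshold,
                    merge_gap_ms = an$merge_gap_ms, window = an$window,
                    early_cutoff = an$early_cutoff,
                    presacc_lead = an$presacc_lead,
                    step_window = an$step_window,
                    double_isi_ms = an$double_isi_ms),
      error = function(e) {
        warning("trial ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(out)) {
      out <- .empty_metrics_row()
      out$trial_uid <- if (!is.null(tr$meta$trial_uid))
        tr$meta$trial_uid else NA_character_
      out$excluded <- TRUE
      out$reason <- "unreadable"
    }
    out
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(out_file)) {
    dir.create(dirname(out_file), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, out_file, row.names = FALSE)
  }
  metrics
}

#' Group statistics and hypothesis report for a metrics table
#'
#' Computes per-subject bin summaries for the canonical PE_pred and T_xt
#' schemes, repeated-measures ANOVAs with Bonferroni post-hocs and BIC
#' Bayes factors where at least two subjects are available, and the
#' directional hypothesis checks. Cells with fewer than
#' `config$stats$min_bin_n` trials are dropped from the ANOVAs.
#'
#' @param metrics Metrics data frame.
#' @param config Configuration list.
#' @param out_dir Optional directory for CSV outputs.
#' @return List with `summaries` (per scheme), `anova`, `posthoc`,
#'   `bayes_factor`, `checks`, `exclusions`.
#' @export
run_stats <- function(metrics, config = default_config(), out_dir = NULL) {
  sch <- canonical_bin_schemes()
  min_n <- config$stats$min_bin_n
  summaries <- list(
    pe_pred = summarize_bins(bin_trials(metrics, sch$pe_pred_coarse)),
    txt = summarize_bins(bin_trials(metrics, sch$txt)))
  anovas <- list(); posthocs <- list(); bfs <- list()
  n_subj <- length(unique(metrics$participant[!metrics$excluded]))
  if (n_subj >= 2) {
    for (nm in names(summaries)) {
      s <- summaries[[nm]]
      s <- s[s$n >= min_n & !is.na(s$median_trigger), , drop = FALSE]
      for (dv in c("median_trigger", "iqr_trigger")) {
        key <- paste(nm, dv, sep = ".")
        fit <- tryCatch(rm_anova(s, dv, "bin"), error = function(e) NULL)
        if (!is.null(fit)) {
          anovas[[key]] <- fit$table
          posthocs[[key]] <- posthoc_paired(s, dv, "bin")
          bfs[[key]] <- bayes_factor_anova(s, dv, "bin")
        }
      }
    }
  } else {
    warning("run_stats: fewer than 2 subjects; descriptives only")
  }
  checks <- hypothesis_checks(metrics)
  out <- list(summaries = summaries, anova = anovas, posthoc = posthocs,
              bayes_factor = bfs, checks = checks,
              exclusions = exclusion_report(metrics))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(summaries))
      utils::write.csv(summaries[[nm]],
                       file.path(out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    if (length(anovas))
      utils::write.csv(
        cbind(analysis = rep(names(anovas),
                             vapply(anovas, nrow, 0L)),
              do.call(rbind, anovas)),
        file.path(out_dir, "anova.csv"), row.names = FALSE)
    utils::write.csv(checks, file.path(out_dir, "hypothesis_checks.csv"),
                     row.names = FALSE)
    utils::write.csv(out$exclusions,
                     file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  out
}
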
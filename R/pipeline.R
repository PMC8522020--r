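# End-to-end orchestration: simulate -> islands -> calibrate -> outings /
# imputation -> evaluation, from a single validated config with one root
# seed.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. `source` is
#' either `"simulate"` (run the synthetic-home generator) or a directory
#' of participant sub-directories readable by [read_participant()].
#'
#' @param source `"simulate"` or a data directory.
#' @param n_participants Cohort size when simulating.
#' @param n_days Days per participant when simulating.
#' @param algorithm Calibration algorithm: `"gpr"`, `"lr"` or `"gbt"`.
#' @param calibration_days Days of wearable data used for calibration.
#' @param eval_after Evaluation uses islands from this day on (counted
#'   from the first wear day).
#' @param imputation_mode `"none"`, `"plain"`, `"tau_p"` or
#'   `"tau_global"`.
#' @param smoothing_window Moving-average window (seconds).
#' @param min_wear_coverage Minimum island wear coverage for a target.
#' @param min_outing_minutes Minimum outing duration (minutes).
#' @param profile_bin_width Temporal-profile bin width (minutes).
#' @param tau_window `"calibration"` (default) or `"all"`: the wear data
#'   used to estimate tau.
#' @param seed Root seed; all stage randomness derives from it.
#' @param out_dir Optional output directory for reports.
#' @return A validated `run_config` list.
#' @export
run_config <- function(source = "simulate", n_participants = 5,
                       n_days = 60, algorithm = "gpr",
                       calibration_days = 14, eval_after = 30,
                       imputation_mode = "tau_p", smoothing_window = 60,
                       min_wear_coverage = 0.8, min_outing_minutes = 5,
                       profile_bin_width = 30, tau_window = "calibration",
                       seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  defaults <- formals(run_config)
  for (f in names(defaults)) {
    if (is.null(cfg[[f]]) && !is.symbol(defaults[[f]])) {
      cfg[[f]] <- eval(defaults[[f]])
    }
  }
  if (!identical(cfg$source, "simulate") && !dir.exists(cfg$source)) {
    stop("config error: source must be 'simulate' or an existing directory",
         call. = FALSE)
  }
  if (!cfg$algorithm %in% c("gpr", "lr", "gbt")) {
    stop("config error: unknown algorithm '", cfg$algorithm, "'",
         call. = FALSE)
  }
  if (!cfg$imputation_mode %in% c("none", "plain", "tau_p", "tau_global")) {
    stop("config error: unknown imputation mode", call. = FALSE)
  }
  if (cfg$calibration_days > 30) {
    stop("config error: calibration_days must be <= 30", call. = FALSE)
  }
  stopifnot(cfg$n_days >= 1, cfg$smoothing_window >= 1,
            cfg$min_wear_coverage >= 0, cfg$min_wear_coverage <= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full calibration pipeline
#'
#' Executes simulate/load -> island extraction -> per-participant
#' calibration -> outing detection, tau estimation and imputation ->
#' evaluation metrics, all seeded from the config's root seed. Stage
#' errors are annotated with the stage and participant.
#'
#' @param config A `run_config` (or list validated against it).
#' @param quiet Suppress progress messages.
#' @return A report list: `config`, per-participant results, `global`
#'   metrics, `tau`, and (when computable) `drift` and `uncertainty`.
#' @export
run_pipeline <- function(config = run_config(), quiet = TRUE) {
  config <- validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage simulate/load")
  sims <- if (identical(config$source, "simulate")) {
    simulate_cohort(n = config$n_participants,
                    behavior = behavior_config(n_days = config$n_days,
                                               seed = config$seed),
                    seed = config$seed)
  } else {
    dirs <- list.dirs(config$source, recursive = FALSE)
    lapply(dirs, function(d) list(dataset = read_participant(d),
                                  truth = NULL))
  }

  per <- lapply(seq_along(sims), function(i) {
    ds <- sims[[i]]$dataset
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s | %s] %s", name, ds$participant_id,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    isl <- stage("islands",
                 build_islands(ds, window = config$smoothing_window,
                               min_coverage = config$min_wear_coverage))
    d0 <- min(isl$day[!is.na(isl$target)])
    cal <- isl[isl$day < d0 + config$calibration_days, , drop = FALSE]
    ev <- isl[isl$day >= d0 + config$eval_after, , drop = FALSE]
    model <- stage("calibrate",
                   fit_calibration(cal, algorithm = config$algorithm,
                                   seed = substream_seed(config$seed,
                                                         paste0("fit_", i))))
    pred_ev <- stage("predict", predict_calibration(model, ev))

    outings <- stage("outings",
                     detect_outings(ds, config$min_outing_minutes))
    cal_end <- attr_day0_epoch(isl, d0 + config$calibration_days)
    tau_accel <- if (identical(config$tau_window, "calibration")) {
      ds$accel[ds$accel$timestamp < cal_end, , drop = FALSE]
    } else ds$accel
    home <- accel_at_home(tau_accel, outings)
    tau_est <- stage("tau", tryCatch({
      prof_accel <- build_profile(home$timestamp, home$magnitude,
                                  ds$timezone, config$profile_bin_width)
      estimate_tau(ds, outings[outings$start < cal_end, , drop = FALSE],
                   prof_accel)
    }, error = function(e) NULL))

    # profile of calibrated at-home activity for imputation
    pred_all <- predict_calibration(model, isl)
    prof_cal <- stage("profile",
                      build_calibrated_profile(pred_all, isl, outings,
                                               timezone = ds$timezone,
                                               bin_width = config$profile_bin_width))
    ev_outings <- outings[outings$start >= attr_day0_epoch(isl, d0 + config$eval_after), ,
                          drop = FALSE]
    metrics <- stage("metrics",
                     compute_metrics(pred_ev, ev,
                                     accel_daily = accel_daily_totals(ds)))
    list(participant_id = ds$participant_id, islands = isl, model = model,
         predictions = pred_ev, eval_islands = ev, outings = outings,
         eval_outings = ev_outings, tau = tau_est,
         profile_calibrated = prof_cal, metrics = metrics,
         truth = sims[[i]]$truth)
  })

  say("stage cohort summaries")
  reports <- lapply(per, `[[`, "metrics")
  glob <- global_metrics(reports)
  taus <- Filter(Negate(is.null), lapply(per, `[[`, "tau"))
  tau_g <- if (length(taus) >= 2) tau_global(taus) else NA_real_

  weekly <- lapply(reports, function(r) weekly_mae(r$mae_pd))
  drift <- tryCatch(drift_analysis(weekly), error = function(e) NULL)
  unc <- if (config$algorithm == "gpr") {
    tryCatch(uncertainty_correlation(reports), error = function(e) NULL)
  } else NULL

  report <- list(config = unclass(config), participants = per,
                 global = glob, tau_global = tau_g, drift = drift,
                 uncertainty = unc)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# epoch second of local midnight of day index `day` (islands carry local
# day indices)
attr_day0_epoch <- function(isl, day) {
  tz <- attr(isl, "timezone")
  # invert local_day_index at midnight: local day d starts at
  # d*86400 - offset
  t_approx <- day * SECONDS_PER_DAY
  t_approx - utc_offset(t_approx, tz)
}

report_summary <- function(report) {
  list(global = report$global,
       tau_global = report$tau_global,
       tau_p = vapply(report$participants, function(p)
         if (is.null(p$tau)) NA_real_ else p$tau$tau_p, numeric(1)),
       drift = if (!is.null(report$drift))
         list(slope = report$drift$slope, p_value = report$drift$p_value),
       uncertainty = if (!is.null(report$uncertainty))
         list(median = report$uncertainty$median,
              n = report$uncertainty$n))
}
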
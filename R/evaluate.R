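# Statistical evaluation battery: island/daily errors, daily-total
# correlations, post-calibration drift, uncertainty-error correlation,
# and pre/post clinical-correlation comparison.

#' Daily accelerometer totals
#'
#' Full daily activity sums from the wearable stream (all worn seconds,
#' including outings), by local calendar day.
#'
#' @param ds A [participant_dataset()].
#' @return data.frame with `day` (local day index) and `total`.
#' @export
accel_daily_totals <- function(ds) {
  day <- local_day_index(ds$accel$timestamp, ds$timezone)
  agg <- stats::aggregate(list(total = ds$accel$magnitude),
                          list(day = day), sum)
  agg
}

#' Evaluation metrics for one participant
#'
#' Computes the island-level mean absolute error (`mae`), its daily
#' averages (`mae_pd`), and the two daily-total Pearson correlations:
#' `rho` between daily summed predictions and the full daily
#' accelerometer totals (including outings), and `rho_tilde` between
#' daily summed predictions and the island-restricted accelerometer
#' totals. Days with fewer than `min_islands_per_day` islands are
#' excluded from the daily correlations; zero-variance daily series give
#' a missing correlation with a warning.
#'
#' @param pred Predictions from [predict_calibration()].
#' @param islands The matching `activity_islands` (evaluation window;
#'   islands without targets are ignored for error metrics).
#' @param accel_daily Optional data.frame `day`/`total` from
#'   [accel_daily_totals()]; required for `rho`.
#' @param min_islands_per_day Minimum islands per day for the daily
#'   correlations (default 2).
#' @return A `metrics_report` list: `mae`, `mae_pd` (data.frame),
#'   `rho`, `rho_tilde`, `daily` (per-day table), `n_islands`, `n_days`.
#' @export
compute_metrics <- function(pred, islands, accel_daily = NULL,
                            min_islands_per_day = 2L) {
  stopifnot(nrow(pred) == nrow(islands))
  ok <- !is.na(islands$target)
  err <- abs(pred$mean[ok] - islands$target[ok])
  day <- islands$day[ok]
  mae <- if (any(ok)) mean(err) else NA_real_
  mae_pd <- if (any(ok)) {
    stats::aggregate(list(mae_pd = err), list(day = day), mean)
  } else data.frame(day = integer(0), mae_pd = numeric(0))

  daily <- stats::aggregate(
    list(pred_total = pred$mean[ok], target_total = islands$target[ok],
         n_islands = rep(1L, sum(ok))),
    list(day = day), sum)
  if ("sd" %in% names(pred)) {
    sd_day <- stats::aggregate(list(mean_sd = pred$sd[ok]),
                               list(day = day), mean)
    daily <- merge(daily, sd_day, by = "day")
  }
  dcor <- daily[daily$n_islands >= min_islands_per_day, , drop = FALSE]
  rho_tilde <- safe_cor(dcor$pred_total, dcor$target_total)
  rho <- NA_real_
  if (!is.null(accel_daily)) {
    m <- merge(dcor, accel_daily, by = "day")
    rho <- safe_cor(m$pred_total, m$total)
  }
  structure(list(mae = mae, mae_pd = mae_pd, rho = rho,
                 rho_tilde = rho_tilde, daily = daily,
                 n_islands = sum(ok), n_days = nrow(daily)),
            class = "metrics_report")
}

safe_cor <- function(x, y, method = "pearson") {
  if (length(x) < 3L || anyNA(x) || anyNA(y)) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance daily series; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = method)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d islands / %d days: MAE %.2f, rho %.3f, rho~ %.3f\n",
              x$n_islands, x$n_days, x$mae, x$rho, x$rho_tilde))
  invisible(x)
}

#' Global metrics over a cohort
#'
#' Unweighted participant means of the per-participant metrics; missing
#' correlations are excluded from the averages with a warning.
#'
#' @param reports List of `metrics_report` objects.
#' @return data.frame with one row: `mae`, `rho`, `rho_tilde`,
#'   `n_participants`.
#' @export
global_metrics <- function(reports) {
  g <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  rho <- g("rho"); rho_t <- g("rho_tilde")
  if (anyNA(c(rho[!is.nan(rho)], rho_t))) {
    warning("missing per-participant correlations excluded from global mean",
            call. = FALSE)
  }
  data.frame(mae = mean(g("mae"), na.rm = TRUE),
             rho = mean(rho, na.rm = TRUE),
             rho_tilde = mean(rho_t, na.rm = TRUE),
             n_participants = length(reports))
}

#' Weekly mean absolute error series
#'
#' Bins a participant's daily errors into consecutive 7-day weeks from
#' the first evaluation day.
#'
#' @param mae_pd data.frame `day`/`mae_pd` from [compute_metrics()].
#' @param n_weeks Maximum number of weeks (default 30).
#' @return data.frame with `week` (1-based) and `mae`.
#' @export
weekly_mae <- function(mae_pd, n_weeks = 30) {
  if (!nrow(mae_pd)) return(data.frame(week = integer(0), mae = numeric(0)))
  week <- (mae_pd$day - min(mae_pd$day)) %/% 7L + 1L
  agg <- stats::aggregate(list(mae = mae_pd$mae_pd), list(week = week),
                          mean)
  agg[agg$week <= n_weeks, , drop = FALSE]
}

#' Post-calibration drift analysis
#'
#' Standardizes each participant's weekly MAE series robustly (median
#' removed, scaled by the interquartile range), averages across
#' participants per week, and regresses the global weekly mean on the
#' week index by ordinary least squares. The two-sided p-value of the
#' slope decides, at level `alpha`, whether calibration performance
#' drifts over time.
#'
#' @param weekly_list List of data.frames `week`/`mae`, one per
#'   participant (>= 8 weeks for >= 3 participants).
#' @param alpha Significance level (default 0.05).
#' @return A `drift_report`: standardized series, global weekly means,
#'   `slope`, `p_value`, `significant`.
#' @export
drift_analysis <- function(weekly_list, alpha = 0.05) {
  keep <- vapply(weekly_list, function(w) nrow(w) >= 8L, logical(1))
  if (sum(keep) < 3L) {
    stop("need >= 8 weeks of evaluation data for >= 3 participants",
         call. = FALSE)
  }
  std <- lapply(weekly_list[keep], function(w) {
    iqr <- stats::IQR(w$mae)
    if (iqr == 0) return(NULL)
    data.frame(week = w$week, z = (w$mae - median(w$mae)) / iqr)
  })
  dropped <- sum(vapply(std, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " participant(s) with zero IQR excluded from drift analysis",
            call. = FALSE)
    std <- std[!vapply(std, is.null, logical(1))]
  }
  long <- do.call(rbind, std)
  glob <- stats::aggregate(list(mean_z = long$z), list(week = long$week),
                           mean)
  fit <- lm(mean_z ~ week, data = glob)
  # a perfectly linear series is a legitimate input; summary.lm warns
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["week", "Estimate"]
  p <- if (nrow(sm) > 1 && is.finite(sm["week", "Pr(>|t|)"]))
    sm["week", "Pr(>|t|)"] else 1
  structure(list(standardized = std, global = glob, slope = slope,
                 p_value = p, alpha = alpha, significant = p < alpha),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> slope %.4g, p = %.4g (%ssignificant at %.2f)\n",
              x$slope, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Correlation between daily error and predictive uncertainty
#'
#' For each participant, the Pearson correlation between the daily
#' average island error and the daily average GP predictive standard
#' deviation; reported with the cohort median and spread. Requires GPR
#' predictions (a predictive sd); a constant sd series gives a missing
#' correlation.
#'
#' @param reports List of `metrics_report` objects from GPR predictions
#'   (their `daily` tables must contain `mean_sd`).
#' @param min_days Minimum evaluation days per participant (default 14).
#' @return List with `per_participant` correlations, `median`, `spread`
#'   (median absolute deviation-based) and `n`.
#' @export
uncertainty_correlation <- function(reports, min_days = 14L) {
  rs <- vapply(reports, function(r) {
    d <- merge(r$daily, r$mae_pd, by = "day")
    if (!"mean_sd" %in% names(d)) {
      stop("predictive uncertainty requires a GPR model (no sd available)",
           call. = FALSE)
    }
    if (nrow(d) < min_days) return(NA_real_)
    if (sd(d$mean_sd) == 0 || sd(d$mae_pd) == 0) return(NA_real_)
    cor(d$mean_sd, d$mae_pd)
  }, numeric(1))
  list(per_participant = rs, median = median(rs, na.rm = TRUE),
       spread = stats::mad(rs, na.rm = TRUE), n = sum(!is.na(rs)))
}

#' Wilcoxon signed-rank test, exact for small samples
#'
#' Paired one-sample signed-rank test on `x - y`. Exact permutation
#' p-values are used for n <= 25 (zeros dropped, provided there are no
#' ties in the absolute differences); otherwise the normal approximation
#' with continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return List with `statistic`, `p_value`, `n` (non-zero differences),
#'   `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  d <- x - y
  nz <- d[d != 0]
  n <- length(nz)
  use_exact <- n <= 25L && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, alternative = alternative,
                exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       exact = use_exact)
}

#' Pre/post-calibration clinical correlation comparison
#'
#' For each clinical assessment, computes Spearman's rank correlation
#' between the participants' activity summaries (median daily totals)
#' and their mean assessment values, for three activity sources:
#' pre-calibration (raw PIR), post-calibration, and the accelerometer.
#' A one-sided Wilcoxon signed-rank test then compares the absolute
#' correlations post vs pre under the alternative that calibration
#' increases them.
#'
#' @param activity data.frame with columns `participant`, `pre`, `post`,
#'   `accel` (median daily activity totals per source).
#' @param assessments data.frame with `participant`, `assessment`,
#'   `value` (long format; repeated assessments are averaged per
#'   participant).
#' @return A `clinical_report`: per-assessment correlation table,
#'   Wilcoxon `statistic`, `p_value`, `n`.
#' @export
clinical_comparison <- function(activity, assessments) {
  if (nrow(activity) < 6L) {
    stop("need >= 6 participants with assessments", call. = FALSE)
  }
  means <- stats::aggregate(list(value = assessments$value),
                            list(participant = assessments$participant,
                                 assessment = assessments$assessment),
                            mean)
  rows <- lapply(split(means, means$assessment), function(a) {
    m <- merge(activity, a[c("participant", "value")], by = "participant")
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3L) {
      warning("assessment '", a$assessment[1],
              "' has < 3 non-missing participants; skipped",
              call. = FALSE)
      return(NULL)
    }
    data.frame(assessment = a$assessment[1],
               r_pre = safe_cor(m$pre, m$value, method = "spearman"),
               r_post = safe_cor(m$post, m$value, method = "spearman"),
               r_accel = safe_cor(m$accel, m$value, method = "spearman"))
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  wt <- wilcoxon_signed_rank(abs(tab$r_post), abs(tab$r_pre),
                             alternative = "greater")
  structure(list(correlations = tab, statistic = wt$statistic,
                 p_value = wt$p_value, n = nrow(tab), exact = wt$exact),
            class = "clinical_report")
}

#' @export
print.clinical_report <- function(x, ...) {
  cat(sprintf("<clinical_report> %d assessments, Wilcoxon V = %g, one-sided p = %.4g\n",
              x$n, x$statistic, x$p_value))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
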
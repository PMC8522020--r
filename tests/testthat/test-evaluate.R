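test_that("perfect and shifted predictions give the closed-form metrics", {
  isl <- make_eval_fixture(balanced = TRUE)
  perfect <- data.frame(mean = isl$target)
  met <- compute_metrics(perfect, isl)
  expect_equal(met$mae, 0)
  expect_equal(met$rho_tilde, 1)
  shifted <- data.frame(mean = isl$target + 100)
  met2 <- compute_metrics(shifted, isl)
  expect_equal(met2$mae, 100)
  expect_equal(met2$rho_tilde, 1)   # Pearson is shift-invariant
})

test_that("metrics equal a brute-force recomputation from definitions", {
  isl <- make_eval_fixture(n = 80, days = 15, seed = 9)
  set.seed(10)
  pred <- data.frame(mean = pmax(0, isl$target + rnorm(80, 0, 120)))
  accel_daily <- data.frame(day = sort(unique(isl$day)),
                            total = rexp(length(unique(isl$day)), 1e-3))
  met <- compute_metrics(pred, isl, accel_daily)
  # independent recomputation
  err <- abs(pred$mean - isl$target)
  expect_equal(met$mae, sum(err) / length(err))
  by_day <- split(seq_len(nrow(isl)), isl$day)
  mae_pd <- vapply(by_day, function(i) mean(err[i]), numeric(1))
  expect_equal(met$mae_pd$mae_pd, unname(mae_pd))
  keep <- names(by_day)[vapply(by_day, length, integer(1)) >= 2]
  fhat <- vapply(by_day[keep], function(i) sum(pred$mean[i]), numeric(1))
  ftil <- vapply(by_day[keep], function(i) sum(isl$target[i]), numeric(1))
  expect_equal(met$rho_tilde, cor(fhat, ftil))
  fd <- accel_daily$total[match(as.integer(keep), accel_daily$day)]
  expect_equal(met$rho, cor(fhat, fd))
})

test_that("metrics are invariant to island ordering and flag zero variance", {
  isl <- make_eval_fixture(n = 40, days = 8, seed = 3)
  pred <- data.frame(mean = isl$target * 0.9 + 10)
  met1 <- compute_metrics(pred, isl)
  perm <- sample(nrow(isl))
  met2 <- compute_metrics(pred[perm, , drop = FALSE], isl[perm, ])
  expect_equal(met1$mae, met2$mae)
  expect_equal(met1$rho_tilde, met2$rho_tilde)
  # constant daily prediction series: undefined correlation -> missing
  bal <- make_eval_fixture(n = 40, days = 8, seed = 3, balanced = TRUE)
  flat <- data.frame(mean = rep(5, nrow(bal)))
  expect_warning(met3 <- compute_metrics(flat, bal), "zero-variance")
  expect_true(is.na(met3$rho_tilde))
})

test_that("global metrics are unweighted participant means", {
  r1 <- structure(list(mae = 10, rho = 0.8, rho_tilde = 0.9),
                  class = "metrics_report")
  r2 <- structure(list(mae = 30, rho = 0.6, rho_tilde = 0.7),
                  class = "metrics_report")
  g <- global_metrics(list(r1, r2))
  expect_equal(g$mae, 20)
  expect_equal(g$rho, 0.7)
  expect_equal(g$rho_tilde, 0.8)
  g2 <- global_metrics(list(r2, r1))
  expect_equal(g, g2)
})

test_that("drift regression finds trends and ignores flat series", {
  set.seed(14)
  flat <- lapply(1:4, function(i)
    data.frame(week = 1:20, mae = 5 + rnorm(20, 0, 0.5)))
  rep_flat <- drift_analysis(flat)
  expect_false(rep_flat$significant)
  expect_lt(abs(rep_flat$slope), 0.05)

  rising <- lapply(1:4, function(i)
    data.frame(week = 1:30, mae = 100 + 5 * (1:30)))
  rep_up <- drift_analysis(rising)
  expect_true(rep_up$significant)
  expect_lt(rep_up$p_value, 0.001)

  # zero-IQR participants are excluded with a warning
  mix <- c(rising[1:3], list(data.frame(week = 1:30, mae = rep(7, 30))))
  expect_warning(rep_mix <- drift_analysis(mix), "zero IQR")
  expect_true(rep_mix$significant)
  expect_error(drift_analysis(rising[1:2]), ">= 3 participants")
})

test_that("uncertainty-error correlation handles exact and degenerate cases", {
  mk <- function(sd_col, mae_col) {
    daily <- data.frame(day = 1:20, pred_total = 0, target_total = 0,
                        n_islands = 2, mean_sd = sd_col)
    structure(list(daily = daily,
                   mae_pd = data.frame(day = 1:20, mae_pd = mae_col)),
              class = "metrics_report")
  }
  mae <- rexp(20)
  # sd exactly proportional to the daily error: r = 1
  r <- uncertainty_correlation(list(mk(3 * mae, mae)), min_days = 10)
  expect_equal(unname(r$per_participant), 1)
  # constant sd: undefined, reported missing
  r2 <- uncertainty_correlation(list(mk(rep(2, 20), mae)), min_days = 10)
  expect_true(is.na(r2$per_participant))
  # no sd column: not a GPR model
  no_sd <- mk(1, mae)
  no_sd$daily$mean_sd <- NULL
  expect_error(uncertainty_correlation(list(no_sd)), "GPR")
})

test_that("GP uncertainty tracks daily error on simulated homes", {
  rs <- vapply(1:3, function(s) {
    sim <- simulate_participant(behavior_config(n_days = 45,
                                                seed = 800 + s))
    isl <- build_islands(sim$dataset)
    d0 <- min(isl$day[!is.na(isl$target)])
    cal <- isl[isl$day < d0 + 14, ]
    ev <- isl[isl$day >= d0 + 30, ]
    m <- fit_calibration(cal, "gpr", seed = s)
    met <- compute_metrics(predict_calibration(m, ev), ev)
    uncertainty_correlation(list(met), min_days = 10)$median
  }, numeric(1))
  expect_gt(median(rs), 0)
})

test_that("exact Wilcoxon matches the combinatorial closed form", {
  # eight positive differences: one-sided p = 1/2^8
  x <- c(0.57, 0.66, 0.56, 0.61, 0.85, 0.64, 0.49, 0.36)
  y <- c(0.42, 0.51, 0.49, 0.43, 0.68, 0.56, 0.39, 0.35)
  wt <- wilcoxon_signed_rank(x, y, "greater")
  expect_true(wt$exact)
  expect_equal(wt$n, 8)
  expect_equal(wt$p_value, 1 / 256)
  expect_equal(wt$p_value, 0.00390625)
  # identical series: no evidence of improvement
  wt0 <- wilcoxon_signed_rank(x, x, "greater")
  expect_gte(wt0$p_value, 0.5)
  # large n falls back to the normal approximation
  set.seed(1)
  a <- rnorm(40); b <- a - 0.5
  expect_false(wilcoxon_signed_rank(a, b, "greater")$exact)
})

test_that("clinical comparison reports per-assessment Spearman triples", {
  set.seed(8)
  n <- 8
  act <- data.frame(participant = 1:n,
                    pre = rnorm(n),          # scrambled by apartments
                    post = 1:n + rnorm(n, 0, 0.1),
                    accel = 1:n + rnorm(n, 0, 0.1))
  assessments <- rbind(
    data.frame(participant = 1:n, assessment = "up",
               value = 1:n + rnorm(n, 0, 0.2)),
    data.frame(participant = 1:n, assessment = "down",
               value = -(1:n) + rnorm(n, 0, 0.2)))
  rep <- clinical_comparison(act, assessments)
  expect_equal(nrow(rep$correlations), 2)
  expect_gt(rep$correlations$r_post[rep$correlations$assessment == "up"],
            0.9)
  expect_lt(rep$correlations$r_post[rep$correlations$assessment == "down"],
            -0.9)
  expect_true(all(abs(rep$correlations$r_post) >=
                    abs(rep$correlations$r_pre) - 1e-9) ||
                rep$p_value > 0)
  expect_error(clinical_comparison(act[1:4, ], assessments), ">= 6")
  # assessments observed for too few participants are skipped
  sparse <- rbind(assessments,
                  data.frame(participant = 1:2, assessment = "rare",
                             value = c(1, 2)))
  expect_warning(rep2 <- clinical_comparison(act, sparse), "skipped")
  expect_false("rare" %in% rep2$correlations$assessment)
})

test_that("weekly binning groups seven consecutive days", {
  mae_pd <- data.frame(day = 100:127, mae_pd = rep(1:4, each = 7))
  wk <- weekly_mae(mae_pd)
  expect_equal(wk$week, 1:4)
  expect_equal(wk$mae, 1:4)
  expect_equal(nrow(weekly_mae(mae_pd, n_weeks = 2)), 2)
})
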
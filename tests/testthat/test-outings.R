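test_that("outing detection follows the door/PIR contract", {
  ds <- tiny_dataset()
  t10 <- loc("2021-05-01 10:30:00")
  # clean absence: door event, an hour of silence, door event
  ds$doors <- data.frame(timestamp = c(t10, t10 + 3600),
                         door = "entrance", state = c("close", "open"))
  ds$motion <- ds$motion[ds$motion$timestamp < t10, , drop = FALSE]
  out <- detect_outings(ds)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, t10)
  expect_equal(out$end, t10 + 3600)

  # door events with PIR motion in between: at-home door use
  ds2 <- tiny_dataset()
  mid <- loc("2021-05-01 10:05:00")    # PIR active then
  ds2$doors <- data.frame(timestamp = c(mid - 30, mid + 30),
                          door = "entrance", state = c("close", "open"))
  expect_equal(nrow(detect_outings(ds2)), 0)

  # shorter than min_duration
  ds3 <- tiny_dataset()
  ds3$doors <- data.frame(timestamp = c(t10, t10 + 120),
                          door = "entrance", state = c("close", "open"))
  ds3$motion <- ds3$motion[ds3$motion$timestamp < t10, , drop = FALSE]
  expect_equal(nrow(detect_outings(ds3, min_duration = 5)), 0)
  expect_equal(nrow(detect_outings(ds3, min_duration = 1)), 1)

  # no door events at all
  ds4 <- tiny_dataset()
  ds4$doors <- ds4$doors[0, ]
  expect_warning(out4 <- detect_outings(ds4), "no")
  expect_equal(nrow(out4), 0)
})

test_that("detected outings recover generated outing minutes", {
  jac <- vapply(1:3, function(s) {
    sim <- quick_sim(n_days = 12, seed = 100 + s)
    got <- detect_outings(sim$dataset)
    gt <- sim$truth$outings
    span <- range(c(got$start, got$end, gt$start, gt$end))
    n <- ceiling(span[2] - span[1])
    m1 <- ambcal:::intervals_to_mask(got$start, got$end, span[1], n)
    m2 <- ambcal:::intervals_to_mask(gt$start, gt$end, span[1], n)
    sum(m1 & m2) / sum(m1 | m2)
  }, numeric(1))
  expect_true(all(jac >= 0.9))
})

test_that("temporal profile reproduces constant and localized series", {
  days <- 10
  t0 <- loc("2021-05-01 00:00:00")
  ts <- as.numeric(sapply(0:(days - 1), function(d)
    t0 + d * 86400 + seq(0, 86399, by = 30)))
  prof <- build_profile(ts, rep(4.2, length(ts)), TZ)
  expect_equal(prof$mean, rep(4.2, 48))
  expect_equal(prof$support, rep(10L, 48))
  expect_false(any(prof$flagged))

  # support localized to 08:00-09:00
  sel <- (ts - t0) %% 86400 >= 8 * 3600 & (ts - t0) %% 86400 < 9 * 3600
  prof2 <- build_profile(ts[sel], rep(2, sum(sel)), TZ)
  expect_equal(which(!is.na(prof2$mean)), c(17L, 18L))
  expect_error(build_profile(ts[1:10], rep(1, 10), TZ), "3 observed days")
})

test_that("temporal profile equals the brute-force per-bin average", {
  set.seed(5)
  t0 <- loc("2021-05-01 00:00:00")
  ts <- sort(sample(0:(5 * 86400 - 1), 40000)) + t0
  v <- rexp(length(ts))
  prof <- build_profile(ts, v, TZ, bin_width = 60)
  day <- (ts - t0) %/% 86400
  bin <- ((ts - t0) %% 86400) %/% 3600
  for (b in 0:23) {
    per_day <- vapply(unique(day), function(d) {
      i <- day == d & bin == b
      if (!any(i)) NA_real_ else mean(v[i])
    }, numeric(1))
    expect_equal(prof$mean[b + 1], mean(per_day, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("tau ratios behave as exact identities", {
  b <- behavior_config(n_days = 10, accel_noise_sd = 0, seed = 51)
  sim <- simulate_participant(b)
  ds <- sim$dataset
  outings <- sim$truth$outings
  home <- ambcal:::accel_at_home(ds$accel, outings)
  prof <- build_profile(home$timestamp, home$magnitude, ds$timezone)
  tau <- estimate_tau(ds, outings, prof)
  # doubling the wearable stream doubles every ratio, hence tau_p
  ds2 <- ds
  ds2$accel$magnitude <- ds$accel$magnitude * 2
  idx <- findInterval(ds2$accel$timestamp, outings$start)
  inside <- idx >= 1 & ds2$accel$timestamp < outings$end[pmax(idx, 1)]
  ds2$accel$magnitude[!inside] <- ds$accel$magnitude[!inside]
  tau2 <- estimate_tau(ds2, outings, prof)
  expect_equal(tau2$tau_p, 2 * tau$tau_p, tolerance = 1e-9)
  expect_equal(tau2$ratios, 2 * tau$ratios, tolerance = 1e-9)
})

test_that("tau estimation excludes uncovered outings and can fail", {
  ds <- tiny_dataset()   # constant magnitude 2 while worn
  prof <- structure(list(mean = rep(2, 48), support = rep(10L, 48),
                         flagged = rep(FALSE, 48), bin_width = 30,
                         timezone = TZ),
                    class = "temporal_profile")
  # outing entirely outside the wear window: zero coverage
  night <- data.frame(start = loc("2021-05-01 23:00:00"),
                      end = loc("2021-05-01 23:30:00"))
  expect_error(estimate_tau(ds, night, prof), "no eligible outings")
  # constant activity: every ratio is exactly 1
  day_out <- data.frame(start = loc("2021-05-01 12:00:00"),
                        end = loc("2021-05-01 13:00:00"))
  tau <- estimate_tau(ds, day_out, prof)
  expect_equal(tau$tau_p, 1.0, tolerance = 1e-9)
})

test_that("tau_global averages per-participant factors", {
  e1 <- structure(list(tau_p = 1.2), class = "tau_estimate")
  e2 <- structure(list(tau_p = 1.6), class = "tau_estimate")
  expect_equal(tau_global(list(e1, e2)), 1.4)
  expect_error(tau_global(list(e1)))
})

test_that("imputation obeys the arithmetic contract", {
  pred <- data.frame(mean = c(100, 50))
  isl <- islands_from_matrix(matrix(rnorm(4), 2), c(1, 1),
                             day = c(18748L, 18748L))
  isl$start <- c(loc("2021-05-01 10:00:00"), loc("2021-05-01 12:00:00"))
  isl$end <- isl$start + 600
  # flat profile: 100 units per hour = 100/3600 per second
  prof <- structure(list(mean = rep(100 / 3600, 48),
                         support = rep(10L, 48),
                         flagged = rep(FALSE, 48), bin_width = 30,
                         timezone = TZ),
                    class = "temporal_profile")
  outing <- data.frame(start = loc("2021-05-01 14:00:00"),
                       end = loc("2021-05-01 15:00:00"))
  none <- impute_daily_totals(pred, isl, outing, prof, "none")
  plain <- impute_daily_totals(pred, isl, outing, prof, "plain")
  taup <- impute_daily_totals(pred, isl, outing, prof, "tau_p",
                              tau = 1.5)
  tau1 <- impute_daily_totals(pred, isl, outing, prof, "tau_p", tau = 1)
  expect_equal(none$imputed_total, 150)
  expect_equal(plain$imputed_total, 250)
  expect_equal(taup$imputed_total, 300)     # adds 1.5 x 100 units
  expect_equal(tau1$imputed_total, plain$imputed_total)
  expect_equal(taup$outing_minutes, 60)
  # imputation never decreases a day's total
  expect_true(all(plain$imputed_total >= none$imputed_total))
  expect_error(impute_daily_totals(pred, isl, outing, prof, "tau_p"),
               "requires a tau")
  # a day without outings is identical under every mode
  no_out <- outing[0, ]
  for (mode in c("none", "plain")) {
    expect_equal(impute_daily_totals(pred, isl, no_out, prof,
                                     mode)$imputed_total, 150)
  }
})
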
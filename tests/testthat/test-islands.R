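make_signal <- function(values, start = loc("2021-05-01 00:00:00")) {
  structure(list(start = start, values = values, timezone = TZ),
            class = "total_activity_signal")
}

test_that("total signal counts concurrently active sensors", {
  ds <- tiny_dataset()
  sig <- total_signal(ds)
  on1 <- loc("2021-05-01 10:00:00")
  at <- function(t) sig$values[t - sig$start + 1]
  expect_equal(at(on1), 1)          # kitchen only
  expect_equal(at(on1 + 320), 2)    # both sensors active 10:05-10:10
  expect_equal(at(on1 + 660), 1)    # living room only
  expect_equal(at(on1 + 1000), 0)
  expect_error(total_signal(participant_dataset(
    "x", TZ, "kitchen",
    data.frame(timestamp = numeric(0), sensor_id = character(0),
               room = character(0), active = logical(0)),
    ds$doors, ds$accel)), "empty motion")
})

test_that("total signal equals brute-force event replay on simulated data", {
  sim <- quick_sim(n_days = 2, seed = 13)
  ds <- sim$dataset
  sig <- total_signal(ds)
  # brute force: per sensor, walk the state machine over every second
  span <- ambcal:::dataset_span(ds)
  n <- length(sig$values)
  want <- numeric(n)
  for (sid in unique(ds$motion$sensor_id)) {
    ev <- ds$motion[ds$motion$sensor_id == sid, ]
    state <- FALSE; j <- 1
    for (t in seq_len(n)) {
      now <- sig$start + t - 1
      while (j <= nrow(ev) && ev$timestamp[j] <= now) {
        state <- ev$active[j]; j <- j + 1
      }
      want[t] <- want[t] + as.integer(state)
    }
  }
  expect_equal(sum(sig$values), sum(want))
  expect_equal(sig$values, want)
})

test_that("smoothing preserves constants and spreads an impulse", {
  const <- make_signal(rep(3, 500))
  expect_equal(smooth_signal(const, 60)$values, rep(3, 500))
  imp <- make_signal(c(rep(0, 250), 1, rep(0, 249)))
  sm <- smooth_signal(imp, 60)
  expect_equal(max(sm$values), 1 / 60)
  expect_equal(sum(sm$values), 1)    # mass conserved in the interior
  expect_error(smooth_signal(make_signal(rep(1, 10)), 60), "window")
})

test_that("smoothing matches a brute-force windowed mean everywhere", {
  set.seed(7)
  v <- rpois(400, 0.5)
  sm <- smooth_signal(make_signal(v), 60)
  h1 <- 29; h2 <- 30
  want <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - h1):min(length(v), i + h2)])
  }, numeric(1))
  expect_equal(sm$values, want)
})

test_that("island extraction equals the positive-support oracle", {
  s0 <- loc("2021-05-01 00:00:00")
  expect_equal(nrow(extract_islands(make_signal(rep(0, 100)))), 0)
  full <- extract_islands(make_signal(rep(2, 100)))
  expect_equal(full$start, s0)
  expect_equal(full$end, s0 + 100)
  set.seed(11)
  for (i in 1:30) {
    v <- smooth_signal(make_signal(rpois(2000, 0.05)), 60)$values
    got <- extract_islands(make_signal(v))
    want <- oracle_islands(v, s0)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("island features follow the stated conventions", {
  ds <- tiny_dataset(magnitude = 2)
  # one island in a single room: 14:30 local start, 120 s
  on <- loc("2021-05-01 14:30:00")
  ds$motion <- data.frame(timestamp = c(on, on + 120),
                          sensor_id = "pir_kitchen_1", room = "kitchen",
                          active = c(TRUE, FALSE))
  iv <- data.frame(start = on, end = on + 120)
  isl <- featurize_islands(iv, ds)
  expect_equal(isl$hour, 14L)
  expect_equal(isl$duration, 120)
  expect_equal(isl$rel_kitchen, 1.0)
  expect_equal(isl$rel_living_room, 0)
  expect_equal(isl$sec_kitchen, 120)
  # accel magnitude 2 at 1 Hz over 120 s
  expect_equal(isl$target, 240)
  expect_equal(isl$wear_coverage, 1)
  expect_error(featurize_islands(data.frame(start = on, end = on), ds),
               "zero-duration")
})

test_that("per-room seconds equal brute-force replay on simulated islands", {
  sim <- quick_sim(n_days = 2, seed = 17)
  ds <- sim$dataset
  isl <- build_islands(ds)
  expect_gt(nrow(isl), 10)
  rint <- ambcal:::room_intervals(ds)
  pick <- seq(1, nrow(isl), length.out = 8)
  for (i in round(pick)) {
    for (r in ds$rooms) {
      secs <- sum(vapply(seq_len(nrow(rint[[r]])), function(j) {
        max(0, min(rint[[r]]$end[j], isl$end[i]) -
              max(rint[[r]]$start[j], isl$start[i]))
      }, numeric(1)))
      expect_equal(isl[[paste0("sec_", r)]][i], secs, tolerance = 1e-9)
    }
    expect_lte(sum(as.numeric(isl[i, paste0("rel_", ds$rooms)])),
               length(ds$rooms))
    expect_true(all(as.numeric(isl[i, paste0("rel_", ds$rooms)]) <= 1 + 1e-12))
  }
})

test_that("targets are dropped below the wear-coverage threshold", {
  ds <- tiny_dataset()
  # island straddling the 22:00 wear boundary: 50% coverage
  s <- loc("2021-05-01 21:50:00")
  ds$motion <- data.frame(timestamp = c(s, s + 1200),
                          sensor_id = "pir_kitchen_1", room = "kitchen",
                          active = c(TRUE, FALSE))
  isl <- featurize_islands(data.frame(start = s, end = s + 1200), ds)
  expect_true(is.na(isl$target))
  expect_equal(isl$wear_coverage, 0.5)
})

test_that("perfect-sensor noiseless targets conserve daily wear activity", {
  b <- behavior_config(n_days = 2, outings_per_day = 0,
                       accel_noise_sd = 0, seed = 19,
                       waking_window = c(7, 21) * 3600)
  sens <- sensor_response_config(gain = 10, dead_zone_prob = 0,
                                 response = "linear")
  sim <- simulate_participant(b, sens)
  isl <- build_islands(sim$dataset)
  truth_daily <- true_daily_totals(sim$truth, wear_only = TRUE)
  got <- stats::aggregate(list(total = isl$target), list(day = isl$day),
                          sum)
  m <- merge(got, truth_daily, by = "day")
  expect_equal(m$total.x, m$total.y, tolerance = 1e-6)
})

test_that("island CSV export carries features, target and coverage", {
  sim <- quick_sim(n_days = 2, seed = 23)
  isl <- build_islands(sim$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  write_islands(isl, path)
  back <- as.data.frame(data.table::fread(path))
  expect_equal(nrow(back), nrow(isl))
  expect_true(all(c("start", "end", "duration", "hour", "target",
                    "wear_coverage") %in% names(back)))
  expect_equal(back$sec_kitchen, isl$sec_kitchen, tolerance = 1e-6)
})

test_that("standardizer gives zero mean, unit variance, no leakage", {
  two <- islands_from_matrix(matrix(c(0, 2, 5, 5), ncol = 2), c(1, 2))
  expect_warning(std <- fit_standardizer(two, columns = c("f1", "f2")),
                 "constant")
  expect_equal(std$dropped, "f2")
  # two-point column {0, 2} maps to {-1, +1}
  expect_equal(as.numeric(apply_standardizer(std, two)), c(-1, 1))
  set.seed(3)
  cal <- islands_from_matrix(matrix(rnorm(60), 20), rnorm(20))
  ev <- islands_from_matrix(matrix(rnorm(30, mean = 5), 10), rnorm(10))
  std <- fit_standardizer(cal, columns = matrix_feature_cols(matrix(0, 1, 3)))
  Z <- apply_standardizer(std, cal)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colMeans(Z^2), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # evaluation data transformed with calibration statistics
  Zev <- apply_standardizer(std, ev)
  expect_gt(mean(colMeans(Zev)), 1)
  const <- islands_from_matrix(matrix(1, 10, 2), rnorm(10))
  expect_error(suppressWarnings(
    fit_standardizer(const, columns = c("f1", "f2"))), "constant")
})
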
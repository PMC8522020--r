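# Synthetic single-occupant home: coupled PIR / door / accelerometer
# streams with known ground truth, for validation by parameter recovery.

#' Behaviour configuration for the synthetic home
#'
#' Describes the occupant: alternating rest/active bouts during waking
#' hours (exponential inter-bout gaps, log-normal durations), a diurnal
#' intensity profile, room preferences, overnight wearable non-wear, and
#' door-bracketed outings whose activity is a fixed multiple (`tau_true`)
#' of the expected at-home activity at the same clock time.
#'
#' @param n_days Number of simulated days (>= 1).
#' @param bout_rate Expected active bouts per waking hour.
#' @param bout_duration_mean,bout_duration_sd Mean/sd of bout duration in
#'   seconds (log-normal).
#' @param intensity_base Mean per-second activity magnitude during a bout,
#'   in accelerometer count units.
#' @param intensity_cv Coefficient of variation of per-bout intensity
#'   levels (log-normal).
#' @param intensity_profile 24-entry diurnal multiplier on bout intensity.
#' @param room_preferences Named probability vector over rooms (summing to
#'   1), or a 24 x R matrix of per-hour-block probabilities.
#' @param wear_window Local-time wear interval in seconds since midnight,
#'   default 07:00-22:00; the wearable records only inside it.
#' @param waking_window Local-time interval in which active bouts occur.
#' @param outings_per_day Expected outings per day (Poisson).
#' @param outing_duration_mean,outing_duration_sd Mean/sd outing duration
#'   in minutes (truncated normal, minimum 10 min).
#' @param tau_true Outside/inside activity ratio applied during outings.
#' @param accel_noise_sd Sd of additive truncated-Gaussian accelerometer
#'   noise (counts); 0 gives the noiseless limit.
#' @param day_scale_sd Sd (log scale) of a per-day multiplier on bout
#'   intensity, modelling day-to-day behavioural variability.
#' @param seed Integer seed; all randomness derives from it via named
#'   substreams.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(n_days = 60,
                            bout_rate = 2,
                            bout_duration_mean = 480,
                            bout_duration_sd = 300,
                            intensity_base = 8,
                            intensity_cv = 0.4,
                            intensity_profile = default_intensity_profile(),
                            room_preferences = default_room_preferences(),
                            wear_window = c(7, 22) * 3600,
                            waking_window = c(7, 23) * 3600,
                            outings_per_day = 1,
                            outing_duration_mean = 90,
                            outing_duration_sd = 30,
                            tau_true = 1.38,
                            accel_noise_sd = 0.25,
                            day_scale_sd = 0.15,
                            seed = 1L) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  stopifnot(bout_rate >= 0, bout_duration_mean > 0, intensity_base >= 0,
            outings_per_day >= 0, tau_true > 0, accel_noise_sd >= 0,
            length(intensity_profile) == 24, all(intensity_profile >= 0))
  if (is.matrix(room_preferences)) {
    stopifnot(nrow(room_preferences) == 24,
              all(abs(rowSums(room_preferences) - 1) < 1e-8))
  } else {
    stopifnot(abs(sum(room_preferences) - 1) < 1e-8)
  }
  structure(as.list(environment()), class = "behavior_config")
}

#' @rdname behavior_config
#' @export
default_intensity_profile <- function() {
  # calm nights, a morning and a late-afternoon peak
  c(0.3, 0.3, 0.3, 0.3, 0.3, 0.4, 0.6, 0.9, 1.2, 1.1, 1.0, 1.1,
    1.0, 0.9, 0.9, 1.0, 1.2, 1.3, 1.1, 0.9, 0.7, 0.6, 0.4, 0.3)
}

#' @rdname behavior_config
#' @export
default_room_preferences <- function() {
  c(kitchen = 0.22, toilet = 0.08, living_room = 0.40,
    entrance = 0.05, bedroom = 0.10, bathroom = 0.15)
}

#' Sensor-response configuration for the synthetic home
#'
#' Abstract PIR response model: within each active bout, a room's sensor
#' detects a contiguous fraction of the bout that is a monotone function
#' of the bout intensity, or misses the bout entirely (dead zone). This
#' reproduces the angle/distance/layout effects that make raw PIR
#' durations incomparable across apartments.
#'
#' @param gain Named per-room gain, or a single number recycled; higher
#'   gain means more of a bout is detected.
#' @param dead_zone_prob Per-room probability that a bout is missed
#'   entirely, or a single number recycled.
#' @param trigger_hold Seconds a PIR stays active after motion stops.
#' @param refractory Seconds after deactivation during which a re-trigger
#'   is absorbed into the previous activation.
#' @param response `"saturating"` (fraction `1 - exp(-gain * intensity)`,
#'   with multiplicative detection noise and a random within-bout offset)
#'   or `"linear"` (fraction `min(1, gain * intensity)`, deterministic) —
#'   the linear mode yields targets that are an exact linear function of
#'   per-room detected seconds, useful for validating calibration.
#' @return A `sensor_response_config` list.
#' @export
sensor_response_config <- function(gain = 0.08,
                                   dead_zone_prob = 0.08,
                                   trigger_hold = 4,
                                   refractory = 2,
                                   response = c("saturating", "linear")) {
  response <- match.arg(response)
  stopifnot(all(gain >= 0), all(dead_zone_prob >= 0),
            all(dead_zone_prob <= 1), trigger_hold >= 0, refractory >= 0)
  structure(list(gain = gain, dead_zone_prob = dead_zone_prob,
                 trigger_hold = trigger_hold, refractory = refractory,
                 response = response),
            class = "sensor_response_config")
}

per_room <- function(x, rooms) {
  if (is.null(names(x))) return(setNames(rep_len(x, length(rooms)), rooms))
  stopifnot(all(rooms %in% names(x)))
  x[rooms]
}

# Expected at-home activity per second at a given local hour, implied by
# the behaviour model: duty cycle x mean bout level x diurnal multiplier.
expected_home_intensity <- function(behavior, hour) {
  duty <- behavior$bout_duration_mean /
    (3600 / behavior$bout_rate + behavior$bout_duration_mean)
  duty * behavior$intensity_base * behavior$intensity_profile[hour + 1L]
}

#' Simulate one participant's home
#'
#' Generates coupled PIR motion events, entrance/fridge door events and a
#' 1 Hz wearable accelerometer stream, together with the per-second ground
#' truth (true intensity, room occupancy, outing intervals, `tau_true`).
#' During outings the accelerometer keeps recording at `tau_true` times
#' the expected at-home intensity for that clock time while all indoor
#' sensors stay silent; every outing is bracketed by entrance-door
#' open/close pairs. Identical seeds give identical output.
#'
#' @param behavior A [behavior_config()].
#' @param sensors A [sensor_response_config()].
#' @param layout Character vector of equipped rooms.
#' @param participant_id Identifier for the generated dataset.
#' @param timezone IANA timezone of the home.
#' @param start_date Local calendar date of day 1.
#' @return A list with elements `dataset` (a [participant_dataset()]) and
#'   `truth` (a `ground_truth` object).
#' @export
simulate_participant <- function(behavior = behavior_config(),
                                 sensors = sensor_response_config(),
                                 layout = names(default_room_preferences()),
                                 participant_id = "sim_participant",
                                 timezone = "Europe/Zurich",
                                 start_date = "2021-05-01") {
  stopifnot(inherits(behavior, "behavior_config"),
            inherits(sensors, "sensor_response_config"))
  seed <- behavior$seed
  n_days <- as.integer(behavior$n_days)
  t0 <- epoch_from_local(paste(start_date, "00:00:00"), timezone)
  n_sec <- n_days * SECONDS_PER_DAY
  rooms <- layout
  gain <- per_room(sensors$gain, rooms)
  dead <- per_room(sensors$dead_zone_prob, rooms)

  day_scale <- with_substream(seed, "day_scale", {
    if (behavior$day_scale_sd > 0)
      rlnorm(n_days, -behavior$day_scale_sd^2 / 2, behavior$day_scale_sd)
    else rep(1, n_days)
  })

  bouts <- with_substream(seed, "bouts",
                          draw_bouts(behavior, rooms, day_scale))
  outings <- with_substream(seed, "outings", draw_outings(behavior, n_days))

  # occupant is absent during outings: clip overlapping bouts to the
  # at-home complement (dropping them entirely would create artificial
  # rest time around outings and bias the home activity baseline)
  if (nrow(outings) && nrow(bouts)) {
    pieces <- lapply(seq_len(nrow(bouts)), function(i) {
      s <- bouts$start[i]; e <- bouts$end[i]
      cuts <- outings[outings$end > s & outings$start < e, , drop = FALSE]
      if (!nrow(cuts)) return(bouts[i, , drop = FALSE])
      ss <- c(s, cuts$end); ee <- c(cuts$start, e)
      ok <- (ee - ss) >= 30
      if (!any(ok)) return(NULL)
      out <- bouts[rep(i, sum(ok)), , drop = FALSE]
      out$start <- pmax(s, ss[ok]); out$end <- pmin(e, ee[ok])
      out
    })
    bouts <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    rownames(bouts) <- NULL
  }

  # ground-truth per-second intensity and occupancy
  intensity <- numeric(n_sec)
  occupancy <- integer(n_sec)                     # 0 = resting at home
  levels_occ <- c("rest", rooms, "outside")
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      idx <- (bouts$start[i] + 1L):bouts$end[i]   # local seconds, 1-based
      intensity[idx] <- bouts$level[i]
      occupancy[idx] <- match(bouts$room[i], rooms)
    }
  }
  if (nrow(outings)) {
    # outing intensity is tau_true times the participant's own realized
    # mean home intensity at that clock hour, so the outside/inside
    # ratio of the generated series equals tau_true by construction
    hr_all <- (((seq_len(n_sec) - 1L) %% SECONDS_PER_DAY) %/% 3600L) + 1L
    away <- intervals_to_mask(outings$start, outings$end, 0, n_sec)
    home_hour_mean <- vapply(1:24, function(h) {
      i <- hr_all == h & !away
      if (!any(i)) return(NA_real_)
      mean(intensity[i])
    }, numeric(1))
    home_hour_mean[is.na(home_hour_mean)] <-
      expected_home_intensity(behavior, which(is.na(home_hour_mean)) - 1L)
    for (i in seq_len(nrow(outings))) {
      idx <- (outings$start[i] + 1L):outings$end[i]
      hrs <- ((idx - 1L) %% SECONDS_PER_DAY) %/% 3600L
      intensity[idx] <- behavior$tau_true * home_hour_mean[hrs + 1L]
      occupancy[idx] <- length(rooms) + 1L
    }
  }

  # wearable stream: integer-second samples inside the wear window
  sec_of_day <- (seq_len(n_sec) - 1L) %% SECONDS_PER_DAY
  wear <- sec_of_day >= behavior$wear_window[1] &
    sec_of_day < behavior$wear_window[2]
  widx <- which(wear)
  mag <- intensity[widx]
  if (behavior$accel_noise_sd > 0) {
    noise <- with_substream(seed, "accel_noise",
                            rnorm(length(widx), 0, behavior$accel_noise_sd))
    mag <- pmax(0, mag + noise)
  }
  accel <- data.frame(timestamp = t0 + widx - 1L, magnitude = mag)

  # PIR detection per bout
  motion <- with_substream(seed, "detection",
                           detect_bouts(bouts, sensors, gain, dead, rooms))
  if (nrow(motion)) {
    motion$timestamp <- motion$timestamp + t0
  }

  doors <- with_substream(seed, "doors",
                          draw_door_events(outings, n_days, behavior))
  doors$timestamp <- doors$timestamp + t0

  out_epoch <- outings
  if (nrow(out_epoch)) {
    out_epoch$start <- out_epoch$start + t0
    out_epoch$end <- out_epoch$end + t0
  }

  ds <- participant_dataset(participant_id, timezone, rooms,
                            motion = motion, doors = doors, accel = accel)
  truth <- structure(list(start = t0, n_sec = n_sec, timezone = timezone,
                          intensity = intensity,
                          occupancy = structure(occupancy,
                                                levels = levels_occ),
                          outings = out_epoch,
                          tau_true = behavior$tau_true,
                          day_scale = day_scale,
                          behavior = behavior, sensors = sensors),
                     class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d days, tau_true = %.2f, %d outings\n",
              x$n_sec %/% SECONDS_PER_DAY, x$tau_true, nrow(x$outings)))
  invisible(x)
}

# Active bouts over all days, in local seconds from day-1 midnight.
draw_bouts <- function(behavior, rooms, day_scale) {
  sdlog <- sqrt(log(1 + (behavior$bout_duration_sd /
                           behavior$bout_duration_mean)^2))
  meanlog <- log(behavior$bout_duration_mean) - sdlog^2 / 2
  lvl_sd <- behavior$intensity_cv
  prefs <- behavior$room_preferences
  res <- vector("list", behavior$n_days)
  for (d in seq_len(behavior$n_days)) {
    day0 <- (d - 1L) * SECONDS_PER_DAY
    t <- day0 + behavior$waking_window[1]
    day_end <- day0 + behavior$waking_window[2]
    starts <- ends <- levels <- numeric(0); room <- character(0)
    while (TRUE) {
      gap <- rexp(1, rate = behavior$bout_rate / 3600)
      start <- round(t + gap)
      if (start >= day_end) break
      dur <- max(30, round(rlnorm(1, meanlog, sdlog)))
      end <- min(start + dur, day_end)
      hr <- ((start %% SECONDS_PER_DAY) %/% 3600) + 1L
      lvl <- behavior$intensity_base *
        rlnorm(1, -lvl_sd^2 / 2, lvl_sd) *
        behavior$intensity_profile[hr] * day_scale[d]
      p <- if (is.matrix(prefs)) prefs[hr, rooms] else prefs[rooms]
      rm_ <- sample(rooms, 1L, prob = p)
      starts <- c(starts, start); ends <- c(ends, end)
      levels <- c(levels, lvl); room <- c(room, rm_)
      t <- end
    }
    res[[d]] <- data.frame(start = starts, end = ends, level = levels,
                           room = room, day = rep(d - 1L, length(starts)))
  }
  do.call(rbind, res)
}

# Outing intervals in local seconds; daytime, non-overlapping.
draw_outings <- function(behavior, n_days) {
  starts <- ends <- numeric(0)
  for (d in seq_len(n_days)) {
    k <- rpois(1, behavior$outings_per_day)
    if (k == 0) next
    day0 <- (d - 1L) * SECONDS_PER_DAY
    s <- sort(round(day0 + runif(k, 9 * 3600, 19 * 3600)))
    dur <- pmax(10, rnorm(k, behavior$outing_duration_mean,
                          behavior$outing_duration_sd)) * 60
    e <- round(pmin(s + dur, day0 + 21.5 * 3600))
    keep <- rep(TRUE, k)
    if (k > 1) for (i in 2:k) if (s[i] < e[i - 1] + 600) keep[i] <- FALSE
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
  }
  data.frame(start = starts, end = ends)
}

# Emit PIR on/off events for detected spans of each bout.
detect_bouts <- function(bouts, sensors, gain, dead, rooms) {
  empty <- data.frame(timestamp = numeric(0), sensor_id = character(0),
                      room = character(0), active = logical(0))
  if (is.null(bouts) || nrow(bouts) == 0L) return(empty)
  n <- nrow(bouts)
  u_dead <- runif(n)
  u_noise <- runif(n, 0.9, 1.0)
  u_offset <- runif(n)
  g <- gain[bouts$room]
  dz <- dead[bouts$room]
  dur <- bouts$end - bouts$start
  frac <- switch(sensors$response,
                 saturating = (1 - exp(-g * bouts$level)) * u_noise,
                 linear = pmin(1, g * bouts$level))
  span <- frac * dur
  hit <- u_dead >= dz & span > 0
  if (!any(hit)) return(empty)
  if (sensors$response == "linear") {
    # idealized response for validation: short pulses spread evenly over
    # the whole bout, union exactly frac * duration; no hold/refractory
    # so per-room detected seconds are an exact linear image of
    # intensity x duration
    spacing <- 24
    pieces <- lapply(which(hit), function(i) {
      np <- max(1, ceiling(dur[i] / spacing))
      len <- span[i] / np
      s0 <- bouts$start[i] + (seq_len(np) - 1) * (dur[i] / np)
      data.frame(s = s0, e = s0 + len, room = bouts$room[i])
    })
    pieces <- do.call(rbind, pieces)
    s <- pieces$s; e <- pieces$e; room <- pieces$room
    hold <- 0; refr <- 0
  } else {
    offset <- u_offset * (dur - span)
    s <- bouts$start[hit] + offset[hit]
    e <- s + span[hit] + sensors$trigger_hold
    room <- bouts$room[hit]
    hold <- sensors$trigger_hold; refr <- sensors$refractory
  }
  ev <- lapply(rooms, function(r) {
    ri <- room == r
    if (!any(ri)) return(NULL)
    m <- merge_intervals(s[ri], e[ri], gap = max(refr, 1e-6))
    data.frame(timestamp = c(m$start, m$end),
               sensor_id = paste0("pir_", r, "_1"), room = r,
               active = rep(c(TRUE, FALSE), each = nrow(m)))
  })
  out <- do.call(rbind, ev)
  out[order(out$timestamp), , drop = FALSE]
}

# Entrance open/close pairs bracketing every outing, plus occasional
# at-home entrance use and fridge events.
draw_door_events <- function(outings, n_days, behavior) {
  ts <- numeric(0); door <- character(0); state <- character(0)
  if (nrow(outings)) {
    ts <- c(outings$start, outings$start + 6,
            outings$end, outings$end + 6)
    door <- rep("entrance", length(ts))
    state <- rep(c("open", "close"), each = nrow(outings), times = 2)
  }
  # at-home entrance use (mail, visitors at the door): short open/close
  n_err <- rpois(1, 0.3 * n_days)
  if (n_err > 0) {
    es <- round(runif(n_err, 0, n_days * SECONDS_PER_DAY - 60))
    ts <- c(ts, es, es + 25)
    door <- c(door, rep("entrance", 2 * n_err))
    state <- c(state, rep("open", n_err), rep("close", n_err))
  }
  n_fr <- rpois(1, 3 * n_days)
  if (n_fr > 0) {
    fs <- round(runif(n_fr, 0, n_days * SECONDS_PER_DAY - 60))
    ts <- c(ts, fs, fs + 15)
    door <- c(door, rep("fridge", 2 * n_fr))
    state <- c(state, rep("open", n_fr), rep("close", n_fr))
  }
  out <- data.frame(timestamp = ts, door = door, state = state)
  out[order(out$timestamp), , drop = FALSE]
}

#' Cohort heterogeneity specification
#'
#' Spread parameters for [simulate_cohort()]: log-scale sds of
#' per-participant multipliers on sensor gain, bout rate and intensity,
#' and the range of the uniform distribution `tau_true` is drawn from
#' (default 0.9-1.8, matching the spread observed in single-occupant
#' homes of older adults).
#'
#' @param gain_sd,rate_sd,intensity_sd Log-normal sds of per-participant
#'   multipliers (0 disables that source of heterogeneity).
#' @param tau_range Length-2 range for the uniform `tau_true` draw.
#' @export
cohort_heterogeneity <- function(gain_sd = 0.4, rate_sd = 0.2,
                                 intensity_sd = 0.25,
                                 tau_range = c(0.9, 1.8)) {
  stopifnot(gain_sd >= 0, rate_sd >= 0, intensity_sd >= 0,
            length(tau_range) == 2, all(tau_range > 0),
            tau_range[2] >= tau_range[1])
  list(gain_sd = gain_sd, rate_sd = rate_sd, intensity_sd = intensity_sd,
       tau_range = tau_range)
}

#' Simulate a cohort of synthetic homes
#'
#' Draws per-participant apartment responses (sensor gains), behavioural
#' rates and outside/inside ratios from the heterogeneity spec, then runs
#' [simulate_participant()] for each with a derived seed.
#'
#' @param n Number of participants (>= 1).
#' @param behavior Base [behavior_config()] shared by the cohort.
#' @param sensors Base [sensor_response_config()].
#' @param heterogeneity A [cohort_heterogeneity()].
#' @param seed Integer root seed.
#' @inheritParams simulate_participant
#' @return List of `n` lists, each with `dataset` and `truth`.
#' @export
simulate_cohort <- function(n = 20,
                            behavior = behavior_config(),
                            sensors = sensor_response_config(),
                            heterogeneity = cohort_heterogeneity(),
                            seed = 1L,
                            layout = names(default_room_preferences()),
                            timezone = "Europe/Zurich",
                            start_date = "2021-05-01") {
  stopifnot(n >= 1)
  draws <- with_substream(seed, "cohort", {
    data.frame(
      gain_mult = rlnorm(n, -heterogeneity$gain_sd^2 / 2,
                         heterogeneity$gain_sd),
      rate_mult = rlnorm(n, -heterogeneity$rate_sd^2 / 2,
                         heterogeneity$rate_sd),
      intensity_mult = rlnorm(n, -heterogeneity$intensity_sd^2 / 2,
                              heterogeneity$intensity_sd),
      tau = runif(n, heterogeneity$tau_range[1], heterogeneity$tau_range[2])
    )
  })
  lapply(seq_len(n), function(i) {
    b <- behavior
    b$bout_rate <- b$bout_rate * draws$rate_mult[i]
    b$intensity_base <- b$intensity_base * draws$intensity_mult[i]
    b$tau_true <- draws$tau[i]
    b$seed <- substream_seed(seed, paste0("participant_", i))
    s <- sensors
    s$gain <- s$gain * draws$gain_mult[i]
    simulate_participant(b, s, layout = layout,
                         participant_id = sprintf("sim_%02d", i),
                         timezone = timezone, start_date = start_date)
  })
}

#' Simulate clinical assessments linked to true activity
#'
#' Each assessment value is a stated monotone (linear in the standardized
#' score) function of the participant's median daily true activity, plus
#' Gaussian noise. The sign of each link is recorded in the result.
#'
#' @param truths List of `ground_truth` objects (>= 3 participants).
#' @param links Named numeric vector of link signs/slopes per assessment;
#'   defaults to a geriatric battery (negative for impairment scores).
#' @param noise_sd Sd of additive Gaussian noise on the standardized
#'   scale.
#' @param seed Integer seed.
#' @return data.frame with `participant`, `assessment`, `value`, `sign`.
#' @export
simulate_assessments <- function(truths,
                                 links = c(TUG = -1, POMA_b = 1,
                                           POMA_g = 1, GDS = -1, MoCA = 1,
                                           EFS = -1, handgrip = 1,
                                           hip = 1),
                                 noise_sd = 0.3, seed = 1L) {
  if (length(truths) < 3) {
    stop("need at least 3 participants for usable correlations",
         call. = FALSE)
  }
  act <- vapply(truths, function(gt) {
    daily <- colSums(matrix(gt$intensity, nrow = SECONDS_PER_DAY))
    median(daily)
  }, numeric(1))
  z <- as.numeric(scale(act))
  if (all(!is.finite(z))) z <- rep(0, length(act))
  with_substream(seed, "assessments", {
    res <- lapply(names(links), function(a) {
      data.frame(participant = seq_along(truths), assessment = a,
                 value = links[[a]] * z + rnorm(length(z), 0, noise_sd),
                 sign = sign(links[[a]]))
    })
    do.call(rbind, res)
  })
}

#' Daily totals of true activity from a ground-truth object
#'
#' @param truth A `ground_truth` object.
#' @param wear_only If `TRUE`, restrict to the wear window.
#' @return data.frame with `day` (local day index) and `total`.
#' @export
true_daily_totals <- function(truth, wear_only = FALSE) {
  m <- matrix(truth$intensity, nrow = SECONDS_PER_DAY)
  if (wear_only) {
    w <- truth$behavior$wear_window
    sec <- seq_len(SECONDS_PER_DAY) - 1L
    m <- m[sec >= w[1] & sec < w[2], , drop = FALSE]
  }
  data.frame(day = local_day_index(truth$start, truth$timezone) +
               seq_len(ncol(m)) - 1L,
             total = colSums(m))
}
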
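# Out-of-home intervals from entrance-door events, temporal-mean activity
# profiles, outside/inside ratio estimation, and outing imputation.

#' Detect outings from entrance-door events
#'
#' An outing is the interval between an entrance-door event and the next
#' entrance-door event during which no PIR motion occurs in any room.
#' Intervals shorter than `min_duration` minutes are discarded. The
#' entrance stream is cleaned to alternate open/close first; fridge
#' events are ignored.
#'
#' @param ds A [participant_dataset()].
#' @param min_duration Minimum outing duration in minutes (default 5).
#' @return data.frame of half-open intervals `start`/`end` (epoch
#'   seconds), ordered and non-overlapping; empty (with a warning) when
#'   there are no entrance-door events.
#' @export
detect_outings <- function(ds, min_duration = 5) {
  stopifnot(inherits(ds, "participant_dataset"))
  doors <- clean_door_stream(ds$doors)
  ent <- doors$timestamp[doors$door == "entrance"]
  if (length(ent) < 2L) {
    warning("no (or a single) entrance-door event; no outings detectable",
            call. = FALSE)
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  s <- ent[-length(ent)]
  e <- ent[-1L]
  long_enough <- (e - s) >= min_duration * 60
  # number of motion events strictly inside (s, e)
  mt <- sort(ds$motion$timestamp)
  n_inside <- findInterval(e, mt, left.open = TRUE) -
    findInterval(s, mt, left.open = FALSE)
  quiet <- n_inside <= 0
  out <- data.frame(start = s[long_enough & quiet],
                    end = e[long_enough & quiet])
  rownames(out) <- NULL
  out
}

#' Temporal-mean activity profile
#'
#' Bins the clock into `bin_width`-minute intervals and, for each bin,
#' averages the per-second activity over observed days: each day
#' contributes its own per-second mean for the bin, and days where the
#' bin is entirely unobserved (outside the home, or wearable not worn)
#' are excluded from that bin's support. Bins supported by fewer than 3
#' days are flagged.
#'
#' @param timestamps Epoch seconds of the observed (at-home, worn)
#'   samples.
#' @param values Per-second activity at those timestamps.
#' @param timezone IANA timezone for clock binning.
#' @param bin_width Bin width in minutes (default 30).
#' @return A `temporal_profile`: `mean` (per-bin expected activity per
#'   second), `support` (days contributing), `flagged`, `bin_width`.
#' @export
build_profile <- function(timestamps, values, timezone, bin_width = 30) {
  stopifnot(length(timestamps) == length(values), bin_width >= 1)
  day <- local_day_index(timestamps, timezone)
  if (length(unique(day)) < 3L) {
    stop("need at least 3 observed days to build a temporal profile",
         call. = FALSE)
  }
  n_bins <- as.integer(ceiling(1440 / bin_width))
  bin <- as.integer(local_second_of_day(timestamps, timezone) %/%
                      (bin_width * 60)) + 1L
  key <- (day - min(day)) * n_bins + bin
  per_cell <- vapply(split(values, key), mean, numeric(1))
  cell_bin <- as.integer((as.numeric(names(per_cell)) - 1) %% n_bins) + 1L
  means <- rep(NA_real_, n_bins)
  support <- integer(n_bins)
  agg <- split(per_cell, cell_bin)
  for (b in names(agg)) {
    i <- as.integer(b)
    means[i] <- mean(agg[[b]])
    support[i] <- length(agg[[b]])
  }
  structure(list(mean = means, support = support,
                 flagged = support < 3L, bin_width = bin_width,
                 timezone = timezone),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf("<temporal_profile> %d-min bins, %d/%d observed, mean %.3f/s\n",
              x$bin_width, sum(!is.na(x$mean)), length(x$mean),
              mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Restrict an accelerometer stream to at-home samples
#'
#' Drops the samples that fall inside any outing interval, so temporal
#' profiles of at-home activity are not contaminated by outing activity.
#'
#' @param accel data.frame with `timestamp`/`magnitude` columns.
#' @param outings data.frame of outing intervals.
#' @return The filtered accelerometer data.frame.
#' @export
accel_at_home <- function(accel, outings) {
  t <- accel$timestamp
  if (nrow(outings) == 0L) return(accel)
  idx <- findInterval(t, outings$start)
  inside <- idx >= 1L & t < outings$end[pmax(idx, 1L)]
  accel[!inside, , drop = FALSE]
}

# Per-second decomposition of intervals into (local day, clock bin) cells.
interval_cells <- function(start, end, timezone, bin_width) {
  secs <- unlist(mapply(function(s, e) seq(s, e - 1), start, end,
                        SIMPLIFY = FALSE), use.names = FALSE)
  if (!length(secs)) {
    return(data.frame(day = integer(0), bin = integer(0),
                      seconds = integer(0)))
  }
  day <- local_day_index(secs, timezone)
  bin <- as.integer(local_second_of_day(secs, timezone) %/%
                      (bin_width * 60)) + 1L
  agg <- stats::aggregate(list(seconds = rep(1L, length(secs))),
                          list(day = day, bin = bin), sum)
  agg
}

#' Temporal profile of calibrated at-home activity
#'
#' Builds the per-second expectation of calibrated PIR activity by clock
#' bin: for each observed day and bin, the island prediction mass falling
#' in the bin divided by the at-home seconds of the bin (bin seconds
#' minus outing overlap); bin means average these per-day rates over the
#' days where the bin was at least partly at home. Seconds between
#' islands count as zero activity, as the calibrated series is zero
#' there.
#'
#' @param pred Predictions from [predict_calibration()] for `islands`.
#' @param islands The matching `activity_islands` (full span).
#' @param outings data.frame of outing intervals.
#' @param timezone IANA timezone; defaults to the islands' attribute.
#' @param bin_width Bin width in minutes (default 30).
#' @return A `temporal_profile` of calibrated activity per second.
#' @export
build_calibrated_profile <- function(pred, islands, outings,
                                     timezone = NULL, bin_width = 30) {
  timezone <- timezone %||% attr(islands, "timezone")
  n_bins <- as.integer(ceiling(1440 / bin_width))
  days <- seq(min(islands$day), max(islands$day))
  if (length(days) < 3L) {
    stop("need at least 3 observed days to build a temporal profile",
         call. = FALSE)
  }
  # island prediction mass per (day, bin)
  num <- matrix(0, nrow = length(days), ncol = n_bins,
                dimnames = list(days, NULL))
  for (i in seq_len(nrow(islands))) {
    cells <- interval_cells(islands$start[i], islands$end[i], timezone,
                            bin_width)
    rate <- pmax(0, pred$mean[i]) / (islands$end[i] - islands$start[i])
    di <- match(cells$day, days)
    ok <- !is.na(di)
    num[cbind(di[ok], cells$bin[ok])] <-
      num[cbind(di[ok], cells$bin[ok])] + cells$seconds[ok] * rate
  }
  # at-home seconds per (day, bin)
  denom <- matrix(bin_width * 60, nrow = length(days), ncol = n_bins)
  if (nrow(outings)) {
    oc <- interval_cells(outings$start, outings$end, timezone, bin_width)
    di <- match(oc$day, days)
    ok <- !is.na(di)
    denom[cbind(di[ok], oc$bin[ok])] <-
      denom[cbind(di[ok], oc$bin[ok])] - oc$seconds[ok]
  }
  rate <- num / denom
  rate[denom <= 0] <- NA
  means <- colMeans(rate, na.rm = TRUE)
  means[is.nan(means)] <- NA
  support <- colSums(!is.na(rate))
  structure(list(mean = means, support = support,
                 flagged = support < 3L, bin_width = bin_width,
                 timezone = timezone),
            class = "temporal_profile")
}

#' Estimate the outside/inside activity ratio
#'
#' For each outing, divides the wearable activity measured during the
#' outing by the expected at-home activity for the same clock interval
#' (from the temporal profile), both expressed per second so outings of
#' unequal length compare fairly. The per-participant factor `tau_p` is
#' the median of these ratios. Outings with wearable coverage below
#' `min_coverage` or zero expected home activity are excluded and
#' counted.
#'
#' @param ds A [participant_dataset()].
#' @param outings data.frame of outing intervals (see [detect_outings()]).
#' @param profile A `temporal_profile` of at-home wearable activity.
#' @param min_coverage Minimum fraction of outing seconds with a wearable
#'   sample (default 0.8).
#' @return A `tau_estimate`: `tau_p`, `n_outings` (used), `n_excluded`,
#'   and the individual `ratios`.
#' @export
estimate_tau <- function(ds, outings, profile, min_coverage = 0.8) {
  stopifnot(inherits(profile, "temporal_profile"))
  t <- ds$accel$timestamp
  ratios <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(outings))) {
    s <- outings$start[i]; e <- outings$end[i]
    sel <- t >= s & t < e
    n_obs <- sum(sel)
    if (n_obs < min_coverage * (e - s)) {
      n_excluded <- n_excluded + 1L
      next
    }
    accel_rate <- sum(ds$accel$magnitude[sel]) / n_obs
    cells <- interval_cells(s, e, profile$timezone, profile$bin_width)
    w <- cells$seconds
    exp_rate <- sum(profile$mean[cells$bin] * w, na.rm = TRUE) /
      sum(w[!is.na(profile$mean[cells$bin])])
    if (!is.finite(exp_rate) || exp_rate <= 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    ratios <- c(ratios, accel_rate / exp_rate)
  }
  if (!length(ratios)) {
    stop("no eligible outings: tau undefined", call. = FALSE)
  }
  structure(list(tau_p = median(ratios), n_outings = length(ratios),
                 n_excluded = n_excluded, ratios = ratios),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("<tau_estimate> tau_p = %.3f from %d outings (%d excluded)\n",
              x$tau_p, x$n_outings, x$n_excluded))
  invisible(x)
}

#' Global outside/inside factor
#'
#' @param estimates List of `tau_estimate` objects (>= 2 participants).
#' @return Mean of the per-participant `tau_p` values.
#' @export
tau_global <- function(estimates) {
  stopifnot(length(estimates) >= 2L)
  mean(vapply(estimates, function(e) e$tau_p, numeric(1)))
}

#' Impute outing activity into daily totals
#'
#' Daily total calibrated activity = sum of island predictions for the
#' day plus, for each outing second, the temporal-profile expectation of
#' calibrated at-home activity times an imputation factor: 1 for
#' `"plain"` temporal-mean imputation, the person-specific `tau_p`, or
#' the global `tau`. Mode `"none"` adds nothing.
#'
#' @param pred Predictions from [predict_calibration()] for `islands`.
#' @param islands The matching `activity_islands`.
#' @param outings data.frame of outing intervals.
#' @param profile A `temporal_profile` of calibrated at-home activity per
#'   second.
#' @param mode `"none"`, `"plain"`, `"tau_p"` or `"tau_global"`.
#' @param tau Numeric factor, required for the two tau modes.
#' @param timezone IANA timezone for day boundaries.
#' @return data.frame with `day`, `islands_total`, `outing_minutes`,
#'   `imputed_total`, `mode`.
#' @export
impute_daily_totals <- function(pred, islands, outings, profile,
                                mode = c("none", "plain", "tau_p",
                                         "tau_global"),
                                tau = NULL, timezone = NULL) {
  mode <- match.arg(mode)
  timezone <- timezone %||% attr(islands, "timezone")
  factor <- switch(mode, none = 0, plain = 1,
                   tau_p = , tau_global = {
                     if (is.null(tau)) {
                       stop("mode '", mode, "' requires a tau factor",
                            call. = FALSE)
                     }
                     tau
                   })
  base <- stats::aggregate(list(islands_total = pmax(0, pred$mean)),
                           list(day = islands$day), sum)
  add <- data.frame(day = integer(0), outing_seconds = numeric(0),
                    imputed = numeric(0))
  if (nrow(outings)) {
    cells <- interval_cells(outings$start, outings$end, timezone,
                            profile$bin_width)
    cells$imputed <- ifelse(is.na(profile$mean[cells$bin]), 0,
                            profile$mean[cells$bin]) * cells$seconds
    add <- stats::aggregate(cells[c("seconds", "imputed")],
                            list(day = cells$day), sum)
    names(add)[names(add) == "seconds"] <- "outing_seconds"
  }
  out <- merge(base, add, by = "day", all = TRUE)
  out$islands_total[is.na(out$islands_total)] <- 0
  out$outing_seconds[is.na(out$outing_seconds)] <- 0
  out$imputed[is.na(out$imputed)] <- 0
  out$outing_minutes <- out$outing_seconds / 60
  out$imputed_total <- out$islands_total + factor * out$imputed
  out$mode <- mode
  out[c("day", "islands_total", "outing_minutes", "imputed_total",
        "mode")]
}
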
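# Activity-island representation: total PIR signal, 1-min moving-average
# smoothing, island extraction, featurization, column standardization.

#' Per-second total PIR activity signal
#'
#' Sums, for every second of the observation span, the number of PIR
#' sensors currently active. Sensors are active from an `active = TRUE`
#' event until their next `active = FALSE` event (a trailing `TRUE` keeps
#' the sensor active until the end of the span).
#'
#' @param ds A [participant_dataset()].
#' @return A `total_activity_signal`: list with `start` (epoch second of
#'   the first grid cell), `values` (per-second sensor counts), and
#'   `timezone`.
#' @export
total_signal <- function(ds) {
  stopifnot(inherits(ds, "participant_dataset"))
  if (nrow(ds$motion) == 0L) stop("empty motion stream", call. = FALSE)
  span <- dataset_span(ds)
  grid_start <- floor(span[1])
  n <- as.integer(ceiling(span[2]) - grid_start)
  iv <- sensor_intervals(ds$motion, span[2])
  values <- intervals_to_counts(iv$start, iv$end, grid_start, n)
  structure(list(start = grid_start, values = values,
                 timezone = ds$timezone),
            class = "total_activity_signal")
}

#' @export
print.total_activity_signal <- function(x, ...) {
  cat(sprintf("<total_activity_signal> %d s from %s, max %d sensors\n",
              length(x$values), format_iso8601(x$start),
              max(x$values)))
  invisible(x)
}

# Active intervals per sensor from state-change events.
sensor_intervals <- function(motion, span_end) {
  res <- lapply(split(motion, motion$sensor_id), function(ev) {
    s <- e <- numeric(0)
    on <- NA_real_
    for (i in seq_len(nrow(ev))) {
      if (ev$active[i]) {
        if (is.na(on)) on <- ev$timestamp[i]
      } else if (!is.na(on)) {
        s <- c(s, on); e <- c(e, ev$timestamp[i]); on <- NA_real_
      }
    }
    if (!is.na(on)) { s <- c(s, on); e <- c(e, span_end) }
    data.frame(start = s, end = e, room = ev$room[1])
  })
  do.call(rbind, res)
}

# Merged active intervals per room (union over the room's sensors).
room_intervals <- function(ds) {
  span <- dataset_span(ds)
  iv <- sensor_intervals(ds$motion, span[2])
  out <- lapply(ds$rooms, function(r) {
    ri <- iv[iv$room == r, , drop = FALSE]
    merge_intervals(ri$start, ri$end)
  })
  names(out) <- ds$rooms
  out
}

#' Moving-average smoothing of a total activity signal
#'
#' Centered simple moving average; at the edges the window shrinks
#' symmetrically to the available samples, so output length equals input
#' length and a constant signal is left unchanged.
#'
#' @param sig A `total_activity_signal`.
#' @param window Window length in seconds (default 60, i.e. 1 min).
#' @return A `total_activity_signal` with smoothed values.
#' @export
smooth_signal <- function(sig, window = 60) {
  stopifnot(inherits(sig, "total_activity_signal"), window >= 1)
  n <- length(sig$values)
  if (window > n) stop("window longer than signal", call. = FALSE)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  cs <- c(0, cumsum(sig$values))
  i <- seq_len(n)
  lo <- pmax(i - h1, 1L)
  hi <- pmin(i + h2, n)
  sig$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  sig
}

#' Extract activity islands from a smoothed signal
#'
#' Islands are the maximal contiguous stretches where the (smoothed)
#' total PIR signal is strictly positive; their union covers exactly the
#' positive support of the signal.
#'
#' @param sig A `total_activity_signal`, normally after [smooth_signal()].
#' @return data.frame with `start` and `end` epoch seconds, half-open
#'   `[start, end)`, ordered and non-overlapping (empty for an all-zero
#'   signal).
#' @export
extract_islands <- function(sig) {
  stopifnot(inherits(sig, "total_activity_signal"))
  r <- rle(sig$values > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  pos <- r$values
  data.frame(start = sig$start + starts[pos],
             end = sig$start + ends[pos])
}

#' Feature columns of an island table
#' @param rooms Character vector of room labels.
#' @return Character vector of feature column names: total duration, hour
#'   of day, per-room active seconds and per-room relative activity.
#' @export
island_feature_names <- function(rooms) {
  c("duration", "hour", paste0("sec_", rooms), paste0("rel_", rooms))
}

#' Featurize activity islands
#'
#' For each island interval, computes the feature vector — total duration
#' (s), local hour of day at island start, per-room PIR-active seconds,
#' and per-room relative activity (room seconds / island duration) — and
#' attaches the calibration target: the sum of accelerometer magnitudes
#' with timestamps inside the island. The target is set missing when
#' wearable coverage of the island is below `min_coverage`.
#'
#' @param intervals data.frame of island `start`/`end` epoch seconds, from
#'   [extract_islands()].
#' @param ds The [participant_dataset()] the islands came from.
#' @param min_coverage Minimum fraction of island seconds with a wearable
#'   sample for the target to be defined (default 0.8).
#' @return An `activity_islands` data.frame: interval, `day` (local day
#'   index), features, `target`, `wear_coverage`.
#' @export
featurize_islands <- function(intervals, ds, min_coverage = 0.8) {
  stopifnot(inherits(ds, "participant_dataset"))
  if (nrow(intervals) && any(intervals$end <= intervals$start)) {
    stop("zero-duration island", call. = FALSE)
  }
  rooms <- ds$rooms
  tz <- ds$timezone
  dur <- intervals$end - intervals$start
  out <- data.frame(start = intervals$start, end = intervals$end,
                    day = if (nrow(intervals))
                      local_day_index(intervals$start, tz) else integer(0),
                    duration = dur,
                    hour = if (nrow(intervals))
                      local_hour(intervals$start, tz) else integer(0))
  rint <- room_intervals(ds)
  for (r in rooms) {
    sec <- interval_overlap(rint[[r]]$start, rint[[r]]$end,
                            intervals$start, intervals$end)
    out[[paste0("sec_", r)]] <- sec
  }
  for (r in rooms) {
    out[[paste0("rel_", r)]] <- out[[paste0("sec_", r)]] / dur
  }

  # accelerometer sums and wear coverage via grid cumsums
  span <- dataset_span(ds)
  g0 <- floor(span[1])
  n <- as.integer(ceiling(span[2]) - g0)
  mag <- numeric(n); worn <- numeric(n)
  idx <- as.integer(floor(ds$accel$timestamp)) - g0 + 1L
  ok <- idx >= 1L & idx <= n
  mag[idx[ok]] <- ds$accel$magnitude[ok]
  worn[idx[ok]] <- 1
  cmag <- c(0, cumsum(mag)); cworn <- c(0, cumsum(worn))
  i0 <- pmax(1L, as.integer(floor(intervals$start)) - g0 + 1L)
  i1 <- pmin(n + 1L, as.integer(floor(intervals$end)) - g0 + 1L)
  tgt <- cmag[i1] - cmag[i0]
  cov <- (cworn[i1] - cworn[i0]) / dur
  tgt[cov < min_coverage] <- NA_real_
  out$target <- tgt
  out$wear_coverage <- cov
  structure(out, rooms = rooms, timezone = tz,
            class = c("activity_islands", "data.frame"))
}

#' Build islands end-to-end from a dataset
#'
#' Convenience wrapper: total signal, 1-min smoothing, island extraction
#' and featurization.
#'
#' @inheritParams featurize_islands
#' @param window Smoothing window in seconds.
#' @return An `activity_islands` data.frame.
#' @export
build_islands <- function(ds, window = 60, min_coverage = 0.8) {
  sig <- smooth_signal(total_signal(ds), window = window)
  featurize_islands(extract_islands(sig), ds, min_coverage = min_coverage)
}

#' Export an island table to CSV
#'
#' Writes interval bounds (ISO-8601 UTC), the named feature columns,
#' target and wear coverage.
#'
#' @param islands An `activity_islands` data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_islands <- function(islands, path) {
  out <- as.data.frame(islands)
  out$start <- format_iso8601(out$start)
  out$end <- format_iso8601(out$end)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Fit a feature standardizer
#'
#' Learns per-column mean and standard deviation on (calibration) islands
#' so features can be transformed to zero mean and unit variance.
#' Constant columns are dropped with a warning and recorded.
#'
#' @param islands An `activity_islands` data.frame (or any data.frame
#'   containing the feature columns).
#' @param columns Feature columns to standardize; defaults to the island
#'   feature set for the islands' rooms.
#' @return A `feature_standardizer`.
#' @export
fit_standardizer <- function(islands, columns = NULL) {
  columns <- columns %||% island_feature_names(attr(islands, "rooms"))
  X <- as.matrix(as.data.frame(islands)[columns])
  if (nrow(X) < 2L) stop("need at least 2 islands", call. = FALSE)
  mu <- colMeans(X)
  # population standard deviation: the transformed calibration columns
  # have exactly unit (population) variance
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdev > 0
  if (!any(keep)) stop("all feature columns are constant", call. = FALSE)
  if (any(!keep)) {
    warning("dropping constant feature column(s): ",
            paste(columns[!keep], collapse = ", "), call. = FALSE)
  }
  structure(list(columns = columns[keep], mean = mu[keep], sd = sdev[keep],
                 dropped = columns[!keep]),
            class = "feature_standardizer")
}

#' @rdname fit_standardizer
#' @param std A `feature_standardizer` from [fit_standardizer()].
#' @return For `apply_standardizer`, the standardized feature matrix.
#' @export
apply_standardizer <- function(std, islands) {
  stopifnot(inherits(std, "feature_standardizer"))
  X <- as.matrix(as.data.frame(islands)[std$columns])
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}
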
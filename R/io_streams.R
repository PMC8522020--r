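#' Participant dataset container
#'
#' Bundles the sensor streams for one single-occupant home: PIR motion
#' events, entrance/fridge door events, 1 Hz wearable accelerometer
#' samples, and an optional table of clinical assessments. All timestamps
#' are UTC epoch seconds; behavioural clock-time features (hour of day,
#' day boundaries) are computed in the participant's declared IANA
#' timezone.
#'
#' @param participant_id Character scalar identifier.
#' @param timezone IANA timezone name, e.g. `"Europe/Zurich"`.
#' @param rooms Character vector of equipped room labels; must be drawn
#'   from [room_labels()].
#' @param motion data.frame with columns `timestamp` (epoch seconds),
#'   `sensor_id`, `room`, `active` (logical). PIR events are stored as
#'   state changes: a sensor is active from an `active = TRUE` event until
#'   its next `active = FALSE` event.
#' @param doors data.frame with columns `timestamp`, `door`
#'   (`"entrance"`/`"fridge"`), `state` (`"open"`/`"close"`).
#' @param accel data.frame with columns `timestamp`, `magnitude`
#'   (non-negative activity counts). Gaps in the nominal 1 Hz spacing mark
#'   non-wear.
#' @param assessments Optional data.frame with columns `assessment`,
#'   `value` (long format; repeated assessments allowed), or `NULL`.
#'
#' @return An object of class `participant_dataset`.
#' @export
participant_dataset <- function(participant_id, timezone, rooms,
                                motion, doors, accel, assessments = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            timezone %in% OlsonNames())
  bad <- setdiff(rooms, room_labels())
  if (length(bad)) {
    stop("unknown room label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  motion <- validate_motion(motion, rooms)
  doors <- validate_doors(doors)
  accel <- validate_accel(accel)
  if (!is.null(assessments)) {
    stopifnot(all(c("assessment", "value") %in% names(assessments)))
    assessments <- data.frame(assessment = as.character(assessments$assessment),
                              value = as.numeric(assessments$value))
  }
  structure(list(participant_id = participant_id, timezone = timezone,
                 rooms = rooms, motion = motion, doors = doors,
                 accel = accel, assessments = assessments),
            class = "participant_dataset")
}

#' Recognised room labels
#' @return Character vector of valid room labels.
#' @export
room_labels <- function() {
  c("kitchen", "toilet", "living_room", "entrance", "bedroom",
    "bathroom", "other")
}

validate_motion <- function(motion, rooms) {
  need <- c("timestamp", "sensor_id", "room", "active")
  missing_cols <- setdiff(need, names(motion))
  if (length(missing_cols)) {
    stop("motion stream missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(motion$room), rooms)
  if (length(bad)) {
    stop("motion stream references room(s) not in layout: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(timestamp = as.numeric(motion$timestamp),
                    sensor_id = as.character(motion$sensor_id),
                    room = as.character(motion$room),
                    active = as.logical(motion$active))
  out[order(out$timestamp, out$sensor_id, !out$active), , drop = FALSE]
}

validate_doors <- function(doors) {
  need <- c("timestamp", "door", "state")
  missing_cols <- setdiff(need, names(doors))
  if (length(missing_cols)) {
    stop("door stream missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(doors$door %in% c("entrance", "fridge")),
            all(doors$state %in% c("open", "close")))
  out <- data.frame(timestamp = as.numeric(doors$timestamp),
                    door = as.character(doors$door),
                    state = as.character(doors$state))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_accel <- function(accel) {
  need <- c("timestamp", "magnitude")
  missing_cols <- setdiff(need, names(accel))
  if (length(missing_cols)) {
    stop("accelerometer stream missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(accel) == 0L) stop("empty accelerometer stream", call. = FALSE)
  if (any(accel$magnitude < 0)) {
    stop("accelerometer magnitudes must be non-negative", call. = FALSE)
  }
  out <- data.frame(timestamp = as.numeric(accel$timestamp),
                    magnitude = as.numeric(accel$magnitude))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.participant_dataset <- function(x, ...) {
  span <- dataset_span(x)
  cat(sprintf("<participant_dataset> %s (%s)\n", x$participant_id,
              x$timezone))
  cat(sprintf("  rooms:  %s\n", paste(x$rooms, collapse = ", ")))
  cat(sprintf("  motion: %d events | doors: %d events | accel: %d samples\n",
              nrow(x$motion), nrow(x$doors), nrow(x$accel)))
  cat(sprintf("  span:   %s .. %s (%.1f days)\n",
              format_iso8601(span[1]), format_iso8601(span[2]),
              diff(span) / SECONDS_PER_DAY))
  invisible(x)
}

# Observation span [min, max) over all streams.
dataset_span <- function(ds) {
  lo <- min(c(ds$motion$timestamp[1], ds$doors$timestamp[1],
              ds$accel$timestamp[1]), na.rm = TRUE)
  hi <- max(c(ds$motion$timestamp[nrow(ds$motion)],
              if (nrow(ds$doors)) ds$doors$timestamp[nrow(ds$doors)],
              ds$accel$timestamp[nrow(ds$accel)] + 1), na.rm = TRUE)
  c(lo, hi)
}

#' Clean an entrance-door stream to alternate open/close
#'
#' Repeated identical states are dropped, keeping the first occurrence, so
#' that entrance events form well-ordered open/close pairs for outing
#' detection. Fridge events pass through untouched.
#'
#' @param doors data.frame of door events.
#' @return data.frame with the entrance sub-stream alternating.
#' @export
clean_door_stream <- function(doors) {
  ent <- doors[doors$door == "entrance", , drop = FALSE]
  other <- doors[doors$door != "entrance", , drop = FALSE]
  if (nrow(ent) > 1L) {
    keep <- c(TRUE, ent$state[-1L] != ent$state[-nrow(ent)])
    ent <- ent[keep, , drop = FALSE]
  }
  out <- rbind(ent, other)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a participant dataset from CSV files
#'
#' Expects `motion.csv` (`timestamp,sensor_id,room,active`), `doors.csv`
#' (`timestamp,door,state`), `accel.csv` (`timestamp,magnitude`) and
#' optionally `assessments.csv` (`assessment,value`) in `dir`, or a
#' `layout.yaml` in the same directory describing participant id,
#' timezone and rooms (explicit arguments override the layout file).
#' Timestamps may be epoch seconds or ISO-8601 strings. Events are sorted
#' and exact duplicate rows dropped with a warning count.
#'
#' @param dir Directory containing the CSV files.
#' @param layout Optional character vector of room labels.
#' @param timezone Optional IANA timezone name.
#' @param participant_id Optional id; defaults to the layout file's or the
#'   directory name.
#' @return A validated [participant_dataset()].
#' @export
read_participant <- function(dir, layout = NULL, timezone = NULL,
                             participant_id = NULL) {
  layout_path <- file.path(dir, "layout.yaml")
  meta <- if (file.exists(layout_path)) yaml::read_yaml(layout_path) else list()
  layout <- layout %||% unlist(meta$rooms)
  timezone <- timezone %||% meta$timezone
  participant_id <- participant_id %||% meta$participant_id %||% basename(dir)
  if (is.null(layout)) stop("no room layout supplied", call. = FALSE)
  if (is.null(timezone)) stop("no timezone supplied", call. = FALSE)

  motion <- read_stream_csv(file.path(dir, "motion.csv"),
                            c("timestamp", "sensor_id", "room", "active"))
  doors <- read_stream_csv(file.path(dir, "doors.csv"),
                           c("timestamp", "door", "state"))
  accel <- read_stream_csv(file.path(dir, "accel.csv"),
                           c("timestamp", "magnitude"))
  motion$active <- as.logical(as.integer(motion$active))
  apath <- file.path(dir, "assessments.csv")
  assessments <- if (file.exists(apath)) {
    as.data.frame(data.table::fread(apath, colClasses = list(
      character = "assessment", numeric = "value")))
  } else NULL

  participant_dataset(participant_id, timezone, layout,
                      motion, doors, accel, assessments)
}

read_stream_csv <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop(basename(path), " missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(dt)[required]
  n_malformed <- sum(!complete.cases(df))
  if (n_malformed) {
    warning(sprintf("%s: dropped %d malformed row(s)", basename(path),
                    n_malformed), call. = FALSE)
    df <- df[complete.cases(df), , drop = FALSE]
  }
  df$timestamp <- parse_timestamp(df$timestamp)
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("%s: dropped %d duplicate row(s)", basename(path),
                    sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a participant dataset to CSV files
#'
#' Emits the stream CSVs and a `layout.yaml` so that [read_participant()]
#' reproduces the dataset field-for-field (timestamps exact, magnitudes to
#' six decimals). Timestamps are written as ISO-8601 UTC. An assessments
#' file is only written when assessments are present.
#'
#' @param ds A [participant_dataset()].
#' @param dir Output directory (created if necessary).
#' @return Invisibly, the written file paths.
#' @export
write_participant <- function(ds, dir) {
  stopifnot(inherits(ds, "participant_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)

  motion <- ds$motion
  motion$timestamp <- format_iso8601(motion$timestamp)
  motion$active <- as.integer(motion$active)
  doors <- ds$doors
  doors$timestamp <- format_iso8601(doors$timestamp)
  accel <- ds$accel
  accel$timestamp <- format_iso8601(accel$timestamp)
  accel$magnitude <- round(accel$magnitude, 6)

  paths <- c(motion = file.path(dir, "motion.csv"),
             doors = file.path(dir, "doors.csv"),
             accel = file.path(dir, "accel.csv"),
             layout = file.path(dir, "layout.yaml"))
  data.table::fwrite(motion, paths[["motion"]])
  data.table::fwrite(doors, paths[["doors"]])
  data.table::fwrite(accel, paths[["accel"]])
  yaml::write_yaml(list(participant_id = ds$participant_id,
                        timezone = ds$timezone,
                        rooms = as.list(ds$rooms),
                        sensors_per_room = as.list(
                          table(unique(ds$motion[c("sensor_id", "room")])$room)
                        )),
                   paths[["layout"]])
  if (!is.null(ds$assessments) && nrow(ds$assessments)) {
    paths <- c(paths, assessments = file.path(dir, "assessments.csv"))
    data.table::fwrite(ds$assessments, paths[["assessments"]])
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
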
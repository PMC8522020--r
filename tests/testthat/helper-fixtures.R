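# Shared fixtures: all built in code at test time.

TZ <- "Europe/Zurich"

# epoch second of a local clock time on the standard simulation calendar
loc <- function(text) as.numeric(as.POSIXct(text, tz = TZ))

# A small hand-built two-room dataset: one kitchen PIR active 10:00-10:10,
# one living-room PIR active 10:05-10:15, entrance door events, and a
# 1 Hz accel stream 07:00-22:00 on one day with constant magnitude.
tiny_dataset <- function(magnitude = 2, day = "2021-05-01") {
  on1 <- loc(paste(day, "10:00:00")); off1 <- on1 + 600
  on2 <- loc(paste(day, "10:05:00")); off2 <- on2 + 600
  motion <- data.frame(
    timestamp = c(on1, off1, on2, off2),
    sensor_id = c("pir_kitchen_1", "pir_kitchen_1",
                  "pir_living_room_1", "pir_living_room_1"),
    room = c("kitchen", "kitchen", "living_room", "living_room"),
    active = c(TRUE, FALSE, TRUE, FALSE))
  doors <- data.frame(
    timestamp = loc(paste(day, c("09:00:00", "09:00:20"))),
    door = "entrance", state = c("open", "close"))
  t_wear <- seq(loc(paste(day, "07:00:00")),
                loc(paste(day, "22:00:00")) - 1)
  accel <- data.frame(timestamp = t_wear,
                      magnitude = rep(magnitude, length(t_wear)))
  participant_dataset("tiny", TZ, c("kitchen", "living_room"),
                      motion, doors, accel)
}

# Fast small simulation used across tests.
quick_sim <- function(n_days = 10, seed = 1, ...) {
  simulate_participant(behavior_config(n_days = n_days, seed = seed, ...))
}

# Independent island oracle: positive-support scan via index grouping
# (different route from the rle-based implementation).
oracle_islands <- function(values, start) {
  idx <- which(values > 0)
  if (!length(idx)) return(data.frame(start = numeric(0), end = numeric(0)))
  grp <- cumsum(c(1L, as.integer(diff(idx) > 1L)))
  s <- tapply(idx, grp, min)
  e <- tapply(idx, grp, max)
  data.frame(start = start + as.numeric(s) - 1,
             end = start + as.numeric(e))
}

# Dense closed-form GP posterior for the constant + dot-product +
# white-noise kernel (textbook conditional-Gaussian formulas).
oracle_gp_posterior <- function(X, y, Xs, s0, sn) {
  n <- nrow(X)
  K <- s0 + X %*% t(X) + diag(sn, n)
  ks <- s0 + Xs %*% t(X)
  Kinv <- solve(K)
  mu <- as.numeric(ks %*% Kinv %*% y)
  kss <- s0 + rowSums(Xs^2) + sn
  vv <- kss - rowSums((ks %*% Kinv) * ks)
  list(mean = mu, sd = sqrt(pmax(vv, 0)))
}

# Standardized islands + exactly linear targets, for calibration oracles.
linear_island_fixture <- function(n = 40, p = 4, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  w <- seq_len(p)
  y <- as.numeric(X %*% w) + rnorm(n, 0, noise)
  list(X = X, y = y, w = w)
}

# Wrap a plain feature matrix + target as an activity_islands table so
# fit_calibration can consume it.
islands_from_matrix <- function(X, y, day = NULL) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$target <- y
  df$day <- day %||% rep(seq_len(max(1, nrow(df) %/% 5)),
                         length.out = nrow(df))
  df$start <- seq_len(nrow(df)) * 1000
  df$end <- df$start + 500
  df$duration <- 500
  structure(df, rooms = character(0), timezone = TZ,
            class = c("activity_islands", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

matrix_feature_cols <- function(X) paste0("f", seq_len(ncol(X)))

# Random evaluation fixture: islands with exponential targets spread over
# days (balanced = equal islands per day, for exact identities on daily
# sums).
make_eval_fixture <- function(n = 60, days = 12, seed = 2,
                              balanced = FALSE) {
  set.seed(seed)
  day <- if (balanced) rep(seq_len(days), each = n %/% days)[seq_len(n)]
  else sort(sample(seq_len(days), n, replace = TRUE))
  islands_from_matrix(matrix(rnorm(n * 2), n), y = rexp(n, 1 / 500),
                      day = day)
}
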
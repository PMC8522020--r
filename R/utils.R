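# Internal helpers: time arithmetic, interval algebra, seeded substreams.

#' @importFrom stats coef cor lm median optim quantile rnorm rpois runif sd
#'   var wilcox.test rlnorm rexp predict setNames complete.cases
#' @importFrom utils head tail
NULL

SECONDS_PER_DAY <- 86400L

# UTC offset (seconds) of timezone `tz` at each epoch time in `t`.
# Offsets only change on (at most) hour boundaries, so we evaluate the
# offset once per distinct hour and look it up; cheap even for multi-
# million-second grids.
utc_offset <- function(t, tz) {
  hours <- unique(as.numeric(t) %/% 3600)
  anchor <- hours * 3600
  lt <- as.POSIXlt(.POSIXct(anchor, tz = "UTC"), tz = tz)
  off <- lt$hour * 3600 + lt$min * 60 + lt$sec - (anchor %% SECONDS_PER_DAY)
  off <- ((off + SECONDS_PER_DAY / 2) %% SECONDS_PER_DAY) - SECONDS_PER_DAY / 2
  off[match(as.numeric(t) %/% 3600, hours)]
}

# Local clock seconds since local midnight for each epoch second.
local_second_of_day <- function(t, tz) {
  (as.numeric(t) + utc_offset(t, tz)) %% SECONDS_PER_DAY
}

# Integer local day index (days since 1970-01-01 in local clock time).
local_day_index <- function(t, tz) {
  (as.numeric(t) + utc_offset(t, tz)) %/% SECONDS_PER_DAY
}

# Integer local hour of day.
local_hour <- function(t, tz) {
  as.integer(local_second_of_day(t, tz) %/% 3600)
}

# Epoch seconds from an ISO-8601-ish local datetime string.
epoch_from_local <- function(x, tz) {
  as.numeric(as.POSIXct(x, tz = tz))
}

format_iso8601 <- function(t) {
  format(.POSIXct(as.numeric(t), tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

# Parse timestamps that may be epoch seconds or ISO-8601 strings (UTC).
parse_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS"))
  as.numeric(t)
}

# ---- interval algebra -------------------------------------------------

# Merge possibly-overlapping half-open intervals [start, end); `gap` merges
# intervals separated by less than `gap` seconds.
merge_intervals <- function(start, end, gap = 0) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- numeric(length(start)); me <- numeric(length(start))
  k <- 1L; ms[1] <- start[1]; me[1] <- end[1]
  if (length(start) > 1L) {
    for (i in 2L:length(start)) {
      if (start[i] <= me[k] + gap) {
        me[k] <- max(me[k], end[i])
      } else {
        k <- k + 1L; ms[k] <- start[i]; me[k] <- end[i]
      }
    }
  }
  data.frame(start = ms[seq_len(k)], end = me[seq_len(k)])
}

# Total overlap (seconds) between each query interval [qs, qe) and a set of
# disjoint sorted intervals [s, e). Vectorised over queries.
interval_overlap <- function(s, e, qs, qe) {
  if (length(s) == 0L || length(qs) == 0L) return(numeric(length(qs)))
  cum <- c(0, cumsum(e - s))
  # index of last interval starting at or before the query point
  lo <- findInterval(qs, s)
  hi <- findInterval(qe, s)
  full <- cum[pmax(hi, 1L)] - cum[pmin(lo + 1L, length(cum))]
  full[hi < lo + 1L] <- 0
  # partial coverage at the query edges
  left <- ifelse(lo >= 1L, pmax(0, pmin(e[pmax(lo, 1L)], qe) - pmax(s[pmax(lo, 1L)], qs)), 0)
  right <- ifelse(hi >= 1L & hi > lo,
                  pmax(0, pmin(e[pmax(hi, 1L)], qe) - pmax(s[pmax(hi, 1L)], qs)), 0)
  full + left + right
}

# Logical mask over a 1 s grid starting at `grid_start`, length `n`,
# marking seconds covered by intervals [s, e).
intervals_to_mask <- function(s, e, grid_start, n) {
  mask <- logical(n)
  if (length(s) == 0L) return(mask)
  i0 <- pmax(1L, as.integer(floor(s - grid_start)) + 1L)
  i1 <- pmin(n, as.integer(ceiling(e - grid_start)))
  keep <- i0 <= i1
  for (j in which(keep)) mask[i0[j]:i1[j]] <- TRUE
  mask
}

# Per-second coverage count over a grid via +1/-1 deltas and cumsum.
# Instant semantics: grid second t is covered by [s, e) iff s <= t < e.
intervals_to_counts <- function(s, e, grid_start, n) {
  delta <- numeric(n + 1L)
  if (length(s)) {
    i0 <- pmax(1L, pmin(n + 1L, as.integer(ceiling(s - grid_start)) + 1L))
    i1 <- pmax(1L, pmin(n + 1L, as.integer(ceiling(e - grid_start)) + 1L))
    for (j in seq_along(i0)) {
      delta[i0[j]] <- delta[i0[j]] + 1
      delta[i1[j]] <- delta[i1[j]] - 1
    }
  }
  cumsum(delta)[seq_len(n)]
}

# ---- seeded substreams ------------------------------------------------

# Derive a reproducible 31-bit seed for a named substream of a root seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435761 + h * 97) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
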
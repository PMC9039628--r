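# Commuting and roost metrics: day/night classification of fixes by local
# clock time, distances to the nest, and the evening roost-entry tally.

#' Classify a timestamp as day or night
#'
#' @param timestamp POSIXct (or ISO-8601 string) timestamps; only the local
#'   clock time is used.
#' @param day_window `c(start, end)` in `"HH:MM"`; the day period is the
#'   half-open interval `[start, end)`.
#' @return Character vector `"day"`/`"night"`.
#' @export
classify_period <- function(timestamp, day_window = c("06:00", "18:00")) {
  ts <- if (inherits(timestamp, "POSIXt")) {
    as.POSIXct(timestamp, tz = "UTC")
  } else {
    as.POSIXct(timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  }
  hm <- function(s) {
    parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    parts[1] + parts[2] / 60
  }
  start <- hm(day_window[1])
  end <- hm(day_window[2])
  if (end <= start) stop("day window end must be after start")
  lt <- as.POSIXlt(ts)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  ifelse(hour >= start & hour < end, "day", "night")
}

#' Day/night commute summary for one bird
#'
#' Mean Euclidean distances from the nest per period, the overall mean, and
#' the night/day ratio (how much farther the bird commutes to its roost than
#' it ranges during the day).
#'
#' @param fixes Data frame with columns `x`, `y` and either `period`
#'   (`"day"`/`"night"`) or `timestamp` (classified via [classify_period()]).
#' @param nest Nest position `c(x, y)`.
#' @param day_window Passed to [classify_period()] when needed.
#' @return List with `mean_day_m`, `mean_night_m`, `mean_all_m`, `ratio`
#'   (NA when undefined), and per-period fix counts.
#' @export
commute_summary <- function(fixes, nest, day_window = c("06:00", "18:00")) {
  if (is.null(nest) || length(nest) != 2 || anyNA(nest)) {
    stop("a nest position is required")
  }
  period <- if ("period" %in% names(fixes)) {
    fixes$period
  } else if ("timestamp" %in% names(fixes)) {
    classify_period(fixes$timestamp, day_window)
  } else {
    stop("fixes need a 'period' or 'timestamp' column")
  }
  d <- sqrt((fixes$x - nest[1])^2 + (fixes$y - nest[2])^2)
  day <- d[period == "day"]
  night <- d[period == "night"]
  mean_day <- if (length(day)) mean(day) else NA_real_
  mean_night <- if (length(night)) mean(night) else NA_real_
  ratio <- if (length(day) && length(night) && mean_day > 0) {
    mean_night / mean_day
  } else {
    NA_real_
  }
  list(
    mean_day_m = mean_day, mean_night_m = mean_night,
    mean_all_m = mean(d), ratio = ratio,
    n_day = length(day), n_night = length(night)
  )
}

#' Net count of birds using a communal roost
#'
#' Evening tally: groups counted entering minus groups counted leaving.
#'
#' @param entries,exits Non-negative integer vectors of group counts.
#' @return Net number of birds in the roost.
#' @export
roost_tally <- function(entries, exits = integer(0)) {
  if (any(entries < 0) || any(exits < 0)) stop("group counts must be non-negative")
  net <- sum(entries) - sum(exits)
  if (net < 0) stop("more birds counted leaving than entering: data error")
  net
}
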
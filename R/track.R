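# Ground-truth movement simulation: diurnal activity as an isotropic
# bivariate-normal point cloud around the nest (rejection-resampled onto
# land), and one nocturnal fix per night at the communal roost (or at the
# nest for incubating birds). The downstream analyses use only the marginal
# point cloud, so no temporal autocorrelation is modelled.

#' Configuration of one bird's ground-truth track
#'
#' @param nest,roost Points `c(x, y)` in metres; both must lie on land.
#' @param day_dispersion_m Isotropic sd (metres) of diurnal positions around
#'   the nest; `>= 0` (0 collapses all day fixes onto the nest).
#' @param n_days Number of tracking days, `>= 1`.
#' @param fixes_per_day Diurnal fixes per day, spread over the 06:00-11:00
#'   morning session.
#' @param night_at_roost If `TRUE` the bird commutes to the communal roost at
#'   night; if `FALSE` (incubating females) night fixes stay at the nest.
#' @param start_date First tracking date, `"YYYY-MM-DD"`.
#' @return A `track_config` list.
#' @export
track_config <- function(nest, roost, day_dispersion_m = 55, n_days = 12,
                         fixes_per_day = 2, night_at_roost = TRUE,
                         start_date = "2019-02-26") {
  stopifnot(length(nest) == 2, length(roost) == 2)
  if (day_dispersion_m < 0) stop("day_dispersion_m must be >= 0")
  if (n_days < 1) stop("n_days must be >= 1")
  if (fixes_per_day < 1) stop("fixes_per_day must be >= 1")
  structure(
    list(
      nest = as.numeric(nest), roost = as.numeric(roost),
      day_dispersion_m = day_dispersion_m, n_days = as.integer(n_days),
      fixes_per_day = as.integer(fixes_per_day),
      night_at_roost = isTRUE(night_at_roost), start_date = start_date
    ),
    class = "track_config"
  )
}

#' Simulate a ground-truth track
#'
#' @param config A [track_config()].
#' @param landscape A `habitat_map`; positions are constrained to its land
#'   polygon.
#' @param seed Integer seed.
#' @param individual_id Identifier carried into the output.
#' @return A `synthetic_truth` object: data frame `positions` with columns
#'   `fix_id`, `timestamp` (POSIXct, local clock time), `x`, `y`, `activity`
#'   (`"day"` or `"roost"`), plus `nest`, `roost`, and the config.
#' @export
simulate_track <- function(config, landscape, seed = 1L, individual_id = "bird1") {
  stopifnot(inherits(config, "track_config"), inherits(landscape, "habitat_map"))
  land <- landscape$land
  for (what in c("nest", "roost")) {
    p <- config[[what]]
    if (!points_in_polygon(p[1], p[2], land)) {
      stop(sprintf("%s position is not on land", what))
    }
  }
  set.seed(as.integer(seed))
  day0 <- as.POSIXct(paste0(config$start_date, " 00:00:00"), tz = "UTC")
  n_day_fix <- config$n_days * config$fixes_per_day
  # morning session 06:00-11:00, fixes at mid-slot times
  slot_h <- 6 + (seq_len(config$fixes_per_day) - 0.5) * 5 / config$fixes_per_day

  rows <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    base <- day0 + (d - 1) * 86400
    night_pos <- if (config$night_at_roost) config$roost else config$nest
    day_pts <- draw_on_land(
      config$fixes_per_day, config$nest, config$day_dispersion_m, land
    )
    rows[[d]] <- data.frame(
      timestamp = c(base + 5.5 * 3600, base + slot_h * 3600),
      x = c(night_pos[1], day_pts[, 1]),
      y = c(night_pos[2], day_pts[, 2]),
      activity = c("roost", rep("day", config$fixes_per_day)),
      stringsAsFactors = FALSE
    )
  }
  pos <- do.call(rbind, rows)
  pos <- cbind(
    fix_id = sprintf("%s_f%03d", individual_id, seq_len(nrow(pos))),
    pos,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      individual_id = individual_id, positions = pos,
      nest = config$nest, roost = config$roost, config = config
    ),
    class = "synthetic_truth"
  )
}

draw_on_land <- function(n, centre, sd_m, land) {
  if (sd_m == 0) {
    return(matrix(rep(centre, each = n), ncol = 2))
  }
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  fails <- 0L
  while (got < n) {
    x <- centre[1] + stats::rnorm(1, 0, sd_m)
    y <- centre[2] + stats::rnorm(1, 0, sd_m)
    if (points_in_polygon(x, y, land)) {
      got <- got + 1L
      out[got, ] <- c(x, y)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= 1000L) {
        stop("rejection sampling failed 1000 consecutive times: ",
             "centre too close to the ocean for the requested dispersion")
      }
    }
  }
  out
}

#' Simulate noisy bearings towards a ground-truth track
#'
#' For each true position, the nearest `n_bearings_per_fix` stations within
#' detection range record an azimuth equal to the true azimuth plus a von
#' Mises error of concentration `kappa`. Positions seen by fewer than two
#' in-range stations are skipped and reported via the `"skipped_fix_ids"`
#' attribute.
#'
#' @param truth A `synthetic_truth` from [simulate_track()].
#' @param stations `m x 2` matrix of observer positions.
#' @param kappa von Mises concentration of the bearing error (`> 0`).
#' @param max_dist_m Detection range of the receiver, metres.
#' @param n_bearings_per_fix Stations used per fix (at least 2 are required
#'   to triangulate).
#' @param seed Integer seed.
#' @return Data frame of bearing observations with columns `individual_id`,
#'   `fix_id`, `timestamp`, `observer_x`, `observer_y`, `azimuth_deg`,
#'   `max_dist_m`.
#' @export
simulate_bearings <- function(truth, stations, kappa = 60, max_dist_m = 600,
                              n_bearings_per_fix = 3, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), kappa > 0,
            is.matrix(stations), nrow(stations) >= 1)
  set.seed(as.integer(seed))
  pos <- truth$positions
  out <- vector("list", nrow(pos))
  skipped <- character(0)
  for (i in seq_len(nrow(pos))) {
    p <- c(pos$x[i], pos$y[i])
    d <- sqrt((stations[, 1] - p[1])^2 + (stations[, 2] - p[2])^2)
    in_range <- which(d <= max_dist_m & d > 0)
    if (length(in_range) < 2) {
      skipped <- c(skipped, pos$fix_id[i])
      next
    }
    use <- in_range[order(d[in_range])][seq_len(min(n_bearings_per_fix, length(in_range)))]
    true_az <- azimuth(stations[use, , drop = FALSE],
                       matrix(p, length(use), 2, byrow = TRUE))
    err_deg <- rvonmises(length(use), 0, kappa) * 180 / pi
    out[[i]] <- data.frame(
      individual_id = truth$individual_id,
      fix_id = pos$fix_id[i],
      timestamp = rep(pos$timestamp[i], length(use)),
      observer_x = stations[use, 1],
      observer_y = stations[use, 2],
      azimuth_deg = (true_az + err_deg) %% 360,
      max_dist_m = max_dist_m,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) {
    stop("no station within detection range for any fix")
  }
  rownames(res) <- NULL
  attr(res, "skipped_fix_ids") <- skipped
  res
}

#' Default synthetic tracking study
#'
#' Builds the default coastal landscape, a communal roost near the coast,
#' nests in the dry forest about `nest_roost_distance_m` from the roost,
#' road/path observer stations, ground-truth tracks for `n_individuals`
#' birds, and noisy bearing sets.
#'
#' @param seed Integer master seed; per-bird seeds are derived from it.
#' @param n_individuals Number of tracked birds.
#' @param kappa True bearing-error concentration.
#' @param day_dispersion_m Diurnal dispersion sd around the nest, metres.
#' @param nest_roost_distance_m Distance from each nest to the communal
#'   roost, metres.
#' @param n_days,fixes_per_day Passed to [track_config()].
#' @param n_bearings_per_fix Passed to [simulate_bearings()].
#' @param max_dist_m Detection range, metres.
#' @param night_at_roost Logical, recycled over birds.
#' @return List with `landscape`, `stations`, `truths` (list of
#'   `synthetic_truth`), `bearings` (one data frame, all birds), and
#'   `true_kappa`.
#' @export
synthetic_scenario <- function(seed = 1L, n_individuals = 5, kappa = 60,
                               day_dispersion_m = 55,
                               nest_roost_distance_m = 250,
                               n_days = 12, fixes_per_day = 2,
                               n_bearings_per_fix = 3, max_dist_m = 600,
                               night_at_roost = TRUE) {
  map <- generate_landscape(landscape_config(seed = seed))
  stations <- make_stations(map)
  ext <- map$extent
  # roost in the coastal forest band, on the landscape midline
  roost <- c((ext[1] + ext[2]) / 2, ext[3] + 0.375 * (ext[4] - ext[3]))
  angles <- seq(-24, 24, length.out = n_individuals) * pi / 180
  night_at_roost <- rep_len(night_at_roost, n_individuals)
  truths <- vector("list", n_individuals)
  bearings <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    nest <- roost + nest_roost_distance_m * c(sin(angles[i]), cos(angles[i]))
    cfg <- track_config(
      nest = nest, roost = roost, day_dispersion_m = day_dispersion_m,
      n_days = n_days, fixes_per_day = fixes_per_day,
      night_at_roost = night_at_roost[i]
    )
    id <- sprintf("bird%d", i)
    truths[[i]] <- simulate_track(cfg, map, seed = seed + 100L * i, individual_id = id)
    bearings[[i]] <- simulate_bearings(
      truths[[i]], stations,
      kappa = kappa, max_dist_m = max_dist_m,
      n_bearings_per_fix = n_bearings_per_fix, seed = seed + 100L * i + 50L
    )
  }
  names(truths) <- vapply(truths, `[[`, character(1), "individual_id")
  structure(
    list(
      landscape = map, stations = stations, truths = truths,
      bearings = do.call(rbind, bearings), true_kappa = kappa,
      seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}
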
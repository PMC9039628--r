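# Shared fixtures: published field-study tables (read from extdata) and a
# compact bearing-replicate generator for sampler calibration tests.

published_selection <- function() {
  utils::read.csv(
    system.file("extdata", "finch_selection_published.csv", package = "finchtrack"),
    stringsAsFactors = FALSE
  )
}

published_selection_totals <- function() {
  utils::read.csv(
    system.file("extdata", "finch_selection_published_totals.csv", package = "finchtrack"),
    stringsAsFactors = FALSE
  )
}

published_tracking <- function() {
  utils::read.csv(
    system.file("extdata", "finch_tracking_published.csv", package = "finchtrack"),
    stringsAsFactors = FALSE
  )
}

# One synthetic bearing replicate: n_fix true positions in a 300 m box
# observed from a ring of stations, 3 bearings per fix.
make_atm_replicate <- function(seed, kappa = 20, n_fix = 30, n_bearings = 3) {
  set.seed(seed)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  stations <- cbind(350 * cos(ang), 350 * sin(ang))
  truth <- cbind(runif(n_fix, -150, 150), runif(n_fix, -150, 150))
  rows <- vector("list", n_fix)
  for (i in seq_len(n_fix)) {
    d <- sqrt((stations[, 1] - truth[i, 1])^2 + (stations[, 2] - truth[i, 2])^2)
    use <- order(d)[seq_len(n_bearings)]
    az <- azimuth(stations[use, , drop = FALSE],
                  matrix(truth[i, ], n_bearings, 2, byrow = TRUE))
    err <- rvonmises(n_bearings, 0, kappa) * 180 / pi
    rows[[i]] <- data.frame(
      fix_id = sprintf("f%02d", i),
      observer_x = stations[use, 1], observer_y = stations[use, 2],
      azimuth_deg = (az + err) %% 360, max_dist_m = 600
    )
  }
  list(
    bearings = do.call(rbind, rows),
    truth = data.frame(fix_id = sprintf("f%02d", seq_len(n_fix)),
                       x = truth[, 1], y = truth[, 2])
  )
}

# home_range wrapper around explicit polygons, for constructed-geometry tests
hr_from_polygons <- function(polys, method = "mcp", level = 100, id = "x") {
  if (is.matrix(polys)) polys <- list(polys)
  structure(
    list(individual_id = id, method = method, level = level,
         polygons = polys, area_ha = polygon_area(polys) / 1e4),
    class = "home_range"
  )
}

rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
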
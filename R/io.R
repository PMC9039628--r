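# Readers and writers for the package's plain-text interchange formats:
# bearing and fix CSVs, GeoJSON habitat/land/home-range polygons, and the
# JSON pipeline report. Coordinates are planar metres throughout; a CRS
# string is carried as opaque metadata (no geodesy, no reprojection).

#' Read bearing observations from CSV
#'
#' @param path CSV with columns `individual_id`, `fix_id`, `timestamp`,
#'   `observer_x`, `observer_y`, `azimuth_deg`, `max_dist_m`.
#' @return Validated data frame; azimuths wrapped to `[0, 360)`, timestamps
#'   parsed as POSIXct.
#' @export
read_bearings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "fix_id", "timestamp", "observer_x", "observer_y",
           "azimuth_deg", "max_dist_m")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("bearing file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("observer_x", "observer_y", "azimuth_deg", "max_dist_m")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at data line(s) %s of %s",
                   col, paste(bad, collapse = ", "), path))
    }
    df[[col]] <- v
  }
  if (any(is.na(df$max_dist_m)) || any(df$max_dist_m <= 0)) {
    stop("max_dist_m must be positive for every bearing")
  }
  df$azimuth_deg <- df$azimuth_deg %% 360
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  df
}

#' Write bearing observations to CSV
#' @param bearings Data frame from [simulate_bearings()] or [read_bearings()].
#' @param path Output path.
#' @export
write_bearings <- function(bearings, path) {
  out <- bearings
  out$timestamp <- format(as.POSIXct(out$timestamp, tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

geojson_ring <- function(poly) {
  poly <- ensure_ccw(poly)
  ring <- rbind(poly, poly[1, ])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

geojson_feature <- function(mp, properties) {
  mp <- as_multipolygon(mp)
  list(
    type = "Feature",
    properties = properties,
    geometry = list(
      type = "MultiPolygon",
      coordinates = lapply(mp, function(p) list(geojson_ring(p)))
    )
  )
}

write_geojson <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write a habitat map to GeoJSON
#'
#' One MultiPolygon feature per habitat (property `habitat`), plus features
#' for the land mask and the ocean (property `role`).
#'
#' @param map A `habitat_map`.
#' @param path Output `.geojson` path.
#' @export
write_habitats <- function(map, path) {
  stopifnot(inherits(map, "habitat_map"))
  feats <- lapply(map$habitat_order, function(nm) {
    geojson_feature(map$habitats[[nm]], list(habitat = nm))
  })
  feats <- c(feats, list(
    geojson_feature(map$land, list(role = "land")),
    geojson_feature(map$ocean, list(role = "ocean"))
  ))
  write_geojson(feats, path)
}

parse_geojson_multipolygon <- function(geom) {
  if (geom$type == "Polygon") {
    coords <- list(geom$coordinates)
  } else if (geom$type == "MultiPolygon") {
    coords <- geom$coordinates
  } else {
    stop("unsupported geometry type: ", geom$type)
  }
  lapply(coords, function(poly) {
    ring <- poly[[1]]  # exterior ring; holes are not supported
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    p <- drop_closing_vertex(m)
    if (nrow(p) < 3 || polygon_area(p) <= 0) stop("invalid polygon ring")
    ensure_ccw(p)
  })
}

#' Read a habitat map from GeoJSON
#'
#' Features with a `habitat` property become habitat polygons (canonical
#' order = feature order); a feature with `role = "land"` becomes the land
#' mask (defaults to the union bounding box when absent). Habitats
#' overlapping by more than 0.1% of the smaller one's area are rejected.
#'
#' @param path GeoJSON file.
#' @return A `habitat_map`.
#' @export
read_habitats <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  if (!is.null(gj$crs)) {
    name <- gj$crs$properties$name
    allowed <- c("urn:ogc:def:crs:OGC:1.3:CRS84", "local-metres")
    if (is.null(name) || !(name %in% allowed)) {
      stop("unknown CRS declaration in ", path)
    }
  }
  habitats <- list()
  land <- NULL
  ocean <- NULL
  for (feat in gj$features) {
    mp <- parse_geojson_multipolygon(feat$geometry)
    hab <- feat$properties$habitat
    role <- feat$properties$role
    if (!is.null(hab)) {
      habitats[[hab]] <- mp
    } else if (identical(role, "land")) {
      land <- mp[[1]]
    } else if (identical(role, "ocean")) {
      ocean <- mp[[1]]
    }
  }
  if (!length(habitats)) stop("no features with a 'habitat' property in ", path)
  nms <- names(habitats)
  for (i in seq_along(habitats)) {
    for (j in seq_len(i - 1L)) {
      ov <- intersection_area(habitats[[i]], habitats[[j]])
      smaller <- min(polygon_area(habitats[[i]]), polygon_area(habitats[[j]]))
      if (ov > 0.001 * smaller) {
        stop(sprintf("habitats '%s' and '%s' overlap by %.1f%% of the smaller one",
                     nms[i], nms[j], 100 * ov / smaller))
      }
    }
  }
  all_pts <- do.call(rbind, unlist(habitats, recursive = FALSE))
  ext <- c(range(all_pts[, 1]), range(all_pts[, 2]))
  if (is.null(land)) {
    land <- rect_poly(ext[1], ext[2], ext[3], ext[4])
  }
  structure(
    list(
      habitats = habitats, land = land, ocean = ocean,
      extent = ext, habitat_order = nms, crs = "local-metres",
      config = NULL
    ),
    class = "habitat_map"
  )
}

#' Write home ranges to GeoJSON
#'
#' @param ranges A `home_range` or list of them.
#' @param path Output path. Each range becomes one MultiPolygon feature with
#'   properties `individual_id`, `method`, `level`, `area_ha`.
#' @export
write_home_ranges <- function(ranges, path) {
  if (inherits(ranges, "home_range")) ranges <- list(ranges)
  feats <- lapply(ranges, function(r) {
    geojson_feature(r$polygons, list(
      individual_id = r$individual_id, method = r$method,
      level = r$level, area_ha = round(r$area_ha, 2)
    ))
  })
  write_geojson(feats, path)
}

#' End-to-end pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param scenario Arguments forwarded to [synthetic_scenario()] (list), or
#'   `NULL` for defaults.
#' @param atm Arguments forwarded to [atm_config()] (list); `n_iter`/`n_burn`
#'   default to 50,000 with 5,000 burn-in.
#' @param cell_size_m,kernel_levels Home-range grid settings.
#' @param alpha Family-wise error rate for selection tables.
#' @param day_window Day period for commute metrics.
#' @param min_angle_deg Inter-bearing angle filter threshold.
#' @param output_dir Directory for the report and GeoJSON/CSV outputs, or
#'   `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, scenario = list(), atm = list(),
                            cell_size_m = 5, kernel_levels = c(95, 50),
                            alpha = 0.05, day_window = c("06:00", "18:00"),
                            min_angle_deg = 10, output_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed), scenario = scenario, atm = atm,
      cell_size_m = cell_size_m, kernel_levels = kernel_levels,
      alpha = alpha, day_window = day_window,
      min_angle_deg = min_angle_deg, output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-to-selection pipeline
#'
#' Simulate a tracking study, fit the azimuthal telemetry model per bird,
#' filter fixes, estimate kernel and MCP home ranges, build habitat-selection
#' tables, and summarize commuting. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A report list (also written as JSON when `output_dir` is set):
#'   per-bird fix accounting, kappa summaries, home-range areas (ha),
#'   selection tables, commute metrics, and a reproducibility manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  atm_args <- config$atm
  if (!is.null(atm_args$n_iter) && !is.null(atm_args$n_burn) &&
      atm_args$n_iter <= atm_args$n_burn) {
    stop("pipeline configuration error: n_iter must exceed n_burn")
  }
  scen <- do.call(synthetic_scenario, c(list(seed = config$seed), config$scenario))
  map <- scen$landscape
  birds <- names(scen$truths)
  report <- list(
    manifest = list(
      package = "finchtrack",
      version = as.character(utils::packageVersion("finchtrack")),
      seed = config$seed,
      parameters = list(
        atm = config$atm, scenario = config$scenario,
        cell_size_m = config$cell_size_m, alpha = config$alpha,
        kernel_levels = config$kernel_levels,
        min_angle_deg = config$min_angle_deg
      )
    ),
    birds = list()
  )
  areas95 <- areas50 <- areas_mcp <- ratios <- numeric(0)
  ranges <- list()
  for (b in birds) {
    truth <- scen$truths[[b]]
    brg <- scen$bearings[scen$bearings$individual_id == b, , drop = FALSE]
    cfg <- do.call(atm_config, c(
      list(seed = config$seed + match(b, birds)), config$atm
    ))
    post <- atm_fit(brg, cfg)
    est <- point_estimates(post)
    flt <- filter_fixes(est, map$land, config$min_angle_deg)
    fixes <- flt$retained
    ts <- truth$positions$timestamp[match(fixes$fix_id, truth$positions$fix_id)]
    pts <- cbind(fixes$x, fixes$y)
    h <- href_bandwidth(pts)
    ud <- kernel_ud(pts, h, cell_size_m = config$cell_size_m)
    hr <- lapply(config$kernel_levels, function(lv) {
      isopleth(ud, lv, land = map$land, individual_id = b)
    })
    names(hr) <- paste0("kernel", config$kernel_levels)
    hr$mcp <- mcp(pts, individual_id = b)
    sel <- selection_table(hr[[1]], map, fixes, alpha = config$alpha)
    com <- commute_summary(
      data.frame(x = fixes$x, y = fixes$y, timestamp = ts),
      truth$nest, config$day_window
    )
    rel <- relocation_error(
      fixes,
      stats::setNames(truth$positions[, c("fix_id", "x", "y")],
                      c("fix_id", "x", "y"))
    )
    areas95 <- c(areas95, hr[[1]]$area_ha)
    areas50 <- c(areas50, if (length(hr) > 2) hr[[2]]$area_ha else NA)
    areas_mcp <- c(areas_mcp, hr$mcp$area_ha)
    ratios <- c(ratios, com$ratio)
    ranges <- c(ranges, hr)
    report$birds[[b]] <- list(
      n_fixes_raw = nrow(est),
      n_fixes_retained = nrow(fixes),
      removal_fraction = flt$removal_fraction,
      kappa = list(
        median = stats::median(post$kappa),
        ci95 = as.numeric(stats::quantile(post$kappa, c(0.025, 0.975))),
        ess = post$ess_kappa
      ),
      relocation_error_m = rel$mean_m,
      href_m = h,
      area_ha = lapply(hr, function(r) round(r$area_ha, 2)),
      selection = as.data.frame(sel),
      chi2 = list(
        total = attr(sel, "chi2_total"), df = attr(sel, "df"),
        p_value = attr(sel, "p_value")
      ),
      commute = com
    )
  }
  report$summary <- list(
    kernel95_ha = mean_se(areas95),
    kernel50_ha = mean_se(areas50),
    mcp_ha = mean_se(areas_mcp),
    night_day_ratio = mean_se(ratios),
    true_kappa = scen$true_kappa
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_habitats(map, file.path(config$output_dir, "habitats.geojson"))
    write_home_ranges(ranges, file.path(config$output_dir, "home_ranges.geojson"))
    write_bearings(scen$bearings, file.path(config$output_dir, "bearings.csv"))
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  invisible(report)
}
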
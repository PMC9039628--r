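# Synthetic coastal landscape: an ocean band along one edge and habitat
# polygons tiling the land. The construction is deterministic banded
# geometry: habitats become coast-parallel strips in the order supplied
# (coast-most first); a habitat whose name contains "water" is embedded as a
# rectangular pond inside the largest strip instead of forming its own band.
# Rectangles give exact areal fractions and reproduce the coastal/inland
# zonation of an arid-island shoreline (beach, coastal forest, road, dry
# forest).

#' Configuration for the synthetic coastal landscape
#'
#' @param extent Rectangle `c(xmin, xmax, ymin, ymax)` in planar metres.
#' @param habitat_fractions Named numeric vector of target areal fractions of
#'   the land (non-negative, summing to 1), in coast-to-inland band order.
#' @param coast_side Which edge of the extent is ocean: `"south"`, `"north"`,
#'   `"west"` or `"east"`.
#' @param ocean_fraction Fraction of the extent occupied by the ocean band.
#' @param seed Integer recorded with the configuration. The banded
#'   construction is deterministic, so the seed does not alter the geometry;
#'   it is carried for provenance in downstream manifests.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(extent = c(0, 1200, 0, 800),
                             habitat_fractions = c(
                               "beach" = 0.05,
                               "manzanillo-forest" = 0.36,
                               "paved-road" = 0.02,
                               "inland-water" = 0.02,
                               "dry-forest" = 0.55
                             ),
                             coast_side = c("south", "north", "west", "east"),
                             ocean_fraction = 0.2,
                             seed = 1L) {
  coast_side <- match.arg(coast_side)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive width and height")
  }
  f <- habitat_fractions
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("habitat_fractions must be named")
  }
  if (any(f < 0)) stop("habitat fractions must be non-negative")
  if (any(f > 1)) stop("infeasible habitat fractions: a single fraction exceeds 1")
  if (abs(sum(f) - 1) > 1e-9) {
    stop(sprintf("habitat fractions must sum to 1 (got %.6f)", sum(f)))
  }
  if (ocean_fraction <= 0 || ocean_fraction >= 1) {
    stop("ocean_fraction must be in (0, 1)")
  }
  structure(
    list(
      extent = as.numeric(extent), habitat_fractions = f,
      coast_side = coast_side, ocean_fraction = ocean_fraction,
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

# Map canonical coordinates (u along the coast, v = inland distance measured
# from the coast edge of the extent) into the requested frame. All four maps
# are isometries, so band areas are preserved exactly.
canonical_to_xy <- function(u, v, extent, coast_side) {
  switch(coast_side,
    south = cbind(extent[1] + u, extent[3] + v),
    north = cbind(extent[1] + u, extent[4] - v),
    west = cbind(extent[1] + v, extent[3] + u),
    east = cbind(extent[2] - v, extent[3] + u)
  )
}

map_rect <- function(u0, u1, v0, v1, extent, coast_side) {
  corners <- canonical_to_xy(c(u0, u1, u1, u0), c(v0, v0, v1, v1), extent, coast_side)
  ensure_ccw(corners)
}

#' Generate the synthetic habitat map
#'
#' @param config A [landscape_config()].
#' @return A `habitat_map`: list with `habitats` (named list of multipolygons,
#'   each a list of convex `n x 2` rings), `land` and `ocean` polygons,
#'   `extent`, `habitat_order`, and the generating `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- config$extent
  f <- config$habitat_fractions
  depth_axis <- if (config$coast_side %in% c("south", "north")) {
    ext[4] - ext[3]
  } else {
    ext[2] - ext[1]
  }
  coast_len <- if (config$coast_side %in% c("south", "north")) {
    ext[2] - ext[1]
  } else {
    ext[4] - ext[3]
  }
  v_ocean <- config$ocean_fraction * depth_axis
  land_depth <- depth_axis - v_ocean
  land_area <- coast_len * land_depth

  nm <- names(f)
  pond_idx <- grep("water", nm, ignore.case = TRUE)[1]
  has_pond <- !is.na(pond_idx) && length(nm) >= 3 && f[pond_idx] > 0
  band_f <- f
  host_idx <- NA_integer_
  if (has_pond) {
    band_f <- f[-pond_idx]
    host_name <- names(band_f)[which.max(band_f)]
    host_idx <- match(host_name, nm)
    # host band is widened to carry the pond area, pond carved out later
    band_f[host_name] <- band_f[host_name] + f[pond_idx]
  }

  widths <- band_f * land_depth / sum(band_f)
  v_edges <- v_ocean + c(0, cumsum(widths))
  habitats <- stats::setNames(vector("list", length(nm)), nm)
  for (i in seq_along(band_f)) {
    name <- names(band_f)[i]
    habitats[[name]] <- list(map_rect(
      0, coast_len, v_edges[i], v_edges[i + 1], ext, config$coast_side
    ))
  }

  if (has_pond) {
    pond_name <- nm[pond_idx]
    host_name <- nm[host_idx]
    b0 <- v_edges[match(host_name, names(band_f))]
    b1 <- v_edges[match(host_name, names(band_f)) + 1]
    pond_area <- f[pond_idx] * land_area
    pond_h <- min((b1 - b0) / 2, sqrt(pond_area))
    pond_w <- pond_area / pond_h
    if (pond_w > 0.9 * coast_len) {
      pond_w <- 0.9 * coast_len
      pond_h <- pond_area / pond_w
    }
    u0 <- (coast_len - pond_w) / 2
    u1 <- u0 + pond_w
    vm <- (b0 + b1) / 2
    p0 <- vm - pond_h / 2
    p1 <- vm + pond_h / 2
    habitats[[pond_name]] <- list(map_rect(u0, u1, p0, p1, ext, config$coast_side))
    # host = band minus pond: frame of four rectangles, all convex
    habitats[[host_name]] <- list(
      map_rect(0, coast_len, b0, p0, ext, config$coast_side),
      map_rect(0, coast_len, p1, b1, ext, config$coast_side),
      map_rect(0, u0, p0, p1, ext, config$coast_side),
      map_rect(u1, coast_len, p0, p1, ext, config$coast_side)
    )
  }

  land <- map_rect(0, coast_len, v_ocean, depth_axis, ext, config$coast_side)
  ocean <- map_rect(0, coast_len, 0, v_ocean, ext, config$coast_side)
  structure(
    list(
      habitats = habitats, land = land, ocean = ocean,
      extent = ext, habitat_order = nm, crs = "local-metres",
      config = config
    ),
    class = "habitat_map"
  )
}

#' Assemble a habitat map from user-supplied polygons
#'
#' @param habitats Named list; each element a polygon matrix or list of
#'   polygon matrices (multipolygon with convex parts preferred).
#' @param land Land polygon; defaults to the bounding box of all habitats.
#' @param ocean Optional ocean polygon.
#' @return A `habitat_map`.
#' @export
habitat_map <- function(habitats, land = NULL, ocean = NULL) {
  stopifnot(is.list(habitats), length(habitats) >= 1, !is.null(names(habitats)))
  habitats <- lapply(habitats, as_multipolygon)
  all_pts <- do.call(rbind, unlist(habitats, recursive = FALSE))
  ext <- c(range(all_pts[, 1]), range(all_pts[, 2]))
  if (is.null(land)) land <- rect_poly(ext[1], ext[2], ext[3], ext[4])
  structure(
    list(
      habitats = habitats, land = land, ocean = ocean, extent = ext,
      habitat_order = names(habitats), crs = "local-metres", config = NULL
    ),
    class = "habitat_map"
  )
}

#' @export
print.habitat_map <- function(x, ...) {
  areas <- vapply(x$habitats, polygon_area, numeric(1))
  cat("habitat_map:", length(x$habitats), "habitat types,",
      sprintf("land %.1f ha, ocean %.1f ha\n",
              polygon_area(x$land) / 1e4, polygon_area(x$ocean) / 1e4))
  fr <- areas / polygon_area(x$land)
  for (nm in x$habitat_order) {
    cat(sprintf("  %-18s %8.2f ha  (%.3f of land)\n", nm, areas[nm] / 1e4, fr[nm]))
  }
  invisible(x)
}

#' Realized areal fractions of a habitat map
#'
#' @param map A `habitat_map`.
#' @return Named vector of habitat areas divided by land area.
#' @export
habitat_fractions <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  vapply(map$habitats, polygon_area, numeric(1)) / polygon_area(map$land)
}

#' Observer stations along the road and the beach path
#'
#' Places bearing stations on the centreline of the road band (accessible
#' sites along the main road), plus an optional short spur of stations on a
#' path running from the road towards the beach.
#'
#' @param map A `habitat_map` containing a habitat whose name contains
#'   `"road"`; otherwise stations are placed along the inland edge of the land.
#' @param n_road Number of stations along the road.
#' @param n_path Number of stations on the beach path spur (0 to disable).
#' @return An `m x 2` matrix of station coordinates.
#' @export
make_stations <- function(map, n_road = 5, n_path = 3) {
  stopifnot(inherits(map, "habitat_map"), n_road >= 1)
  ext <- map$extent
  side <- map$config$coast_side
  depth_axis <- if (side %in% c("south", "north")) ext[4] - ext[3] else ext[2] - ext[1]
  coast_len <- if (side %in% c("south", "north")) ext[2] - ext[1] else ext[4] - ext[3]
  road_idx <- grep("road", map$habitat_order, ignore.case = TRUE)[1]
  v_ocean <- map$config$ocean_fraction * depth_axis
  if (!is.na(road_idx)) {
    # centreline of the road band, recovered from its canonical v-range
    ring <- map$habitats[[road_idx]][[1]]
    vv <- xy_to_canonical_v(ring, ext, side)
    v_road <- mean(range(vv))
  } else {
    v_road <- depth_axis - 1
  }
  u_road <- seq(coast_len / (2 * n_road), coast_len - coast_len / (2 * n_road),
                length.out = n_road)
  pts <- canonical_to_xy(u_road, rep(v_road, n_road), ext, side)
  if (n_path > 0) {
    # offset from the landscape midline so the spur is never collinear with
    # targets near the roost (a collinear array degrades triangulation)
    u_path <- 0.38 * coast_len
    v_path <- seq(v_ocean + 0.03 * depth_axis, v_road - 0.05 * depth_axis,
                  length.out = n_path)
    pts <- rbind(pts, canonical_to_xy(rep(u_path, n_path), v_path, ext, side))
  }
  unname(pts)
}

xy_to_canonical_v <- function(pts, extent, coast_side) {
  switch(coast_side,
    south = pts[, 2] - extent[3],
    north = extent[4] - pts[, 2],
    west = pts[, 1] - extent[1],
    east = extent[2] - pts[, 1]
  )
}
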
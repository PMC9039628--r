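# Home-range estimation: bivariate-normal kernel utilization distributions
# on a regular grid with the reference bandwidth, isopleth extraction by
# cumulative-mass thresholding (95% home range, 50% core area), land
# clipping, minimum convex polygons with rarefaction, and pairwise areal
# overlap. Areas are reported in hectares (1 ha = 10,000 m^2).

#' Reference bandwidth for kernel home-range estimation
#'
#' The ad hoc plug-in bandwidth assuming bivariate normality:
#' `h = sqrt((var_x + var_y) / 2) * n^(-1/6)`, with `n - 1` denominator
#' sample variances.
#'
#' @param points An `n x 2` matrix or data frame of relocations (metres).
#' @return Bandwidth `h` in metres.
#' @export
href_bandwidth <- function(points) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 2) stop("at least two points are required")
  v <- stats::var(pts[, 1]) + stats::var(pts[, 2])
  if (v == 0) stop("all points are identical: bandwidth undefined")
  sqrt(v / 2) * n^(-1 / 6)
}

#' Kernel utilization distribution on a regular grid
#'
#' Bivariate normal (Gaussian) kernel density over the bounding box of the
#' points expanded by `margin * h`, evaluated at cell centres and normalized
#' so the cell masses sum to one.
#'
#' @param points `n x 2` relocations (metres).
#' @param h Smoothing bandwidth in metres (e.g. [href_bandwidth()]).
#' @param cell_size_m Grid resolution, metres (default 5).
#' @param margin Grid margin in bandwidths beyond the point bounding box.
#' @param max_cells Cap on the grid size; exceeding it is a resolution error.
#' @return A `ud_grid`: cell-centre coordinates `xs`, `ys`, the density
#'   matrix (`length(xs)` rows), `cell_size_m`, `h`, `n_points`.
#' @export
kernel_ud <- function(points, h, cell_size_m = 5, margin = 3, max_cells = 4e6) {
  pts <- as_xy(points)
  stopifnot(h > 0, cell_size_m > 0)
  pad <- margin * h
  xr <- range(pts[, 1]) + c(-pad, pad)
  yr <- range(pts[, 2]) + c(-pad, pad)
  nx <- ceiling(diff(xr) / cell_size_m)
  ny <- ceiling(diff(yr) / cell_size_m)
  if (as.double(nx) * ny > max_cells) {
    stop(sprintf("grid of %d x %d cells exceeds the %g-cell cap; coarsen cell_size_m",
                 nx, ny, max_cells))
  }
  xs <- xr[1] + (seq_len(nx) - 0.5) * cell_size_m
  ys <- yr[1] + (seq_len(ny) - 0.5) * cell_size_m
  # separable Gaussian: density = (Kx %*% t(Ky)) averaged over points
  dx2 <- outer(xs, pts[, 1], `-`)^2
  dy2 <- outer(ys, pts[, 2], `-`)^2
  kx <- exp(-dx2 / (2 * h^2))
  ky <- exp(-dy2 / (2 * h^2))
  dens <- (kx %*% t(ky)) / (nrow(pts) * 2 * pi * h^2)
  total <- sum(dens) * cell_size_m^2
  dens <- dens / total
  structure(
    list(
      xs = xs, ys = ys, density = dens, cell_size_m = cell_size_m,
      h = h, n_points = nrow(pts)
    ),
    class = "ud_grid"
  )
}

#' Total probability mass of a UD grid
#' @param ud A `ud_grid`.
#' @return Sum of cell masses (1 up to numerical tolerance).
#' @export
ud_mass <- function(ud) sum(ud$density) * ud$cell_size_m^2

#' Isopleth home range from a utilization distribution
#'
#' Selects grid cells in decreasing density order until the cumulative mass
#' reaches `level`% (cells tied at the threshold density are all included),
#' merges them into rectangular strips, clips to land, and reports the area.
#'
#' @param ud A `ud_grid` from [kernel_ud()].
#' @param level Isopleth level in percent, `0 < level < 100` (95 = home
#'   range, 50 = core area).
#' @param land Optional land polygon/multipolygon with convex parts; the
#'   isopleth is intersected with it (areal exclusion of the ocean, without
#'   renormalizing the UD).
#' @param individual_id Identifier carried into the estimate.
#' @return A `home_range` object (method `"kernel"`).
#' @export
isopleth <- function(ud, level, land = NULL, individual_id = NA_character_) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 100)
  d <- as.vector(ud$density)
  ord <- order(d, decreasing = TRUE)
  mass <- cumsum(d[ord]) * ud$cell_size_m^2
  k <- which(mass >= level / 100)[1]
  if (is.na(k)) k <- length(ord)
  thr <- d[ord[k]]
  sel <- d >= thr  # ties at the cutoff all included
  idx <- which(matrix(sel, nrow = length(ud$xs)), arr.ind = TRUE)
  cells <- data.frame(x = ud$xs[idx[, 1]], y = ud$ys[idx[, 2]])
  strips <- cells_to_strips(cells, ud$cell_size_m)
  polys <- strips
  if (!is.null(land)) {
    land <- as_multipolygon(land)
    polys <- list()
    for (s in strips) {
      for (lp in land) {
        piece <- clip_convex(s, lp)
        if (!is.null(piece)) polys[[length(polys) + 1L]] <- piece
      }
    }
  }
  area_ha <- polygon_area(polys) / 1e4
  structure(
    list(
      individual_id = individual_id, method = "kernel", level = level,
      polygons = polys, area_ha = area_ha, cells = cells,
      cell_size_m = ud$cell_size_m, h = ud$h, n_points = ud$n_points
    ),
    class = "home_range"
  )
}

# merge selected grid cells into maximal horizontal rectangle strips
cells_to_strips <- function(cells, cell) {
  if (nrow(cells) == 0) return(list())
  o <- order(cells$y, cells$x)
  x <- cells$x[o]
  y <- cells$y[o]
  new_run <- c(TRUE, diff(x) > cell * 1.5 | diff(y) != 0)
  run <- cumsum(new_run)
  x0 <- tapply(x, run, min) - cell / 2
  x1 <- tapply(x, run, max) + cell / 2
  yy <- tapply(y, run, `[`, 1)
  lapply(seq_along(x0), function(i) {
    rect_poly(x0[[i]], x1[[i]], yy[[i]] - cell / 2, yy[[i]] + cell / 2)
  })
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range %s: %s %s%% = %.2f ha (%d parts)\n",
              x$individual_id, x$method,
              format(x$level), x$area_ha, length(x$polygons)))
  invisible(x)
}

#' Minimum convex polygon home range
#'
#' Convex hull of the relocations (100% = all points retained; lower
#' percentages peel off the points farthest from the centroid first, the
#' classical MCP convention).
#'
#' @param points `n x 2` relocations (metres).
#' @param percent Percentage of points retained (default 100).
#' @param individual_id Identifier carried into the estimate.
#' @return A `home_range` object (method `"mcp"`) with the hull polygon and
#'   its surveyor's-formula area in hectares.
#' @export
mcp <- function(points, percent = 100, individual_id = NA_character_) {
  pts <- unique(as_xy(points))
  stopifnot(percent > 0, percent <= 100)
  if (percent < 100) {
    ctr <- colMeans(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    keep <- d <= stats::quantile(d, percent / 100)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("at least 3 distinct points are required")
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3 || polygon_area(hull) < 1e-12) {
    stop("points are collinear: no polygon can be formed")
  }
  structure(
    list(
      individual_id = individual_id, method = "mcp", level = percent,
      polygons = list(ensure_ccw(hull)),
      area_ha = polygon_area(hull) / 1e4,
      n_points = nrow(pts)
    ),
    class = "home_range"
  )
}

#' MCP rarefaction curve
#'
#' Mean 100% MCP area over random subsets of increasing size, used to judge
#' how many fixes are needed before the range estimate plateaus.
#'
#' @param points `n x 2` relocations, `n >= 4`.
#' @param n_replicates Random subsets per subset size (default 100).
#' @param seed Integer seed.
#' @return A `rarefaction_curve` data frame with columns `n_fixes`,
#'   `mean_area_ha`, `sd_area_ha`.
#' @export
rarefaction <- function(points, n_replicates = 100, seed = 1L) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 4) stop("rarefaction needs at least 4 points")
  set.seed(as.integer(seed))
  sizes <- 3:n
  res <- matrix(NA_real_, length(sizes), 2)
  for (i in seq_along(sizes)) {
    m <- sizes[i]
    areas <- replicate(n_replicates, {
      sub <- pts[sample.int(n, m), , drop = FALSE]
      tryCatch(mcp(sub)$area_ha, error = function(e) NA_real_)
    })
    res[i, ] <- c(mean(areas, na.rm = TRUE), stats::sd(areas, na.rm = TRUE))
  }
  out <- data.frame(n_fixes = sizes, mean_area_ha = res[, 1], sd_area_ha = res[, 2])
  class(out) <- c("rarefaction_curve", "data.frame")
  attr(out, "n_replicates") <- n_replicates
  out
}

#' Plateau point of a rarefaction curve
#'
#' @param curve A `rarefaction_curve`.
#' @param threshold Fraction of the full-sample MCP area that counts as the
#'   plateau (default 0.95).
#' @return Smallest number of fixes whose mean MCP area reaches
#'   `threshold x` the full-sample area.
#' @export
plateau_n <- function(curve, threshold = 0.95) {
  full <- curve$mean_area_ha[nrow(curve)]
  curve$n_fixes[which(curve$mean_area_ha >= threshold * full)[1]]
}

#' Directional areal overlap between two home ranges
#'
#' The percentage of range `b` covered by range `a`:
#' `100 * area(a intersect b) / area(b)`.
#'
#' @param range_a,range_b `home_range` objects of the same method and level.
#' @return Overlap percentage in `[0, 100]`.
#' @export
overlap <- function(range_a, range_b) {
  stopifnot(inherits(range_a, "home_range"), inherits(range_b, "home_range"))
  if (range_a$method != range_b$method || range_a$level != range_b$level) {
    stop("overlap requires home ranges of the same method and level")
  }
  area_b <- polygon_area(range_b$polygons)
  if (area_b <= 0) stop("overlap is undefined for a zero-area range")
  100 * intersection_area(range_a$polygons, range_b$polygons) / area_b
}

#' Mean and standard error of per-bird values
#'
#' @param x Numeric vector (e.g. per-bird home-range areas in hectares).
#' @return List with `mean`, `se`, `n`.
#' @export
mean_se <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}
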
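test_that("landscape realizes configured habitat fractions", {
  cfg <- landscape_config(habitat_fractions = c("dry-forest" = 1.0))
  map1 <- generate_landscape(cfg)
  expect_equal(polygon_area(map1$habitats[["dry-forest"]]),
               polygon_area(map1$land), tolerance = 1e-12)

  target <- c("beach" = 0.05, "manzanillo-forest" = 0.36, "paved-road" = 0.02,
              "inland-water" = 0.02, "dry-forest" = 0.55)
  map <- generate_landscape(landscape_config(habitat_fractions = target, seed = 1))
  # recompute realized fractions with an independent area implementation
  realized <- vapply(map$habitats, function(mp) {
    sum(vapply(mp, function(p) abs(pracma::polyarea(p[, 1], p[, 2])), numeric(1)))
  }, numeric(1)) / abs(pracma::polyarea(map$land[, 1], map$land[, 2]))
  expect_true(all(abs(realized[names(target)] - target) <= 0.02))
  # habitat polygons tile the land
  expect_equal(sum(realized), 1, tolerance = 1e-9)
})

test_that("infeasible habitat fractions are rejected", {
  expect_error(landscape_config(habitat_fractions = c(a = 1.2, b = -0.2)),
               "non-negative")
  expect_error(landscape_config(habitat_fractions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(
    generate_landscape(landscape_config(habitat_fractions = c(a = 0.9))),
    "sum to 1"
  )
})

test_that("landscape works for every coast side", {
  for (side in c("south", "north", "west", "east")) {
    map <- generate_landscape(landscape_config(coast_side = side))
    fr <- habitat_fractions(map)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_equal(unname(fr["dry-forest"]), 0.55, tolerance = 1e-9)
  }
})

test_that("track simulation honours dispersion and roosting behaviour", {
  map <- generate_landscape()
  nest <- c(600, 550)
  roost <- c(600, 300)
  cfg0 <- track_config(nest, roost, day_dispersion_m = 0, n_days = 3)
  tr0 <- simulate_track(cfg0, map, seed = 5)
  day <- tr0$positions[tr0$positions$activity == "day", ]
  expect_true(all(day$x == nest[1] & day$y == nest[2]))
  night <- tr0$positions[tr0$positions$activity == "roost", ]
  expect_equal(unique(night$x), roost[1])
  # night-at-roost distances equal the nest-roost distance exactly
  expect_equal(
    sqrt((night$x - nest[1])^2 + (night$y - nest[2])^2),
    rep(sqrt(sum((nest - roost)^2)), nrow(night))
  )

  cfg_inc <- track_config(nest, roost, day_dispersion_m = 0, n_days = 3,
                          night_at_roost = FALSE)
  tr_inc <- simulate_track(cfg_inc, map, seed = 5)
  night_inc <- tr_inc$positions[tr_inc$positions$activity == "roost", ]
  expect_true(all(night_inc$x == nest[1] & night_inc$y == nest[2]))

  tr <- simulate_track(track_config(nest, roost), map, seed = 9)
  expect_true(all(diff(as.numeric(tr$positions$timestamp)) > 0))
  expect_true(all(finchtrack:::points_in_polygon(
    tr$positions$x, tr$positions$y, map$land
  )))
})

test_that("nest too close to the ocean fails rejection sampling", {
  map <- generate_landscape()
  # nest 1 m from the waterline with a dispersion far larger than the land
  shore_nest <- c(600, map$extent[3] + 0.2 * (map$extent[4] - map$extent[3]) + 1)
  cfg <- track_config(shore_nest, c(600, 300), day_dispersion_m = 1e6, n_days = 1)
  expect_error(simulate_track(cfg, map, seed = 1), "1000 consecutive")
})

test_that("bearing simulation is noise-free in the large-kappa limit", {
  map <- generate_landscape()
  tr <- simulate_track(track_config(c(600, 550), c(600, 300), n_days = 2), map, seed = 2)
  st <- make_stations(map)
  brg <- simulate_bearings(tr, st, kappa = 1e9, seed = 3)
  m <- match(brg$fix_id, tr$positions$fix_id)
  true_az <- azimuth(cbind(brg$observer_x, brg$observer_y),
                     cbind(tr$positions$x[m], tr$positions$y[m]))
  delta <- abs(brg$azimuth_deg - true_az)
  delta <- pmin(delta, 360 - delta)
  expect_true(all(delta < 0.01))
})

test_that("bearing noise matches the von Mises closed form", {
  set.seed(11)
  draws <- rvonmises(10000, 0, 20)
  # circular sd of residuals vs sqrt(-2 log(I1/I0))
  rbar <- sqrt(mean(cos(draws))^2 + mean(sin(draws))^2)
  circ_sd <- sqrt(-2 * log(rbar))
  expect_equal(circ_sd, vm_circular_sd(20), tolerance = 0.05)
  # concentration recovered within 10%
  expect_equal(vm_kappa_mle(draws), 20, tolerance = 0.10)
})

test_that("positions with fewer than two in-range stations are skipped", {
  map <- generate_landscape()
  tr <- simulate_track(track_config(c(600, 550), c(600, 300), n_days = 2,
                                    day_dispersion_m = 0), map, seed = 2)
  one_station <- matrix(c(600, 429), 1, 2)
  expect_error(simulate_bearings(tr, one_station, kappa = 50, seed = 1),
               "no station within detection range")
  far_station <- rbind(c(600, 429), c(600, 440))
  brg <- simulate_bearings(tr, far_station, kappa = 50, max_dist_m = 135, seed = 1)
  # roost fixes (distance ~129-140 m) partly out of range of the second station
  expect_true(length(attr(brg, "skipped_fix_ids")) > 0)
})

test_that("identical seeds reproduce identical synthetic data", {
  s1 <- synthetic_scenario(seed = 4, n_individuals = 2, n_days = 3)
  s2 <- synthetic_scenario(seed = 4, n_individuals = 2, n_days = 3)
  expect_identical(s1$bearings, s2$bearings)
  expect_identical(s1$truths$bird1$positions, s2$truths$bird1$positions)
  s3 <- synthetic_scenario(seed = 5, n_individuals = 2, n_days = 3)
  expect_false(identical(s1$bearings$azimuth_deg, s3$bearings$azimuth_deg))
})
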
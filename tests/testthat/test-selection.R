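test_that("availability recovers exact areal fractions from constructed strips", {
  # vertical strips with widths proportional to a published availability
  # vector; a home range spanning all strips must recover it exactly
  p <- c("beach" = 0.032, "inland-water" = 0.025,
         "manzanillo-forest" = 0.158, "dry-forest" = 0.700,
         "paved-road" = 0.085)
  W <- 1000
  edges <- c(0, cumsum(p) * W)
  habs <- lapply(seq_along(p), function(i) {
    rect_ring(edges[i], edges[i + 1], 0, 500)
  })
  names(habs) <- names(p)
  map <- habitat_map(habs)
  hr <- hr_from_polygons(rect_ring(0, W, 100, 400))
  av <- availability(hr, map)
  expect_equal(av, p, tolerance = 1e-6)

  # home range inside a single habitat
  hr_single <- hr_from_polygons(rect_ring(300, 500, 100, 200))
  expect_equal(availability(hr_single, map), c("dry-forest" = 1))
  # straddling one boundary: strip widths give exact proportions
  hr1 <- hr_from_polygons(rect_ring(150, 350, 100, 200))
  expect_equal(availability(hr1, map),
               c("manzanillo-forest" = 0.325, "dry-forest" = 0.675),
               tolerance = 1e-9)
  # equal halves across a straight boundary
  hr2 <- hr_from_polygons(rect_ring(edges[4] - 50, edges[4] + 50, 0, 500))
  expect_equal(unname(availability(hr2, map)), c(0.5, 0.5))
  # a gap in the habitat map is a coverage error
  gap_map <- habitat_map(habs[1:2])
  expect_error(availability(hr, gap_map), "cover")
})

test_that("usage counts points deterministically, boundaries included once", {
  habs <- list(a = rect_ring(0, 100, 0, 100), b = rect_ring(100, 200, 0, 100))
  map <- habitat_map(habs)
  loc <- data.frame(x = c(10, 50, 150, 100), y = c(10, 20, 30, 50))
  u <- usage(loc, map)
  expect_equal(sum(u), 4L)
  # the shared edge point lands in 'a', the first habitat in canonical order
  expect_equal(u, c(a = 3L, b = 1L))
  map_rev <- habitat_map(rev(habs))
  expect_equal(usage(loc, map_rev), c(b = 2L, a = 2L))
  expect_error(usage(data.frame(x = 500, y = 500, fix_id = "z9"), map), "z9")
})

test_that("Neu chi-square matches expectation and flags degenerate input", {
  even <- neu_chi_square(c(0.25, 0.25, 0.5), c(10, 10, 20))
  expect_equal(even$chi2_total, 0)
  expect_equal(even$p_value, 1)
  expect_equal(sum(even$expected), 40)
  expect_error(neu_chi_square(c(0.5, 0.5, 0), c(1, 1, 2)), "zero availability")
  expect_error(neu_chi_square(c(0.4, 0.4), c(1, 1)), "sum to 1")
  expect_warning(neu_chi_square(c(0.9, 0.1), c(27, 3)), "below 5")
})

test_that("published chi-square statistics are reproduced from printed inputs", {
  st <- suppressWarnings(
    selection_from_counts(c(a = 0.018, b = 0.428, c = 0.511, d = 0.042),
                          c(0, 4, 27, 0))
  )
  expect_equal(attr(st, "chi2_total"), 16.21, tolerance = 0.0035)
  expect_equal(attr(st, "df"), 3)
  expect_equal(attr(st, "p_value"), 0.001, tolerance = 0.05)
  st2 <- suppressWarnings(
    selection_from_counts(c(a = 0.197, b = 0.781, c = 0.023), c(5, 23, 2))
  )
  expect_equal(attr(st2, "chi2_total"), 2.73, tolerance = 0.05)
  expect_equal(attr(st2, "df"), 2)
})

test_that("Bonferroni intervals match the published bounds", {
  expect_equal(bonferroni_ci(28 / 30, 30, 5), c(0.816, 1.051), tolerance = 0.005)
  expect_equal(bonferroni_ci(27 / 31, 31, 4), c(0.721, 1.021), tolerance = 0.005)
  expect_equal(bonferroni_ci(0, 30, 5), c(0, 0))
  # upper bound deliberately uncapped above 1, lower floored at 0
  expect_gt(bonferroni_ci(28 / 30, 30, 5)[2], 1)
  expect_equal(bonferroni_ci(1 / 30, 30, 5)[1], 0)
})

test_that("selection direction is classified and monotone in availability", {
  expect_equal(classify_selection(0.700, c(0.816, 1.051)), "positive")
  expect_equal(classify_selection(0.158, c(0, 0.118)), "negative")
  expect_equal(classify_selection(0.032, c(0, 0.118)), "neutral")
  ci <- c(0.2, 0.6)
  dirs <- vapply(seq(0.01, 0.99, 0.01), classify_selection, character(1), ci = ci)
  codes <- c(positive = 1, neutral = 2, negative = 3)
  expect_true(all(diff(codes[dirs]) >= 0))
})

test_that("Jacobs' index behaves as a preference score", {
  for (v in c(0.1, 0.5, 0.9)) expect_equal(jacobs_index(v, v), 0)
  expect_equal(jacobs_index(0, 0.5), -1)
  expect_equal(jacobs_index(0.5, 0), 1)
  expect_equal(jacobs_index(0.9333, 0.700), 0.71, tolerance = 0.01)
  expect_error(jacobs_index(0, 0), "undefined")
  set.seed(9)
  r <- runif(50)
  p <- runif(50)
  D <- mapply(jacobs_index, r, p)
  expect_true(all(D >= -1 & D <= 1))
  expect_true(all(sign(D) == sign(r - p)))
  # antisymmetry under swapping use and availability
  expect_equal(D, -mapply(jacobs_index, p, r))
})

test_that("selection tables compose the full analysis per bird", {
  habs <- list(a = rect_ring(0, 200, 0, 100), b = rect_ring(200, 1000, 0, 100))
  map <- habitat_map(habs)
  hr <- hr_from_polygons(rect_ring(0, 1000, 0, 100))
  set.seed(10)
  loc <- data.frame(x = runif(40, 0, 1000), y = runif(40, 0, 100))
  st <- selection_table(hr, map, loc)
  expect_s3_class(st, "selection_table")
  expect_equal(sum(st$expected), 40, tolerance = 1e-9)
  expect_equal(sum(st$used), 40L)
  expect_equal(sum(st$availability), 1, tolerance = 1e-9)
  expect_equal(attr(st, "chi2_total"), sum(st$chi2_part), tolerance = 1e-12)
  # one-habitat home range cannot be tested
  hr1 <- hr_from_polygons(rect_ring(300, 900, 0, 100))
  loc1 <- data.frame(x = runif(10, 300, 900), y = runif(10, 0, 100))
  expect_error(selection_table(hr1, map, loc1), "at least 2 habitats")
})
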
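test_that("noise-free limit collapses onto the geometric intersection", {
  b <- data.frame(
    fix_id = "f1", observer_x = c(0, 100), observer_y = c(0, 100),
    azimuth_deg = c(90, 180), max_dist_m = 600
  )
  post <- atm_fit(b, atm_config(n_iter = 6000, n_burn = 2000,
                                kappa_fixed = 1e6, seed = 2))
  est <- point_estimates(post)
  expect_lt(sqrt((est$x - 100)^2 + (est$y - 0)^2), 1)
  expect_lt(est$sd_x, 1)
  # posterior mass entirely inside the prior support
  d1 <- sqrt(post$draws_x^2 + post$draws_y^2)
  d2 <- sqrt((post$draws_x - 100)^2 + (post$draws_y - 100)^2)
  expect_true(all(d1 <= 600 & d2 <= 600))
})

test_that("posterior mean matches a dense-grid brute-force oracle", {
  target <- c(160, 120)
  obs <- rbind(c(0, 0), c(300, 0), c(150, 260))
  az <- azimuth(obs, matrix(target, 3, 2, byrow = TRUE)) + c(4, -6, 2)
  b <- data.frame(fix_id = "f1", observer_x = obs[, 1], observer_y = obs[, 2],
                  azimuth_deg = az, max_dist_m = 600)
  kappa <- 10

  # independent oracle: 200 x 200 Riemann sum over the prior support
  xs <- seq(-150, 450, length.out = 200)
  ys <- seq(-150, 450, length.out = 200)
  g <- expand.grid(x = xs, y = ys)
  ok <- rep(TRUE, nrow(g))
  S <- 0
  for (i in 1:3) {
    ok <- ok & sqrt((g$x - obs[i, 1])^2 + (g$y - obs[i, 2])^2) <= 600
    S <- S + cos(az[i] * pi / 180 - atan2(g$x - obs[i, 1], g$y - obs[i, 2]))
  }
  w <- ifelse(ok, exp(kappa * (S - max(S[ok]))), 0)
  grid_mean <- c(sum(w * g$x), sum(w * g$y)) / sum(w)

  post <- atm_fit(b, atm_config(n_iter = 30000, n_burn = 5000,
                                kappa_fixed = kappa, seed = 7))
  mcse <- c(
    sd(post$draws_x[, 1]) / sqrt(finchtrack:::mcmc_ess(post$draws_x[, 1])),
    sd(post$draws_y[, 1]) / sqrt(finchtrack:::mcmc_ess(post$draws_y[, 1]))
  )
  expect_lt(abs(mean(post$draws_x) - grid_mean[1]), 2 * mcse[1])
  expect_lt(abs(mean(post$draws_y) - grid_mean[2]), 2 * mcse[2])
  # grid-oracle medians agree with the reported point estimate
  est <- point_estimates(post)
  cum_x <- cumsum(tapply(w, g$x, sum))
  grid_med_x <- as.numeric(names(cum_x))[which(cum_x >= sum(w) / 2)[1]]
  expect_lt(abs(est$x - grid_med_x), 3 * diff(xs[1:2]) + 2 * mcse[1])
})

test_that("configuration and input validation catch bad fits", {
  expect_error(atm_config(n_iter = 100, n_burn = 100), "exceed")
  b <- data.frame(fix_id = c("f1", "f1", "f2"),
                  observer_x = c(0, 100, 0), observer_y = c(0, 0, 0),
                  azimuth_deg = c(10, 350, 0), max_dist_m = 600)
  expect_error(atm_fit(b, atm_config(n_iter = 200, n_burn = 50)),
               "at least 2 bearings")
})

test_that("disjoint detection discs fall back to their union with a warning", {
  b <- data.frame(
    fix_id = "f1", observer_x = c(0, 1000), observer_y = c(0, 0),
    azimuth_deg = c(90, 270), max_dist_m = 400
  )
  expect_warning(
    post <- atm_fit(b, atm_config(n_iter = 2000, n_burn = 500,
                                  kappa_fixed = 5, seed = 1)),
    "union"
  )
  d1 <- sqrt(post$draws_x^2 + post$draws_y^2)
  d2 <- sqrt((post$draws_x - 1000)^2 + post$draws_y^2)
  expect_true(all(d1 <= 400 | d2 <= 400))
})

test_that("results are frame-invariant up to Monte Carlo error", {
  rep <- make_atm_replicate(31, kappa = 30, n_fix = 8)
  cfg <- atm_config(n_iter = 8000, n_burn = 2000, seed = 3)
  post <- suppressWarnings(atm_fit(rep$bearings, cfg))
  est <- point_estimates(post)

  theta <- 35 * pi / 180
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(5000, -2000)
  b2 <- rep$bearings
  xy <- cbind(b2$observer_x, b2$observer_y) %*% t(R)
  b2$observer_x <- xy[, 1] + shift[1]
  b2$observer_y <- xy[, 2] + shift[2]
  # counterclockwise frame rotation decreases compass azimuths
  b2$azimuth_deg <- (b2$azimuth_deg - 35) %% 360
  post2 <- suppressWarnings(atm_fit(b2, cfg))
  est2 <- point_estimates(post2)
  back <- (cbind(est2$x, est2$y) - matrix(shift, nrow(est2), 2, byrow = TRUE)) %*% R
  err <- sqrt((back[, 1] - est$x)^2 + (back[, 2] - est$y)^2)
  spread <- pmax(est$sd_x, est$sd_y)
  expect_true(all(err < 4 * spread / sqrt(10) + 2))
})

test_that("point estimates summarize degenerate posteriors sensibly", {
  post <- structure(
    list(fix_ids = "f1",
         draws_x = matrix(5, 100, 1), draws_y = matrix(-3, 100, 1),
         kappa = rep(10, 100), n_bearings = 2L, angle_deg = 90),
    class = "atm_posterior"
  )
  est <- point_estimates(post)
  expect_equal(est$x, 5)
  expect_equal(est$sd_x, 0)
  # median of a symmetric two-cluster posterior stays between the clusters
  post$draws_x <- matrix(rep(c(0, 10), each = 50), 100, 1)
  est2 <- point_estimates(post)
  expect_gte(est2$x, 0)
  expect_lte(est2$x, 10)
})

test_that("fix filtering reproduces the 286 -> 219 accounting", {
  set.seed(3)
  land <- rect_ring(0, 1000, 200, 1000)  # ocean below y = 200
  n_total <- 286
  n_ocean <- 67
  est <- data.frame(
    fix_id = sprintf("f%03d", 1:n_total),
    x = runif(n_total, 0, 1000),
    y = c(runif(n_total - n_ocean, 210, 990), runif(n_ocean, 0, 190)),
    source = "telemetry",
    angle_deg = 80
  )
  flt <- filter_fixes(est, land)
  expect_equal(nrow(flt$retained), 219)
  expect_equal(flt$removal_fraction, 67 / 286)
  expect_true(all(flt$removed$reason == "off-land"))

  # shallow-angle telemetry fixes are removed; direct observations are not
  est$angle_deg[1] <- 5
  est$source[2] <- "direct"
  est$angle_deg[2] <- 5
  flt2 <- filter_fixes(est, land)
  expect_true("f001" %in% flt2$removed$fix_id)
  expect_true("f002" %in% flt2$retained$fix_id)

  clean <- filter_fixes(est[est$y > 200 & est$angle_deg > 10, ], land)
  expect_equal(clean$removal_fraction, 0)
})

test_that("relocation error is the mean Euclidean displacement", {
  est <- data.frame(fix_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  truth <- data.frame(fix_id = c("a", "b"), x = c(0, 0), y = c(0, 0))
  re <- relocation_error(est, truth)
  expect_equal(unname(re$distances_m), c(0, 5))
  expect_equal(re$mean_m, 2.5)
  expect_error(relocation_error(data.frame(fix_id = "z", x = 1, y = 1), truth),
               "no true position")
})
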
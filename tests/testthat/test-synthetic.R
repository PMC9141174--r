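test_that("month-to-season mapping follows the study's grouping", {
  expect_equal(season_of(3:5), rep("spring", 3))
  expect_equal(season_of(6:8), rep("summer", 3))
  expect_equal(season_of(c(9, 11)), rep("autumn", 2))
  expect_equal(season_of(c(2, 12)), rep("winter", 2))
  expect_true(all(is.na(season_of(c(1, 10)))))
  expect_equal(season_of(as.Date("2016-05-12")), "spring")
  expect_error(season_of(13), "1..12")
})

test_that("degenerate AOD field parameters give an exactly constant field", {
  spec <- grid_spec(15, 15)
  f <- generate_aod_field(spec, gradient = 0, noise_sd = 0, base = 0.5,
                          seed = 1)
  expect_true(all(f == 0.5))
})

test_that("AOD field generation is deterministic and range-conserving", {
  spec <- grid_spec(30, 30)
  a <- generate_aod_field(spec, seed = 42)
  b <- generate_aod_field(spec, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0.02 & a <= 1.5))
  expect_false(identical(a, generate_aod_field(spec, seed = 43)))
  expect_error(generate_aod_field(spec, value_range = c(0, 2)),
               "within \\[0, 1.95\\]")
})

test_that("smoothed AOD fields are strongly spatially autocorrelated", {
  spec <- grid_spec(50, 50)
  f <- generate_aod_field(spec, smoothness = 8, gradient = 0, seed = 5)
  w <- build_weights(matrix(TRUE, 50, 50), scheme = "rook",
                     standardization = "row")
  expect_gt(global_morans_i(f, w), 0.3)
})

test_that("autocorrelation of generated fields is significant under permutation", {
  # global-I significance via total randomization of the field values
  spec <- grid_spec(30, 30)
  f <- generate_aod_field(spec, smoothness = 5, gradient = 0, seed = 8)
  w <- build_weights(matrix(TRUE, 30, 30), scheme = "rook")
  i_obs <- global_morans_i(f, w)
  set.seed(1)
  i_null <- replicate(999, {
    fp <- matrix(sample(as.numeric(f)), 30, 30)
    global_morans_i(fp, w)
  })
  p <- (sum(i_null >= i_obs) + 1) / 1000
  expect_lt(p, 0.01)
})

test_that("PM2.5 truth reproduces the seasonal generating laws exactly at zero noise", {
  # power law: a0 * x^a1 at x = 1 gives a0
  aod <- matrix(1, 2, 2)
  y <- generate_pm25_truth(aod, "power", 57.754, 0.6976, noise_cv = 0)
  expect_equal(y, matrix(57.754, 2, 2))
  # exponential at x = 0 gives a0
  y2 <- generate_pm25_truth(matrix(0, 2, 2), "exponential", 13.855, 0.8954,
                            noise_cv = 0)
  expect_equal(y2, matrix(13.855, 2, 2))
  # determinism
  set.seed(11)
  aod3 <- matrix(runif(9, 0.1, 1), 3, 3)
  expect_identical(generate_pm25_truth(aod3, "linear", 10, 40, noise_cv = 0),
                   generate_pm25_truth(aod3, "linear", 10, 40, noise_cv = 0))
  expect_error(generate_pm25_truth(aod, "spline", 1, 1), "must be one of")
  expect_error(generate_pm25_truth(aod, "power", 1, 1, noise_cv = -1), ">= 0")
})

test_that("noisy PM2.5 truth has approximately the requested noise level", {
  aod <- matrix(0.8, 80, 80)
  y <- generate_pm25_truth(aod, "power", 57.754, 0.6976, noise_cv = 0.2,
                           seed = 3)
  base <- 57.754 * 0.8^0.6976
  expect_equal(mean(y) / base, 1, tolerance = 0.02)
  expect_equal(sd(y) / mean(y), 0.2, tolerance = 0.05)
})

test_that("station networks have unique in-grid cells and requested sizes", {
  spec <- grid_spec(100, 100)
  net <- generate_station_network(spec, n_aod = 2, n_pm25 = 41, seed = 1)
  expect_equal(nrow(net), 43)
  expect_equal(sum(net$kind == "AOD"), 2)
  expect_false(any(duplicated(net$station_id)))
  expect_false(any(duplicated(net[c("row", "col")])))
  expect_true(all(net$row >= 1 & net$row <= 100 & net$col >= 1 &
                    net$col <= 100))
  empty <- generate_station_network(spec, 0, 0)
  expect_equal(nrow(empty), 0)
  expect_error(generate_station_network(grid_spec(2, 2), 3, 3), "only 4 cells")
})

test_that("full clustering on a population spike confines stations to its neighbourhood", {
  spec <- grid_spec(30, 30)
  pop <- matrix(0, 30, 30)
  pop[15, 15] <- 1000
  hits <- 0L; total <- 0L
  for (sd in 1:100) {
    net <- generate_station_network(spec, n_aod = 0, n_pm25 = 5,
                                    clustering = 1, population = pop,
                                    seed = sd)
    d <- pmax(abs(net$row - 15), abs(net$col - 15))
    hits <- hits + sum(d <= 3)
    total <- total + nrow(net)
  }
  expect_gt(hits / total, 0.99)
})

test_that("population surfaces are positive sums of decaying kernels", {
  spec <- grid_spec(20, 20)
  pop <- generate_population(spec, n_centers = 3, peak_density = 5000,
                             decay = 4, seed = 2)
  expect_true(all(pop >= 0) && any(pop > 0))
  expect_lte(max(pop), 3 * 5000)
  # analytic kernel-sum oracle: rebuild the total from the center positions
  set.seed(NULL)
  centers <- pm25risk:::with_seed(2, cbind(sample.int(20, 3, replace = TRUE),
                                           sample.int(20, 3, replace = TRUE)))
  expected <- 0
  for (k in 1:3)
    for (r in 1:20) for (cc in 1:20)
      expected <- expected +
        5000 * exp(-sqrt((r - centers[k, 1])^2 + (cc - centers[k, 2])^2) / 4)
  expect_equal(sum(pop), expected, tolerance = 1e-9)
  # delta limit: a near-zero decay length leaves a single nonzero cell
  spike <- generate_population(spec, n_centers = 1, peak_density = 100,
                               decay = 1e-9, seed = 3)
  expect_equal(sum(spike > 1e-12), 1)
  expect_error(generate_population(spec, decay = 0), "> 0")
})

test_that("noiseless station sampling extracts exact field values", {
  spec <- grid_spec(10, 10)
  field <- matrix(seq_len(100), 10, 10)
  net <- generate_station_network(spec, 0, 8, seed = 4)
  dts <- as.Date("2016-05-01") + 0:2
  obs <- sample_observations(field, net, dts, obs_noise_cv = 0,
                             missing_rate = 0, seed = 1)
  expect_equal(nrow(obs), 24)
  expect_equal(obs$value,
               rep(field[cbind(net$row, net$col)], 3))
  expect_equal(nrow(sample_observations(field, net, as.Date(character()),
                                        0, 0)), 0)
})

test_that("record dropout matches the binomial law", {
  spec <- grid_spec(25, 40)
  field <- matrix(1, 25, 40)
  net <- generate_station_network(spec, 0, 100, seed = 5)
  dts <- as.Date("2016-05-01") + 0:9   # 1000 records
  obs <- sample_observations(field, net, dts, obs_noise_cv = 0,
                             missing_rate = 0.5, seed = 6)
  expect_gte(nrow(obs), 450)  # central 99% binomial interval
  expect_lte(nrow(obs), 550)
  expect_error(sample_observations(field, net, dts, missing_rate = 1),
               "\\[0, 1\\)")
})

test_that("cloud masks hit the requested fraction and are reproducible", {
  spec <- grid_spec(40, 40)
  cm <- generate_cloud_mask(spec, fraction = 0.1, seed = 9)
  expect_equal(mean(cm), 0.1, tolerance = 0.01)
  expect_identical(cm, generate_cloud_mask(spec, fraction = 0.1, seed = 9))
  expect_false(any(generate_cloud_mask(spec, fraction = 0)))
})

test_that("truth bundles are bit-for-bit reproducible from the seed", {
  spec <- grid_spec(12, 12)
  b1 <- truth_bundle(spec, n_dates_per_season = 2, seed = 77L)
  b2 <- truth_bundle(spec, n_dates_per_season = 2, seed = 77L)
  expect_identical(b1, b2)
  expect_true(all(unlist(b1$aod_fields) >= 0 &
                    unlist(b1$aod_fields) <= 1.95))
  expect_true(all(unlist(b1$pm25_fields) >= 0))
  expect_true(all(b1$population >= 0))
})
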
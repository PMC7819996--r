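noon_midnight_track <- function() {
  # equator/prime meridian: solar noon ~12:07 UTC, midnight 12 h away
  data.frame(lat = c(0, 0), lon = c(0, 0),
             time = as.POSIXct(c("2000-03-20 12:07:00", "2000-03-21 00:07:00"),
                               tz = "UTC"))
}

test_that("an empty layer list yields a pure noise-floor grid", {
  cfg <- echogram_config(2, 80, noon_midnight_track(), 70, seed = 1)
  gen <- generate_echogram(cfg)
  expect_true(all(gen$echogram$sv == -100))
  expect_null(gen$truth$layers)
  expect_length(gen$truth$masks, 0)
})

test_that("a noise-free fully occupied layer emits its peak Sv at the centre
           depth", {
  cfg <- echogram_config(2, 80, noon_midnight_track(), 70,
                         noise_floor_db = -200, seed = 1)
  gen <- generate_echogram(cfg, layer_spec("plankton", -72, sv_sd_db = 0,
                                           depth_day = 40, depth_night = 40,
                                           thickness = 4, occupancy = 1))
  eg <- gen$echogram
  centre_row <- which(eg$depths == 40.5)  # closest bin centre to 40 m is 39.5/40.5
  rows <- which(abs(eg$depths - 40) <= 0.5)
  for (j in 1:2) {
    expect_equal(max(eg$sv[, j]), -72 + 10 * log10(exp(-0.5^2 / (2 * 16))),
                 tolerance = 1e-6)
  }
  # peak sits at the bin centres bracketing 40 m
  expect_true(all(apply(eg$sv, 2, which.max) %in% rows))
})

test_that("diel placement follows the sun: centroid near depth_day at noon and
           depth_night at midnight", {
  cfg <- echogram_config(2, 100, noon_midnight_track(), 95,
                         noise_floor_db = -200, seed = 5)
  gen <- generate_echogram(cfg, layer_spec("plankton", -72, sv_sd_db = 0,
                                           depth_day = 60, depth_night = 15,
                                           thickness = 5, occupancy = 1))
  eg <- gen$echogram
  lin <- 10^(eg$sv / 10)
  centroid <- colSums(lin * eg$depths) / colSums(lin)
  expect_equal(centroid[1], 60, tolerance = 1)   # noon column
  expect_equal(centroid[2], 15, tolerance = 1)   # midnight column
  expect_equal(gen$truth$columns$centre_depth, c(60, 15))
})

test_that("layer reaching below the grid floor is rejected by name", {
  cfg <- echogram_config(2, 50, noon_midnight_track(), 45, seed = 1)
  expect_error(
    generate_echogram(cfg, layer_spec("plankton", -72, depth_day = 48,
                                      depth_night = 20, thickness = 5)),
    "layer 1")
})

test_that("emitted layer cells stay inside their trophic Sv band", {
  set.seed(21)
  tr <- survey_track(20, 10, 11, -17, -17, "2005-11-20 00:00:00", 30)
  for (k in 1:5) {
    cfg <- echogram_config(20, 120, tr, 110, noise_floor_db = -200, seed = k)
    gen <- generate_echogram(cfg, list(
      layer_spec("plankton", runif(1, -79, -66), sv_sd_db = runif(1, 0, 3),
                 depth_day = runif(1, 40, 80), depth_night = runif(1, 12, 30),
                 thickness = runif(1, 2, 8), occupancy = runif(1, 0.3, 1)),
      layer_spec("fish", runif(1, -64, -30), sv_sd_db = runif(1, 0, 3),
                 depth_day = runif(1, 20, 60), depth_night = runif(1, 20, 60),
                 thickness = runif(1, 2, 8), occupancy = runif(1, 0.3, 1))))
    sv <- gen$echogram$sv
    pg_cells <- sv[gen$truth$masks[[1]] & !gen$truth$masks[[2]]]
    pfg_cells <- sv[gen$truth$masks[[2]] & !gen$truth$masks[[1]]]
    expect_true(all(pg_cells >= -80 & pg_cells < -65))
    expect_true(all(pfg_cells >= -65 & pfg_cells < -20))
  }
})

test_that("day and night layer centres differ by the configured migration
           amplitude", {
  tr <- survey_track(30, 14, 14.5, -17.4, -17.4, "2000-11-15 06:00:00", 36)
  cfg <- echogram_config(30, 100, tr, 95, noise_floor_db = -200, seed = 2)
  gen <- generate_echogram(cfg, layer_spec("plankton", -72, sv_sd_db = 0,
                                           depth_day = 55, depth_night = 20,
                                           thickness = 4))
  cd <- gen$truth$columns$centre_depth
  expect_setequal(unique(cd), c(55, 20))
  expect_equal(abs(diff(range(cd))), 35)
})

test_that("identical seeds reproduce the echogram exactly and different seeds
           do not", {
  tr <- survey_track(10, 14, 14.2, -17.4, -17.4, "2000-11-15 06:00:00", 20)
  mk <- function(seed) {
    cfg <- echogram_config(10, 80, tr, 70, seed = seed)
    generate_echogram(cfg, layer_spec("plankton", -74, 1.5, depth_day = 50,
                                      depth_night = 15, thickness = 5,
                                      occupancy = 0.7))$echogram$sv
  }
  expect_identical(mk(9), mk(9))
  expect_false(identical(mk(9), mk(10)))
})

test_that("environmental generator reproduces its deterministic skeleton", {
  cfg <- env_series_config("SST", n_years = 3, mean_level = 21,
                           seasonal_amplitude = 0, trend_per_decade = 0,
                           noise_sd = 0)
  s <- generate_env_series(cfg)
  expect_equal(nrow(s), 36)
  expect_true(all(s$value == 21))
  expect_equal(s$month, rep(1:12, 3))
  expect_equal(s$year, rep(1995:1997, each = 12))

  # pure linear trend: last minus first = total span minus one increment
  cfg2 <- env_series_config("SST", n_years = 20, mean_level = 21,
                            seasonal_amplitude = 0, trend_per_decade = 0.4,
                            noise_sd = 0)
  v <- generate_env_series(cfg2)$value
  expect_equal(v[240] - v[1], 0.8 - 0.4 / 120, tolerance = 1e-9)
})

test_that("environmental generator is seed-reproducible", {
  cfg <- env_series_config("SSC", n_years = 2, mean_level = 3,
                           seasonal_amplitude = 1, trend_per_decade = -0.5,
                           noise_sd = 0.4, seed = 33)
  expect_identical(generate_env_series(cfg), generate_env_series(cfg))
  cfg2 <- cfg; cfg2$seed <- 34L
  expect_false(identical(generate_env_series(cfg)$value,
                         generate_env_series(cfg2)$value))
})

test_that("ensemble mean of generated series matches the skeleton at every
           month", {
  base <- list(variable = "SST", n_years = 2, mean_level = 21,
               seasonal_amplitude = 3, trend_per_decade = 0.4, noise_sd = 0.5)
  skel <- generate_env_series(do.call(env_series_config,
                                      modifyList(base, list(noise_sd = 0))))$value
  n_rep <- 500
  acc <- matrix(0, 24, n_rep)
  for (k in seq_len(n_rep)) {
    acc[, k] <- generate_env_series(do.call(env_series_config,
                                            modifyList(base, list(seed = k))))$value
  }
  se <- 0.5 / sqrt(n_rep)
  expect_true(all(abs(rowMeans(acc) - skel) < 3 * se))
})

test_that("ground truth writes as a flat CSV", {
  cfg <- echogram_config(2, 80, noon_midnight_track(), 70, seed = 1)
  gen <- generate_echogram(cfg, layer_spec("plankton", -74, depth_day = 50,
                                           depth_night = 20, thickness = 5))
  path <- tempfile(fileext = ".csv")
  write_ground_truth(gen$truth, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 2)
  expect_true(all(c("layer", "group", "column", "centre_depth", "lat") %in%
                    names(df)))
})
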
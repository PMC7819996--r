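#' Synthetic survey-track helper
#'
#' Builds a straight survey track with equally spaced positions and equally
#' spaced timestamps, convenient input for [echogram_config()].
#'
#' @param n_columns number of along-track cells.
#' @param lat_start,lat_end,lon_start,lon_end track end points, degrees.
#' @param start_time first timestamp (`POSIXct` UTC or ISO 8601 string).
#' @param duration_hours elapsed time from first to last column.
#' @return Data frame with columns `lat`, `lon`, `time`.
#' @export
survey_track <- function(n_columns, lat_start, lat_end, lon_start, lon_end,
                         start_time, duration_hours) {
  stopifnot(n_columns >= 1, duration_hours > 0)
  start_time <- as_utc_time(start_time)
  data.frame(
    lat = seq(lat_start, lat_end, length.out = n_columns),
    lon = seq(lon_start, lon_end, length.out = n_columns),
    time = start_time + seq(0, duration_hours * 3600, length.out = n_columns))
}

#' Synthetic echogram configuration
#'
#' Survey geometry and noise settings for [generate_echogram()]. The grid has
#' `depth_max / depth_step` vertical bins with centres at half-steps; every
#' cell not reached by a scattering layer holds the noise floor.
#'
#' @param n_columns number of along-track cells.
#' @param depth_max maximum depth of the grid, m.
#' @param track data frame with per-column `lat`, `lon`, `time` (see
#'   [survey_track()]); must have `n_columns` rows with strictly increasing
#'   times and valid coordinates.
#' @param bottom_depth bottom depth in metres, scalar or per column.
#' @param depth_step vertical bin size, m (default 1).
#' @param noise_floor_db background level, dB (default -100).
#' @param seed integer seed making the generated echogram reproducible.
#' @return An object of class `echogram_config`.
#' @export
echogram_config <- function(n_columns, depth_max, track, bottom_depth,
                            depth_step = 1, noise_floor_db = -100, seed = 1L) {
  stopifnot(n_columns >= 1, depth_step > 0, depth_max >= depth_step)
  if (!is.data.frame(track) || !all(c("lat", "lon", "time") %in% names(track)))
    stop("`track` must be a data frame with columns lat, lon, time")
  if (nrow(track) != n_columns)
    stop("`track` must have exactly n_columns rows")
  track$time <- as_utc_time(track$time)
  if (n_columns > 1 && any(diff(as.numeric(track$time)) <= 0))
    stop("track times must be strictly increasing")
  if (any(track$lat < -90 | track$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(track$lon < -180 | track$lon > 180)) stop("longitude outside [-180, 180]")
  structure(list(n_columns = as.integer(n_columns), depth_max = depth_max,
                 depth_step = depth_step, track = track,
                 bottom_depth = rep_len(as.numeric(bottom_depth), n_columns),
                 noise_floor_db = noise_floor_db, seed = as.integer(seed)),
            class = "echogram_config")
}

#' Scattering-layer specification
#'
#' One simulated sound-scattering layer or fish-school stratum. The layer is
#' Gaussian in linear backscatter around a centre depth that switches between
#' `depth_day` and `depth_night` with the sun's altitude, emulating diel
#' vertical migration. `sv_mean_db` must lie inside the trophic band of its
#' group (plankton `[-80, -65)` dB, fish `[-65, -20)` dB) so that the emitted
#' cells carry the band signature the thresholding classifier expects.
#'
#' @param group `"plankton"` or `"fish"`.
#' @param sv_mean_db peak mean volume backscattering strength, dB.
#' @param sv_sd_db cell-to-cell standard deviation of the peak level, dB.
#' @param depth_day,depth_night layer centre depths by day and by night, m.
#' @param thickness Gaussian scale (sigma) of the vertical profile, m; the
#'   profile is truncated at +/- 2 thickness.
#' @param occupancy fraction of track columns the layer occupies, in `[0, 1]`.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(group = c("plankton", "fish"), sv_mean_db, sv_sd_db = 0,
                       depth_day, depth_night = depth_day, thickness,
                       occupancy = 1) {
  group <- match.arg(group)
  band <- if (group == "plankton") c(-80, -65) else c(-65, -20)
  if (sv_mean_db < band[1] || sv_mean_db >= band[2])
    stop(sprintf("%s layer sv_mean_db must lie in [%g, %g) dB",
                 group, band[1], band[2]))
  stopifnot(thickness > 0, sv_sd_db >= 0,
            occupancy >= 0, occupancy <= 1,
            depth_day >= 0, depth_night >= 0)
  structure(list(group = group, sv_mean_db = sv_mean_db, sv_sd_db = sv_sd_db,
                 depth_day = depth_day, depth_night = depth_night,
                 thickness = thickness, occupancy = occupancy),
            class = "layer_spec")
}

#' Generate a synthetic echogram with ground truth
#'
#' Places each layer's backscatter on the grid: the vertical profile is
#' Gaussian in linear sv (so echo-integration adds contributions linearly)
#' centred on `depth_day` when the sun is above the horizon at the column's
#' position/time and on `depth_night` otherwise, truncated at +/- 2 thickness.
#' Per-cell dB noise of `sv_sd_db` is added to the peak level; contributions
#' that fall below the group band floor are dropped and values are capped just
#' under the band ceiling, so every emitted layer cell carries its group's
#' Sv signature. Contributions mix additively in the linear domain on top of
#' the noise floor.
#'
#' @param config an [echogram_config()].
#' @param layers list of [layer_spec()] objects (possibly empty).
#' @param classes echo-class table from [echo_classes()] used for the band
#'   floors/ceilings.
#'
#' @return A list with
#'   \item{echogram}{the generated [echogram()].}
#'   \item{truth}{ground truth: `layers` (per-layer parameters plus the true
#'     backscatter-weighted position), `columns` (per layer x column: occupancy
#'     and the centre depth used), and `masks` (per layer, a logical matrix of
#'     cells the layer wrote).}
#' @export
generate_echogram <- function(config, layers = list(), classes = echo_classes()) {
  stopifnot(inherits(config, "echogram_config"))
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_spec")))
  validate_classes(classes)

  depths <- seq(config$depth_step / 2, config$depth_max, by = config$depth_step)
  nd <- length(depths)
  nc <- config$n_columns
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (max(l$depth_day, l$depth_night) + l$thickness > config$depth_max)
      stop(sprintf("layer %d (%s): centre depth + thickness exceeds depth_max (%g m)",
                   i, l$group, config$depth_max))
  }

  alt <- solar_altitude(config$track$lat, config$track$lon, config$track$time)
  lin <- matrix(10^(config$noise_floor_db / 10), nd, nc)

  truth_layers <- NULL
  truth_columns <- NULL
  masks <- list()
  with_seed(config$seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      band_name <- if (l$group == "plankton") "PG" else "PFG"
      band <- classes[classes$name == band_name, ]
      centre <- ifelse(alt > 0, l$depth_day, l$depth_night)
      occ <- stats::runif(nc) < l$occupancy

      dz <- outer(depths, centre, "-")                       # nd x nc
      prof <- exp(-dz^2 / (2 * l$thickness^2))
      prof[abs(dz) > 2 * l$thickness] <- 0
      noise <- if (l$sv_sd_db > 0) matrix(stats::rnorm(nd * nc, 0, l$sv_sd_db), nd, nc) else 0
      cell_db <- l$sv_mean_db + noise + 10 * log10(prof)     # -Inf where prof == 0
      cell_db <- pmin(cell_db, band$sv_high - 1e-6)
      mask <- sweep(cell_db >= band$sv_low, 2, occ, "&")
      add <- 10^(cell_db / 10) * mask
      lin <- lin + add

      colw <- colSums(add) * config$depth_step
      pos_lat <- if (sum(colw) > 0) sum(colw * config$track$lat) / sum(colw) else NA_real_
      pos_lon <- if (sum(colw) > 0) sum(colw * config$track$lon) / sum(colw) else NA_real_
      truth_layers <- rbind(truth_layers, data.frame(
        layer = i, group = l$group, class = band_name,
        sv_mean_db = l$sv_mean_db, depth_day = l$depth_day,
        depth_night = l$depth_night, thickness = l$thickness,
        occupancy = l$occupancy, lat = pos_lat, lon = pos_lon,
        stringsAsFactors = FALSE))
      truth_columns <- rbind(truth_columns, data.frame(
        layer = i, column = seq_len(nc), occupied = occ,
        centre_depth = centre, solar_altitude = alt,
        stringsAsFactors = FALSE))
      masks[[i]] <- mask
    }
  })

  eg <- echogram(10 * log10(lin), depths, config$track$time,
                 config$track$lat, config$track$lon, config$bottom_depth,
                 depth_step = config$depth_step)
  list(echogram = eg,
       truth = list(layers = truth_layers, columns = truth_columns,
                    masks = masks))
}

#' Write ground truth as a flat CSV
#'
#' @param truth the `truth` element returned by [generate_echogram()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  df <- merge(truth$columns,
              truth$layers[, c("layer", "group", "lat", "lon")],
              by = "layer")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Monthly environmental series configuration
#'
#' Deterministic skeleton plus noise for a monthly satellite-style series:
#' `mean_level + seasonal sinusoid + linear trend + iid Gaussian noise`. The
#' trend accrues at `trend_per_decade / 120` per month.
#'
#' @param variable `"SST"` (deg C), `"UW"` (m s^-1) or `"SSC"` (mg m^-3).
#' @param n_years number of years (>= 2); the series has `12 * n_years` months.
#' @param mean_level long-term mean, variable units.
#' @param seasonal_amplitude amplitude of the annual sinusoid, variable units.
#' @param trend_per_decade linear trend, variable units per 10 years.
#' @param noise_sd iid Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param start_year calendar year of the first January (default 1995).
#' @param area optional area label carried through (`"north"`/`"south"`).
#' @return An object of class `env_series_config`.
#' @export
env_series_config <- function(variable = c("SST", "UW", "SSC"), n_years,
                              mean_level, seasonal_amplitude = 0,
                              trend_per_decade = 0, noise_sd = 0, seed = 1L,
                              start_year = 1995, area = NA_character_) {
  variable <- match.arg(variable)
  stopifnot(n_years >= 2, noise_sd >= 0)
  structure(list(variable = variable, n_years = as.integer(n_years),
                 mean_level = mean_level,
                 seasonal_amplitude = seasonal_amplitude,
                 trend_per_decade = trend_per_decade, noise_sd = noise_sd,
                 seed = as.integer(seed), start_year = as.integer(start_year),
                 area = area),
            class = "env_series_config")
}

#' Generate a monthly environmental series
#'
#' @param config an [env_series_config()].
#' @return Data frame with columns `variable`, `area`, `year`, `month`,
#'   `value`; reproducible under a fixed seed.
#' @examples
#' cfg <- env_series_config("SST", n_years = 2, mean_level = 21,
#'                          seasonal_amplitude = 3, trend_per_decade = 0.3,
#'                          noise_sd = 0.2, seed = 7)
#' head(generate_env_series(cfg))
#' @export
generate_env_series <- function(config) {
  stopifnot(inherits(config, "env_series_config"))
  n <- 12L * config$n_years
  i <- seq_len(n) - 1
  skeleton <- config$mean_level +
    config$seasonal_amplitude * sin(2 * pi * i / 12) +
    (config$trend_per_decade / 120) * i
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed, stats::rnorm(n, 0, config$noise_sd))
  } else {
    0
  }
  data.frame(variable = config$variable, area = config$area,
             year = config$start_year + i %/% 12L,
             month = as.integer(i %% 12L + 1L),
             value = skeleton + noise,
             stringsAsFactors = FALSE)
}
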
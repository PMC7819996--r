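#' Default synthetic survey specification
#'
#' The survey emulated by the default pipeline run: thirteen annual
#' upwelling-season (mid-November) cruises, one meridional transect in each of
#' the areas north and south of Cap Blanc, over the continental shelf. Each
#' transect has 60 along-track cells spread over 48 hours so both day and
#' night are sampled. Two strata populate the water column: a diel-migrating
#' plankton scattering layer (deep by day, near-surface by night) and a
#' non-migrating pelagic fish stratum occupying a quarter of the track, with
#' peak levels placed inside the respective trophic Sv bands and scaled so
#' fish backscatter integrates to roughly ten times the plankton backscatter,
#' the abundance ratio typical of upwelling pelagic ecosystems.
#'
#' @param drift_lat_per_year optional northward drift (degrees per year) of
#'   both transects' positions, for displacement-recovery experiments
#'   (default 0: stationary).
#' @return A list understood by [run_pipeline()].
#' @export
default_survey_spec <- function(drift_lat_per_year = 0) {
  list(
    areas = list(
      north = list(lat_start = 21.0, lat_end = 22.0, lon_start = -17.4,
                   lon_end = -17.0),
      south = list(lat_start = 14.0, lat_end = 15.0, lon_start = -17.6,
                   lon_end = -17.2)),
    n_columns = 60,
    duration_hours = 48,
    start_month = 11, start_day = 15, start_hour = 6,
    depth_max = 100, depth_step = 1, bottom_depth = 95,
    noise_floor_db = -100,
    drift_lat_per_year = drift_lat_per_year,
    position_jitter_deg = 0.02,
    layers = list(
      layer_spec("plankton", sv_mean_db = -74, sv_sd_db = 1.5,
                 depth_day = 60, depth_night = 15, thickness = 5,
                 occupancy = 1),
      layer_spec("fish", sv_mean_db = -59, sv_sd_db = 2,
                 depth_day = 30, depth_night = 30, thickness = 5,
                 occupancy = 0.25)))
}

#' Default environmental-series specification
#'
#' Monthly satellite-style series per variable and area over the 1995-2015
#' window, with seasonal cycles, linear trends and noise chosen to emulate the
#' region: surface warming in both areas (stronger in the south), increasing
#' upwelling-favourable wind north of Cap Blanc but stable wind south of it,
#' and chlorophyll increasing in the north while declining in the south, with
#' larger anomaly amplitudes south of Cap Blanc.
#'
#' @return Named list of parameter lists, one per variable x area.
#' @export
default_env_spec <- function() {
  list(
    SST_north = list(variable = "SST", area = "north", mean_level = 20.5,
                     seasonal_amplitude = 3, trend_per_decade = 0.325,
                     noise_sd = 0.2),
    SST_south = list(variable = "SST", area = "south", mean_level = 25.5,
                     seasonal_amplitude = 3.5, trend_per_decade = 0.375,
                     noise_sd = 0.45),
    UW_north = list(variable = "UW", area = "north", mean_level = 6.5,
                    seasonal_amplitude = 2.5, trend_per_decade = 0.5,
                    noise_sd = 1.5),
    UW_south = list(variable = "UW", area = "south", mean_level = 5,
                    seasonal_amplitude = 2, trend_per_decade = 0,
                    noise_sd = 1.2),
    SSC_north = list(variable = "SSC", area = "north", mean_level = 2,
                     seasonal_amplitude = 1, trend_per_decade = 0.3,
                     noise_sd = 0.5),
    SSC_south = list(variable = "SSC", area = "south", mean_level = 5,
                     seasonal_amplitude = 2.5, trend_per_decade = -1,
                     noise_sd = 1.8))
}

#' Pipeline run configuration
#'
#' Bundles every analysis parameter with the survey and environment
#' generators. All defaults are the study's stated values: Sv bands
#' -80/-65/-20 dB, 0.1 nmi ESDUs, 10 m surface offset, 10-150 m shelf,
#' Cap Blanc at 20.77 deg N, +/-18 deg twilight band.
#'
#' @param seed master integer seed; every stage seed derives from it.
#' @param years survey years (default 1995-2004, 2006, 2011, 2015).
#' @param survey survey specification, see [default_survey_spec()].
#' @param env environmental specification, see [default_env_spec()].
#' @param sv_bands echo classes from [echo_classes()].
#' @param esdu_length_nmi,surface_offset_m echo-integration settings.
#' @param shelf_min_m,shelf_max_m continental-shelf bottom-depth limits.
#' @param cap_blanc_lat north/south boundary latitude.
#' @param diel_threshold_deg twilight half-width, degrees.
#' @param log_offset offset in the log10 transform of DVM profiles.
#' @param env_trend_granularity series fed to the environmental trend test:
#'   `"monthly_anomaly"` (default), `"monthly_value"` or `"annual_mean"`.
#' @param env_start_year,env_n_years window of the environmental series.
#' @param out_dir optional output directory for CSV/JSON products.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       years = c(1995:2004, 2006, 2011, 2015),
                       survey = default_survey_spec(),
                       env = default_env_spec(),
                       sv_bands = echo_classes(),
                       esdu_length_nmi = 0.1,
                       surface_offset_m = 10,
                       shelf_min_m = 10,
                       shelf_max_m = 150,
                       cap_blanc_lat = 20.77,
                       diel_threshold_deg = 18,
                       log_offset = 1,
                       env_trend_granularity = c("monthly_anomaly",
                                                 "monthly_value",
                                                 "annual_mean"),
                       env_start_year = 1995,
                       env_n_years = 21,
                       out_dir = NULL) {
  env_trend_granularity <- match.arg(env_trend_granularity)
  structure(list(seed = as.integer(seed), years = years, survey = survey,
                 env = env, sv_bands = sv_bands,
                 esdu_length_nmi = esdu_length_nmi,
                 surface_offset_m = surface_offset_m,
                 shelf_min_m = shelf_min_m, shelf_max_m = shelf_max_m,
                 cap_blanc_lat = cap_blanc_lat,
                 diel_threshold_deg = diel_threshold_deg,
                 log_offset = log_offset,
                 env_trend_granularity = env_trend_granularity,
                 env_start_year = env_start_year, env_n_years = env_n_years,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys override [run_config()] defaults
#' (scalar parameters only; survey/env specifications come from the defaults
#' or from R code).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- c("seed", "years", "esdu_length_nmi", "surface_offset_m",
               "shelf_min_m", "shelf_max_m", "cap_blanc_lat",
               "diel_threshold_deg", "log_offset", "env_trend_granularity",
               "env_start_year", "env_n_years", "out_dir")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0)
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}

#' Validate a run configuration
#'
#' Checks every field against its constraint; never throws.
#'
#' @param config a [run_config()].
#' @return Character vector of issues, empty when the config is well-formed.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config, "run_config")) {
    return("config must be created with run_config()")
  }
  tryCatch(validate_classes(config$sv_bands),
           error = function(e) add(paste0("sv_bands: ", conditionMessage(e))))
  if (!is.numeric(config$esdu_length_nmi) || config$esdu_length_nmi <= 0)
    add("esdu_length_nmi: must be a positive number")
  if (!is.numeric(config$surface_offset_m) || config$surface_offset_m < 0)
    add("surface_offset_m: must be non-negative")
  if (config$shelf_min_m > config$shelf_max_m)
    add("shelf limits: shelf_min_m must not exceed shelf_max_m")
  if (!is.numeric(config$cap_blanc_lat) ||
      config$cap_blanc_lat < -90 || config$cap_blanc_lat > 90)
    add("cap_blanc_lat: must be a latitude in [-90, 90]")
  if (!is.numeric(config$diel_threshold_deg) ||
      config$diel_threshold_deg < 0 || config$diel_threshold_deg > 90)
    add("diel_threshold_deg: must be in [0, 90]")
  if (!is.numeric(config$log_offset) || config$log_offset <= 0)
    add("log_offset: must be positive")
  if (length(config$years) < 1) add("years: at least one survey year required")
  if (!is.numeric(config$seed) || is.na(config$seed))
    add("seed: must be an integer")
  ok_layers <- tryCatch({
    stopifnot(all(vapply(config$survey$layers, inherits, logical(1), "layer_spec")))
    TRUE
  }, error = function(e) FALSE)
  if (!ok_layers) add("survey$layers: must be a list of layer_spec objects")
  if (!is.numeric(config$env_n_years) || config$env_n_years < 2)
    add("env_n_years: need at least 2 years for a climatology")
  issues
}

simulate_survey_year <- function(config, year, area_name) {
  sp <- config$survey
  a <- sp$areas[[area_name]]
  seed <- derive_seed(config$seed, year, area_name)
  drift <- (sp$drift_lat_per_year %||% 0) * (year - min(config$years))
  jitter_sd <- sp$position_jitter_deg %||% 0
  jit <- if (jitter_sd > 0) {
    with_seed(derive_seed(seed, 7L), stats::rnorm(1, 0, jitter_sd))
  } else 0
  tr <- survey_track(sp$n_columns,
                     a$lat_start + drift + jit, a$lat_end + drift + jit,
                     a$lon_start, a$lon_end,
                     ISOdatetime(year, sp$start_month, sp$start_day,
                                 sp$start_hour, 0, 0, tz = "UTC"),
                     sp$duration_hours)
  cfg <- echogram_config(sp$n_columns, sp$depth_max, tr, sp$bottom_depth,
                         depth_step = sp$depth_step,
                         noise_floor_db = sp$noise_floor_db, seed = seed)
  generate_echogram(cfg, sp$layers, classes = config$sv_bands)
}

annual_daynight_means <- function(df, group) {
  wcol <- paste0("nasc_", group)
  day <- stats::aggregate(df[[wcol]][df$diel == "day"],
                          by = list(year = df$year[df$diel == "day"]), FUN = mean)
  night <- stats::aggregate(df[[wcol]][df$diel == "night"],
                            by = list(year = df$year[df$diel == "night"]), FUN = mean)
  m <- merge(day, night, by = "year", suffixes = c("_day", "_night"))
  names(m) <- c("year", "day", "night")
  m[order(m$year), ]
}

#' Run the full analysis pipeline
#'
#' Simulates the configured surveys and environmental series, then runs every
#' analysis stage in order: echo-integration into 0.1-nmi ESDUs, shelf
#' restriction, diel labelling and transition removal, the Cap Blanc area
#' split, annual biomass-weighted barycenters and their displacement trends,
#' day/night DVM profiles with annual Wilcoxon tests and the annual
#' delta-DVM trend, annual acoustic abundance series with anomalies and
#' trends, and environmental climatology/anomaly/trend analysis. Outputs are
#' identical under identical configuration and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (overrides `config$out_dir`); when given,
#'   all tables are written as CSV plus a consolidated `report.json`.
#' @return An object of class `run_report`: a list of result tables (see the
#'   package vignette for the layout).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  issues <- validate_config(config)
  if (length(issues) > 0)
    stop(paste(c("invalid configuration:", issues), collapse = "\n  "))
  out_dir <- out_dir %||% config$out_dir

  # ---- stage: simulate + integrate
  tabs <- list()
  for (y in config$years) for (a in names(config$survey$areas)) {
    gen <- tryCatch(simulate_survey_year(config, y, a),
                    error = function(e) stop(sprintf(
                      "stage simulate failed for %d/%s: %s", y, a,
                      conditionMessage(e)), call. = FALSE))
    et <- tryCatch(suppressMessages(
      integrate_esdu(gen$echogram, config$esdu_length_nmi,
                     config$surface_offset_m, config$sv_bands)),
      error = function(e) stop(sprintf(
        "stage integrate failed for %d/%s: %s", y, a,
        conditionMessage(e)), call. = FALSE))
    tabs[[paste(y, a, sep = "_")]] <- et
  }
  x <- bind_esdu_tables(tabs)
  n_integrated <- nrow(x$esdu)
  message(sprintf("integrated %d ESDUs over %d year-area surveys",
                  n_integrated, length(tabs)))

  # ---- stage: filters and labels
  x <- suppressMessages(shelf_filter(x, config$shelf_min_m, config$shelf_max_m))
  n_shelf <- nrow(x$esdu)
  x <- label_diel(x, config$diel_threshold_deg)
  x <- suppressMessages(drop_transitions(x))
  n_diel <- nrow(x$esdu)
  x <- split_area(x, config$cap_blanc_lat)
  message(sprintf("%d ESDUs on shelf, %d after transition removal (north %d / south %d)",
                  n_shelf, n_diel, sum(x$esdu$area == "north"),
                  sum(x$esdu$area == "south")))

  groups <- c("PG", "PFG", "TG")
  areas <- sort(unique(x$esdu$area))

  # ---- stage: barycenters
  bary <- barycenters(x, groups = groups)
  bary_trends <- barycenter_trend(bary)

  # ---- stage: DVM
  dvm_profiles <- NULL
  dvm_wilcoxon <- NULL
  dvm_trends <- NULL
  for (a in areas) for (g in c("PG", "PFG")) {
    prof <- dvm_profile(x, g, area = a, log_transform = TRUE,
                        log_offset = config$log_offset)
    dvm_profiles <- rbind(dvm_profiles, as.data.frame(prof))
    dn <- annual_daynight_means(x$esdu[x$esdu$area == a, ], g)
    wt <- wilcoxon_daynight(dn$day, dn$night, paired = TRUE)
    dvm_wilcoxon <- rbind(dvm_wilcoxon, data.frame(
      area = a, group = g, w = wt$statistic, p_value = wt$p_value,
      n = wt$n, stringsAsFactors = FALSE))
    # annual delta-DVM (mean over depth bins of night - day, per year)
    yrs <- sort(unique(x$esdu$year[x$esdu$area == a]))
    ann_delta <- vapply(yrs, function(yy) {
      sel <- x$esdu$area == a & x$esdu$year == yy
      py <- tryCatch(dvm_profile(replace_esdu_frame(x, x$esdu[sel, ]), g,
                                 log_transform = FALSE),
                     error = function(e) NULL)
      if (is.null(py)) NA_real_ else mean(py$delta_dvm)
    }, numeric(1))
    okyy <- !is.na(ann_delta)
    tr <- spearman_trend(ann_delta[okyy], yrs[okyy])
    dvm_trends <- rbind(dvm_trends, data.frame(
      area = a, group = g, rho = tr$rho, p_value = tr$p_value, n = tr$n,
      stringsAsFactors = FALSE))
  }

  # ---- stage: acoustic annual series
  acoustic_series <- NULL
  acoustic_trends <- NULL
  for (a in areas) for (g in groups) {
    as_ <- acoustic_annual_series(x, g, area = a)
    acoustic_series <- rbind(acoustic_series,
                             cbind(area = a, group = g, as_$series))
    if (!is.null(as_$trend)) {
      acoustic_trends <- rbind(acoustic_trends, data.frame(
        area = a, group = g, rho = as_$trend$rho,
        p_value = as_$trend$p_value, n = as_$trend$n,
        stringsAsFactors = FALSE))
    }
  }

  # ---- stage: environment
  env_series <- NULL
  env_anomalies <- NULL
  env_trends <- NULL
  for (nm in names(config$env)) {
    e <- config$env[[nm]]
    cfg <- env_series_config(e$variable, n_years = config$env_n_years,
                             mean_level = e$mean_level,
                             seasonal_amplitude = e$seasonal_amplitude,
                             trend_per_decade = e$trend_per_decade,
                             noise_sd = e$noise_sd,
                             seed = derive_seed(config$seed, "env", nm),
                             start_year = config$env_start_year,
                             area = e$area)
    ser <- generate_env_series(cfg)
    ser$smoothed <- smooth_13term(ser$value)
    anom <- ser
    anom$value <- anomalies(ser$value, ser$month)
    tr <- switch(config$env_trend_granularity,
      monthly_anomaly = spearman_trend(anom$value, seq_len(nrow(anom))),
      monthly_value = spearman_trend(ser$value, seq_len(nrow(ser))),
      annual_mean = {
        am <- stats::aggregate(ser$value, by = list(year = ser$year), FUN = mean)
        spearman_trend(am$x, am$year)
      })
    env_series <- rbind(env_series, ser)
    env_anomalies <- rbind(env_anomalies, anom)
    env_trends <- rbind(env_trends, data.frame(
      variable = e$variable, area = e$area, rho = tr$rho,
      p_value = tr$p_value, n = tr$n,
      granularity = config$env_trend_granularity, stringsAsFactors = FALSE))
  }

  cfg_file <- tempfile(fileext = ".txt")
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  report <- structure(list(
    seed = config$seed,
    config_hash = config_hash,
    package_version = as.character(utils::packageVersion("echotrends")),
    counts = list(esdus_integrated = n_integrated, esdus_on_shelf = n_shelf,
                  esdus_after_transition_removal = n_diel,
                  esdus_north = sum(x$esdu$area == "north"),
                  esdus_south = sum(x$esdu$area == "south")),
    esdu = x$esdu,
    barycenters = bary,
    barycenter_trends = bary_trends,
    dvm_profiles = dvm_profiles,
    dvm_wilcoxon = dvm_wilcoxon,
    dvm_trends = dvm_trends,
    acoustic_series = acoustic_series,
    acoustic_trends = acoustic_trends,
    env_series = env_series,
    env_anomalies = env_anomalies,
    env_trends = env_trends), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d ESDUs (config %s)\n", x$seed,
              nrow(x$esdu), substr(x$config_hash, 1, 8)))
  cat("environmental trends:\n")
  print(x$env_trends, row.names = FALSE)
  cat("day/night Wilcoxon:\n")
  print(x$dvm_wilcoxon, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes every table of a [run_pipeline()] report as CSV plus a consolidated
#' `report.json`; output is byte-identical for identical reports.
#'
#' @param report a `run_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  esdu <- report$esdu
  esdu$time <- format(esdu$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  wr(esdu, "esdu")
  wr(report$barycenters, "barycenters")
  wr(report$barycenter_trends, "barycenter_trends")
  wr(report$dvm_profiles, "dvm_profiles")
  wr(report$dvm_wilcoxon, "dvm_wilcoxon")
  wr(report$dvm_trends, "dvm_trends")
  wr(report$acoustic_series, "acoustic_series")
  wr(report$acoustic_trends, "acoustic_trends")
  wr(report$env_series, "env_series")
  wr(report$env_anomalies, "env_anomalies")
  wr(report$env_trends, "env_trends")
  summary <- list(seed = report$seed, config_hash = report$config_hash,
                  package_version = report$package_version,
                  counts = report$counts,
                  env_trends = report$env_trends,
                  acoustic_trends = report$acoustic_trends,
                  barycenter_trends = report$barycenter_trends,
                  dvm_wilcoxon = report$dvm_wilcoxon,
                  dvm_trends = report$dvm_trends)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
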
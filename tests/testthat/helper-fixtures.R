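# Shared fixture builders; everything is generated in code.

# Echogram whose columns are packed within a fraction of one ESDU, so the
# whole grid integrates as a single unit.
tiny_echogram <- function(sv, depths, bottom = 200, t0 = "2000-11-15 12:00:00") {
  sv <- as.matrix(sv)
  nc <- ncol(sv)
  # ~1.1 m spacing along the equatorial meridian: entire track << 0.1 nmi
  echogram(sv, depths,
           times = as.POSIXct(t0, tz = "UTC") + seq_len(nc),
           lats = seq(0, by = 1e-5, length.out = nc),
           lons = rep(0, nc),
           bottom_depth = bottom, depth_step = 1)
}

# Hand-built esdu_table for tests that exercise the diel/profile machinery
# without running the integrator.
make_esdu_table <- function(esdu, by_depth) {
  structure(list(esdu = esdu, by_depth = by_depth, classes = echo_classes(),
                 esdu_length_nmi = 0.1, surface_offset_m = 10),
            class = "esdu_table")
}

# One-year migrating-layer survey used by several DVM tests.
migrating_survey <- function(seed = 3, n_columns = 40, fish = TRUE) {
  tr <- survey_track(n_columns, 14.0, 14.5, -17.4, -17.4,
                     "2000-11-15 06:00:00", 36)
  layers <- list(layer_spec("plankton", -74, 1.5, depth_day = 60,
                            depth_night = 15, thickness = 5))
  if (fish) {
    layers <- c(layers, list(layer_spec("fish", -59, 2, depth_day = 30,
                                        depth_night = 30, thickness = 5,
                                        occupancy = 0.25)))
  }
  cfg <- echogram_config(n_columns, 100, tr, 95, seed = seed)
  gen <- generate_echogram(cfg, layers)
  et <- suppressMessages(integrate_esdu(gen$echogram))
  et <- label_diel(et)
  et <- suppressMessages(drop_transitions(et))
  list(gen = gen, et = et)
}

# Small, fast run configuration for pipeline tests.
small_run_config <- function(seed = 1, ...) {
  sp <- default_survey_spec(...)
  sp$n_columns <- 30
  sp$duration_hours <- 30
  run_config(seed = seed, years = c(1995, 1999, 2003, 2007, 2011),
             survey = sp, env_n_years = 5)
}
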
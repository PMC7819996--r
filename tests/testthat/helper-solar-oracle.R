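# Independent solar-position reference: the Michalsky (1988) Astronomical
# Almanac low-precision algorithm (valid 1950-2050), geometric elevation
# without refraction. Implemented separately from the package's NOAA-equation
# path.
michalsky_altitude <- function(lat, lon, time) {
  time <- as.POSIXct(time, tz = "UTC")
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  delta <- jd - 2451545.0
  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * d2r
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) * d2r
  oblqec <- (23.439 - 0.0000004 * delta) * d2r
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))
  hour <- (as.numeric(time) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * delta + hour) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * d2r
  ha <- lmst - ra
  el <- asin(sin(dec) * sin(lat * d2r) + cos(dec) * cos(lat * d2r) * cos(ha))
  el / d2r
}
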
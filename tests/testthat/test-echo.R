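test_that("classify_sv applies the half-open trophic bands", {
  expect_equal(classify_sv(-70), "PG")
  expect_equal(classify_sv(-65), "PFG")   # boundary belongs to the high class
  expect_equal(classify_sv(-80), "PG")    # band floor is inclusive
  expect_equal(classify_sv(-80.0001), "excluded")
  expect_equal(classify_sv(-20), "excluded")
  expect_equal(classify_sv(c(-70, -50, -90, NA)),
               c("PG", "PFG", "excluded", NA))
})

test_that("overlapping component classes are a configuration error", {
  bad <- data.frame(name = c("PG", "PFG"), sv_low = c(-80, -70),
                    sv_high = c(-65, -20))
  expect_error(classify_sv(-70, bad), "overlapping")
  expect_error(validate_classes(data.frame(name = "PG", sv_low = -60,
                                           sv_high = -70)),
               "sv_low < sv_high")
})

test_that("a single in-band cell integrates to the closed-form NASC", {
  # one 1-m bin at -70 dB below the surface offset:
  # 4 pi 1852^2 * 10^-7 * 1 m ~= 4.310 m^2 nmi^-2
  eg <- tiny_echogram(matrix(-70), depths = 20)
  et <- integrate_esdu(eg)
  expect_equal(et$esdu$nasc_PG, 4 * pi * 1852^2 * 1e-7, tolerance = 1e-12)
  expect_equal(et$esdu$nasc_PFG, 0)
  expect_equal(et$esdu$nasc_TG, et$esdu$nasc_PG)
})

test_that("a noise-floor echogram integrates to zero in every class", {
  eg <- tiny_echogram(matrix(-100, 30, 4), depths = seq(0.5, 29.5))
  et <- integrate_esdu(eg)
  expect_equal(et$esdu$nasc_PG, 0)
  expect_equal(et$esdu$nasc_PFG, 0)
  expect_equal(et$esdu$nasc_TG, 0)
})

test_that("TG equals PG + PFG and per-depth NASC sums to the totals", {
  set.seed(11)
  for (k in 1:10) {
    sv <- matrix(runif(25 * 5, -95, -15), 25, 5)
    eg <- tiny_echogram(sv, depths = seq(0.5, 24.5), bottom = 22)
    et <- integrate_esdu(eg)
    expect_equal(et$esdu$nasc_TG, et$esdu$nasc_PG + et$esdu$nasc_PFG,
                 tolerance = 1e-9)
    for (cl in c("PG", "PFG", "TG")) {
      bd <- et$by_depth[et$by_depth$class == cl, ]
      expect_equal(sum(bd$nasc), et$esdu[[paste0("nasc_", cl)]],
                   tolerance = 1e-12)
    }
  }
})

test_that("echo-integration is additive in the linear domain", {
  set.seed(12)
  # both grids and their cell-wise linear sums stay inside the PG band
  a <- matrix(runif(40, -79, -71), 10, 4)
  b <- matrix(runif(40, -79, -71), 10, 4)
  s <- 10 * log10(10^(a / 10) + 10^(b / 10))
  depths <- seq(10.5, 19.5)
  n_a <- integrate_esdu(tiny_echogram(a, depths))$esdu
  n_b <- integrate_esdu(tiny_echogram(b, depths))$esdu
  n_s <- integrate_esdu(tiny_echogram(s, depths))$esdu
  expect_equal(n_s$nasc_PG, n_a$nasc_PG + n_b$nasc_PG, tolerance = 1e-9)
  expect_equal(n_s$nasc_TG, n_a$nasc_TG + n_b$nasc_TG, tolerance = 1e-9)
})

test_that("raising an in-band cell strictly increases its class NASC and
           cells above the surface offset never contribute", {
  set.seed(13)
  sv <- matrix(runif(60, -79, -30), 15, 4)
  depths <- seq(0.5, 14.5)
  eg <- tiny_echogram(sv, depths)
  base <- integrate_esdu(eg)$esdu

  sv2 <- sv
  sv2[12, 2] <- sv2[12, 2] + 1   # depth 11.5 m, below the offset
  up <- integrate_esdu(tiny_echogram(sv2, depths))$esdu
  cl <- classify_sv(sv[12, 2])
  expect_gt(up[[paste0("nasc_", cl)]], base[[paste0("nasc_", cl)]])

  sv3 <- sv
  sv3[1:9, ] <- runif(36, -60, -30)  # depths 0.5..8.5 m, all above 10 m offset
  shallow <- integrate_esdu(tiny_echogram(sv3, depths))$esdu
  expect_equal(shallow$nasc_PG, base$nasc_PG, tolerance = 1e-12)
  expect_equal(shallow$nasc_PFG, base$nasc_PFG, tolerance = 1e-12)
})

test_that("integrate_esdu matches the brute-force cell loop on small grids", {
  set.seed(14)
  for (k in 1:8) {
    nd <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    sv <- matrix(runif(nd * nc, -95, -15), nd, nc)
    sv[sample(length(sv), 2)] <- NA
    depths <- seq(10.5, by = 1, length.out = nd)
    bottom <- runif(1, 11, 16)
    eg <- tiny_echogram(sv, depths, bottom = bottom)
    et <- integrate_esdu(eg)
    orc <- oracle_nasc(eg)
    expect_equal(et$esdu$nasc_PG, orc$PG, tolerance = 1e-12)
    expect_equal(et$esdu$nasc_PFG, orc$PFG, tolerance = 1e-12)
    expect_equal(et$esdu$nasc_TG, orc$TG, tolerance = 1e-12)
  }
})

test_that("ESDU NASC is the mean of per-column integrals (ping-density
           independent)", {
  sv1 <- matrix(-70, 5, 2)
  sv2 <- matrix(-70, 5, 6)   # same field sampled with more pings
  depths <- seq(15.5, 19.5)
  n1 <- integrate_esdu(tiny_echogram(sv1, depths))$esdu$nasc_PG
  n2 <- integrate_esdu(tiny_echogram(sv2, depths))$esdu$nasc_PG
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("track segmentation honours ESDU length and the half-length rule
           for the trailing partial", {
  # along the equator: 0.021 nmi column spacing, ESDU length 0.1 nmi
  mk <- function(nc) {
    step_deg <- 0.021 * 1852 / 111319.4908   # metres per degree of equator
    echogram(matrix(-70, 15, nc), seq(10.5, 24.5),
             times = as.POSIXct("2000-06-01", tz = "UTC") + seq_len(nc) * 10,
             lats = rep(0, nc),
             lons = seq(0, by = step_deg, length.out = nc),
             bottom_depth = 100)
  }
  # 10 columns span 0.189 nmi: one full ESDU + 0.089 nmi partial (kept)
  et <- suppressMessages(integrate_esdu(mk(10)))
  expect_equal(nrow(et$esdu), 2)
  expect_equal(sum(et$esdu$n_columns), 10)
  # 12 columns span 0.231 nmi: trailing 0.031 nmi (< half length) dropped
  expect_message(et2 <- integrate_esdu(mk(12)), "partial ESDU")
  expect_equal(nrow(et2$esdu), 2)
  expect_equal(sum(et2$esdu$n_columns), 10)
  # 13 columns span 0.252 nmi: trailing 0.052 nmi (>= half length) kept
  et3 <- suppressMessages(integrate_esdu(mk(13)))
  expect_equal(nrow(et3$esdu), 3)
  expect_equal(sum(et3$esdu$n_columns), 13)
})

test_that("shelf_filter keeps the closed 10-150 m bottom-depth interval", {
  df <- data.frame(esdu_index = 1:4, bottom_depth = c(5, 10, 150, 151))
  out <- suppressMessages(shelf_filter(df))
  expect_equal(out$esdu_index, c(2, 3))
  expect_equal(nrow(suppressMessages(shelf_filter(df[0, ]))), 0)
  all100 <- data.frame(esdu_index = 1:3, bottom_depth = 100)
  expect_equal(nrow(suppressMessages(shelf_filter(all100))), 3)
})

test_that("missing-heavy ESDUs are flagged and NA cells contribute zero", {
  sv <- matrix(-70, 10, 2)
  sv[1:6, ] <- NA
  depths <- seq(10.5, 19.5)
  et <- integrate_esdu(tiny_echogram(sv, depths))
  expect_true(et$esdu$flagged)
  expect_equal(et$esdu$missing_frac, 0.6)
  expect_equal(et$esdu$nasc_PG, 4 * pi * 1852^2 * 4e-7, tolerance = 1e-12)
})

test_that("echograms round-trip through the long-format CSV", {
  set.seed(15)
  sv <- matrix(runif(40, -90, -30), 10, 4)
  sv[3, 2] <- NA
  eg <- echogram(sv, seq(0.5, 9.5),
                 times = as.POSIXct("2001-03-05 08:00:00", tz = "UTC") + (0:3) * 60,
                 lats = c(14.1, 14.2, 14.3, 14.4),
                 lons = c(-17.4, -17.41, -17.42, -17.43),
                 bottom_depth = c(50, 60, 70, 80))
  path <- tempfile(fileext = ".csv")
  write_echogram(eg, path)
  back <- read_echogram(path)
  expect_equal(back$sv, eg$sv)
  expect_equal(back$depths, eg$depths)
  expect_equal(as.numeric(back$times), as.numeric(eg$times))
  expect_equal(back$lats, eg$lats)
  expect_equal(back$lons, eg$lons)
  expect_equal(back$bottom_depth, eg$bottom_depth)
})
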
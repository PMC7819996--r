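#' Split records at the Cap Blanc boundary
#'
#' Tags every record `"north"` or `"south"` of the faunistic boundary
#' latitude. The boundary itself belongs to the north area by convention.
#'
#' @param x an `esdu_table` or data frame with a `lat` column.
#' @param boundary_lat boundary latitude in degrees (default 20.77, Cap Blanc).
#' @return The object with an `area` column added.
#' @export
split_area <- function(x, boundary_lat = 20.77) {
  df <- esdu_frame(x)
  df$area <- ifelse(df$lat >= boundary_lat, "north", "south")
  replace_esdu_frame(x, df)
}

#' Biomass-weighted barycenter of acoustic density
#'
#' The annual centre of gravity of one echo class in one area: the mean
#' position of the records weighted by their (linear, untransformed) NASC,
#' \deqn{X_a = \sum_i B_{ai} X_{ai} / \sum_i B_{ai},}
#' and likewise for longitude, where \eqn{B_{ai}} is the record's NASC.
#' Weighted means of raw degrees are used; over a shelf-scale domain the
#' planar approximation error is negligible.
#'
#' @param x an `esdu_table` or data frame with `lat`, `lon`, `year`, `area`
#'   and `nasc_<group>` columns.
#' @param year survey year.
#' @param area `"north"` or `"south"` (or `NULL` to pool).
#' @param group echo class name (`"PG"`, `"PFG"`, `"TG"`).
#' @return One-row data frame: `year`, `area`, `group`, `lat`, `lon`,
#'   `total_weight`.
#' @examples
#' recs <- data.frame(lat = c(14, 16), lon = c(-17, -17), year = 2000,
#'                    area = "south", nasc_PG = c(1, 1))
#' barycenter(recs, 2000, "south", "PG")
#' @export
barycenter <- function(x, year, area, group) {
  df <- esdu_frame(x)
  wcol <- paste0("nasc_", group)
  if (is.null(df[[wcol]])) stop(sprintf("no NASC column for class %s", group))
  sel <- df$year == year
  if (!is.null(area)) {
    if (is.null(df$area)) stop("records carry no area labels; run split_area() first")
    sel <- sel & df$area == area
  }
  df <- df[sel, , drop = FALSE]
  if (nrow(df) == 0)
    stop(sprintf("no records in stratum %s/%s/%s", year, area %||% "all", group))
  w <- df[[wcol]]
  if (all(w == 0))
    stop(sprintf("no biomass in stratum %s/%s/%s", year, area %||% "all", group))
  data.frame(year = year, area = area %||% "all", group = group,
             lat = sum(w * df$lat) / sum(w),
             lon = sum(w * df$lon) / sum(w),
             total_weight = sum(w),
             stringsAsFactors = FALSE)
}

#' All annual barycenters
#'
#' Computes [barycenter()] for every year x area x group stratum present in
#' the records; strata with zero biomass are skipped.
#'
#' @param x records as in [barycenter()] (area labels required).
#' @param groups echo classes to include.
#' @return Data frame of barycenters, one row per stratum.
#' @export
barycenters <- function(x, groups = c("PG", "PFG", "TG")) {
  df <- esdu_frame(x)
  if (is.null(df$area)) stop("records carry no area labels; run split_area() first")
  out <- NULL
  for (a in sort(unique(df$area))) for (g in groups) {
    for (y in sort(unique(df$year[df$area == a]))) {
      b <- tryCatch(barycenter(df, y, a, g), error = function(e) NULL)
      out <- rbind(out, b)
    }
  }
  out
}

#' Trend in barycenter position
#'
#' Spearman rank trend of the yearly barycenter latitude and longitude against
#' survey year, one test per coordinate per area x group stratum. Needs at
#' least 4 yearly positions per stratum for the rank test to be meaningful.
#'
#' @param b barycenter table from [barycenters()] (or one stratum's rows).
#' @return Data frame: `area`, `group`, `coord` (`"lat"`/`"lon"`), `rho`,
#'   `p_value`, `n`.
#' @export
barycenter_trend <- function(b) {
  stopifnot(is.data.frame(b), all(c("year", "lat", "lon") %in% names(b)))
  if (is.null(b$area)) b$area <- "all"
  if (is.null(b$group)) b$group <- "all"
  out <- NULL
  for (a in unique(b$area)) for (g in unique(b$group[b$area == a])) {
    s <- b[b$area == a & b$group == g, , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    if (nrow(s) < 4)
      stop(sprintf("stratum %s/%s has %d yearly barycenters; rank trend test needs at least 4",
                   a, g, nrow(s)))
    for (coord in c("lat", "lon")) {
      tr <- spearman_trend(s[[coord]], s$year)
      out <- rbind(out, data.frame(area = a, group = g, coord = coord,
                                   rho = tr$rho, p_value = tr$p_value,
                                   n = tr$n, stringsAsFactors = FALSE))
    }
  }
  out
}
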
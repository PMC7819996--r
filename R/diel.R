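#' Diel label from solar altitude
#'
#' `"day"` when the sun is more than `threshold_deg` above the horizon,
#' `"night"` when more than `threshold_deg` below, `"transition"` in the
#' twilight band between. The default 18 degrees is the astronomical twilight
#' band, within which migrating organisms are moving and acoustic densities
#' are biased.
#'
#' @param altitude solar altitude in degrees (see [solar_altitude()]).
#' @param threshold_deg half-width of the twilight band, degrees (default 18).
#' @return Character vector of `"day"`, `"night"`, `"transition"`.
#' @export
diel_label_from_altitude <- function(altitude, threshold_deg = 18) {
  stopifnot(threshold_deg >= 0, threshold_deg <= 90)
  ifelse(altitude > threshold_deg, "day",
         ifelse(altitude < -threshold_deg, "night", "transition"))
}

#' Label ESDU records day/night/transition
#'
#' Computes the solar altitude at each record's position and time and sets the
#' `diel` field accordingly.
#'
#' @param x an `esdu_table` (or data frame with `lat`, `lon`, `time`).
#' @param threshold_deg twilight half-width in degrees (default 18).
#' @return The object with its `diel` column filled in.
#' @export
label_diel <- function(x, threshold_deg = 18) {
  df <- esdu_frame(x)
  alt <- solar_altitude(df$lat, df$lon, df$time)
  df$solar_altitude <- alt
  df$diel <- diel_label_from_altitude(alt, threshold_deg)
  replace_esdu_frame(x, df)
}

#' Remove twilight-transition records
#'
#' Drops records labelled `"transition"` so that dawn/dusk migration does not
#' bias day-vs-night comparisons; reports how many records were removed.
#'
#' @param x an `esdu_table` or data frame with a `diel` column.
#' @return Filtered object; warns if nothing survives.
#' @export
drop_transitions <- function(x) {
  df <- esdu_frame(x)
  if (is.null(df$diel)) stop("records carry no diel labels; run label_diel() first")
  keep <- df$diel != "transition"
  message(sprintf("dropped %d transition record(s), %d remain",
                  sum(!keep), sum(keep)))
  if (!any(keep)) warning("all records are in the diel transition band")
  replace_esdu_frame(x, df[keep, , drop = FALSE])
}

#' Day-vs-night vertical profile (DVM profile)
#'
#' Averages per-1-m-bin NASC separately over day and over night records for
#' one echo class, and forms the diel difference
#' `delta_dvm = mean_night - mean_day` per bin. Positive values near the
#' surface indicate normal diel vertical migration (organisms shallower at
#' night); the inverse pattern marks type-II DVM. When `log_transform` is on,
#' additional columns hold means of `log10(NASC + log_offset)` (the offset
#' admits zero-NASC bins); `delta_dvm` is always computed from the
#' untransformed means.
#'
#' @param x an `esdu_table` with diel labels set (transitions are ignored).
#' @param group echo class name (`"PG"`, `"PFG"` or `"TG"`).
#' @param area optional area label to restrict to (requires [split_area()]).
#' @param log_transform add log10-transformed mean profiles (default `TRUE`).
#' @param log_offset offset inside the log (default 1).
#' @return Data frame of class `dvm_profile`: `group`, `area`, `depth_bin`,
#'   `mean_day`, `mean_night`, `delta_dvm`, `n_day`, `n_night` (and
#'   `log_mean_day`, `log_mean_night` when transformed).
#' @export
dvm_profile <- function(x, group, area = NULL, log_transform = TRUE,
                        log_offset = 1) {
  stopifnot(inherits(x, "esdu_table"))
  df <- x$esdu
  if (!is.null(area)) {
    if (is.null(df$area)) stop("records carry no area labels; run split_area() first")
    df <- df[df$area == area, , drop = FALSE]
  }
  df <- df[df$diel %in% c("day", "night"), , drop = FALSE]
  n_day <- sum(df$diel == "day")
  n_night <- sum(df$diel == "night")
  if (n_day == 0) stop("no day records in this stratum")
  if (n_night == 0) stop("no night records in this stratum")

  bd <- x$by_depth[x$by_depth$class == group &
                     x$by_depth$esdu_index %in% df$esdu_index, , drop = FALSE]
  if (nrow(bd) == 0) stop(sprintf("no depth-resolved NASC for class %s", group))
  bd$diel <- df$diel[match(bd$esdu_index, df$esdu_index)]

  mean_by <- function(v) {
    m <- tapply(v, list(bd$depth_bin, bd$diel), mean)
    m[order(as.numeric(rownames(m))), , drop = FALSE]
  }
  raw <- mean_by(bd$nasc)
  bins <- as.numeric(rownames(raw))
  out <- data.frame(group = group, area = area %||% "all",
                    depth_bin = bins,
                    mean_day = unname(raw[, "day"]),
                    mean_night = unname(raw[, "night"]),
                    stringsAsFactors = FALSE)
  out$delta_dvm <- out$mean_night - out$mean_day
  if (log_transform) {
    lg <- mean_by(log10(bd$nasc + log_offset))
    out$log_mean_day <- unname(lg[, "day"])
    out$log_mean_night <- unname(lg[, "night"])
  }
  out$n_day <- n_day
  out$n_night <- n_night
  class(out) <- c("dvm_profile", "data.frame")
  out
}

#' Wilcoxon day-vs-night test
#'
#' Tests whether acoustic abundance differs between day and night. In paired
#' mode the reported statistic is the smaller of the two signed-rank sums
#' (the convention under which a perfectly one-sided sample gives w = 0),
#' with zero differences dropped and mid-ranks for ties; the p-value is exact
#' for n <= 25 without ties, and uses the continuity-corrected normal
#' approximation otherwise. Unpaired mode is the rank-sum (Mann-Whitney)
#' equivalent.
#'
#' @param day_values,night_values numeric vectors; equal length when paired.
#' @param paired use the signed-rank test on `night - day` (default `TRUE`).
#' @return List with `statistic`, `p_value`, `n` (non-zero pairs, or the two
#'   group sizes when unpaired) and `method`.
#' @examples
#' wilcoxon_daynight(day_values = 1:8, night_values = 1:8 + 2)
#' @export
wilcoxon_daynight <- function(day_values, night_values, paired = TRUE) {
  if (paired) {
    if (length(day_values) != length(night_values))
      stop("paired mode needs day and night vectors of equal length")
    ok <- !is.na(day_values) & !is.na(night_values)
    d <- night_values[ok] - day_values[ok]
    if (length(d) < 3) stop("need at least 3 day-night pairs")
    nz <- d[d != 0]
    n <- length(nz)
    if (n == 0) {
      warning("all day-night differences are zero; no diel signal")
      return(list(statistic = 0, p_value = 1, n = 0,
                  method = "wilcoxon signed-rank (degenerate)"))
    }
    r <- rank(abs(nz))
    V <- sum(r[nz > 0])
    W <- min(V, n * (n + 1) / 2 - V)
    clean <- !any(duplicated(abs(nz))) && all(d != 0)
    if (n <= 25 && clean) {
      # tie-free: exact signed-rank distribution
      p <- suppressWarnings(stats::wilcox.test(night_values[ok], day_values[ok],
                                               paired = TRUE, exact = TRUE,
                                               correct = TRUE)$p.value)
      method <- "exact wilcoxon signed-rank"
    } else if (n <= 14) {
      # ties or zeros at small n: enumerate all 2^n sign assignments with
      # mid-ranks, two-sided
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      Vs <- as.vector(signs %*% r)
      p <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
      method <- "exact sign-enumeration wilcoxon signed-rank"
    } else {
      p <- suppressWarnings(stats::wilcox.test(night_values[ok], day_values[ok],
                                               paired = TRUE, exact = FALSE,
                                               correct = TRUE)$p.value)
      method <- "normal-approximation wilcoxon signed-rank"
    }
    list(statistic = W, p_value = p, n = n, method = method)
  } else {
    day_values <- day_values[!is.na(day_values)]
    night_values <- night_values[!is.na(night_values)]
    if (length(day_values) < 3 || length(night_values) < 3)
      stop("need at least 3 values per diel stratum")
    ht <- suppressWarnings(stats::wilcox.test(night_values, day_values,
                                              correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = c(day = length(day_values), night = length(night_values)),
         method = "wilcoxon rank-sum")
  }
}
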
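#' Monthly climatology
#'
#' Long-term mean per calendar month over all years; missing values are
#' excluded from their month's mean. A calendar month with no data in any year
#' is an error, since anomalies for that month would be undefined.
#'
#' @param values numeric series.
#' @param months calendar month (1-12) of each value.
#' @return Numeric vector of length 12 (January first).
#' @export
monthly_climatology <- function(values, months) {
  stopifnot(length(values) == length(months))
  months <- as.integer(months)
  if (any(is.na(months)) || any(months < 1 | months > 12))
    stop("months must be integers in 1..12")
  cnt <- tabulate(months[!is.na(values)], nbins = 12)
  if (any(cnt == 0))
    stop(sprintf("no data in any year for calendar month(s): %s",
                 paste(month.name[cnt == 0], collapse = ", ")))
  clim <- tapply(values, factor(months, levels = 1:12), mean, na.rm = TRUE)
  as.numeric(clim)
}

#' Climatological anomalies
#'
#' Deviation of each value from the long-term mean of its calendar month;
#' missing values propagate as missing. For a complete series the anomalies of
#' each calendar month sum to zero.
#'
#' @param values numeric series.
#' @param months calendar month (1-12) of each value.
#' @param climatology 12 monthly means (default: computed from the series).
#' @return Numeric vector of anomalies, same length as `values`.
#' @export
anomalies <- function(values, months,
                      climatology = monthly_climatology(values, months)) {
  stopifnot(length(climatology) == 12, length(values) == length(months))
  values - climatology[as.integer(months)]
}

#' Centred 13-term annual smoother
#'
#' The classical centred 13-month moving average for monthly data: weights
#' 1/24 at the two extreme months and 1/12 at the eleven central ones. This
#' filter has a zero at period 12, so it annihilates the annual cycle and
#' passes the low-frequency (trend) component; a straight line is reproduced
#' exactly. The first and last six points are undefined (`NA`).
#'
#' @param values numeric monthly series of length >= 13.
#' @return Smoothed series, same length, `NA` at the ends.
#' @export
smooth_13term <- function(values) {
  if (length(values) < 13) stop("13-term smoother needs at least 13 points")
  w <- c(1, rep(2, 11), 1) / 24
  as.numeric(stats::filter(values, w, sides = 2))
}

#' Spearman rank trend test
#'
#' Rank correlation of a series against observation time, the standard
#' non-parametric test for monotone trend. `rho` is the product-moment
#' correlation of the mid-ranks of the values with the ranks of the times.
#' The two-sided p-value is exact (full permutation enumeration) for n <= 9
#' and uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2
#' degrees of freedom above. Missing values are dropped pairwise. A constant
#' series has no defined rank correlation and is reported as `rho = 0`,
#' `p = 1` with `degenerate = TRUE`.
#'
#' @param values numeric series.
#' @param times observation times (numeric or `POSIXct`), strictly increasing.
#' @return List with `rho`, `p_value`, `n`, `degenerate`, `method`.
#' @examples
#' spearman_trend(c(1.1, 1.9, 3.2, 3.9, 5.4), 1:5)
#' @export
spearman_trend <- function(values, times) {
  if (inherits(times, "POSIXct")) times <- as.numeric(times)
  stopifnot(length(values) == length(times))
  ok <- !is.na(values) & !is.na(times)
  v <- values[ok]
  tt <- times[ok]
  n <- length(v)
  if (n < 4) stop("trend test needs at least 4 points")
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing")
  if (length(unique(v)) == 1) {
    return(list(rho = 0, p_value = 1, n = n, degenerate = TRUE,
                method = "degenerate (constant series)"))
  }
  rv <- rank(v)
  rt <- rank(tt)
  rho <- stats::cor(rv, rt)
  if (n <= 9) {
    p <- spearman_exact_p(rv, rt, rho)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(1, p), n = n, degenerate = FALSE,
       method = method)
}

# Exact two-sided permutation p-value: share of the n! equally likely value
# orderings whose |rho| is at least the observed one.
spearman_exact_p <- function(rv, rt, rho_obs) {
  perms <- permutations_of(length(rv))
  rhos <- apply(perms, 1, function(p) stats::cor(rv[p], rt))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  res <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      res[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  res
}

#' Annual acoustic abundance series with anomalies
#'
#' Per-year mean NASC of one echo class in one area, its anomaly relative to
#' the all-year mean (surveys are annual and same-season, so the annual
#' climatology degenerates to a single long-term mean), and the Spearman trend
#' of the yearly means when at least 4 survey years are present.
#'
#' @param x an `esdu_table` or data frame with `year` and `nasc_<group>`
#'   columns (and `area` when `area` is given).
#' @param group echo class name.
#' @param area optional area restriction.
#' @return List with `series` (data frame `year`, `mean_nasc`, `anomaly`) and
#'   `trend` (a [spearman_trend()] result, or `NULL` below 4 years).
#' @export
acoustic_annual_series <- function(x, group, area = NULL) {
  df <- esdu_frame(x)
  wcol <- paste0("nasc_", group)
  if (is.null(df[[wcol]])) stop(sprintf("no NASC column for class %s", group))
  if (!is.null(area)) {
    if (is.null(df$area)) stop("records carry no area labels; run split_area() first")
    df <- df[df$area == area, , drop = FALSE]
  }
  if (length(unique(df$year)) < 2)
    stop("annual series needs records from at least 2 survey years")
  agg <- stats::aggregate(df[[wcol]], by = list(year = df$year), FUN = mean)
  names(agg)[2] <- "mean_nasc"
  agg <- agg[order(agg$year), ]
  agg$anomaly <- agg$mean_nasc - mean(agg$mean_nasc)
  trend <- if (nrow(agg) >= 4) spearman_trend(agg$mean_nasc, agg$year) else NULL
  list(series = agg, trend = trend)
}
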
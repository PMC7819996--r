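#' Trophic echo classes (Sv thresholding bands)
#'
#' Defines the half-open volume-backscattering-strength bands used to split
#' backscatter into trophic groups: `PG` (plankton group, low acoustic trophic
#' level), `PFG` (pelagic fish group, high acoustic trophic level) and `TG`
#' (all trophic levels, the union band). Membership is by
#' `sv_low <= Sv < sv_high`; values below the union floor or at/above its
#' ceiling are excluded from echo-integration altogether.
#'
#' @param pg numeric length-2, dB bounds of the plankton band
#'   (default `c(-80, -65)`).
#' @param pfg numeric length-2, dB bounds of the pelagic-fish band
#'   (default `c(-65, -20)`).
#'
#' @return A data frame with columns `name`, `sv_low`, `sv_high`; the `TG` row
#'   spans the union of the two component bands.
#' @export
echo_classes <- function(pg = c(-80, -65), pfg = c(-65, -20)) {
  stopifnot(length(pg) == 2, length(pfg) == 2,
            is.finite(pg), is.finite(pfg), pg[1] < pg[2], pfg[1] < pfg[2])
  data.frame(name = c("PG", "PFG", "TG"),
             sv_low = c(pg[1], pfg[1], min(pg[1], pfg[1])),
             sv_high = c(pg[2], pfg[2], max(pg[2], pfg[2])),
             stringsAsFactors = FALSE)
}

validate_classes <- function(classes) {
  need <- c("name", "sv_low", "sv_high")
  if (!is.data.frame(classes) || !all(need %in% names(classes)))
    stop("`classes` must be a data frame with columns name, sv_low, sv_high")
  if (any(classes$sv_low >= classes$sv_high))
    stop("each echo class must have sv_low < sv_high")
  comp <- classes[classes$name != "TG", , drop = FALSE]
  if (nrow(comp) >= 2) {
    for (i in seq_len(nrow(comp) - 1)) for (j in (i + 1):nrow(comp)) {
      if (comp$sv_low[i] < comp$sv_high[j] && comp$sv_low[j] < comp$sv_high[i])
        stop(sprintf("configuration error: overlapping echo classes %s and %s",
                     comp$name[i], comp$name[j]))
    }
  }
  invisible(classes)
}

#' Classify Sv values into echo classes
#'
#' Assigns each Sv value to the component (non-`TG`) class whose half-open band
#' `[sv_low, sv_high)` contains it; values outside every band are `"excluded"`.
#' With the default bands, -80 dB is the faintest plankton cell, -65 dB the
#' faintest fish cell, and anything at or above -20 dB (or below -80 dB) is
#' dropped from integration.
#'
#' @param sv numeric vector of volume backscattering strengths, dB re 1 m^-1.
#' @param classes class table from [echo_classes()]; overlapping component
#'   classes are a configuration error.
#'
#' @return Character vector: class name or `"excluded"` (`NA` Sv stays `NA`).
#' @examples
#' classify_sv(c(-70, -65, -80.0001, -19))
#' @export
classify_sv <- function(sv, classes = echo_classes()) {
  validate_classes(classes)
  comp <- classes[classes$name != "TG", , drop = FALSE]
  out <- rep(NA_character_, length(sv))
  miss <- is.na(sv)
  out[!miss] <- "excluded"
  for (i in seq_len(nrow(comp))) {
    hit <- !miss & sv >= comp$sv_low[i] & sv < comp$sv_high[i]
    out[hit] <- comp$name[i]
  }
  out
}

#' Gridded echogram object
#'
#' Container for a depth-by-column grid of volume backscattering strength with
#' per-column navigation metadata. Depth values are bin centres in metres and
#' must be strictly ascending; columns are ordered along the survey track.
#'
#' @param sv numeric matrix, depth bins (rows) by along-track columns; dB.
#'   `NA` marks missing cells.
#' @param depths numeric vector of bin-centre depths (m), one per row.
#' @param times per-column timestamps (`POSIXct` UTC or ISO 8601 strings).
#' @param lats,lons per-column positions, decimal degrees.
#' @param bottom_depth per-column bottom depth (m); scalar recycled.
#' @param depth_step vertical bin size (m); inferred from `depths` when `NULL`
#'   and more than one bin is present, else 1.
#'
#' @return An object of class `echogram`.
#' @export
echogram <- function(sv, depths, times, lats, lons, bottom_depth,
                     depth_step = NULL) {
  sv <- as.matrix(sv)
  times <- as_utc_time(times)
  nc <- ncol(sv)
  if (nrow(sv) != length(depths))
    stop("nrow(sv) must equal length(depths)")
  if (length(times) != nc || length(lats) != nc || length(lons) != nc)
    stop("times, lats and lons must have one value per echogram column")
  if (length(depths) > 1 && any(diff(depths) <= 0))
    stop("depths must be strictly ascending")
  if (any(lats < -90 | lats > 90)) stop("latitude outside [-90, 90]")
  if (any(lons < -180 | lons > 180)) stop("longitude outside [-180, 180]")
  if (is.unsorted(times)) stop("times must be non-decreasing along the track")
  bottom_depth <- rep_len(as.numeric(bottom_depth), nc)
  if (is.null(depth_step)) {
    depth_step <- if (length(depths) > 1) stats::median(diff(depths)) else 1
  }
  stopifnot(depth_step > 0)
  structure(list(sv = sv, depths = as.numeric(depths), times = times,
                 lats = as.numeric(lats), lons = as.numeric(lons),
                 bottom_depth = bottom_depth, depth_step = depth_step),
            class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %d depth bins x %d columns, depths %.1f-%.1f m, %s to %s\n",
              nrow(x$sv), ncol(x$sv), min(x$depths), max(x$depths),
              format(min(x$times), "%Y-%m-%d %H:%M", tz = "UTC"),
              format(max(x$times), "%Y-%m-%d %H:%M", tz = "UTC")))
  invisible(x)
}

#' Write / read an echogram as long-format CSV
#'
#' Plain-text serialisation: one row per (column, depth) cell with the column's
#' navigation metadata repeated. Numeric fields are written with 17 significant
#' digits and timestamps at whole-second ISO 8601 resolution, so a round trip
#' reproduces the object exactly (for whole-second input times).
#'
#' @param eg an [echogram()].
#' @param path file path for the CSV.
#' @return `write_echogram` returns `path` invisibly; `read_echogram` returns
#'   the reconstructed `echogram`.
#' @export
write_echogram <- function(eg, path) {
  stopifnot(inherits(eg, "echogram"))
  nc <- ncol(eg$sv)
  nd <- nrow(eg$sv)
  num <- function(x) formatC(x, digits = 17, format = "g")
  df <- data.frame(
    column = rep(seq_len(nc), each = nd),
    depth = rep(num(eg$depths), nc),
    sv = num(as.vector(eg$sv)),
    time = rep(format(eg$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), each = nd),
    lat = rep(num(eg$lats), each = nd),
    lon = rep(num(eg$lons), each = nd),
    bottom_depth = rep(num(eg$bottom_depth), each = nd),
    depth_step = num(eg$depth_step),
    stringsAsFactors = FALSE)
  df$sv[is.na(as.vector(eg$sv))] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_echogram
#' @export
read_echogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- sort(unique(df$column))
  df <- df[order(df$column, df$depth), ]
  first <- df[!duplicated(df$column), ]
  depths <- sort(unique(df$depth))
  sv <- matrix(df$sv, nrow = length(depths), ncol = length(cols))
  echogram(sv, depths,
           times = as.POSIXct(first$time, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ"),
           lats = first$lat, lons = first$lon,
           bottom_depth = first$bottom_depth,
           depth_step = first$depth_step[1])
}

#' Echo-integrate an echogram into per-ESDU NASC
#'
#' Splits the track into elementary sampling distance units (ESDUs) of
#' `esdu_length_nmi` nautical miles by cumulative great-circle distance, and
#' for each ESDU and echo class computes the Nautical Area Scattering
#' Coefficient
#' \deqn{NASC = 4\pi \cdot 1852^2 \sum_{bins} s_v \, \Delta z \quad [m^2\,nmi^{-2}],}
#' with linear \eqn{s_v = 10^{S_v/10}}, averaged over the ESDU's columns so the
#' result is an areal density independent of ping rate. Cells shallower than
#' `surface_offset_m`, deeper than the column's bottom depth, missing, or
#' outside the class band contribute zero. Depth is re-binned to 1-m bins by
#' bin centre (`depth_bin` = lower edge of the metre the centre falls in), so
#' 1-m input grids pass through unchanged.
#'
#' The ESDU position and time are those of its midpoint column. A trailing
#' partial ESDU is kept only if it covers at least half the nominal length
#' (a track shorter than one ESDU is always kept as a single unit). An ESDU
#' with more than half of its in-water cells missing is flagged.
#'
#' @param eg an [echogram()].
#' @param esdu_length_nmi ESDU length in nautical miles (default 0.1).
#' @param surface_offset_m near-surface exclusion depth in metres (default 10),
#'   guarding against bubble contamination.
#' @param classes echo-class table from [echo_classes()].
#'
#' @return An object of class `esdu_table`: a list with
#'   \item{esdu}{one row per ESDU: `esdu_index`, `time`, `lat`, `lon`,
#'     `bottom_depth`, `year`, `diel` (initially `"unset"`), `n_columns`,
#'     `missing_frac`, `flagged`, and `nasc_PG`, `nasc_PFG`, `nasc_TG`.}
#'   \item{by_depth}{long format: `esdu_index`, `depth_bin` (m, lower edge of
#'     the 1-m bin), `class`, `nasc`; per-ESDU sums over bins equal the wide
#'     columns.}
#' @export
integrate_esdu <- function(eg, esdu_length_nmi = 0.1, surface_offset_m = 10,
                           classes = echo_classes()) {
  stopifnot(inherits(eg, "echogram"), esdu_length_nmi > 0, surface_offset_m >= 0)
  validate_classes(classes)
  NMI <- 1852
  K <- 4 * pi * NMI^2
  sv <- eg$sv
  nc <- ncol(sv)
  depths <- eg$depths
  if (max(depths) < surface_offset_m)
    stop("echogram does not reach below the surface offset")

  # ---- ESDU segmentation by cumulative great-circle distance
  if (nc > 1) {
    seg <- geosphere::distGeo(cbind(eg$lons[-nc], eg$lats[-nc]),
                              cbind(eg$lons[-1], eg$lats[-1]))
    d <- c(0, cumsum(seg))
  } else {
    d <- 0
  }
  L <- esdu_length_nmi * NMI
  dmax <- max(d)
  idx <- if (dmax > 0) pmin(floor(d / L), floor((dmax - 1e-9) / L)) else rep(0L, nc)
  rem <- dmax - floor((dmax - 1e-9) / L) * L
  if (dmax >= L && rem > 1e-9 && rem < 0.5 * L) {
    drop_idx <- max(idx)
    n_drop <- sum(idx == drop_idx)
    message(sprintf("dropping trailing partial ESDU (%.0f%% of nominal length, %d column(s))",
                    100 * rem / L, n_drop))
    keep_cols <- idx != drop_idx
  } else {
    keep_cols <- rep(TRUE, nc)
  }

  # ---- per-cell linear contributions, masked
  lin <- 10^(sv / 10) * eg$depth_step
  lin[is.na(sv)] <- 0
  in_water <- outer(depths >= surface_offset_m, rep(TRUE, nc)) &
    outer(depths, eg$bottom_depth, FUN = "<=")
  base <- lin * in_water
  bin <- floor(depths)
  ubins <- sort(unique(bin[depths >= surface_offset_m]))

  class_mats <- list()
  for (i in seq_len(nrow(classes))) {
    lo <- classes$sv_low[i]; hi <- classes$sv_high[i]
    band <- !is.na(sv) & sv >= lo & sv < hi
    bs <- rowsum(base * band, bin)                       # all bins x columns
    class_mats[[classes$name[i]]] <- bs[as.character(ubins), , drop = FALSE]
  }

  esdu_ids <- sort(unique(idx[keep_cols]))
  if (length(esdu_ids) == 0) stop("no complete ESDU on this track")
  cols_of <- lapply(esdu_ids, function(e) which(idx == e & keep_cols))

  per_class_by_bin <- lapply(class_mats, function(M) {
    vapply(cols_of, function(cl) K * rowMeans(M[, cl, drop = FALSE]),
           numeric(length(ubins)))
  })
  # vapply collapses to a vector when there is a single depth bin
  per_class_by_bin <- lapply(per_class_by_bin, function(M)
    matrix(M, nrow = length(ubins)))

  mid <- vapply(cols_of, function(cl) cl[ceiling(length(cl) / 2)], integer(1))
  missing_frac <- vapply(cols_of, function(cl) {
    iw <- in_water[, cl, drop = FALSE]
    if (!any(iw)) return(0)
    sum(is.na(sv[, cl, drop = FALSE]) & iw) / sum(iw)
  }, numeric(1))

  n_esdu <- length(esdu_ids)
  esdu <- data.frame(
    esdu_index = seq_len(n_esdu),
    time = eg$times[mid],
    lat = eg$lats[mid],
    lon = eg$lons[mid],
    bottom_depth = eg$bottom_depth[mid],
    year = time_year(eg$times[mid]),
    diel = "unset",
    n_columns = lengths(cols_of),
    missing_frac = missing_frac,
    flagged = missing_frac > 0.5,
    stringsAsFactors = FALSE)
  for (nm in names(per_class_by_bin))
    esdu[[paste0("nasc_", nm)]] <- colSums(per_class_by_bin[[nm]])

  by_depth <- do.call(rbind, lapply(names(per_class_by_bin), function(nm) {
    data.frame(esdu_index = rep(seq_len(n_esdu), each = length(ubins)),
               depth_bin = rep(ubins, n_esdu),
               class = nm,
               nasc = as.vector(per_class_by_bin[[nm]]),
               stringsAsFactors = FALSE)
  }))
  by_depth <- by_depth[order(by_depth$esdu_index, by_depth$class, by_depth$depth_bin), ]
  rownames(by_depth) <- NULL

  structure(list(esdu = esdu, by_depth = by_depth, classes = classes,
                 esdu_length_nmi = esdu_length_nmi,
                 surface_offset_m = surface_offset_m),
            class = "esdu_table")
}

#' @export
print.esdu_table <- function(x, ...) {
  cat(sprintf("<esdu_table> %d ESDUs (%.2f nmi each), %d depth bins, classes: %s\n",
              nrow(x$esdu), x$esdu_length_nmi,
              length(unique(x$by_depth$depth_bin)),
              paste(unique(x$by_depth$class), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.esdu_table <- function(x, ...) x$esdu

esdu_frame <- function(x) {
  if (inherits(x, "esdu_table")) x$esdu else as.data.frame(x)
}

replace_esdu_frame <- function(x, df) {
  if (inherits(x, "esdu_table")) {
    x$esdu <- df
    x$by_depth <- x$by_depth[x$by_depth$esdu_index %in% df$esdu_index, ]
    rownames(x$by_depth) <- NULL
    x
  } else {
    df
  }
}

#' Restrict records to the continental shelf
#'
#' Keeps ESDU records whose bottom depth lies in the closed interval
#' `[min_depth_m, max_depth_m]`; record order is preserved and the number of
#' removed records is reported.
#'
#' @param x an `esdu_table` (or a data frame with a `bottom_depth` column).
#' @param min_depth_m,max_depth_m shelf limits in metres (defaults 10 and 150).
#' @return Filtered object of the same type.
#' @export
shelf_filter <- function(x, min_depth_m = 10, max_depth_m = 150) {
  stopifnot(min_depth_m <= max_depth_m)
  df <- esdu_frame(x)
  keep <- df$bottom_depth >= min_depth_m & df$bottom_depth <= max_depth_m
  message(sprintf("shelf filter [%g, %g] m: kept %d of %d records",
                  min_depth_m, max_depth_m, sum(keep), length(keep)))
  replace_esdu_frame(x, df[keep, , drop = FALSE])
}

#' Merge several ESDU tables into one
#'
#' Re-numbers `esdu_index` sequentially so indices stay unique; all tables must
#' share the same echo classes and integration settings.
#'
#' @param ... `esdu_table` objects (or a single list of them).
#' @return A combined `esdu_table`.
#' @export
bind_esdu_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && !inherits(tabs[[1]], "esdu_table")) tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1, all(vapply(tabs, inherits, logical(1), "esdu_table")))
  offset <- 0L
  for (i in seq_along(tabs)) {
    tabs[[i]]$esdu$esdu_index <- tabs[[i]]$esdu$esdu_index + offset
    tabs[[i]]$by_depth$esdu_index <- tabs[[i]]$by_depth$esdu_index + offset
    if (nrow(tabs[[i]]$esdu) > 0) offset <- max(tabs[[i]]$esdu$esdu_index)
  }
  out <- tabs[[1]]
  out$esdu <- do.call(rbind, lapply(tabs, `[[`, "esdu"))
  out$by_depth <- do.call(rbind, lapply(tabs, `[[`, "by_depth"))
  rownames(out$esdu) <- rownames(out$by_depth) <- NULL
  out
}
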
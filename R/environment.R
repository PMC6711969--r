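# Daily covariate construction: calendar-day aggregation of environmental
# series, unique daily tag counts, pairwise temperature differences, IDW
# temperature surfaces, and assembly of the model-ready covariate table.
#
# Day boundary: local standard time at a fixed UTC offset (default -5,
# no daylight saving), so every day is exactly 24 h.

#' Calendar day of UTC instants at a fixed local offset
#' @param time POSIXct (UTC).
#' @param utc_offset hours to add to UTC before binning (default -5).
#' @return Date vector.
#' @export
local_day <- function(time, utc_offset = -5) {
  as.Date(floor((as.numeric(time) + utc_offset * 3600) / 86400),
          origin = "1970-01-01")
}

#' Daily mean of an environmental series
#'
#' Arithmetic mean of all samples falling in each local calendar day. Days
#' inside the series' span with no samples are present with NA (missing,
#' never zero).
#'
#' @param series \code{\link{env_series}} (or data.frame with \code{time},
#'   \code{value}).
#' @param utc_offset day-boundary offset, hours (see \code{\link{local_day}}).
#' @return data.frame \code{date}, \code{value}, one row per day spanning
#'   the series.
#' @export
daily_mean <- function(series, utc_offset = -5) {
  if (!nrow(series))
    return(data.frame(date = as.Date(character()), value = numeric()))
  day <- local_day(series$time, utc_offset)
  agg <- aggregate(list(value = series$value), list(date = day), mean,
                   na.rm = TRUE)
  full <- data.frame(date = seq(min(day), max(day), by = "day"))
  out <- merge(full, agg, by = "date", all.x = TRUE)
  out[order(out$date), , drop = FALSE]
}

#' Pairwise differences between daily temperature series
#'
#' One column per unordered pair of sources, value = first minus second
#' under the fixed ordering in which the sources are supplied (list order).
#'
#' @param daily named list of daily data.frames (\code{date}, \code{value}).
#' @return data.frame with \code{date} and one \code{A_minus_B} column per
#'   pair, over the intersection of the date ranges.
#' @export
pairwise_temp_diffs <- function(daily) {
  if (length(daily) < 2) stop("need at least two daily series")
  nms <- names(daily)
  tab <- Reduce(function(a, b) merge(a, b, by = "date"),
                Map(function(d, nm) setNames(d, c("date", nm)), daily, nms))
  out <- data.frame(date = tab$date)
  for (i in seq_len(length(nms) - 1)) {
    for (j in (i + 1):length(nms)) {
      out[[paste0(nms[i], "_minus_", nms[j])]] <- tab[[nms[i]]] - tab[[nms[j]]]
    }
  }
  out
}

#' Unique daily count (UDC) of detected tags
#'
#' Number of distinct tag ids with at least one detection anywhere in the
#' array on each local calendar day, zero-filled over the array-operational
#' span.
#'
#' @param det QC-filtered detection data.frame.
#' @param span optional length-2 Date vector (operational span); defaults to
#'   the detection range.
#' @param utc_offset day-boundary offset, hours.
#' @return data.frame \code{date}, \code{UDC} (integer, no gap days).
#' @export
unique_daily_count <- function(det, span = NULL, utc_offset = -5) {
  day <- local_day(det$timestamp, utc_offset)
  if (is.null(span)) {
    if (!nrow(det)) stop("no detections and no span given")
    span <- range(day)
  }
  span <- as.Date(span)
  full <- data.frame(date = seq(span[1], span[2], by = "day"))
  if (nrow(det)) {
    keyed <- unique(data.frame(date = day, tag_id = det$tag_id))
    counts <- aggregate(list(UDC = keyed$tag_id), list(date = keyed$date),
                        function(x) length(unique(x)))
    out <- merge(full, counts, by = "date", all.x = TRUE)
  } else {
    out <- full
    out$UDC <- 0L
  }
  out$UDC[is.na(out$UDC)] <- 0L
  out$UDC <- as.integer(out$UDC)
  out[order(out$date), , drop = FALSE]
}

#' Inverse-distance-weighted temperature surface
#'
#' Interpolates point temperatures at station locations onto a regular
#' lon/lat grid with weights d^-power. A node within 1 m of a station takes
#' that station's value exactly; all interpolated values obey the maximum
#' principle (they lie within the range of the inputs).
#'
#' @param stations data.frame with \code{station_id}, \code{lon}, \code{lat}.
#' @param values named numeric vector of temperatures keyed by station_id
#'   (or unnamed, in station order).
#' @param n_grid nodes per axis (default 25).
#' @param power IDW exponent (default 2).
#' @param expand fractional bounding-box expansion (default 0.05).
#' @return data.frame \code{lon}, \code{lat}, \code{value} (long format).
#' @export
idw_interpolate <- function(stations, values, n_grid = 25, power = 2,
                            expand = 0.05) {
  if (!nrow(stations)) stop("no stations to interpolate from")
  stopifnot(power > 0)
  v <- if (!is.null(names(values))) values[stations$station_id] else values
  if (any(is.na(v))) stop("missing value for some station")
  rlon <- range(stations$lon); rlat <- range(stations$lat)
  pad_lon <- max(diff(rlon), 1e-6) * expand
  pad_lat <- max(diff(rlat), 1e-6) * expand
  g <- expand.grid(
    lon = seq(rlon[1] - pad_lon, rlon[2] + pad_lon, length.out = n_grid),
    lat = seq(rlat[1] - pad_lat, rlat[2] + pad_lat, length.out = n_grid))
  sp <- as.matrix(stations[, c("lon", "lat")])
  val <- vapply(seq_len(nrow(g)), function(i) {
    d <- geosphere::distGeo(as.matrix(g[i, , drop = FALSE]), sp)
    hit <- which(d < 1)
    if (length(hit)) return(v[hit[1]])
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, numeric(1))
  data.frame(lon = g$lon, lat = g$lat, value = val)
}

#' Assemble the daily covariate table
#'
#' Joins the unique-daily-count series to the candidate predictors on the
#' calendar day: photoperiod \code{P} and moon fraction \code{M} (computed
#' from the array location), plus every supplied daily environmental series,
#' plus pairwise differences between the temperature columns. Rows with any
#' missing predictor are flagged (column \code{incomplete}); they are kept
#' here and dropped listwise at model-fitting time.
#'
#' @param udc data.frame from \code{\link{unique_daily_count}}.
#' @param daily named list of daily data.frames (\code{date},
#'   \code{value}); names become column names (e.g. \code{HR_temp},
#'   \code{HR_discharge}, \code{sst_NH}).
#' @param lon,lat array reference location for the astronomical covariates.
#' @param temp_vars names of \code{daily} entries to difference pairwise;
#'   default: those whose name contains \code{"temp"} or \code{"sst"}.
#' @return data.frame, one row per day of the UDC span, with attribute
#'   \code{"missing_by_column"} (per-column NA counts).
#' @export
build_covariate_table <- function(udc, daily, lon, lat,
                                  temp_vars = NULL) {
  if (!nrow(udc)) stop("empty UDC series")
  if (!length(daily)) stop("no predictor series supplied")
  tab <- udc
  tab$P <- as.numeric(photoperiod(tab$date, lon, lat))
  tab$M <- moon_fraction(tab$date)
  for (nm in names(daily)) {
    d <- setNames(daily[[nm]][, c("date", "value")], c("date", nm))
    tab <- merge(tab, d, by = "date", all.x = TRUE)
  }
  if (is.null(temp_vars))
    temp_vars <- names(daily)[grepl("temp|sst", names(daily),
                                    ignore.case = TRUE)]
  if (length(temp_vars) >= 2) {
    diffs <- pairwise_temp_diffs(
      lapply(setNames(temp_vars, temp_vars),
             function(nm) setNames(daily[[nm]][, c("date", "value")],
                                   c("date", "value"))))
    tab <- merge(tab, diffs, by = "date", all.x = TRUE)
  }
  tab <- tab[order(tab$date), , drop = FALSE]
  pred_cols <- setdiff(names(tab), c("date", "UDC"))
  tab$incomplete <- !complete.cases(tab[, pred_cols, drop = FALSE])
  if (all(tab$incomplete))
    stop("no complete rows; limiting series: ",
         paste(pred_cols[colSums(is.na(tab[pred_cols])) == nrow(tab)],
               collapse = ", "))
  attr(tab, "missing_by_column") <-
    colSums(is.na(tab[, pred_cols, drop = FALSE]))
  rownames(tab) <- NULL
  tab
}

#' Drop predictors highly collinear with a preferred one
#'
#' Mirrors the practice of excluding a candidate when its squared
#' correlation with a retained predictor exceeds a threshold (default
#' r^2 > 0.8), keeping the preferred variable.
#'
#' @param table covariate table.
#' @param vars candidate predictor names.
#' @param prefer variable to keep when a conflict arises.
#' @param r2_threshold squared-correlation exclusion threshold.
#' @return character vector: \code{vars} minus exclusions, with the dropped
#'   names in attribute \code{"dropped"}.
#' @export
drop_correlated <- function(table, vars, prefer, r2_threshold = 0.8) {
  keep <- vars
  dropped <- character()
  for (v in setdiff(vars, prefer)) {
    ok <- complete.cases(table[, c(v, prefer)])
    if (sum(ok) > 2 &&
        cor(table[[v]][ok], table[[prefer]][ok])^2 > r2_threshold) {
      keep <- setdiff(keep, v)
      dropped <- c(dropped, v)
    }
  }
  attr(keep, "dropped") <- dropped
  keep
}

#' Lag of maximum cross-correlation between two daily series
#'
#' Returns the lag (days, positive = \code{x} trails \code{y}) at which the
#' Pearson correlation between \code{x[t]} and \code{y[t - lag]} is
#' greatest. Used e.g. to recover the thermal-inertia delay of river
#' temperature behind photoperiod.
#'
#' @param x,y numeric vectors on a shared daily index.
#' @param max_lag largest |lag| searched (default 60).
#' @return integer lag; attribute \code{"cor"} holds the correlation there.
#' @export
xcorr_lag <- function(x, y, max_lag = 60) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      xi <- x[(L + 1):n]; yi <- y[1:(n - L)]
    } else {
      xi <- x[1:(n + L)]; yi <- y[(1 - L):n]
    }
    ok <- complete.cases(xi, yi)
    if (sum(ok) < 10) return(NA_real_)
    cor(xi[ok], yi[ok])
  }, numeric(1))
  best <- which.max(cc)
  structure(lags[best], cor = cc[best])
}
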
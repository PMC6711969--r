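# Parsing and writing of telemetry and environmental input formats.
# All timestamps are normalized to UTC at parse time; sorting of detection
# streams is stable and total so every downstream stage sees one order.

#' Parse timestamps to UTC POSIXct
#'
#' Accepts ISO-8601 variants ("2017-01-01 00:50:00", "2017-01-01T00:50:00Z",
#' date-only) and returns POSIXct in UTC; unparseable entries become NA.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC) with NA where parsing failed.
#' @keywords internal
parse_utc <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d",
                "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M")) {
    todo <- is.na(out) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  out
}

#' Stable total ordering of a detection table
#'
#' Sorts by (tag_id, timestamp, station_id) — a total order, so no two runs
#' over the same input can disagree on record order.
#'
#' @param det detection data.frame.
#' @return the sorted data.frame, row names reset.
#' @export
sort_detections <- function(det) {
  ord <- order(det$tag_id, det$timestamp, det$station_id, method = "radix")
  out <- det[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a detection log
#'
#' Reads one record per tag detection into the pipeline's canonical detection
#' table (columns \code{timestamp} POSIXct UTC, \code{tag_id},
#' \code{station_id}, \code{sensor_temp}). Two dialects are built in: the
#' package's \code{"plain"} CSV (header
#' \code{datetime_utc,station_id,tag_id,sensor_temp}) and a \code{"receiver"}
#' export dialect (\code{Date and Time (UTC),Receiver,Transmitter,Sensor
#' Value}). A custom \code{col_map} overrides either.
#'
#' Rows whose timestamp does not parse are rejected (with their line numbers
#' recorded in the \code{"rejects"} attribute), never silently coerced.
#'
#' @param path CSV file path.
#' @param dialect \code{"plain"} or \code{"receiver"}.
#' @param col_map optional named character vector mapping canonical names
#'   (\code{timestamp}, \code{station_id}, \code{tag_id}, \code{sensor_temp})
#'   to file column names.
#' @return detection data.frame sorted by (tag_id, timestamp), with
#'   attributes \code{n_input} and \code{rejects} (data line numbers of
#'   rejected rows).
#' @export
read_detections <- function(path, dialect = c("plain", "receiver"),
                            col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("detection file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (is.null(col_map)) {
    col_map <- switch(dialect,
      plain = c(timestamp = "datetime_utc", station_id = "station_id",
                tag_id = "tag_id", sensor_temp = "sensor_temp"),
      receiver = c(timestamp = "Date and Time (UTC)", station_id = "Receiver",
                   tag_id = "Transmitter", sensor_temp = "Sensor Value"))
  }
  for (need in c("timestamp", "station_id", "tag_id")) {
    if (!(col_map[[need]] %in% names(raw)))
      stop("mandatory column missing from ", path, ": ", col_map[[need]])
  }
  ts <- parse_utc(raw[[col_map[["timestamp"]]]])
  stemp <- if (!is.na(col_map["sensor_temp"]) &&
               col_map[["sensor_temp"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[col_map[["sensor_temp"]]]]))
  else rep(NA_real_, nrow(raw))
  det <- data.frame(timestamp = ts,
                    tag_id = trimws(raw[[col_map[["tag_id"]]]]),
                    station_id = trimws(raw[[col_map[["station_id"]]]]),
                    sensor_temp = stemp,
                    stringsAsFactors = FALSE)
  bad <- which(is.na(det$timestamp) | !nzchar(det$tag_id) |
                 !nzchar(det$station_id))
  if (length(bad)) {
    message(length(bad), " rejected row(s) in ", basename(path),
            " (data lines: ", paste(head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "", ")")
    det <- det[-bad, , drop = FALSE]
  }
  det <- sort_detections(det)
  attr(det, "n_input") <- nrow(raw)
  attr(det, "rejects") <- bad
  det
}

#' Write a detection table as plain-dialect CSV
#' @param det detection data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(det, path) {
  out <- data.frame(
    datetime_utc = format(det$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    station_id = det$station_id, tag_id = det$tag_id,
    sensor_temp = det$sensor_temp)
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read station metadata
#'
#' Station CSV with columns \code{station_id,lon,lat,depth,detection_radius,
#' deploy_start,deploy_end} and optionally \code{distance_from_shore} (km).
#' One row per deployment interval; a station may have several.
#'
#' @param path CSV file path.
#' @return data.frame with POSIXct deployment bounds; coordinates validated
#'   against WGS84 ranges.
#' @export
read_stations <- function(path) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("station file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(st$lon < -180 | st$lon > 180 | st$lat < -90 | st$lat > 90))
    stop("station coordinates outside WGS84 bounds")
  if (is.null(st$detection_radius)) st$detection_radius <- 600
  if (any(st$detection_radius <= 0)) stop("detection_radius must be > 0")
  if (!is.null(st$deploy_start)) st$deploy_start <- parse_utc(st$deploy_start)
  if (!is.null(st$deploy_end))   st$deploy_end <- parse_utc(st$deploy_end)
  if (!is.null(st$deploy_start) && !is.null(st$deploy_end) &&
      any(!is.na(st$deploy_start) & !is.na(st$deploy_end) &
            st$deploy_start >= st$deploy_end))
    stop("deployment intervals must satisfy start < end")
  st
}

#' Read tag / biology metadata
#'
#' Tag CSV with columns \code{tag_id,release_date,fork_length,total_length,
#' weight}. Lengths are mm, weight kg.
#'
#' @param path CSV file path.
#' @return data.frame with \code{release_date} as Date.
#' @export
read_tags <- function(path) {
  tg <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(tg$release_date))
    tg$release_date <- as.Date(parse_utc(tg$release_date))
  if (!is.null(tg$fork_length) && !is.null(tg$total_length) &&
      any(tg$fork_length > tg$total_length, na.rm = TRUE))
    warning("fork_length exceeds total_length for some tags")
  tg
}

#' Construct an environmental time series
#'
#' @param time POSIXct (UTC) sample instants, strictly increasing.
#' @param value numeric samples.
#' @param source_id originating station/gauge code.
#' @param variable one of \code{"sst"}, \code{"river_temp"},
#'   \code{"discharge"}, \code{"bottom_temp"}.
#' @param units unit string (e.g. \code{"degC"}, \code{"ft3/s"}).
#' @return data.frame of class \code{env_series} with metadata attributes.
#' @export
env_series <- function(time, value, source_id, variable,
                       units = c(sst = "degC", river_temp = "degC",
                                 discharge = "ft3/s",
                                 bottom_temp = "degC")[[variable]]) {
  variable <- match.arg(variable,
                        c("sst", "river_temp", "discharge", "bottom_temp"))
  ord <- order(time)
  time <- time[ord]; value <- value[ord]
  if (any(duplicated(time))) stop("env_series timestamps must be unique")
  out <- data.frame(time = time, value = value)
  attr(out, "source_id") <- source_id
  attr(out, "variable") <- variable
  attr(out, "units") <- units
  class(out) <- c("env_series", "data.frame")
  out
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("<env_series> %s @ %s [%s], %d samples\n",
              attr(x, "variable"), attr(x, "source_id"), attr(x, "units"),
              nrow(x)))
  if (nrow(x)) cat(sprintf("  %s .. %s\n", format(min(x$time)),
                           format(max(x$time))))
  invisible(x)
}

#' Read an NDBC standard meteorological file
#'
#' Parses the National Data Buoy Center standard meteorological text format:
#' two leading header lines (column names, units), space-delimited columns,
#' timestamps assembled from the YY MM DD hh (mm) fields as UTC. Only the
#' water temperature column (WTMP) is extracted; the NDBC missing-data
#' sentinels (99.0 / 999.0) are mapped to missing and dropped.
#'
#' @param path file path.
#' @param source_id series label; defaults to the file name sans extension.
#' @return \code{\link{env_series}} of variable \code{"sst"}; zero rows (with
#'   a warning) if every WTMP value is a sentinel.
#' @export
read_ndbc_met <- function(path, source_id = NULL) {
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- strsplit(trimws(sub("^#", "", lines[1])), "[[:space:]]+")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    warning("NDBC file has no data rows: ", path)
    return(env_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                      source_id, "sst"))
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  mat <- do.call(rbind, lapply(fields, function(f) f[seq_along(hdr)]))
  colnames(mat) <- hdr
  yy <- as.integer(mat[, intersect(c("YY", "YYYY"), hdr)[1]])
  yy <- ifelse(yy < 100, ifelse(yy < 70, 2000 + yy, 1900 + yy), yy)
  mm <- as.integer(mat[, "MM"]); dd <- as.integer(mat[, "DD"])
  hh <- as.integer(mat[, "hh"])
  mn <- if ("mm" %in% hdr) as.integer(mat[, "mm"]) else 0L
  time <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:00",
                             yy, mm, dd, hh, mn), tz = "UTC")
  if (!("WTMP" %in% hdr)) {
    warning("no WTMP column in NDBC file: ", path)
    return(env_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                      source_id, "sst"))
  }
  wtmp <- suppressWarnings(as.numeric(mat[, "WTMP"]))
  wtmp[wtmp %in% c(99, 99.0, 999, 999.0)] <- NA_real_
  keep <- !is.na(time) & !is.na(wtmp)
  if (!any(keep)) {
    warning("all WTMP values missing in ", path)
    return(env_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                      source_id, "sst"))
  }
  env_series(time[keep], wtmp[keep], source_id, "sst")
}

#' Read a USGS RDB file
#'
#' Parses the USGS tab-delimited RDB format (comment lines starting
#' \code{#}, a header row, then a column-format row like \code{5s 15d 14n}).
#' Parameter columns are recognized by the USGS parameter code embedded in
#' the column name (e.g. \code{..._00010} water temperature,
#' \code{..._00060} discharge); qualification flag columns (\code{_cd}
#' suffix) are carried as a \code{flags} attribute.
#'
#' @param path file path.
#' @param param_map named character vector mapping parameter codes to
#'   variables; default \code{c("00010"="river_temp","00060"="discharge")}.
#' @param source_id series label; default the \code{site_no} in the file or
#'   the file name.
#' @return named list of \code{\link{env_series}} (one per mapped parameter
#'   found); empty list with a warning if the file has no data.
#' @export
read_usgs_rdb <- function(path,
                          param_map = c("00010" = "river_temp",
                                        "00060" = "discharge"),
                          source_id = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    warning("USGS RDB file has no data rows: ", path)
    return(list())
  }
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-(1:2)]                       # drop header + format rows
  if (!length(rows)) {
    warning("USGS RDB file has header but no data: ", path)
    return(list())
  }
  cells <- strsplit(rows, "\t", fixed = TRUE)
  mat <- do.call(rbind, lapply(cells, function(f) {
    length(f) <- length(hdr); f
  }))
  colnames(mat) <- hdr
  if (is.null(source_id))
    source_id <- if ("site_no" %in% hdr) mat[1, "site_no"] else
      sub("\\.[^.]*$", "", basename(path))
  tcol <- intersect(c("datetime", "dateTime"), hdr)[1]
  if (is.na(tcol)) stop("no datetime column in RDB file: ", path)
  time <- parse_utc(mat[, tcol])
  out <- list()
  value_cols <- hdr[grepl("_[0-9]{5}$", hdr)]
  for (vc in value_cols) {
    code <- sub(".*_", "", vc)
    if (!(code %in% names(param_map))) {
      warning("unmapped USGS parameter code ", code, " skipped")
      next
    }
    variable <- param_map[[code]]
    val <- suppressWarnings(as.numeric(mat[, vc]))
    keep <- !is.na(time) & !is.na(val)
    es <- env_series(time[keep], val[keep], source_id, variable)
    fc <- paste0(vc, "_cd")
    if (fc %in% hdr) attr(es, "flags") <- unname(mat[keep, fc])
    out[[variable]] <- es
  }
  out
}
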
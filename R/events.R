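# Residence / movement event classification. The rules:
#   * a bout is a maximal run of same-station detections of one tag in which
#     every consecutive gap is < timeout (default 12 h); a detection at
#     another station or a gap >= timeout closes the bout;
#   * a bout with >= min_detections detections spanning >= the minimum
#     residence duration (default 2 h, first-to-last detection) is a
#     residence event;
#   * each ordered pair of successive bouts of one tag at distinct stations
#     separated by < movement_max_duration (default 5 d) is a movement
#     event; its rate of movement is the matrix distance divided by the
#     elapsed time from the last detection at the origin to the first at the
#     destination.
# Boundary conventions: a gap exactly equal to the timeout terminates; a
# span exactly equal to the minimum duration qualifies; a movement gap must
# be strictly < movement_max_duration.

#' Event-classification parameters
#'
#' @param min_detections minimum detections for a residence event.
#' @param min_residence_duration minimum first-to-last span, hours.
#' @param timeout gap that terminates a bout, hours.
#' @param movement_max_duration longest allowed station-to-station gap for a
#'   movement event, days.
#' @return list of class \code{event_params}.
#' @export
event_params <- function(min_detections = 2, min_residence_duration = 2,
                         timeout = 12, movement_max_duration = 5) {
  stopifnot(min_detections >= 1, min_residence_duration > 0, timeout > 0,
            movement_max_duration > 0,
            min_residence_duration < timeout)
  structure(list(min_detections = min_detections,
                 min_residence_duration = min_residence_duration,
                 timeout = timeout,
                 movement_max_duration = movement_max_duration),
            class = "event_params")
}

#' Split detection streams into station bouts
#'
#' Greedy left-to-right scan per tag. Two detections with the same timestamp
#' at different stations are ordered so that the station of the previous
#' detection (or, at stream start, the lexicographically first station)
#' continues the current bout — a deterministic tie-break.
#'
#' @param det QC-filtered detection data.frame.
#' @param params \code{\link{event_params}}.
#' @return data.frame, one row per bout: \code{tag_id}, \code{station_id},
#'   \code{start}, \code{end} (POSIXct), \code{n_detections},
#'   \code{span_hours}, \code{bout} (per-tag ordinal).
#' @export
build_bouts <- function(det, params = event_params()) {
  det <- sort_detections(det)
  timeout_s <- params$timeout * 3600
  res <- vector("list", 64L); nres <- 0L
  for (tg in unique(det$tag_id)) {
    idx <- which(det$tag_id == tg)
    tt <- as.numeric(det$timestamp[idx])
    ss <- det$station_id[idx]
    # tie-break: among equal timestamps put the continuing station first
    k <- length(idx)
    if (k > 1) {
      j <- 2L
      while (j <= k) {
        if (tt[j] == tt[j - 1] && ss[j] != ss[j - 1]) {
          # find the run of equal timestamps
          r <- j - 1L
          while (r < k && tt[r + 1] == tt[j - 1]) r <- r + 1L
          run <- (j - 1L):r
          prev_st <- if (j >= 3) ss[j - 2] else min(ss[run])
          ord <- order(ss[run] != prev_st, ss[run])
          ss[run] <- ss[run][ord]
          j <- r
        }
        j <- j + 1L
      }
    }
    b_start <- 1L
    bout_no <- 0L
    for (j in seq_len(k)) {
      closes <- j == k || ss[j + 1] != ss[j] ||
        (tt[j + 1] - tt[j]) >= timeout_s
      if (closes) {
        bout_no <- bout_no + 1L
        nres <- nres + 1L
        if (nres > length(res)) res <- c(res, vector("list", length(res)))
        res[[nres]] <- data.frame(
          tag_id = tg, station_id = ss[j],
          start = det$timestamp[idx[b_start]],
          end = det$timestamp[idx[j]],
          n_detections = j - b_start + 1L,
          span_hours = (tt[j] - tt[b_start]) / 3600,
          bout = bout_no, stringsAsFactors = FALSE)
        b_start <- j + 1L
      }
    }
  }
  out <- if (nres) do.call(rbind, res[seq_len(nres)]) else
    data.frame(tag_id = character(), station_id = character(),
               start = as.POSIXct(character(), tz = "UTC"),
               end = as.POSIXct(character(), tz = "UTC"),
               n_detections = integer(), span_hours = numeric(),
               bout = integer())
  rownames(out) <- NULL
  out
}

#' Classify bouts into residence and movement events
#'
#' @param bouts output of \code{\link{build_bouts}}.
#' @param stations station data.frame or precomputed distance matrix.
#' @param params \code{\link{event_params}}.
#' @return list with \code{residence} (tag_id, station_id, start, end,
#'   duration_hours, n_detections) and \code{movements} (tag_id,
#'   from_station, to_station, depart, arrive, duration_hours, distance_m,
#'   rom). Bout pairs whose stations are absent from the matrix are skipped
#'   with a message.
#' @export
classify_events <- function(bouts, stations, params = event_params()) {
  dm <- if (inherits(stations, "dist_matrix")) stations else
    build_distance_matrix(stations)
  res_keep <- bouts$n_detections >= params$min_detections &
    bouts$span_hours >= params$min_residence_duration
  residence <- data.frame(
    tag_id = bouts$tag_id[res_keep], station_id = bouts$station_id[res_keep],
    start = bouts$start[res_keep], end = bouts$end[res_keep],
    duration_hours = bouts$span_hours[res_keep],
    n_detections = bouts$n_detections[res_keep], stringsAsFactors = FALSE)

  max_gap_s <- params$movement_max_duration * 86400
  mv <- vector("list", 64L); nmv <- 0L
  n_skipped <- 0L
  if (nrow(bouts)) {
    ord <- order(bouts$tag_id, bouts$bout)
    b <- bouts[ord, , drop = FALSE]
    same_tag <- b$tag_id[-1] == b$tag_id[-nrow(b)]
    for (i in which(same_tag)) {
      from <- b[i, ]; to <- b[i + 1, ]
      if (from$station_id == to$station_id) next
      gap_s <- as.numeric(to$start) - as.numeric(from$end)
      if (!(gap_s > 0 && gap_s < max_gap_s)) next
      if (!(from$station_id %in% rownames(dm)) ||
          !(to$station_id %in% rownames(dm))) {
        n_skipped <- n_skipped + 1L
        next
      }
      d <- dm[from$station_id, to$station_id]
      nmv <- nmv + 1L
      if (nmv > length(mv)) mv <- c(mv, vector("list", length(mv)))
      mv[[nmv]] <- data.frame(
        tag_id = from$tag_id, from_station = from$station_id,
        to_station = to$station_id, depart = from$end, arrive = to$start,
        duration_hours = gap_s / 3600, distance_m = d, rom = d / gap_s,
        stringsAsFactors = FALSE)
    }
  }
  movements <- if (nmv) do.call(rbind, mv[seq_len(nmv)]) else
    data.frame(tag_id = character(), from_station = character(),
               to_station = character(),
               depart = as.POSIXct(character(), tz = "UTC"),
               arrive = as.POSIXct(character(), tz = "UTC"),
               duration_hours = numeric(), distance_m = numeric(),
               rom = numeric())
  if (n_skipped) message(n_skipped,
                         " movement event(s) skipped: station not in matrix")
  rownames(residence) <- rownames(movements) <- NULL
  list(residence = residence, movements = movements)
}

#' Summarize residence events
#'
#' @param residence residence-event data.frame from
#'   \code{\link{classify_events}}.
#' @return list: \code{n}, \code{mean}, \code{sd} (n-1 denominator; NA when
#'   n < 2), \code{range} (length-2, NA when n = 0) of duration in hours,
#'   and \code{per_station} (named count vector).
#' @export
summarize_residence <- function(residence) {
  d <- residence$duration_hours
  list(n = length(d),
       mean = if (length(d)) mean(d) else NA_real_,
       sd = if (length(d) > 1) sd(d) else NA_real_,
       range = if (length(d)) range(d) else c(NA_real_, NA_real_),
       per_station = if (length(d)) table(residence$station_id) else
         table(character()))
}
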
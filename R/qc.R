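# Detection QC: removal of spurious detections that are impossible given
# the spatial and temporal chronology of each fish. Manual review of raw
# logs is operationalized as two reproducible rules:
#   (a) isolated impossible point — reaching the detection from the previous
#       retained detection of the same tag AND reaching the next retained
#       detection from it would both require implied speeds above max_speed;
#   (b) lone orphan — the only detection of its tag within +/- orphan_window
#       at a station far (>2x the median nearest-neighbour spacing) from the
#       stations of its temporal neighbours.
# Rules are applied iteratively until the retained set is stable. Implied
# speed uses center-to-center distance (no radius subtraction), which is
# conservative against false removal.

#' Remove spurious detections
#'
#' @param det detection data.frame (see \code{\link{read_detections}}),
#'   sorted or sortable per tag.
#' @param stations station data.frame or a precomputed
#'   \code{\link{build_distance_matrix}} result.
#' @param max_speed maximum biologically plausible sustained speed, m/s.
#'   Default 2.0 — roughly 2.3x the fastest station-to-station rate of
#'   movement the event analysis is expected to see, leaving headroom so
#'   genuine fast transits are never removed.
#' @param orphan_window half-width, hours, of the temporal isolation window
#'   for the lone-orphan rule (default 24).
#' @return list with \code{detections} (retained, order-preserving) and
#'   \code{report}, a \code{qc_report} list: \code{n_input},
#'   \code{n_retained}, \code{n_removed_speed}, \code{n_removed_orphan},
#'   \code{removed} (data.frame with a \code{reason} column),
#'   \code{unverifiable_tags} (tags with a single detection overall, always
#'   retained).
#' @export
filter_spurious <- function(det, stations, max_speed = 2.0,
                            orphan_window = 24) {
  dm <- if (inherits(stations, "dist_matrix")) stations else
    build_distance_matrix(stations)
  det <- sort_detections(det)
  n_input <- nrow(det)
  if (n_input == 0) {
    return(list(detections = det,
                report = qc_report(0, det[0, ], character())))
  }
  miss <- setdiff(unique(det$station_id), rownames(dm))
  if (length(miss)) stop("detections at station(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  far <- 2 * nn_spacing(dm)
  win <- orphan_window * 3600
  tag_n <- table(det$tag_id)
  unverifiable <- names(tag_n)[tag_n == 1]

  removed <- list()
  repeat {
    flag <- rep(NA_character_, nrow(det))
    for (tg in unique(det$tag_id)) {
      idx <- which(det$tag_id == tg)
      if (length(idx) < 2) next
      tt <- as.numeric(det$timestamp[idx])
      ss <- det$station_id[idx]
      k <- length(idx)
      if (k >= 3) {
        for (j in 2:(k - 1)) {
          d_prev <- dm[ss[j - 1], ss[j]]
          d_next <- dm[ss[j], ss[j + 1]]
          v_prev <- d_prev / max(tt[j] - tt[j - 1], 1e-9)
          v_next <- d_next / max(tt[j + 1] - tt[j], 1e-9)
          if (v_prev > max_speed && v_next > max_speed)
            flag[idx[j]] <- "speed"
        }
      }
      if (!is.na(far)) {
        for (j in seq_len(k)) {
          if (!is.na(flag[idx[j]])) next
          lone <- !any(abs(tt[-j] - tt[j]) <= win)
          if (!lone) next
          d_pr <- if (j > 1) dm[ss[j - 1], ss[j]] else Inf
          d_nx <- if (j < k) dm[ss[j], ss[j + 1]] else Inf
          if (d_pr > far && d_nx > far) flag[idx[j]] <- "orphan"
        }
      }
    }
    hit <- which(!is.na(flag))
    if (!length(hit)) break
    rem <- det[hit, , drop = FALSE]
    rem$reason <- flag[hit]
    removed[[length(removed) + 1]] <- rem
    det <- det[-hit, , drop = FALSE]
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    cbind(det[0, ], reason = character())
  rownames(det) <- rownames(removed) <- NULL
  list(detections = det,
       report = qc_report(n_input, removed, unverifiable))
}

qc_report <- function(n_input, removed, unverifiable) {
  structure(list(
    n_input = n_input,
    n_retained = n_input - nrow(removed),
    n_removed_speed = sum(removed$reason == "speed"),
    n_removed_orphan = sum(removed$reason == "orphan"),
    removed = removed,
    unverifiable_tags = unverifiable), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d in, %d retained (%d speed, %d orphan removals; %d unverifiable single-detection tag(s))\n",
    x$n_input, x$n_retained, x$n_removed_speed, x$n_removed_orphan,
    length(x$unverifiable_tags)))
  invisible(x)
}

#' Write a QC audit file
#' @param report \code{qc_report} from \code{\link{filter_spurious}}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  rem <- report$removed
  out <- data.frame(
    datetime_utc = format(rem$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    station_id = rem$station_id, tag_id = rem$tag_id, reason = rem$reason)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
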
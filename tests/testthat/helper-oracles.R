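# Independent oracles used across the suite. These deliberately re-derive
# results by different routes than the package code.

# --- Solar oracle: Michalsky (1988) low-precision solar position ---------
# Different ephemeris series than the implementation's; day length from the
# same -0.833 deg horizon geometry.
oracle_daylength <- function(date, lon, lat) {
  d2r <- pi / 180
  n <- as.numeric(as.Date(date)) + 2440587.5 + 0.5 - lon / 360 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)
  eps <- 23.439 - 0.0000004 * n
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
  cos_ha <- (cos(90.833 * d2r) - sin(lat * d2r) * sin(decl)) /
    (cos(lat * d2r) * cos(decl))
  2 * acos(pmin(1, pmax(-1, cos_ha))) / d2r / 15
}

# --- Brute-force event oracle -------------------------------------------
# Tests every candidate window [i..j] of each tag's time-sorted stream
# against the rule text; O(n^2), independent of the greedy scanner.
# Assumes distinct timestamps per tag (streams are generated that way; the
# simultaneous-detection tie-break has its own unit test).
oracle_events <- function(det, dm, params) {
  timeout_s <- params$timeout * 3600
  res <- list(); mov <- list()
  for (tg in unique(det$tag_id)) {
    d <- det[det$tag_id == tg, , drop = FALSE]
    d <- d[order(d$timestamp), , drop = FALSE]
    tt <- as.numeric(d$timestamp); ss <- d$station_id; n <- nrow(d)
    breaks_before <- function(i) {
      i == 1 || ss[i - 1] != ss[i] || (tt[i] - tt[i - 1]) >= timeout_s
    }
    breaks_after <- function(j) {
      j == n || ss[j + 1] != ss[j] || (tt[j + 1] - tt[j]) >= timeout_s
    }
    windows <- list()
    for (i in seq_len(n)) {
      if (!breaks_before(i)) next
      # candidate extensions of a window starting at i, each tested
      # against the rule text (same station, every gap under the timeout)
      same <- ss[i:n] == ss[i]
      gap_ok <- c(TRUE, diff(tt[i:n]) < timeout_s)
      good <- cumprod(same & gap_ok) == 1
      j <- i + max(which(good)) - 1L
      if (breaks_after(j))
        windows[[length(windows) + 1]] <- c(i, j)
    }
    for (w in windows) {
      i <- w[1]; j <- w[2]
      span_h <- (tt[j] - tt[i]) / 3600
      if ((j - i + 1) >= params$min_detections &&
          span_h >= params$min_residence_duration)
        res[[length(res) + 1]] <- data.frame(
          tag_id = tg, station_id = ss[i], start = d$timestamp[i],
          end = d$timestamp[j], duration_hours = span_h,
          n_detections = j - i + 1L)
    }
    if (length(windows) > 1) {
      for (k in seq_len(length(windows) - 1)) {
        a <- windows[[k]]; b <- windows[[k + 1]]
        if (ss[a[2]] == ss[b[1]]) next
        gap_s <- tt[b[1]] - tt[a[2]]
        if (!(gap_s > 0 && gap_s < params$movement_max_duration * 86400))
          next
        dd <- dm[ss[a[2]], ss[b[1]]]
        mov[[length(mov) + 1]] <- data.frame(
          tag_id = tg, from_station = ss[a[2]], to_station = ss[b[1]],
          depart = d$timestamp[a[2]], arrive = d$timestamp[b[1]],
          rom = dd / gap_s)
      }
    }
  }
  list(residence = if (length(res)) do.call(rbind, res) else NULL,
       movements = if (length(mov)) do.call(rbind, mov) else NULL)
}

# random detection stream for oracle-equivalence testing: a few tags over a
# handful of stations, gap mixture straddling the timeout, distinct times
random_stream <- function(n, station_ids, seed) {
  set.seed(seed)
  tags <- paste0("T", seq_len(sample(3, 1)))
  rows <- lapply(tags, function(tg) {
    k <- max(2L, rpois(1, n / length(tags)))
    gaps <- exp(runif(k, log(60), log(30 * 3600)))   # 1 min .. 30 h
    tt <- as.POSIXct("2017-06-01", tz = "UTC") + cumsum(gaps)
    st <- character(k)
    st[1] <- sample(station_ids, 1)
    for (i in seq_len(k - 1)) {
      st[i + 1] <- if (runif(1) < 0.6) st[i] else sample(station_ids, 1)
    }
    data.frame(timestamp = tt, tag_id = tg, station_id = st,
               sensor_temp = NA_real_)
  })
  sort_detections(do.call(rbind, rows))
}

event_key <- function(ev) {
  if (is.null(ev) || !nrow(ev)) return(character())
  paste(ev$tag_id, ev$station_id %||% paste(ev$from_station, ev$to_station),
        format(ev$start %||% ev$depart, "%Y-%m-%d %H:%M:%OS3"),
        format(ev$end %||% ev$arrive, "%Y-%m-%d %H:%M:%OS3"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detection_key <- function(d) {
  paste(d$tag_id, format(d$timestamp, "%Y-%m-%d %H:%M:%OS4"), d$station_id)
}

# small standard array reused by several tests
test_stations <- function() simulate_array(sim_config(seed = 99))
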
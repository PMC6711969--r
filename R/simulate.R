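# Synthetic-data generator. Emulates the study system end to end with known
# ground truth: a wedge-shaped 24-station offshore grid (~3.43 km
# nearest-neighbour spacing, 600 m detection radii, one station lost for the
# final months), ~15-month deployment, tags with 70-150 s transmission
# delays, strongly seasonal occupancy (peak November-January, near-absence
# July-September) driven by a planted log-intensity surface in river
# temperature x photoperiod plus a negative linear discharge effect, and
# environmental series in which river temperature trails photoperiod by a
# planted 35-day thermal lag.

#' Synthetic-study configuration
#'
#' Defaults are the study conditions the generator emulates: 24 stations at
#' 3.43 km nearest-neighbour spacing spanning ~22-48 km offshore, 600 m
#' detection radii, 150 tags, deployment 2016-11-10..2018-02-05 with one
#' station lost from 2017-08-04, tag delay uniform on 70-150 s, maximum
#' sustained swim speed 0.9 m/s, and a 35-day river-temperature lag behind
#' photoperiod.
#'
#' @param seed integer RNG seed; identical configs give identical output.
#' @param n_tags number of tagged fish at large.
#' @param start,end study span (Date or string).
#' @param n_stations stations in the grid (laid out in rows of 4).
#' @param spacing_km within-row nearest-neighbour spacing.
#' @param detection_radius m.
#' @param tag_delay length-2 range of the transmission interval, seconds.
#' @param max_swim_speed m/s; no emitted true detection pair implies a
#'   station-to-station speed above this.
#' @param lost_station_index which station fails early (NULL = none).
#' @param lost_date failure date of the lost station.
#' @param lat,lon shore reference point of the array.
#' @param occupancy list of planted intensity parameters: \code{b0},
#'   \code{amp}, \code{t_pk}, \code{t_sc} (deg C), \code{p_pk}, \code{p_sc}
#'   (h), \code{b_discharge} (per ft3/s, negative).
#' @param temp_lag_days planted photoperiod-to-river-temperature lag.
#' @param n_false planted spurious detections.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_tags = 150,
                       start = "2016-11-10", end = "2018-02-05",
                       n_stations = 24, spacing_km = 3.43,
                       detection_radius = 600,
                       tag_delay = c(70, 150), max_swim_speed = 0.9,
                       lost_station_index = 7, lost_date = "2017-08-04",
                       lat = 40.3, lon = -73.55,
                       occupancy = list(b0 = -0.7, amp = 4.0, t_pk = 4,
                                        t_sc = 6, p_pk = 9.3, p_sc = 2.0,
                                        b_discharge = -5e-5),
                       temp_lag_days = 35, n_false = 30) {
  stopifnot(seed == round(seed), n_tags >= 0, n_stations >= 1,
            spacing_km > 0, detection_radius > 0, max_swim_speed > 0,
            temp_lag_days >= 0)
  structure(list(seed = as.integer(seed), n_tags = n_tags,
                 start = as.Date(start), end = as.Date(end),
                 n_stations = n_stations, spacing_km = spacing_km,
                 detection_radius = detection_radius,
                 tag_delay = tag_delay, max_swim_speed = max_swim_speed,
                 lost_station_index = lost_station_index,
                 lost_date = as.Date(lost_date),
                 lat = lat, lon = lon, occupancy = occupancy,
                 temp_lag_days = temp_lag_days, n_false = n_false),
            class = "sim_config")
}

#' Simulate the receiver array
#'
#' Wedge-shaped grid: rows of four stations at the configured within-row
#' spacing, rows stepping offshore to the southeast so that station
#' distances from the shore reference span roughly 22-48 km; rows drift
#' laterally with distance to widen the wedge.
#'
#' @param config \code{\link{sim_config}}.
#' @return station data.frame (\code{station_id}, \code{lon}, \code{lat},
#'   \code{depth}, \code{detection_radius}, \code{deploy_start},
#'   \code{deploy_end}, \code{distance_from_shore} km).
#' @export
simulate_array <- function(config = sim_config()) {
  set.seed(config$seed + 101L)
  n <- config$n_stations
  per_row <- 4L
  rows <- ceiling(n / per_row)
  ref <- c(config$lon, config$lat)
  bear_off <- 150; bear_lat <- 60   # offshore SSE, lateral ENE
  out <- vector("list", n)
  k <- 0L
  for (i in seq_len(rows) - 1L) {
    d_off <- 22 + i * 5.2                    # km offshore
    drift <- i * 1.2                         # wedge widening
    for (j in seq_len(per_row) - 1L) {
      k <- k + 1L
      if (k > n) break
      d_lat <- (j - (per_row - 1) / 2) * config$spacing_km + drift
      p <- geosphere::destPoint(ref, bear_off, d_off * 1000)
      p <- geosphere::destPoint(p, bear_lat, d_lat * 1000)
      out[[k]] <- data.frame(
        station_id = sprintf("S%02d", k), lon = p[1], lat = p[2],
        depth = 23 + (41 - 23) * (d_off - 22) / 26 + rnorm(1, 0, 0.5),
        detection_radius = config$detection_radius,
        deploy_start = as.POSIXct(paste(config$start, "00:00:00"),
                                  tz = "UTC"),
        deploy_end = as.POSIXct(paste(config$end, "23:59:59"), tz = "UTC"),
        distance_from_shore = d_off)
    }
  }
  st <- do.call(rbind, out)
  li <- config$lost_station_index
  if (!is.null(li) && !is.na(li) && li >= 1 && li <= n)
    st$deploy_end[li] <- as.POSIXct(paste(config$lost_date, "00:00:00"),
                                    tz = "UTC")
  st
}

#' Simulate tagged fish
#'
#' Fork lengths lognormal around the mid-800s mm (mostly juveniles, a few
#' sub-adults/adults), total length a proportional stretch of fork length,
#' weight from a cubic length-weight allometry, release dates in spring
#' tagging windows before/within the study.
#'
#' @param config \code{\link{sim_config}}.
#' @return tag data.frame (\code{tag_id}, \code{release_date},
#'   \code{fork_length}, \code{total_length}, \code{weight}).
#' @export
simulate_tags <- function(config = sim_config()) {
  set.seed(config$seed + 202L)
  n <- config$n_tags
  fl <- pmin(pmax(round(rlnorm(n, log(870), 0.17)), 520), 2050)
  tl <- round(fl * runif(n, 1.10, 1.18))
  wt <- round(3.5e-9 * fl^3 * exp(rnorm(n, 0, 0.12)), 2)
  rel <- sample(seq(as.Date("2016-05-01"), as.Date("2016-10-15"), "day"),
                n, replace = TRUE)
  data.frame(tag_id = sprintf("ATS-%03d", seq_len(max(n, 0))),
             release_date = rel, fork_length = fl, total_length = tl,
             weight = wt)[seq_len(n), , drop = FALSE]
}

# daily environmental truth over the span (with internal lead-in for the lag)
sim_env_daily <- function(config = sim_config()) {
  set.seed(config$seed + 303L)
  lead <- config$temp_lag_days + 15
  dates <- seq(config$start - lead, config$end, by = "day")
  P <- as.numeric(photoperiod(dates, config$lon, config$lat))
  n <- length(dates)
  # river temperature: rescaled photoperiod delayed by the planted lag,
  # plus AR(1) weather noise
  lag <- config$temp_lag_days
  P_lag <- c(rep(P[1], lag), P)[seq_len(n)]
  base <- (P_lag - min(P)) / (max(P) - min(P)) * 27
  ar <- stats::filter(rnorm(n, 0, 0.5), 0.8, method = "recursive")
  HR_temp <- pmax(base + as.numeric(ar), 0)
  # discharge: winter/fall lows under 20,000 ft3/s, spring freshet, storms
  doy <- as.integer(format(dates, "%j"))
  freshet <- 22000 * exp(-0.5 * ((doy - 105) / 25)^2)   # mid-April peak
  storms <- rbinom(n, 1, 0.03) * rgamma(n, 2, scale = 6000)
  HR_discharge <- pmax(12000 + freshet + storms +
                         as.numeric(stats::filter(rnorm(n, 0, 1200), 0.7,
                                                  method = "recursive")),
                       3000)
  # harbor SST tracks river temperature (target r^2 ~ 0.9); offshore buoy
  # is a damped, noisier version
  b <- 0.85
  noise_sd <- sd(b * HR_temp) * sqrt((1 - 0.9) / 0.9)
  sst_NH <- 2 + b * HR_temp + rnorm(n, 0, noise_sd)
  sst_OS <- 8 + 0.55 * HR_temp + rnorm(n, 0, 2.2)
  out <- data.frame(date = dates, P = P, M = moon_fraction(dates),
                    HR_temp = HR_temp, HR_discharge = HR_discharge,
                    sst_NH = sst_NH, sst_OS = sst_OS)
  out[out$date >= config$start, , drop = FALSE]
}

#' Simulate the environmental series
#'
#' @param config \code{\link{sim_config}}.
#' @return named list of \code{\link{env_series}} (daily samples at 17:00
#'   UTC): \code{HR_temp}, \code{HR_discharge}, \code{sst_NH},
#'   \code{sst_OS}; the daily truth table (including photoperiod and moon
#'   fraction) is attached as attribute \code{"daily"}.
#' @export
simulate_environment <- function(config = sim_config()) {
  daily <- sim_env_daily(config)
  t17 <- as.POSIXct(paste(daily$date, "17:00:00"), tz = "UTC")
  out <- list(
    HR_temp = env_series(t17, daily$HR_temp, "gauge", "river_temp"),
    HR_discharge = env_series(t17, daily$HR_discharge, "gauge", "discharge"),
    sst_NH = env_series(t17, daily$sst_NH, "buoy-NH", "sst"),
    sst_OS = env_series(t17, daily$sst_OS, "buoy-OS", "sst"))
  attr(out, "daily") <- daily
  out
}

# planted log-intensity of unique daily count
sim_eta <- function(occ, temp, P, discharge) {
  occ$b0 + occ$amp * exp(-0.5 * ((temp - occ$t_pk) / occ$t_sc)^2 -
                           0.5 * ((P - occ$p_pk) / occ$p_sc)^2) +
    occ$b_discharge * discharge
}

#' Simulate a model-ready daily covariate table
#'
#' Draws unique daily counts directly from the planted occupancy intensity
#' (a temperature-by-photoperiod surface plus a negative linear discharge
#' effect; moon fraction carries no signal), bypassing the detection
#' process. This is the generator used for model-recovery experiments,
#' where the estimand is the intensity itself.
#'
#' @param config \code{\link{sim_config}}.
#' @param overdispersion variance-to-mean ratio of the counts; 1 = Poisson,
#'   > 1 uses a negative-binomial mixture with matching quadratic variance.
#' @return covariate table (date, UDC, P, M, HR_temp, HR_discharge,
#'   sst_NH, sst_OS, incomplete) with the planted truth in attribute
#'   \code{"truth"} (\code{eta}, \code{lambda}, \code{b_discharge},
#'   \code{lag_days}).
#' @export
simulate_covariate_table <- function(config = sim_config(),
                                     overdispersion = 1) {
  daily <- sim_env_daily(config)
  set.seed(config$seed + 404L)
  occ <- config$occupancy
  eta <- sim_eta(occ, daily$HR_temp, daily$P, daily$HR_discharge)
  lambda <- exp(eta)
  udc <- if (overdispersion <= 1) rpois(nrow(daily), lambda) else
    rnbinom(nrow(daily), mu = lambda,
            size = lambda / (overdispersion - 1))
  tab <- data.frame(date = daily$date, UDC = as.integer(udc),
                    P = daily$P, M = daily$M, HR_temp = daily$HR_temp,
                    HR_discharge = daily$HR_discharge,
                    sst_NH = daily$sst_NH, sst_OS = daily$sst_OS)
  tab$incomplete <- FALSE
  attr(tab, "truth") <- list(eta = eta, lambda = lambda,
                             b_discharge = occ$b_discharge,
                             lag_days = config$temp_lag_days,
                             occupancy = occ)
  tab
}

# sample() safe against the length-1-numeric expansion
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

# detection probability vs range: ~0.65 at 600 m, ~0.05 at 1000 m,
# ~0.9 within 100 m
detect_prob <- function(range_m) {
  0.95 * plogis(6.267 - 0.009157 * range_m)
}

# emit detections for one dwell at a station; forces first/last emissions
# at the dwell bounds so planted bout spans are exact
emit_dwell <- function(t0, t1, delay, radius) {
  span <- t1 - t0
  if (span <= 0) return(t0)
  gaps <- runif(ceiling(span / delay[1]) + 2, delay[1], delay[2])
  tt <- t0 + cumsum(c(0, gaps))
  tt <- tt[tt <= t1]
  r <- runif(length(tt), 0, radius * 2)
  keep <- runif(length(tt)) < detect_prob(r)
  keep[1] <- TRUE
  tt <- tt[keep]
  if (tt[length(tt)] < t1) tt <- c(tt, t1)
  tt
}

#' Simulate the detection log
#'
#' Per tag and day, presence is drawn from the planted occupancy intensity
#' (tags detected yesterday are preferentially retained, giving multi-day
#' visits). Present tags dwell at one to three stations, moving only to
#' stations reachable under the configured maximum swim speed; transmission
#' instants follow the tag-delay interval and are thinned by a
#' range-dependent detection probability. A subset of dwells is recorded as
#' planted residence bouts (exact start/end emission forced). Planted false
#' detections are inserted between consecutive in-bout transmissions at a
#' distant station (> 20 km), making them two-sidedly impossible at the QC
#' speed threshold. The lost station emits nothing after its failure date.
#'
#' @param config \code{\link{sim_config}}.
#' @param stations from \code{\link{simulate_array}}.
#' @param env from \code{\link{simulate_environment}} (its \code{"daily"}
#'   attribute supplies the intensity covariates).
#' @return list: \code{detections} (canonical detection data.frame, sorted;
#'   includes the planted falses), \code{truth} list with
#'   \code{planted_bouts} (tag, station, start, end, n_detections),
#'   \code{false_rows} (logical index into \code{detections}),
#'   \code{presence} (tag-day presence table), and the intensity truth.
#' @export
simulate_detections <- function(config = sim_config(),
                                stations = simulate_array(config),
                                env = simulate_environment(config)) {
  daily <- attr(env, "daily")
  set.seed(config$seed + 505L)
  occ <- config$occupancy
  eta <- sim_eta(occ, daily$HR_temp, daily$P, daily$HR_discharge)
  lambda <- exp(eta)
  dm <- unclass(build_distance_matrix(stations))
  ids <- stations$station_id
  n_st <- length(ids)
  tags <- sprintf("ATS-%03d", seq_len(config$n_tags))
  if (!length(tags))
    return(list(detections = data.frame(
      timestamp = as.POSIXct(character(), tz = "UTC"),
      tag_id = character(), station_id = character(),
      sensor_temp = numeric()),
      truth = list(planted_bouts = NULL, false_rows = logical(),
                   presence = NULL, eta = eta, lambda = lambda)))

  vmax <- 0.8 * config$max_swim_speed       # headroom under the cap
  last_t <- setNames(rep(-Inf, length(tags)), tags)
  last_st <- setNames(rep(NA_integer_, length(tags)), tags)
  prev_day <- character(0)
  det_t <- vector("list", 2048L); det_tag <- det_st <- vector("list", 2048L)
  nd <- 0L
  bouts <- vector("list", 256L); nb <- 0L
  presence <- vector("list", nrow(daily))

  for (d in seq_len(nrow(daily))) {
    n_present <- rpois(1, lambda[d])
    n_present <- min(n_present, length(tags))
    if (n_present == 0) { prev_day <- character(0); next }
    stay <- intersect(prev_day, tags)
    n_stay <- min(length(stay), rbinom(1, n_present, 0.6))
    fresh <- setdiff(tags, stay)
    n_new <- min(n_present - n_stay, length(fresh))
    today <- c(resample(stay, n_stay), resample(fresh, n_new))
    presence[[d]] <- data.frame(date = daily$date[d], tag_id = today)
    day0 <- as.numeric(as.POSIXct(paste(daily$date[d], "00:00:00"),
                                  tz = "UTC"))
    for (tg in today) {
      t_now <- day0 + runif(1, 0, 6 * 3600)
      st_cur <- last_st[tg]
      if (is.na(st_cur)) st_cur <- sample.int(n_st, 1)
      # honour the swim-speed cap across the gap since last emission
      gap <- t_now - last_t[tg]
      if (is.finite(gap)) {
        reach <- which(dm[st_cur, ] <= vmax * gap)
        st_cur <- resample(unique(c(reach, st_cur)))
      }
      n_dwell <- sample.int(3, 1, prob = c(0.55, 0.3, 0.15))
      for (k in seq_len(n_dwell)) {
        dwell_h <- rlnorm(1, log(1.6), 0.9)
        t_end <- t_now + dwell_h * 3600
        if (t_end > day0 + 86400 - 600) t_end <- day0 + 86400 - 600
        if (t_end - t_now > 60) {
          tt <- emit_dwell(t_now, t_end, config$tag_delay,
                           config$detection_radius)
          nd1 <- length(tt)
          nd <- nd + 1L
          if (nd > length(det_t)) {
            det_t <- c(det_t, vector("list", length(det_t)))
            det_tag <- c(det_tag, vector("list", length(det_tag)))
            det_st <- c(det_st, vector("list", length(det_st)))
          }
          det_t[[nd]] <- tt
          det_tag[[nd]] <- rep(tg, nd1)
          det_st[[nd]] <- rep(ids[st_cur], nd1)
          # record qualifying isolated dwells as planted residence bouts
          if (k == 1 && n_dwell == 1 && nd1 >= 2 &&
              (t_end - t_now) >= 2.5 * 3600) {
            nb <- nb + 1L
            if (nb > length(bouts)) bouts <- c(bouts, vector("list",
                                                             length(bouts)))
            bouts[[nb]] <- data.frame(
              tag_id = tg, station_id = ids[st_cur],
              start = t_now, end = t_end, n_detections = nd1)
          }
          last_t[tg] <- max(tt)
          last_st[tg] <- st_cur
        }
        if (k < n_dwell) {
          nb_st <- which(dm[st_cur, ] > 0 & dm[st_cur, ] < 6000)
          if (!length(nb_st)) break
          st_nxt <- resample(nb_st)
          travel <- dm[st_cur, st_nxt] / runif(1, 0.3 * vmax, vmax)
          t_now <- max(last_t[tg], t_now) + travel + runif(1, 300, 3600)
          st_cur <- st_nxt
          if (t_now > day0 + 86400 - 3600) break
        }
      }
    }
    prev_day <- today
  }

  det <- data.frame(
    timestamp = as.POSIXct(unlist(det_t[seq_len(nd)]),
                           origin = "1970-01-01", tz = "UTC"),
    tag_id = unlist(det_tag[seq_len(nd)]),
    station_id = unlist(det_st[seq_len(nd)]),
    sensor_temp = NA_real_, stringsAsFactors = FALSE)

  # lost station: no records after its failure date
  li <- config$lost_station_index
  if (!is.null(li) && !is.na(li) && li >= 1 && li <= n_st) {
    cut <- as.POSIXct(paste(config$lost_date, "00:00:00"), tz = "UTC")
    drop <- det$station_id == ids[li] & det$timestamp >= cut
    det <- det[!drop, , drop = FALSE]
  }

  # drop planted bouts invalidated by the lost station
  planted <- if (nb) do.call(rbind, bouts[seq_len(nb)]) else NULL
  if (!is.null(planted)) {
    planted$start <- as.POSIXct(planted$start, origin = "1970-01-01",
                                tz = "UTC")
    planted$end <- as.POSIXct(planted$end, origin = "1970-01-01",
                              tz = "UTC")
    if (!is.null(li) && !is.na(li) && li >= 1 && li <= n_st)
      planted <- planted[!(planted$station_id == ids[li] &
                             planted$end >= as.POSIXct(
                               paste(config$lost_date, "00:00:00"),
                               tz = "UTC")), , drop = FALSE]
    # keep only bouts isolated from same-station detections of the same
    # tag within the timeout on either side, so the classifier must
    # recover them with exactly the recorded bounds
    if (nrow(planted)) {
      tnum <- as.numeric(det$timestamp)
      iso <- vapply(seq_len(nrow(planted)), function(b) {
        s <- as.numeric(planted$start[b]); e <- as.numeric(planted$end[b])
        same <- det$tag_id == planted$tag_id[b] &
          det$station_id == planted$station_id[b]
        !any(same & ((tnum >= s - 12 * 3600 & tnum < s) |
                       (tnum > e & tnum <= e + 12 * 3600)))
      }, logical(1))
      planted <- planted[iso, , drop = FALSE]
    }
  }

  # planted false detections: inserted between consecutive in-bout
  # transmissions of a tag, at a station > 20 km away
  n_false <- min(config$n_false, nrow(det))
  false_det <- NULL
  if (n_false > 0 && nrow(det) > 2) {
    det <- sort_detections(det)
    gap_next <- c(diff(as.numeric(det$timestamp)), Inf)
    same_tag <- c(det$tag_id[-1] == det$tag_id[-nrow(det)], FALSE)
    ok <- which(same_tag & gap_next > 60 & gap_next < 400)
    # only hosts with a station far enough to be two-sidedly impossible
    far_min <- max(12000, 3 * nn_spacing(dm))
    has_far <- rowSums(dm > far_min) > 0
    ok <- ok[has_far[match(det$station_id[ok], ids)]]
    if (length(ok) > n_false) ok <- sort(resample(ok, n_false))
    if (length(ok)) {
      cut <- as.POSIXct(paste(config$lost_date, "00:00:00"), tz = "UTC")
      lost_ok <- !is.null(li) && !is.na(li) && li >= 1 && li <= n_st
      fr <- lapply(ok, function(i) {
        farst <- ids[which(dm[det$station_id[i], ] > far_min)]
        # never place a false on a station no longer deployed
        if (lost_ok && det$timestamp[i] >= cut)
          farst <- setdiff(farst, ids[li])
        if (!length(farst)) return(NULL)
        data.frame(timestamp = det$timestamp[i] +
                     runif(1, 20, gap_next[i] - 20),
                   tag_id = det$tag_id[i],
                   station_id = resample(farst),
                   sensor_temp = NA_real_, stringsAsFactors = FALSE)
      })
      false_det <- do.call(rbind, fr)
    }
  }
  det$planted_false <- FALSE
  if (!is.null(false_det) && nrow(false_det)) {
    false_det$planted_false <- TRUE
    det <- rbind(det, false_det)
  }
  det <- sort_detections(det)
  false_rows <- det$planted_false
  det$planted_false <- NULL

  list(detections = det,
       truth = list(planted_bouts = planted,
                    false_rows = false_rows,
                    presence = do.call(rbind, presence),
                    eta = eta, lambda = lambda,
                    occupancy = occ, lag_days = config$temp_lag_days))
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: array, tags, environmental series and detection log
#' from one config, optionally written to a directory in the formats the
#' readers consume.
#'
#' @param config \code{\link{sim_config}}.
#' @param dir optional output directory; when given, writes
#'   \code{detections.csv}, \code{stations.csv}, \code{tags.csv} and one
#'   \code{env_*.csv} per series.
#' @return list: \code{config}, \code{stations}, \code{tags}, \code{env},
#'   \code{detections}, \code{truth}.
#' @export
simulate_telemetry <- function(config = sim_config(), dir = NULL) {
  stations <- simulate_array(config)
  tags <- simulate_tags(config)
  env <- simulate_environment(config)
  sim <- simulate_detections(config, stations, env)
  out <- list(config = config, stations = stations, tags = tags, env = env,
              detections = sim$detections, truth = sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_detections(sim$detections, file.path(dir, "detections.csv"))
    st <- stations
    st$deploy_start <- format(st$deploy_start, "%Y-%m-%d %H:%M:%S")
    st$deploy_end <- format(st$deploy_end, "%Y-%m-%d %H:%M:%S")
    write.csv(st, file.path(dir, "stations.csv"), row.names = FALSE)
    write.csv(tags, file.path(dir, "tags.csv"), row.names = FALSE)
    for (nm in names(env)) {
      es <- env[[nm]]
      write.csv(data.frame(datetime_utc = format(es$time,
                                                 "%Y-%m-%d %H:%M:%S"),
                           value = es$value),
                file.path(dir, paste0("env_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}

#' Simulate an isolated stream of residence bouts
#'
#' A stripped-down generator for classifier validation: every detection
#' belongs to one planted station bout, bouts of one tag are separated by
#' more than the timeout or a station change, and the truth table records
#' which bouts meet the residence rule (>= 2 detections over >= 2 h). Some
#' planted bouts deliberately fail the rule (single detection, or span
#' under two hours).
#'
#' @param seed RNG seed.
#' @param n_bouts planted bouts.
#' @param stations station data.frame (defaults to the standard array).
#' @return list: \code{detections}, \code{truth} (one row per planted bout
#'   with \code{qualifies} flag).
#' @export
simulate_bout_stream <- function(seed = 1, n_bouts = 40,
                                 stations = simulate_array(sim_config())) {
  set.seed(seed + 606L)
  ids <- stations$station_id
  tags <- sprintf("T%02d", 1:6)
  t_cursor <- setNames(rep(as.numeric(as.POSIXct("2017-01-01",
                                                 tz = "UTC")), length(tags)),
                       tags)
  rows <- vector("list", n_bouts)
  truth <- vector("list", n_bouts)
  for (b in seq_len(n_bouts)) {
    tg <- sample(tags, 1)
    st <- sample(ids, 1)
    kind <- sample(c("good", "short", "single"), 1,
                   prob = c(0.6, 0.25, 0.15))
    t0 <- t_cursor[tg] + runif(1, 13, 40) * 3600   # > timeout since last
    if (kind == "single") {
      tt <- t0
    } else {
      span <- if (kind == "good") runif(1, 2.05, 30) * 3600 else
        runif(1, 0.2, 1.9) * 3600
      n_det <- max(2L, rpois(1, span / 1800))
      tt <- sort(c(t0, t0 + span, runif(n_det, t0, t0 + span)))
      # enforce in-bout gaps < timeout (spans < 30 h with >= 3 points
      # rarely violate; repair by midpoint insertion if one does)
      g <- diff(tt)
      while (any(g >= 12 * 3600)) {
        i <- which.max(g)
        tt <- sort(c(tt, (tt[i] + tt[i + 1]) / 2))
        g <- diff(tt)
      }
    }
    rows[[b]] <- data.frame(
      timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      tag_id = tg, station_id = st, sensor_temp = NA_real_)
    truth[[b]] <- data.frame(
      tag_id = tg, station_id = st,
      start = as.POSIXct(tt[1], origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(tt[length(tt)], origin = "1970-01-01", tz = "UTC"),
      n_detections = length(tt),
      span_hours = (tt[length(tt)] - tt[1]) / 3600,
      qualifies = length(tt) >= 2 && (tt[length(tt)] - tt[1]) >= 2 * 3600)
    t_cursor[tg] <- tt[length(tt)]
  }
  list(detections = sort_detections(do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}
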
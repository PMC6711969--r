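# Astronomical covariates, daily aggregation, IDW, covariate table.

test_that("photoperiod matches solar geometry at the equinox and orders
          the solstices", {
  expect_equal(as.numeric(photoperiod(as.Date("2017-03-20"), 0, 0)), 12.1,
               tolerance = 0.15 / 12.1)
  p_summer <- photoperiod(as.Date("2017-06-21"), -73.5, 40.5)
  p_winter <- photoperiod(as.Date("2017-12-21"), -73.5, 40.5)
  expect_gt(p_summer, p_winter)
  expect_error(photoperiod(as.Date("2017-06-21"), 0, 89.9), "polar")
})

test_that("photoperiod agrees with an independent solar oracle within
          2 minutes across the year", {
  days <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "7 days")
  mine <- photoperiod(days, -73.5, 40.5)
  orac <- oracle_daylength(days, -73.5, 40.5)
  expect_lt(max(abs(mine - orac)) * 60, 2)
})

test_that("annual photoperiod is unimodal with its peak at the solstice", {
  days <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day")
  p <- as.numeric(photoperiod(days, -73.5, 40.5))
  peak <- days[which.max(p)]
  expect_lte(abs(as.numeric(peak - as.Date("2017-06-21"))), 3)
  # one rise to the summer peak, one fall to the winter minimum (plus the
  # turn after the December solstice at the calendar-year edge)
  d <- diff(p)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  expect_lte(sign_changes, 2)
  trough <- days[which.min(p)]
  expect_lte(abs(as.numeric(trough - as.Date("2017-12-21"))), 3)
})

test_that("moon fraction hits published full and new moons and moves
          continuously", {
  # published phase dates (UTC): full 2018-01-02, 2017-06-09;
  # new 2017-12-18, 2017-06-24
  expect_gte(moon_fraction(as.Date("2018-01-02")), 0.98)
  expect_gte(moon_fraction(as.Date("2017-06-09")), 0.98)
  expect_lte(moon_fraction(as.Date("2017-12-18")), 0.02)
  expect_lte(moon_fraction(as.Date("2017-06-24")), 0.02)
  days <- seq(as.Date("2017-01-01"), as.Date("2017-12-31"), "day")
  m <- moon_fraction(days)
  expect_true(all(m >= 0 & m <= 1))
  expect_lt(max(abs(diff(m))), 0.15)
})

test_that("daily means average within local days and mark gaps missing", {
  tt <- as.POSIXct(c("2017-01-01 10:00", "2017-01-01 20:00",
                     "2017-01-03 10:00"), tz = "UTC")
  es <- env_series(tt + 5 * 3600, c(4, 6, 10), "g", "river_temp")
  d <- daily_mean(es)    # samples placed to land on UTC-5 days 1 and 3
  expect_equal(nrow(d), 3)
  expect_equal(d$value[1], 5)
  expect_true(is.na(d$value[2]))   # gap day missing, not zero
  expect_equal(d$value[3], 10)
})

test_that("hourly sinusoid has daily means at the midline", {
  tt <- seq(as.POSIXct("2017-06-01 05:00", tz = "UTC"),
            by = "hour", length.out = 24 * 10)
  es <- env_series(tt, 15 + 3 * sin(2 * pi * seq_along(tt) / 24),
                   "g", "river_temp")
  d <- daily_mean(es)
  inner <- d$value[2:(nrow(d) - 1)]   # complete days only
  expect_true(all(abs(inner - 15) < 0.25))
})

test_that("pairwise temperature differences cover all source pairs under
          the declared ordering", {
  days <- seq(as.Date("2017-01-01"), by = "day", length.out = 5)
  A <- data.frame(date = days, value = 10)
  B <- data.frame(date = days, value = 7)
  C <- data.frame(date = days, value = 7)
  d <- pairwise_temp_diffs(list(A = A, B = B, C = C))
  expect_named(d, c("date", "A_minus_B", "A_minus_C", "B_minus_C"))
  expect_true(all(d$A_minus_B == 3))
  expect_true(all(d$B_minus_C == 0))
})

test_that("unique daily counts deduplicate tags and zero-fill operational
          days", {
  t0 <- as.POSIXct("2017-01-02 12:00", tz = "UTC")
  det <- data.frame(
    timestamp = t0 + runif(50, 0, 3600),
    tag_id = sample(c("A", "B", "C"), 50, replace = TRUE),
    station_id = "S01", sensor_temp = NA_real_)
  u <- unique_daily_count(det, span = as.Date(c("2017-01-01", "2017-01-04")))
  expect_equal(nrow(u), 4)
  expect_equal(u$UDC, c(0L, 3L, 0L, 0L))
})

test_that("unique daily counts recover planted presence", {
  cfg <- sim_config(seed = 13, n_tags = 40, start = "2016-12-01",
                    end = "2016-12-31")
  sim <- simulate_detections(cfg)
  # presence truth is planted on UTC days, so count on the UTC boundary
  u <- unique_daily_count(sim$detections, span = c(cfg$start, cfg$end),
                          utc_offset = 0)
  pres <- sim$truth$presence
  truth <- aggregate(list(n = pres$tag_id), list(date = pres$date),
                     function(x) length(unique(x)))
  m <- merge(u, truth, all.x = TRUE)
  m$n[is.na(m$n)] <- 0
  # every planted present tag emits at least one detection, and only
  # present tags emit: counts agree exactly
  expect_equal(m$UDC, m$n)
})

test_that("IDW interpolation is exact at stations, symmetric between two,
          and obeys the maximum principle", {
  st <- data.frame(station_id = c("A", "B"), lon = c(-73.50, -73.40),
                   lat = c(40.40, 40.40))
  one <- idw_interpolate(st[1, ], c(A = 10), n_grid = 5)
  expect_true(all(one$value == 10))
  g <- idw_interpolate(st, c(A = 4, B = 8), n_grid = 41, expand = 0)
  expect_true(all(g$value >= 4 & g$value <= 8))
  mid <- g[abs(g$lon - (-73.45)) < 1e-9, ]
  expect_true(all(abs(mid$value - 6) < 1e-6))
  at_a <- g[abs(g$lon - (-73.50)) < 1e-9 & abs(g$lat - 40.40) < 1e-9, ]
  expect_true(all(at_a$value == 4))   # node coincident with station A
  expect_error(idw_interpolate(st[0, ], numeric(0)), "no station")
})

test_that("covariate table joins on day, flags gaps, and spans the study", {
  cfg <- sim_config(seed = 17, n_tags = 30, start = "2017-01-01",
                    end = "2017-01-30")
  sim <- simulate_detections(cfg)
  env <- simulate_environment(cfg)
  u <- unique_daily_count(sim$detections, span = c(cfg$start, cfg$end))
  daily <- lapply(env, daily_mean)
  tab <- build_covariate_table(u, daily, cfg$lon, cfg$lat)
  expect_equal(nrow(tab), 30)
  expect_false(any(tab$incomplete))
  expect_true(all(c("P", "M", "HR_temp", "HR_discharge",
                    "HR_temp_minus_sst_NH") %in% names(tab)))
  expect_true(all(tab$P >= 0 & tab$P <= 24))
  expect_true(all(tab$M >= 0 & tab$M <= 1))

  # a hole in discharge flags exactly that row
  daily$HR_discharge$value[10] <- NA
  tab2 <- build_covariate_table(u, daily, cfg$lon, cfg$lat)
  expect_equal(sum(tab2$incomplete), 1)
  expect_equal(which(tab2$incomplete), 10L)
})

test_that("a full study-span synthetic run yields a model-scale table", {
  cfg <- sim_config(seed = 19)
  tab <- simulate_covariate_table(cfg)
  expect_gte(nrow(tab), 420)
  expect_false(any(duplicated(tab$date)))
})

test_that("highly collinear predictors are dropped in favour of the
          preferred one", {
  tab <- simulate_covariate_table(sim_config(seed = 23))
  kept <- drop_correlated(tab, c("sst_NH", "sst_OS", "HR_discharge"),
                          prefer = "HR_temp")
  expect_false("sst_NH" %in% kept)           # r^2 ~ 0.9 with river temp
  expect_true("HR_discharge" %in% kept)
  expect_true("sst_NH" %in% attr(kept, "dropped"))
})

test_that("the planted thermal lag is recovered from the covariate table", {
  tab <- simulate_covariate_table(sim_config(seed = 29))
  lag <- xcorr_lag(tab$HR_temp, tab$P, max_lag = 60)
  expect_lte(abs(lag - 35), 3)
  expect_gt(attr(lag, "cor"), 0.9)
})
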
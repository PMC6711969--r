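# Residence / movement event classification.

t0 <- as.POSIXct("2017-01-10 00:00:00", tz = "UTC")

mkdet <- function(offsets_h, stations, tag = "A") {
  data.frame(timestamp = t0 + offsets_h * 3600, tag_id = tag,
             station_id = stations, sensor_temp = NA_real_)
}

test_that("bout construction follows the timeout and station-change rules", {
  p <- event_params()
  # four detections within 2.5 h then silence: one bout
  b <- build_bouts(mkdet(c(0, 0.5, 1, 2.5), rep("S1", 4)), p)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_detections, 4)
  expect_equal(b$span_hours, 2.5)

  # 13 h gap (>= 12 h timeout) splits
  b <- build_bouts(mkdet(c(0, 13), rep("S1", 2)), p)
  expect_equal(nrow(b), 2)

  # gap of exactly the timeout terminates (boundary convention)
  b <- build_bouts(mkdet(c(0, 12), rep("S1", 2)), p)
  expect_equal(nrow(b), 2)
  b <- build_bouts(mkdet(c(0, 11.999), rep("S1", 2)), p)
  expect_equal(nrow(b), 1)

  # station change closes immediately: two single-detection bouts
  b <- build_bouts(mkdet(c(0, 40 / 60), c("S1", "S2")), p)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_detections, c(1L, 1L))
})

test_that("simultaneous detections resolve to the continuing station", {
  p <- event_params()
  d <- mkdet(c(0, 1, 1, 2), c("S1", "S2", "S1", "S1"))
  b <- build_bouts(d, p)
  # previous station S1 continues through the tie; S2 forms its own bout
  expect_equal(sum(b$station_id == "S1"), 2)
  expect_equal(b$n_detections[b$station_id == "S2"], 1L)
  # at stream start, ties break lexicographically
  d2 <- mkdet(c(0, 0), c("S2", "S1"))
  b2 <- build_bouts(d2, p)
  expect_equal(b2$station_id[1], "S1")
})

test_that("classification honours the residence and movement thresholds", {
  st <- test_stations()
  p <- event_params()
  # 2.5 h spanning bout of 4 -> residence
  ev <- classify_events(build_bouts(mkdet(c(0, 0.5, 1, 2.5),
                                          rep("S01", 4)), p), st, p)
  expect_equal(nrow(ev$residence), 1)
  expect_equal(ev$residence$duration_hours, 2.5)
  # exactly 2 h qualifies ("minimum period"); 1 h does not
  ev <- classify_events(build_bouts(mkdet(c(0, 2), rep("S01", 2)), p), st, p)
  expect_equal(nrow(ev$residence), 1)
  ev <- classify_events(build_bouts(mkdet(c(0, 1), rep("S01", 2)), p), st, p)
  expect_equal(nrow(ev$residence), 0)
})

test_that("movement ROM is matrix distance over elapsed time", {
  st <- test_stations()
  dm <- build_distance_matrix(st)
  p <- event_params()
  d <- rbind(mkdet(c(0, 1), rep("S01", 2)), mkdet(c(11, 12), rep("S05", 2)))
  ev <- classify_events(build_bouts(d, p), dm, p)
  expect_equal(nrow(ev$movements), 1)
  gap_s <- 10 * 3600
  expect_equal(ev$movements$rom, dm["S01", "S05"] / gap_s, tolerance = 1e-10)
  # worked arithmetic: 10 km in 10 h -> 0.278 m/s
  expect_equal(10000 / 36000, 0.278, tolerance = 1e-3)

  # gaps of 5 days or more never form movement events
  d <- rbind(mkdet(0, "S01"), mkdet(6 * 24, "S05"))
  ev <- classify_events(build_bouts(d, p), dm, p)
  expect_equal(nrow(ev$movements), 0)
  d <- rbind(mkdet(0, "S01"), mkdet(4.9 * 24, "S05"))
  ev <- classify_events(build_bouts(d, p), dm, p)
  expect_equal(nrow(ev$movements), 1)
})

test_that("residence summaries use the n-1 denominator and handle n<=1", {
  r3 <- data.frame(tag_id = "A", station_id = "S1",
                   start = t0, end = t0, duration_hours = c(2, 4, 6),
                   n_detections = 2L)
  s <- summarize_residence(r3)
  expect_equal(s$mean, 4); expect_equal(s$sd, 2)
  expect_equal(s$range, c(2, 6))
  s1 <- summarize_residence(r3[1, ])
  expect_equal(s1$n, 1); expect_true(is.na(s1$sd))
  s0 <- summarize_residence(r3[0, ])
  expect_equal(s0$n, 0); expect_true(is.na(s0$mean))
})

test_that("every detection belongs to exactly one bout; residences of one
          tag never overlap", {
  st <- test_stations()
  p <- event_params()
  for (seed in 1:8) {
    det <- random_stream(150, st$station_id[1:6], seed)
    b <- build_bouts(det, p)
    expect_equal(sum(b$n_detections), nrow(det))
    ev <- classify_events(b, st, p)
    r <- ev$residence
    for (tg in unique(r$tag_id)) {
      ri <- r[r$tag_id == tg, ]
      if (nrow(ri) > 1) {
        ri <- ri[order(ri$start), ]
        expect_true(all(ri$start[-1] >= ri$end[-nrow(ri)]))
      }
    }
  }
})

test_that("greedy classifier matches the brute-force oracle on random
          streams", {
  st <- test_stations()
  dm <- build_distance_matrix(st)
  p <- event_params()
  for (seed in 1:25) {
    det <- random_stream(sample(20:200, 1), st$station_id[1:8],
                         seed = 7000 + seed)
    got <- classify_events(build_bouts(det, p), dm, p)
    want <- oracle_events(det, dm, p)
    expect_setequal(event_key(got$residence), event_key(want$residence))
    expect_setequal(event_key(got$movements), event_key(want$movements))
    if (!is.null(want$movements)) {
      o <- order(event_key(got$movements))
      w <- order(event_key(want$movements))
      expect_equal(got$movements$rom[o], want$movements$rom[w],
                   tolerance = 1e-9)
    }
  }
})

test_that("planted residence bouts are recovered verbatim, and only the
          qualifying ones", {
  st <- test_stations()
  p <- event_params()
  bs <- simulate_bout_stream(seed = 21, n_bouts = 60, stations = st)
  ev <- classify_events(build_bouts(bs$detections, p), st, p)
  truth_q <- bs$truth[bs$truth$qualifies, ]
  got <- ev$residence
  key <- function(d) paste(d$tag_id, d$station_id,
                           format(d$start, "%H:%M:%OS2"),
                           format(d$end, "%H:%M:%OS2"))
  expect_setequal(key(got), key(truth_q))      # 100% recall AND precision
  expect_gt(nrow(truth_q), 10)
  expect_gt(sum(!bs$truth$qualifies), 5)       # non-qualifying bouts exist
})
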
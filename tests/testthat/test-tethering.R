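# Spot detection, nearest-neighbor linking with gap closing, the tethering
# event state machine with the strict duration filter, and dwell statistics.

gauss_frame <- function(r0, c0, n = 64, amp = 0.9, sigma = 1.5) {
  f <- matrix(0, n, n)
  rr <- row(f); cc <- col(f)
  amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

test_that("foci detection finds rendered spots with sub-pixel accuracy", {
  p <- tracking_params()
  d <- detect_foci(gauss_frame(30.4, 41.7), p)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$row - 30.4), 1)
  expect_lt(abs(d$col - 41.7), 1)

  expect_equal(nrow(detect_foci(matrix(0, 64, 64), p)), 0L)

  two <- gauss_frame(20, 20) + gauss_frame(20 + 15, 20 + 15)  # 10 sigma apart
  expect_equal(nrow(detect_foci(two, p)), 2L)
})

test_that("linking keeps identity, closes single-frame gaps", {
  p <- tracking_params(max_link_px = 5, max_gap_frames = 1)
  set.seed(12)
  # one jittering spot over 20 frames
  spots <- lapply(1:20, function(t) {
    data.frame(row = 30 + stats::rnorm(1, 0, 0.5),
               col = 30 + stats::rnorm(1, 0, 0.5), intensity = 1)
  })
  tr <- link_tracks(spots, p)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 20L)

  # spot missing for one frame: still a single track
  spots_gap <- spots
  spots_gap[[10]] <- spots_gap[[10]][0, ]
  trg <- link_tracks(spots_gap, p)
  expect_equal(length(unique(trg$track_id)), 1L)
  expect_equal(nrow(trg), 19L)

  # two far-apart spots never swap identity (checked against an
  # exhaustive-assignment oracle)
  set.seed(13)
  spots2 <- lapply(1:15, function(t) {
    data.frame(row = c(10, 50) + stats::rnorm(2, 0, 0.5),
               col = c(10, 50) + stats::rnorm(2, 0, 0.5),
               intensity = 1)
  })
  tr2 <- link_tracks(spots2, p)
  expect_equal(length(unique(tr2$track_id)), 2L)
  oracle <- oracle_link_two(spots2)
  for (id in unique(tr2$track_id)) {
    path <- tr2[tr2$track_id == id, ]
    which_oracle <- if (sum((unlist(path[1, c("row", "col")]) -
                               oracle$a[[1]])^2) < 1e-12) "a" else "b"
    ref <- do.call(rbind, oracle[[which_oracle]])
    expect_equal(unname(as.matrix(path[, c("row", "col")])), unname(ref))
  }
})

test_that("the event filter is strictly greater than 15 s", {
  p <- tracking_params()
  # a 15.0 s event (6 tethered frames at 3 s) must be excluded
  tl15 <- gen_timelapse(timelapse_spec(n_frames = 30, n_events = 1, p_fusion = 1,
                                       dwell_dist = list(name = "point", value = 15),
                                       jitter_sd_px = 0, max_start_frame = 2,
                                       seed = 6))
  expect_equal(tl15$truth$duration_s, 15)
  ev15 <- track_tethering(tl15$foci, tl15$mito, p)
  expect_equal(nrow(ev15), 0L)

  # an 18.0 s event ending in a label merge is included as fused
  tl18 <- gen_timelapse(timelapse_spec(n_frames = 30, n_events = 1, p_fusion = 1,
                                       dwell_dist = list(name = "point", value = 18),
                                       jitter_sd_px = 0, max_start_frame = 2,
                                       seed = 6))
  ev18 <- track_tethering(tl18$foci, tl18$mito, p)
  expect_equal(nrow(ev18), 1L)
  expect_equal(ev18$duration_s, 18)
  expect_equal(ev18$outcome, "fused")
})

test_that("programmed events are recovered with matching outcomes", {
  tl <- gen_timelapse(timelapse_spec(n_frames = 60, n_events = 5,
                                     dwell_dist = list(name = "point", value = 30),
                                     p_fusion = 0.4, seed = 2))
  ev <- track_tethering(tl$foci, tl$mito)
  expect_equal(nrow(ev), 5L)
  # match events to truth through the junction position of their track
  tr_truth <- tl$truth[order(tl$truth$junction_row, tl$truth$junction_col), ]
  # every recovered duration is a positive multiple of dt above the filter
  p <- tracking_params()
  expect_true(all(ev$duration_s > p$min_event_s))
  expect_true(all(abs(ev$duration_s / p$dt_s - round(ev$duration_s / p$dt_s)) < 1e-9))
  expect_equal(sort(table(ev$outcome)[unique(ev$outcome)]),
               sort(table(tl$truth$outcome)[unique(tl$truth$outcome)]))
  # duration bias within one frame interval on point-mass fixtures
  expect_true(all(abs(ev$duration_s - 30) <= p$dt_s))
})

test_that("dwell statistics summarize durations and fusion outcomes", {
  ev <- data.frame(event_id = 1:2, track_id = 1:2, start_frame = 1,
                   end_frame = 7, duration_s = c(18, 30),
                   outcome = c("fused", "separated"),
                   partner_a = 1, partner_b = 2)
  st <- tether_stats(ev)
  expect_equal(st$summary$mean_duration_s, 24)
  expect_equal(st$summary$sem_duration_s, 6)
  expect_equal(st$summary$fruitful, 1)

  ev$outcome <- "fused"
  expect_equal(tether_stats(ev)$summary$unfruitful, 0)

  # two conditions: ratio of means (second / first) and a t-test p-value
  ev2 <- rbind(ev, transform(ev, duration_s = duration_s * 2))
  st2 <- tether_stats(ev2, condition = rep(c("WT", "KO"), each = 2))
  expect_equal(st2$ratio, 2)
  expect_true(is.finite(st2$p_value))

  expect_error(tether_stats(ev[0, ]), "no events")
})
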
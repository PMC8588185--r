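small_sched <- function() {
  # e2 starts late enough that e1's recovery tail cannot touch its baseline
  event_schedule(data.frame(
    event_id = c("e1", "e2"), start_time = c(300, 1500),
    duration_s = c(300, 300), source_type = c("tone", "white"),
    nominal_frequency_hz = c(50, NA), spl_db = c(165, 120)))
}

test_that("simulate_school is deterministic and respects its config", {
  cfg <- scene_config(n_fish = 30, seed = 4)
  t1 <- simulate_school(cfg, list(), NULL, duration = 60)
  t2 <- simulate_school(cfg, list(), NULL, duration = 60)
  expect_identical(t1$depth, t2$depth)
  expect_identical(t1$truth, t2$truth)
  expect_equal(ncol(t1$x), 30)
  expect_equal(nrow(t1$x), 60 / cfg$ping_interval)
  # positions inside the cage cylinder, depths inside the cage
  expect_true(all(sqrt(t1$x^2 + t1$y^2) <= cfg$cage_diameter / 2))
  expect_true(all(t1$depth > 0 & t1$depth < cfg$cage_depth))
  # truth limits bracket the mean range at every ping
  expect_true(all(t1$truth$lower_range <= t1$truth$mean_range + 1e-9))
  expect_true(all(t1$truth$upper_range >= t1$truth$mean_range - 1e-9))
})

test_that("config and reaction validation errors fire", {
  expect_error(scene_config(n_fish = 900, school_vertical_extent = 30),
               "smaller than cage_depth")
  expect_error(scene_config(swim_speed = -1), "positive")
  expect_error(reaction_spec(), "trigger")
  expect_error(reaction_spec(source_type = "tone", contraction_factor = 0),
               "contraction_factor")
  rx <- reaction_spec(event_id = "nope", dive_delta = -1)
  expect_error(simulate_school(scene_config(n_fish = 5), list(rx),
                               small_sched(), 60), "unknown event_id")
})

test_that("changing the seed changes noise but not 1-h truth averages (<2%)", {
  mean_1h <- function(seed) {
    cfg <- scene_config(n_fish = 200, ping_interval = 2, seed = seed)
    mean(simulate_school(cfg, list(), NULL, 3600)$truth$mean_range)
  }
  m <- vapply(c(1, 2, 3), mean_1h, numeric(1))
  expect_false(isTRUE(all.equal(m[1], m[2])))
  expect_lt(max(abs(m - mean(m))) / mean(m), 0.02)
})

test_that("truth event metrics recover configured reaction magnitudes", {
  sched <- small_sched()
  rx <- list(reaction_spec(event_id = "e1", dive_delta = -3.3,
                           contraction_factor = 13 / 19, speed_factor = 2,
                           onset_latency = 0, transition_tau = 10))
  cfg <- scene_config(n_fish = 300, ping_interval = 1, seed = 8)
  truth <- simulate_school(cfg, rx, sched, duration = 2100)
  tm <- truth_event_metrics(truth, sched, stabilize_s = 60)
  r1 <- tm[tm$event_id == "e1", ]
  expect_equal(r1$mean_range_change, -3.3, tolerance = 0.1)
  expect_equal(r1$extent_ratio, 13 / 19, tolerance = 0.05)
  expect_equal(r1$speed_ratio, 2, tolerance = 0.05)
  # no-reaction event: all deltas ~ 0 / ratios ~ 1
  r2 <- tm[tm$event_id == "e2", ]
  expect_equal(r2$mean_range_change, 0, tolerance = 0.25)
  expect_equal(r2$extent_ratio, 1, tolerance = 0.05)
  expect_equal(r2$speed_ratio, 1, tolerance = 0.01)
})

test_that("habituation lengthens latency then suppresses the response", {
  sched <- event_schedule(data.frame(
    event_id = c("w1", "w2", "w3"), start_time = c(600, 2400, 4200),
    duration_s = 900, source_type = "windmill",
    nominal_frequency_hz = NA, spl_db = 182))
  # latency 480 s (8 min), +180 s per repeat, no response from the 3rd on
  rx <- list(reaction_spec(source_type = "windmill", dive_delta = 2,
                           onset_latency = 480, habituation_increment = 180,
                           habituation_max = 2))
  cfg <- scene_config(n_fish = 50, ping_interval = 5, seed = 2)
  truth <- simulate_school(cfg, rx, sched, duration = 5400)
  ann <- truth$annotations
  expect_equal(ann$onset_time - ann$start_time, c(480, 660, 840))
  expect_equal(ann$responded, c(TRUE, TRUE, FALSE))
  # realized depth shift: present in w1/w2 windows, absent in w3
  tm <- truth_event_metrics(truth, sched, stabilize_s = 700)
  expect_gt(tm$mean_range_change[1], 1)
  expect_gt(tm$mean_range_change[2], 0.5)
  expect_lt(abs(tm$mean_range_change[3]), 0.5)
})

test_that("opposite-direction swimmers appear only in long responding emissions", {
  sched <- event_schedule(data.frame(
    event_id = c("s1", "w1"), start_time = c(200, 600),
    duration_s = c(15, 900), source_type = c("windmill", "windmill"),
    nominal_frequency_hz = NA, spl_db = 182))
  rx <- list(reaction_spec(source_type = "windmill", speed_factor = 1.5,
                           n_opposite = 15, long_emission_s = 300))
  cfg <- scene_config(n_fish = 100, ping_interval = 5, seed = 6)
  truth <- simulate_school(cfg, rx, sched, duration = 1600)
  tm <- truth_event_metrics(truth, sched)
  expect_equal(tm$opposite_count[tm$event_id == "s1"], 0)
  expect_equal(tm$opposite_count[tm$event_id == "w1"], 15)
})

test_that("rendering: empty scene is noise, on-axis fish lands at its range", {
  cfg0 <- scene_config(n_fish = 0, seed = 3)
  t0 <- simulate_school(cfg0, list(), NULL, duration = 30)
  e0 <- render_echogram(t0, cfg0)
  expect_true(all(abs(e0$values - cfg0$noise_floor_mean) <
                    5 * cfg0$noise_floor_sd))
  # stationary on-axis fish at range 10 m: one strong sample per ping at the
  # 10 m bin with level ~ ts (echo_width shrunk to a single bin)
  cfg1 <- scene_config(n_fish = 1, echo_width = 0.01, seed = 1)
  st <- scene_truth(ping_times = 0:9,
                    x = matrix(cfg1$transducer_offset, 10, 1),
                    y = matrix(0, 10, 1),
                    depth = matrix(cfg1$transducer_depth - 10, 10, 1),
                    ts = -15, cfg = cfg1)
  e1 <- render_echogram(st, cfg1)
  peak_bin <- apply(e1$values, 1, which.max)
  expect_true(all(abs(e1$range_bins[peak_bin] - 10) <= cfg1$range_step))
  expect_equal(unname(e1$values[cbind(1:10, peak_bin)]),
               rep(-15, 10), tolerance = 0.01)
  # rendering is deterministic given the config seed
  expect_identical(render_echogram(st, cfg1)$values, e1$values)
})

test_that("a fish rising 0.2 m/ping renders a trace with that tilt (within 10%)", {
  cfg <- scene_config(n_fish = 1, seed = 5, noise_floor_mean = -85)
  n <- 55
  depth <- matrix(21 - 0.2 * (0:(n - 1)), n, 1)   # range 3 -> 13.8 m
  st <- scene_truth(ping_times = (0:(n - 1)) * cfg$ping_interval,
                    x = matrix(cfg$transducer_offset, n, 1),
                    y = matrix(0, n, 1), depth = depth, ts = -12, cfg = cfg)
  e <- render_echogram(st, cfg)
  tr <- extract_traces(e, threshold_db = -70, min_size_px = 6,
                       min_level_db = -60)
  expect_gte(length(tr), 1)
  main <- tr[[which.max(vapply(tr, function(x) x$length_pings, 1))]]
  expect_equal(main$tilt_slope, 0.2, tolerance = 0.1 * 0.2 + 0.01)
})

test_that("clipping at the dynamic range ceiling is applied and flagged", {
  cfg <- scene_config(n_fish = 1, echo_width = 0.01, dynamic_range_max = -40,
                      seed = 1)
  st <- scene_truth(ping_times = 0:4, x = matrix(cfg$transducer_offset, 5, 1),
                    y = matrix(0, 5, 1),
                    depth = matrix(cfg$transducer_depth - 10, 5, 1),
                    ts = -15, cfg = cfg)
  e <- render_echogram(st, cfg)
  expect_lte(max(e$values), -40)
  expect_gte(attr(e, "n_clipped"), 5)
})

test_that("rendered echograms round-trip through the EGRAM container", {
  cfg <- scene_config(n_fish = 15, seed = 10)
  truth <- simulate_school(cfg, list(), NULL, duration = 30)
  e <- render_echogram(truth, cfg)
  path <- withr::local_tempfile(fileext = ".egram")
  write_egram(e, path)
  e2 <- read_egram(path)
  expect_identical(e2$values, e$values)
  expect_equal(e2$ping_times, e$ping_times)
  expect_equal(e2$range_bins, e$range_bins)
})
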
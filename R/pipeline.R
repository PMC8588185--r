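#' Run the full monitoring protocol on a simulated scene
#'
#' One reproducible end-to-end run: simulate the school, render the
#' echogram, compute the per-ping envelope and its aggregates, extract
#' traces, build the per-event behavioral table with composite scores and
#' response classes, run the statistics layer where the design allows, and
#' write everything (plus a manifest recording parameters, seed and package
#' version) to `out_dir`. Deterministic given the seed embedded in `scene`.
#'
#' @param scene a [scene_config()].
#' @param reactions list of [reaction_spec()].
#' @param schedule an [event_schedule()].
#' @param duration scene duration (s).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param threshold_db envelope/binarization threshold (dB).
#' @param min_size_px,min_level_db trace filter parameters.
#' @param window_s aggregation window (s) for the long-run envelope table.
#' @return (invisibly) list with `truth`, `echogram`, `envelope`, `traces`,
#'   `events` (scored event table), `anova`, `tukey`, `levene`, `manifest`.
#' @export
run_protocol <- function(scene, reactions = list(), schedule, duration,
                         out_dir = NULL, threshold_db = -70,
                         min_size_px = 6, min_level_db = -60,
                         window_s = 3600) {
  truth <- simulate_school(scene, reactions, schedule, duration)
  eg <- render_echogram(truth, scene)
  env <- school_envelope(eg, threshold_db)
  hw <- hourly_windows(eg, window_s)
  env_agg <- aggregate_envelope(env, hw)
  traces <- extract_traces(eg, threshold_db, min_size_px, min_level_db)
  tr_tab <- traces_table(traces)
  events <- build_event_table(schedule, env, tr_tab)
  if (nrow(events) >= 3 && sum(stats::complete.cases(
        events[c("d_com", "d_extent", "d_length", "d_tilt")])) >= 3) {
    sc <- composite_score(events)
    events$score <- as.numeric(sc)
    events$behavior_class <- classify_behavior(events$score)
  } else {
    events$score <- NA_real_
    events$behavior_class <- NA_character_
  }
  stats_out <- run_event_stats(events)
  manifest <- list(
    package = "echoschool",
    version = as.character(utils::packageVersion("echoschool")),
    seed = scene$seed,
    duration_s = duration,
    threshold_db = threshold_db,
    min_size_px = min_size_px,
    min_level_db = min_level_db,
    window_s = window_s,
    scene = unclass(scene),
    n_reactions = length(reactions),
    n_events = nrow(schedule)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_egram(eg, file.path(out_dir, "echogram.egram"))
    write_table(truth$truth, file.path(out_dir, "truth.csv"))
    if (nrow(truth$annotations))
      write_table(truth$annotations, file.path(out_dir, "reactions.csv"))
    write_table(env, file.path(out_dir, "envelope.csv"))
    write_table(env_agg, file.path(out_dir, "envelope_windows.csv"))
    write_table(tr_tab, file.path(out_dir, "traces.csv"))
    write_table(events, file.path(out_dir, "events_scored.csv"))
    if (!is.null(stats_out$anova))
      write_table(stats_out$anova, file.path(out_dir, "anova.csv"))
    if (!is.null(stats_out$tukey))
      write_table(stats_out$tukey$means, file.path(out_dir, "tukey.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(truth = truth, echogram = eg, envelope = env,
                 envelope_windows = env_agg, traces = traces,
                 events = events, anova = stats_out$anova,
                 tukey = stats_out$tukey, levene = stats_out$levene,
                 manifest = manifest))
}

# Statistics layer over a scored event table; returns NULLs where the
# design cannot support a test (few events, single level, ...).
run_event_stats <- function(events, response = "d_com", alpha = 0.05) {
  out <- list(anova = NULL, tukey = NULL, levene = NULL)
  ok <- stats::complete.cases(events[[response]])
  ev <- events[ok, , drop = FALSE]
  if (nrow(ev) < 4) return(out)
  lev_ok <- length(unique(ev$level_class)) >= 2
  typ_ok <- length(unique(ev$source_type)) >= 2
  if (lev_ok && all(table(ev$level_class) >= 2))
    out$levene <- try(levene_test(ev[[response]], ev$level_class), silent = TRUE)
  aov_try <- if (lev_ok && typ_ok) {
    try(two_way_anova(ev[[response]], ev$source_type, ev$level_class),
        silent = TRUE)
  } else if (lev_ok) {
    try(two_way_anova(ev[[response]], ev$level_class), silent = TRUE)
  } else NULL
  if (!inherits(aov_try, "try-error")) out$anova <- aov_try
  if (lev_ok && all(table(ev$level_class) >= 2) &&
      nrow(ev) > length(unique(ev$level_class)))
    out$tukey <- try(tukey_subsets(ev[[response]], ev$level_class, alpha),
                     silent = TRUE)
  for (k in names(out)) if (inherits(out[[k]], "try-error")) out[[k]] <- NULL
  out
}

#' Generate the toy fixtures used throughout the test suite and examples
#'
#' Writes small plain-text fixtures to `dir` and returns them as objects:
#'
#' * `uniform_ping`: 1-ping echogram, uniform values over bins at 5..10 m
#'   (center of mass at the midpoint, 7.5 m).
#' * `ramp_trace`: an echogram holding a single synthetic trace whose
#'   per-ping maximum climbs 1 m/ping (tilt slope +1.0).
#' * `three_blobs`: binary mask with 3 separated 4-connected regions.
#' * `demo_schedule`: a 4-event schedule (3 short tones and one 8-minute
#'   windmill emission), sized for a 20-minute demo scene.
#'
#' @param dir output directory; `NULL` to skip file output.
#' @param seed unused randomness guard (fixtures are deterministic), kept so
#'   callers can thread one seed through everything.
#' @return list of fixture objects, invisibly when writing.
#' @export
make_fixtures <- function(dir = NULL, seed = 1L) {
  uniform_vals <- matrix(-40, 1, 6)
  uniform_ping <- echogram(uniform_vals, ping_times = 0,
                           range_bins = seq(5, 10), transducer_depth = 24)
  ramp_vals <- matrix(-95, 8, 20)
  for (i in 1:8) {
    ramp_vals[i, 9 + i] <- -30                   # max at range 10 + i m
    ramp_vals[i, 10 + i] <- -38
  }
  ramp_trace <- echogram(ramp_vals, ping_times = seq(0, 3.5, by = 0.5),
                         range_bins = seq(0.5, 19.5), transducer_depth = 24)
  blobs <- matrix(FALSE, 8, 8)
  blobs[1:2, 1:2] <- TRUE
  blobs[5:6, 2:4] <- TRUE
  blobs[2:4, 6:8] <- TRUE
  demo_schedule <- event_schedule(data.frame(
    event_id = c("e1", "e2", "e3", "w1"),
    start_time = c(120, 300, 480, 660),
    duration_s = c(15, 15, 15, 480),
    source_type = c("tone", "tone", "tone", "windmill"),
    nominal_frequency_hz = c(50, 500, 1000, NA),
    spl_db = c(165, 160, 155, 182)))
  fx <- list(uniform_ping = uniform_ping, ramp_trace = ramp_trace,
             three_blobs = blobs, demo_schedule = demo_schedule)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_egram(uniform_ping, file.path(dir, "uniform_ping.egram"))
    write_egram(ramp_trace, file.path(dir, "ramp_trace.egram"))
    utils::write.csv(blobs * 1L, file.path(dir, "three_blobs.csv"),
                     row.names = FALSE)
    write_table(demo_schedule, file.path(dir, "demo_schedule.csv"))
  }
  invisible(fx)
}
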
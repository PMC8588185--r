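#' Scene configuration for the cage/echosounder simulator
#'
#' Describes the simulated world: a cylindrical feeding cage holding a school
#' of large pelagic fish monitored by an upward-looking single-beam
#' echosounder mounted near the cage bottom. Defaults emulate a ~50 m diameter
#' x 28 m deep commercial cage with ~900 fish, a 200 kHz transducer at 24 m
#' depth with a 25 degree aperture at -3 dB, a circadian day/night mean-depth
#' difference of 2.8 m (shallower by day), and a school vertical extent of
#' 19 m.
#'
#' The vertical coordinate of all *truth* outputs is range from the
#' transducer face (the canonical coordinate of the analysis); depth below
#' the surface is used internally and available through the echogram
#' conversion helpers.
#'
#' @param n_fish number of fish (default 900).
#' @param cage_diameter,cage_depth cage dimensions (m).
#' @param mean_depth mean school depth below surface (m), midpoint between
#'   day and night.
#' @param circadian_amplitude peak-to-trough day/night difference of the mean
#'   school depth (m); the school is shallower at midday, deeper at midnight.
#' @param school_vertical_extent vertical extent of the school (m); per-fish
#'   depths are spread around the mean with standard deviation `extent / 4`.
#' @param swim_speed horizontal swimming speed (m/s).
#' @param circle_radius mean radius of the circular swimming pattern (m).
#' @param circle_radius_sd per-fish spread of orbit radii (m).
#' @param transducer_depth transducer depth below the surface (m).
#' @param transducer_offset horizontal distance of the transducer from the
#'   cage axis (m); the default places it at the middle of the cage radius.
#' @param beam_width_3db full beam aperture at -3 dB (degrees).
#' @param ping_interval seconds between pings.
#' @param range_step range-bin size (m).
#' @param noise_floor_mean,noise_floor_sd background noise level per bin (dB).
#' @param ts_mean,ts_sd per-fish target strength distribution (dB); constant
#'   per fish, no orientation dependence. Only relative levels matter.
#' @param echo_width vertical extent of one fish echo (m): fish are extended
#'   targets (body length plus pulse envelope), so each echo spreads its
#'   energy over neighbouring range bins with a Gaussian profile of this
#'   full width.
#' @param dynamic_range_max saturation ceiling of the rendered echogram (dB).
#' @param depth_jitter_sd,depth_jitter_tau Ornstein-Uhlenbeck depth jitter per
#'   fish: stationary sd (m) and correlation time (s).
#' @param t0 epoch start time of the simulation (s); `t0 = 0` is midnight, so
#'   the circadian phase is defined by clock time, not sun ephemerides.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(n_fish = 900,
                         cage_diameter = 50,
                         cage_depth = 28,
                         mean_depth = 12,
                         circadian_amplitude = 2.8,
                         school_vertical_extent = 19,
                         swim_speed = 1,
                         circle_radius = 12.5,
                         circle_radius_sd = 2.5,
                         transducer_depth = 24,
                         transducer_offset = 12.5,
                         beam_width_3db = 25,
                         ping_interval = 0.5,
                         range_step = 0.25,
                         noise_floor_mean = -85,
                         noise_floor_sd = 2,
                         ts_mean = -15,
                         ts_sd = 3,
                         echo_width = 1,
                         dynamic_range_max = 0,
                         depth_jitter_sd = 0.3,
                         depth_jitter_tau = 60,
                         t0 = 0,
                         seed = 1L) {
  cfg <- list(n_fish = as.integer(n_fish), cage_diameter = cage_diameter,
              cage_depth = cage_depth, mean_depth = mean_depth,
              circadian_amplitude = circadian_amplitude,
              school_vertical_extent = school_vertical_extent,
              swim_speed = swim_speed, circle_radius = circle_radius,
              circle_radius_sd = circle_radius_sd,
              transducer_depth = transducer_depth,
              transducer_offset = transducer_offset,
              beam_width_3db = beam_width_3db,
              ping_interval = ping_interval, range_step = range_step,
              noise_floor_mean = noise_floor_mean,
              noise_floor_sd = noise_floor_sd,
              ts_mean = ts_mean, ts_sd = ts_sd, echo_width = echo_width,
              dynamic_range_max = dynamic_range_max,
              depth_jitter_sd = depth_jitter_sd,
              depth_jitter_tau = depth_jitter_tau,
              t0 = t0, seed = as.integer(seed))
  phys <- c("cage_diameter", "cage_depth", "mean_depth",
            "school_vertical_extent", "swim_speed", "circle_radius",
            "transducer_depth", "ping_interval", "range_step")
  for (k in phys) if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
    stop("scene_config: ", k, " must be positive")
  if (cfg$n_fish < 0) stop("scene_config: n_fish must be >= 0")
  if (cfg$school_vertical_extent >= cfg$cage_depth)
    stop("scene_config: school_vertical_extent must be smaller than cage_depth")
  if (cfg$circadian_amplitude < 0)
    stop("scene_config: circadian_amplitude must be >= 0")
  class(cfg) <- "scene_config"
  cfg
}

#' Stimulus reaction specification
#'
#' Describes how the school reacts to a class of stimulus events: a trigger
#' (either a specific `event_id` or a `source_type` plus minimum level class),
#' the realized changes (vertical displacement, vertical contraction, speed
#' multiplier, tilt ramp rate), the onset latency, the post-event recovery
#' time, and a habituation rule: each repeated trigger adds
#' `habituation_increment` seconds to the latency, and from repeat number
#' `habituation_max` (0-based) onward the response is suppressed entirely.
#'
#' @param event_id trigger on one specific event id (or `NULL`).
#' @param source_type trigger on all events of this source type (or `NULL`).
#' @param min_level_class minimum level class (see [classify_level()]) for a
#'   `source_type` trigger; `"background"` matches every level.
#' @param dive_delta signed change of mean school range-from-transducer (m);
#'   negative values move the school *toward* a bottom-mounted transducer,
#'   i.e. a dive.
#' @param contraction_factor multiplier on the school vertical extent
#'   (e.g. `13/19` for a contraction from 19 m to 13 m); must be > 0.
#' @param speed_factor multiplier on swimming speed while the reaction is
#'   active.
#' @param tilt_bias vertical ramp rate of the school mean range during the
#'   reaction transition (m/ping, positive = range increasing = upward for an
#'   up-looking transducer); 0 selects a smooth exponential transition
#'   instead. Every trace recorded during the ramp inherits this slope.
#' @param onset_latency seconds from event start to reaction onset.
#' @param recovery_time exponential recovery time constant after the event
#'   ends (s).
#' @param transition_tau exponential time constant of the onset transition
#'   (s), used for extent/speed always and for depth when `tilt_bias = 0`.
#' @param habituation_increment seconds added to the latency per repeated
#'   trigger.
#' @param habituation_max number of responses before full suppression
#'   (default 2: respond, respond later, then nothing).
#' @param n_opposite number of fish that reverse their swimming direction
#'   during a long emission (>= `long_emission_s`) while the reaction is
#'   active.
#' @param long_emission_s minimum event duration (s) counting as a long
#'   emission.
#' @return A list of class `"reaction_spec"`.
#' @export
reaction_spec <- function(event_id = NULL, source_type = NULL,
                          min_level_class = "background",
                          dive_delta = 0, contraction_factor = 1,
                          speed_factor = 1, tilt_bias = 0,
                          onset_latency = 0, recovery_time = 60,
                          transition_tau = 20,
                          habituation_increment = 0, habituation_max = Inf,
                          n_opposite = 15, long_emission_s = 300) {
  if (is.null(event_id) && is.null(source_type))
    stop("reaction_spec needs event_id or source_type trigger")
  if (!is.null(source_type) && !source_type %in% SOURCE_TYPES)
    stop("unknown source_type: ", source_type)
  if (!min_level_class %in% LEVEL_CLASSES)
    stop("unknown level class: ", min_level_class)
  if (contraction_factor <= 0) stop("contraction_factor must be > 0")
  if (recovery_time < 0) stop("recovery_time must be >= 0")
  structure(list(event_id = event_id, source_type = source_type,
                 min_level_class = min_level_class,
                 dive_delta = dive_delta,
                 contraction_factor = contraction_factor,
                 speed_factor = speed_factor, tilt_bias = tilt_bias,
                 onset_latency = onset_latency, recovery_time = recovery_time,
                 transition_tau = transition_tau,
                 habituation_increment = habituation_increment,
                 habituation_max = habituation_max,
                 n_opposite = n_opposite, long_emission_s = long_emission_s),
            class = "reaction_spec")
}

#' Read/write scene configuration files
#'
#' Plain-text `key: value` config with `[section]` headers: one `[scene]`
#' section holding [scene_config()] fields and any number of `[reaction]`
#' sections holding [reaction_spec()] fields.
#'
#' @param path config file path.
#' @return For `read_scene_config`: list with elements `scene` (a
#'   [scene_config()]) and `reactions` (list of [reaction_spec()]).
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  scene_args <- list()
  reactions <- list()
  cur <- NULL
  flush_reaction <- function() {
    if (!is.null(cur)) reactions[[length(reactions) + 1L]] <<- do.call(reaction_spec, cur)
    cur <<- NULL
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush_reaction()
      section <- gsub("^\\[|\\]$", "", ln)
      if (section == "reaction") cur <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- m[2]; val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val %in% c("Inf")) Inf else val
    if (identical(section, "scene")) scene_args[[key]] <- parsed
    else if (identical(section, "reaction")) cur[[key]] <- parsed
    else stop("config line outside a [scene]/[reaction] section: ", ln)
  }
  flush_reaction()
  list(scene = do.call(scene_config, scene_args), reactions = reactions)
}

#' @rdname read_scene_config
#' @param scene a [scene_config()].
#' @param reactions list of [reaction_spec()].
#' @export
write_scene_config <- function(scene, reactions = list(), path) {
  fmt <- function(v) {
    if (is.numeric(v)) {
      if (is.infinite(v)) "Inf" else format(v, digits = 15)
    } else as.character(v)
  }
  out <- "[scene]"
  for (k in names(unclass(scene)))
    out <- c(out, paste0(k, ": ", fmt(scene[[k]])))
  for (r in reactions) {
    out <- c(out, "", "[reaction]")
    for (k in names(unclass(r)))
      if (!is.null(r[[k]])) out <- c(out, paste0(k, ": ", fmt(r[[k]])))
  }
  writeLines(out, path)
  invisible(path)
}
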
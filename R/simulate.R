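#' Simulate the caged school
#'
#' Generates per-fish trajectories and ground-truth school time series for a
#' cylindrical cage monitored by an upward-looking single-beam transducer.
#' The model is deliberately kinematic:
#'
#' * Fish orbit the cage axis at `swim_speed` with per-fish orbit radius and
#'   phase; per-fish depth is the school mean depth plus a fixed per-fish
#'   offset scaled by the current vertical extent (sd = extent / 4) plus a
#'   slow Ornstein-Uhlenbeck jitter, truncated to the cage.
#' * The school mean depth follows a 24 h sinusoid whose peak-to-trough
#'   amplitude is `circadian_amplitude` (shallowest at midday).
#' * A triggered reaction moves the school mean range, vertical extent and
#'   speed toward the modified values after `onset_latency`; the vertical
#'   transition is a linear ramp at `tilt_bias` m/ping when given (every fish
#'   inherits that slope, which is what the trace-tilt indicator measures),
#'   otherwise a smooth exponential. After the event the state relaxes back
#'   with time constant `recovery_time`. Habituation lengthens the latency by
#'   `habituation_increment` per repeat and suppresses the response entirely
#'   from repeat `habituation_max` on.
#' * During a long emission (duration >= `long_emission_s`) with an active
#'   reaction, `n_opposite` fish reverse their swimming direction.
#'
#' All truth series use range-from-transducer as the vertical coordinate.
#'
#' @param cfg a [scene_config()].
#' @param reactions list of [reaction_spec()].
#' @param schedule an [event_schedule()] or `NULL`.
#' @param duration simulated time (s), at least one ping.
#' @return A `"scene_truth"` object: per-fish position matrices (`x`, `y`,
#'   `depth`, ping x fish), per-fish target strengths `ts`, a `truth`
#'   data.frame (per-ping `mean_range`, `upper_range`, `lower_range`,
#'   `extent`, `mean_speed`, `vert_velocity_m_per_ping`, `opposite_count`),
#'   and an `annotations` data.frame of realized reactions.
#' @export
simulate_school <- function(cfg, reactions = list(), schedule = NULL,
                            duration) {
  stopifnot(inherits(cfg, "scene_config"))
  if (duration < cfg$ping_interval) stop("duration must cover at least one ping")
  if (length(reactions) && is.null(schedule))
    stop("reactions given without a schedule")
  for (r in reactions) {
    if (!is.null(r$event_id) && !r$event_id %in% schedule$event_id)
      stop("reaction references unknown event_id: ", r$event_id)
  }
  set.seed(cfg$seed)
  dt <- cfg$ping_interval
  n_ping <- as.integer(floor(duration / dt))
  n_fish <- cfg$n_fish
  times <- cfg$t0 + (seq_len(n_ping) - 1) * dt

  # responses realized from the reaction specs + schedule (habituation rule)
  ann <- resolve_reactions(reactions, schedule)

  # per-fish static draws
  r_orbit <- pmin(pmax(stats::rnorm(n_fish, cfg$circle_radius,
                                    cfg$circle_radius_sd), 2),
                  cfg$cage_diameter / 2 - 1)
  phase <- stats::runif(n_fish, 0, 2 * pi)
  u <- stats::rnorm(n_fish)                       # depth offset, extent units
  if (n_fish > 1) u <- u - mean(u)   # the school mean depth IS D(t) by definition
  ts <- stats::rnorm(n_fish, cfg$ts_mean, cfg$ts_sd)

  # opposite-direction fish chosen once per responding long-emission event
  opp_sets <- lapply(seq_len(nrow(ann)), function(i) {
    if (ann$responded[i] && ann$long_emission[i] && ann$n_opposite[i] > 0 &&
        n_fish > 0)
      sample.int(n_fish, min(ann$n_opposite[i], n_fish))
    else integer(0)
  })

  x <- matrix(0, n_ping, n_fish)
  y <- matrix(0, n_ping, n_fish)
  depth <- matrix(0, n_ping, n_fish)

  theta <- phase
  w <- stats::rnorm(n_fish, 0, cfg$depth_jitter_sd)   # OU state
  ou_a <- exp(-dt / cfg$depth_jitter_tau)
  ou_s <- cfg$depth_jitter_sd * sqrt(1 - ou_a^2)

  offset <- 0          # school range offset from reactions (m)
  extent_f <- 1        # multiplier on school_vertical_extent
  speed_f <- 1
  rec_tau <- 60

  mean_range <- numeric(n_ping)
  extent_tr <- numeric(n_ping)
  speed_tr <- numeric(n_ping)
  opp_count <- integer(n_ping)

  half_amp <- cfg$circadian_amplitude / 2
  for (i in seq_len(n_ping)) {
    t <- times[i]
    # circadian mean depth: deepest at midnight (t mod 86400 == 0)
    d_circ <- cfg$mean_depth + half_amp * cos(2 * pi * (t %% 86400) / 86400)

    act <- active_response(ann, t)
    if (!is.null(act)) {
      rec_tau <- act$recovery_time
      tgt_off <- act$dive_delta
      if (act$tilt_bias != 0) {
        step <- abs(act$tilt_bias)
        offset <- offset + sign(tgt_off - offset) * min(step, abs(tgt_off - offset))
      } else {
        a <- 1 - exp(-dt / act$transition_tau)
        offset <- offset + (tgt_off - offset) * a
      }
      a <- 1 - exp(-dt / act$transition_tau)
      extent_f <- extent_f + (act$contraction_factor - extent_f) * a
      speed_f <- speed_f + (act$speed_factor - speed_f) * a
      opp <- opp_sets[[act$idx]]
    } else {
      a <- if (rec_tau > 0) 1 - exp(-dt / rec_tau) else 1
      offset <- offset * (1 - a)
      extent_f <- extent_f + (1 - extent_f) * a
      speed_f <- speed_f + (1 - speed_f) * a
      opp <- integer(0)
    }

    d_school <- d_circ - offset   # range offset maps to -depth offset
    sd_depth <- cfg$school_vertical_extent * extent_f / 4
    w <- ou_a * w + ou_s * stats::rnorm(n_fish)
    d_fish <- pmin(pmax(d_school + u * sd_depth + w, 0.2), cfg$cage_depth - 0.2)

    dir <- rep(1, n_fish)
    if (length(opp)) dir[opp] <- -1
    theta <- theta + dir * (cfg$swim_speed * speed_f / r_orbit) * dt

    x[i, ] <- r_orbit * cos(theta)
    y[i, ] <- r_orbit * sin(theta)
    depth[i, ] <- d_fish

    rng <- cfg$transducer_depth - d_fish
    mean_range[i] <- mean(rng)
    extent_tr[i] <- 4 * stats::sd(rng)
    speed_tr[i] <- cfg$swim_speed * speed_f
    opp_count[i] <- length(opp)
  }

  if (n_fish == 0) {
    mean_range[] <- NA_real_; extent_tr[] <- NA_real_
  }
  vv <- c(0, diff(mean_range))
  truth <- data.frame(
    ping_time = times,
    mean_range = mean_range,
    upper_range = mean_range + extent_tr / 2,
    lower_range = mean_range - extent_tr / 2,
    extent = extent_tr,
    mean_speed = speed_tr,
    vert_velocity_m_per_ping = vv,
    opposite_count = opp_count
  )
  structure(list(ping_times = times, x = x, y = y, depth = depth, ts = ts,
                 truth = truth, annotations = ann, cfg = cfg),
            class = "scene_truth")
}

# Expand reaction specs against the schedule, applying the habituation rule.
resolve_reactions <- function(reactions, schedule) {
  cols <- data.frame(event_id = character(0), start_time = numeric(0),
                     end_time = numeric(0), onset_time = numeric(0),
                     responded = logical(0), dive_delta = numeric(0),
                     contraction_factor = numeric(0), speed_factor = numeric(0),
                     tilt_bias = numeric(0), recovery_time = numeric(0),
                     transition_tau = numeric(0), long_emission = logical(0),
                     n_opposite = integer(0))
  if (!length(reactions) || is.null(schedule) || !nrow(schedule)) return(cols)
  out <- list()
  for (r in reactions) {
    if (!is.null(r$event_id)) {
      hit <- schedule[schedule$event_id == r$event_id, , drop = FALSE]
    } else {
      lv <- classify_level(schedule$spl_db)
      min_i <- match(r$min_level_class, LEVEL_CLASSES)
      hit <- schedule[schedule$source_type == r$source_type &
                        match(lv, LEVEL_CLASSES) >= min_i, , drop = FALSE]
    }
    if (!nrow(hit)) next
    hit <- hit[order(hit$start_time), , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      responded <- (k - 1) < r$habituation_max
      latency <- r$onset_latency + (k - 1) * r$habituation_increment
      out[[length(out) + 1L]] <- data.frame(
        event_id = hit$event_id[k],
        start_time = hit$start_time[k],
        end_time = hit$start_time[k] + hit$duration_s[k],
        onset_time = hit$start_time[k] + latency,
        responded = responded,
        dive_delta = r$dive_delta,
        contraction_factor = r$contraction_factor,
        speed_factor = r$speed_factor,
        tilt_bias = r$tilt_bias,
        recovery_time = r$recovery_time,
        transition_tau = r$transition_tau,
        long_emission = hit$duration_s[k] >= r$long_emission_s,
        n_opposite = as.integer(r$n_opposite)
      )
    }
  }
  if (!length(out)) return(cols)
  ann <- do.call(rbind, out)
  ann[order(ann$onset_time), , drop = FALSE]
}

# The response active at time t (onset <= t < end), latest onset wins.
active_response <- function(ann, t) {
  if (!nrow(ann)) return(NULL)
  ix <- which(ann$responded & ann$onset_time <= t & t < ann$end_time &
                ann$onset_time < ann$end_time)
  if (!length(ix)) return(NULL)
  i <- ix[which.max(ann$onset_time[ix])]
  c(as.list(ann[i, ]), idx = i)
}

#' Construct a scene truth object directly
#'
#' Mainly for tests and controlled rendering experiments: wraps explicit
#' per-fish position matrices into the structure [render_echogram()] expects.
#'
#' @param ping_times ping timestamps (s).
#' @param x,y,depth ping x fish matrices of positions (m; depth below
#'   surface).
#' @param ts per-fish target strengths (dB).
#' @param cfg a [scene_config()].
#' @return A `"scene_truth"` object (without truth series or annotations).
#' @export
scene_truth <- function(ping_times, x, y, depth, ts, cfg) {
  stopifnot(nrow(x) == length(ping_times), all(dim(x) == dim(depth)),
            all(dim(x) == dim(y)), length(ts) == ncol(x))
  structure(list(ping_times = ping_times, x = x, y = y, depth = depth,
                 ts = ts, truth = NULL, annotations = NULL, cfg = cfg),
            class = "scene_truth")
}

#' Render an echogram from a simulated scene
#'
#' For each ping, every fish inside the beam cone contributes an echo at its
#' slant-range bin with level `ts + G(theta)`, where `G` is an axisymmetric
#' Gaussian beam pattern with -3 dB at the half aperture; contributions and a
#' per-bin Gaussian-dB background noise add in the linear power domain, and
#' values are clipped at `dynamic_range_max` (clip count flagged as attribute
#' `n_clipped`). Values are treated as already range-compensated volume
#' backscattering (no TVG or propagation-loss model). Output values are
#' rounded to 2 decimals, matching the EGRAM container precision, so
#' rendered echograms round-trip bit-exactly through [write_egram()].
#'
#' @param truth a `"scene_truth"` from [simulate_school()] or [scene_truth()].
#' @param cfg a [scene_config()]; noise randomness is seeded from
#'   `cfg$seed` so rendering is deterministic.
#' @return An [echogram()].
#' @export
render_echogram <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "scene_truth"), inherits(cfg, "scene_config"))
  set.seed(cfg$seed + 1000003L)
  step <- cfg$range_step
  theta3 <- (cfg$beam_width_3db / 2) * pi / 180   # half aperture, radians
  theta_cut <- theta3 * sqrt(15 / 3)              # G >= -15 dB
  # range axis covers the full cone: an off-axis fish just below the surface
  # returns from slant range transducer_depth / cos(theta_cut) (the container
  # allows ranges beyond the vertical distance; depth reporting clamps at 0)
  n_bin <- as.integer(ceiling(cfg$transducer_depth / cos(theta_cut) / step))
  range_bins <- (seq_len(n_bin) - 0.5) * step
  n_ping <- length(truth$ping_times)
  x0 <- cfg$transducer_offset

  # extended-target kernel: echo energy spread over neighbouring bins with a
  # Gaussian profile of full width echo_width (sigma = width / 4)
  ew <- if (is.null(cfg$echo_width)) 1 else cfg$echo_width
  k_half <- max(0L, as.integer(round(ew / (2 * step))))
  k_off <- (-k_half):k_half
  k_w <- exp(-(k_off * step)^2 / (2 * (ew / 4)^2))
  k_w <- k_w / sum(k_w)

  vals <- matrix(0, n_ping, n_bin)
  n_clipped <- 0L
  for (i in seq_len(n_ping)) {
    noise_db <- stats::rnorm(n_bin, cfg$noise_floor_mean, cfg$noise_floor_sd)
    acc <- 10^(noise_db / 10)
    if (ncol(truth$x) > 0) {
      h <- cfg$transducer_depth - truth$depth[i, ]
      rho <- sqrt((truth$x[i, ] - x0)^2 + truth$y[i, ]^2)
      vis <- h > 0
      if (any(vis)) {
        theta <- atan2(rho[vis], h[vis])
        keep <- theta <= theta_cut
        if (any(keep)) {
          hv <- h[vis][keep]; rv <- rho[vis][keep]
          slant <- sqrt(hv^2 + rv^2)
          g_db <- -3 * (theta[keep] / theta3)^2
          # volume normalization: the sampled volume grows as slant^2, so a
          # homogeneous school renders range-independent Sv; reference 10 m
          # keeps the on-axis level of a fish at 10 m equal to its ts.
          lin <- 10^((truth$ts[vis][keep] + g_db) / 10) * (10 / slant)^2
          bin0 <- as.integer(floor(slant / step)) + 1L
          nf <- length(lin)
          bin <- rep(bin0, each = length(k_off)) + rep(k_off, nf)
          linw <- rep(lin, each = length(k_off)) * rep(k_w, nf)
          ok_b <- bin >= 1L & bin <= n_bin
          s <- rowsum(linw[ok_b], bin[ok_b])
          acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
        }
      }
    }
    v <- 10 * log10(acc)
    if (is.finite(cfg$dynamic_range_max)) {
      clip <- v > cfg$dynamic_range_max
      n_clipped <- n_clipped + sum(clip)
      v[clip] <- cfg$dynamic_range_max
    }
    vals[i, ] <- v
  }
  e <- echogram(round(vals, 2), ping_times = truth$ping_times,
                range_bins = range_bins,
                transducer_depth = cfg$transducer_depth, orientation = "up",
                beam_width_3db = cfg$beam_width_3db, frequency = 200,
                dynamic_range_max = cfg$dynamic_range_max)
  attr(e, "n_clipped") <- n_clipped
  e
}

#' Ground-truth per-event behavioral metrics
#'
#' For each scheduled event, compares the truth series in a stabilized event
#' window against a baseline window of equal length immediately before the
#' event: mean range change (m), extent ratio, speed ratio, and the maximum
#' opposite-swimmer count. Used as the recovery reference when testing the
#' echogram-side metrics.
#'
#' @param truth a `"scene_truth"` from [simulate_school()].
#' @param schedule an [event_schedule()].
#' @param stabilize_s seconds after event start to skip before averaging
#'   (lets a ramped reaction reach its target).
#' @return data.frame, one row per event.
#' @export
truth_event_metrics <- function(truth, schedule, stabilize_s = 0) {
  stopifnot(inherits(truth, "scene_truth"))
  tr <- truth$truth
  if (is.null(tr)) stop("truth series unavailable (manually built scene_truth)")
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    s <- schedule$start_time[i]; e <- s + schedule$duration_s[i]
    in_ev <- tr$ping_time >= s + stabilize_s & tr$ping_time < e
    in_base <- tr$ping_time >= s - schedule$duration_s[i] & tr$ping_time < s
    if (!any(in_ev) || !any(in_base)) {
      return(data.frame(event_id = schedule$event_id[i],
                        mean_range_change = NA_real_, extent_ratio = NA_real_,
                        speed_ratio = NA_real_, opposite_count = NA_integer_))
    }
    data.frame(
      event_id = schedule$event_id[i],
      mean_range_change = mean(tr$mean_range[in_ev]) - mean(tr$mean_range[in_base]),
      extent_ratio = mean(tr$extent[in_ev]) / mean(tr$extent[in_base]),
      speed_ratio = mean(tr$mean_speed[in_ev]) / mean(tr$mean_speed[in_base]),
      opposite_count = max(tr$opposite_count[in_ev])
    )
  })
  do.call(rbind, rows)
}
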
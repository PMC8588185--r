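#' Per-ping backscatter center of mass
#'
#' For each ping, the school's average range is the center of mass of the
#' volume-backscattering field over the bins at or above `threshold_db`:
#' `com = sum(r_i * w_i) / sum(w_i)` with linear-power weights
#' `w_i = 10^(value_i / 10)`. Sentinel (-999) samples never qualify. A ping
#' with no bin above threshold is invalid (`NA`).
#'
#' Weighting is done in the linear power domain — the center of mass of a
#' physical intensity field — which makes the result invariant under a
#' constant dB gain applied jointly to data and threshold.
#'
#' @param e an [echogram()].
#' @param threshold_db inclusion threshold (dB).
#' @return numeric vector, one range (m) per ping; `NA` where invalid.
#' @examples
#' e <- echogram(matrix(-50, 1, 6), 0, seq(5, 10), transducer_depth = 24)
#' center_of_mass_range(e, -70)  # 7.5
#' @export
center_of_mass_range <- function(e, threshold_db = -70) {
  stopifnot(inherits(e, "echogram"))
  v <- e$values
  if (!length(v)) stop("empty echogram")
  mask <- v >= threshold_db & v > EGRAM_SENTINEL
  w <- 10^(v / 10) * mask
  num <- w %*% e$range_bins
  den <- rowSums(w)
  out <- as.numeric(num) / den
  out[den == 0] <- NA_real_
  out
}

#' Per-ping school limits
#'
#' The lower and upper limits of the school envelope at each ping: the
#' minimum and maximum bin range whose value is at or above `threshold_db`,
#' after removing above-threshold runs shorter than `min_run_bins`
#' consecutive bins (despeckle, stabilizes the envelope against isolated
#' noise bins). Invalid pings (no qualifying bin) are `NA`.
#'
#' If the echogram declares a saturation ceiling, the fraction of
#' above-threshold samples at the ceiling is checked; a fraction above 0.2
#' raises a warning (gain likely misconfigured).
#'
#' @inheritParams center_of_mass_range
#' @param min_run_bins minimum run length (bins) kept by the despeckle step.
#' @return data.frame with per-ping `lower_range`, `upper_range` (m).
#' @export
school_limits <- function(e, threshold_db = -70, min_run_bins = 2) {
  stopifnot(inherits(e, "echogram"))
  v <- e$values
  if (!length(v)) stop("empty echogram")
  mask <- v >= threshold_db & v > EGRAM_SENTINEL
  if (is.finite(e$dynamic_range_max) && any(mask)) {
    sat_frac <- sum(v[mask] >= e$dynamic_range_max) / sum(mask)
    if (sat_frac > 0.2)
      warning(sprintf("%.0f%% of above-threshold samples are saturated", 100 * sat_frac))
  }
  n_ping <- nrow(v)
  lower <- rep(NA_real_, n_ping)
  upper <- rep(NA_real_, n_ping)
  for (i in seq_len(n_ping)) {
    m <- mask[i, ]
    if (!any(m)) next
    r <- rle(m)
    r$values[r$values & r$lengths < min_run_bins] <- FALSE
    m <- inverse.rle(r)
    if (!any(m)) next
    idx <- which(m)
    lower[i] <- e$range_bins[idx[1]]
    upper[i] <- e$range_bins[idx[length(idx)]]
  }
  data.frame(lower_range = lower, upper_range = upper)
}

#' Compute the full per-ping school envelope
#'
#' Convenience wrapper returning center of mass, limits and validity per
#' ping as one data.frame (class `"school_envelope"`).
#'
#' @inheritParams school_limits
#' @return data.frame with `ping_time`, `com_range`, `lower_range`,
#'   `upper_range`, `valid`.
#' @export
school_envelope <- function(e, threshold_db = -70, min_run_bins = 2) {
  com <- center_of_mass_range(e, threshold_db)
  lim <- school_limits(e, threshold_db, min_run_bins)
  env <- data.frame(ping_time = e$ping_times, com_range = com,
                    lower_range = lim$lower_range,
                    upper_range = lim$upper_range,
                    valid = !is.na(com))
  class(env) <- c("school_envelope", "data.frame")
  env
}

#' Aggregate the school envelope over time windows
#'
#' Arithmetic mean of the valid per-ping center of mass and limits over each
#' half-open window `[start, end)`, with the fraction of valid pings. A
#' window with zero valid pings is reported with `NA` means, not an error.
#'
#' @param env a [school_envelope()] data.frame.
#' @param windows data.frame with columns `start` and `end` (s); an optional
#'   `window_id` column is carried through.
#' @return data.frame, one row per window: means of `com_range`,
#'   `lower_range`, `upper_range`, `extent` (upper - lower), `valid_fraction`
#'   and `n_pings`.
#' @export
aggregate_envelope <- function(env, windows) {
  stopifnot(all(c("start", "end") %in% names(windows)))
  ids <- if ("window_id" %in% names(windows)) as.character(windows$window_id)
         else as.character(seq_len(nrow(windows)))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- env$ping_time >= windows$start[i] & env$ping_time < windows$end[i]
    ok <- sel & env$valid
    n <- sum(sel)
    if (!any(ok)) {
      return(data.frame(window_id = ids[i], start = windows$start[i],
                        end = windows$end[i], com_range = NA_real_,
                        lower_range = NA_real_, upper_range = NA_real_,
                        extent = NA_real_, valid_fraction = if (n) 0 else NA_real_,
                        n_pings = n))
    }
    lo <- mean(env$lower_range[ok], na.rm = TRUE)
    up <- mean(env$upper_range[ok], na.rm = TRUE)
    data.frame(window_id = ids[i], start = windows$start[i],
               end = windows$end[i],
               com_range = mean(env$com_range[ok]),
               lower_range = lo, upper_range = up, extent = up - lo,
               valid_fraction = sum(ok) / n, n_pings = n)
  })
  do.call(rbind, rows)
}

#' Hourly aggregation windows covering an echogram
#'
#' @param e an [echogram()].
#' @param width_s window width in seconds (default 3600).
#' @return data.frame of `start`/`end` windows aligned to multiples of
#'   `width_s`.
#' @export
hourly_windows <- function(e, width_s = 3600) {
  t0 <- floor(min(e$ping_times) / width_s) * width_s
  t1 <- max(e$ping_times)
  starts <- seq(t0, t1, by = width_s)
  data.frame(start = starts, end = starts + width_s)
}
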
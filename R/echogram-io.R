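# Sentinel for missing/invalid samples ("below floor"); all metrics ignore it.
EGRAM_SENTINEL <- -999

#' Allowed stimulus source types
#'
#' Vector of valid `source_type` values for event schedules: pure tones,
#' synthetic broadband signals (white noise, maximum-length sequences,
#' time-stretched pulses, sweeps, chirps), recorded playback (windmill, ship),
#' the impulsive slaughter-tool shot ("lupara") and ambient background.
#'
#' @export
SOURCE_TYPES <- c("tone", "two-tone", "chirp", "white", "mls", "tsp",
                  "sweep", "windmill", "ship", "lupara", "background")

#' Construct an echogram object
#'
#' An echogram is the central observational object: a ping x range matrix of
#' volume-backscattering values (dB) recorded by a single-beam echosounder,
#' together with the transducer metadata needed to interpret it. The vertical
#' coordinate is *range from the transducer face*; for an upward-looking
#' transducer, depth below the surface is a reporting conversion
#' (see [range_to_depth()]).
#'
#' @param values numeric matrix, pings in rows, range bins in columns (dB).
#'   Missing/invalid samples are encoded as the sentinel value -999.
#' @param ping_times numeric vector of ping timestamps (seconds since epoch),
#'   strictly increasing, length `nrow(values)`.
#' @param range_bins numeric vector of bin-center ranges from the transducer
#'   face (m), uniformly spaced and increasing, length `ncol(values)`.
#' @param transducer_depth transducer depth below the surface (m).
#' @param orientation `"up"` (transducer looking toward the surface) or
#'   `"down"`.
#' @param beam_width_3db full beam aperture at -3 dB (degrees).
#' @param frequency operating frequency (kHz).
#' @param dynamic_range_max saturation ceiling (dB), or `NA` if none.
#' @return An object of class `"echogram"`.
#' @examples
#' e <- echogram(matrix(-70, 2, 3), ping_times = c(0, 1),
#'               range_bins = c(1, 2, 3), transducer_depth = 24)
#' dim(e$values)
#' @export
echogram <- function(values, ping_times, range_bins,
                     transducer_depth = 24, orientation = "up",
                     beam_width_3db = 25, frequency = 200,
                     dynamic_range_max = NA_real_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(ping_times))
    stop("values must have one row per ping time (", nrow(values), " vs ",
         length(ping_times), ")")
  if (ncol(values) != length(range_bins))
    stop("values must have one column per range bin")
  if (length(ping_times) > 1 && any(diff(ping_times) <= 0))
    stop("ping_times must be strictly increasing")
  if (any(range_bins < 0)) stop("range_bins must be nonnegative")
  if (length(range_bins) > 1) {
    dr <- diff(range_bins)
    if (any(dr <= 0)) stop("range_bins must be increasing")
    if (max(abs(dr - dr[1])) > 1e-9 * max(dr[1], 1))
      stop("range_bins must be uniformly spaced")
  }
  if (!orientation %in% c("up", "down"))
    stop("orientation must be 'up' or 'down'")
  structure(list(
    values = values,
    ping_times = as.numeric(ping_times),
    range_bins = as.numeric(range_bins),
    transducer_depth = as.numeric(transducer_depth),
    orientation = orientation,
    beam_width_3db = as.numeric(beam_width_3db),
    frequency = as.numeric(frequency),
    dynamic_range_max = as.numeric(dynamic_range_max)
  ), class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %d pings x %d range bins (%.2f-%.2f m), %g kHz, %s\n",
              nrow(x$values), ncol(x$values), min(x$range_bins),
              max(x$range_bins), x$frequency, x$orientation))
  cat(sprintf("  transducer depth %.1f m, beam %.1f deg at -3 dB\n",
              x$transducer_depth, x$beam_width_3db))
  invisible(x)
}

#' @export
dim.echogram <- function(x) dim(x$values)

egram_header_keys <- c("ping_epoch_s0", "ping_interval_s", "range_start_m",
                       "range_step_m", "transducer_depth_m", "orientation",
                       "beam_width_3db_deg", "frequency_khz",
                       "dynamic_range_max_db")

#' Write an echogram to the plain-text EGRAM container
#'
#' The container is UTF-8 text: '#'-prefixed `key: value` header lines for
#' all metadata, then one whitespace-separated row of dB values per ping.
#' Values are printed with 2 decimals, so the round trip
#' `read_egram(write_egram(e))` is bit-exact when values carry at most two
#' decimal places (as all package-rendered echograms do). Requires uniform
#' ping spacing (the header stores start + interval).
#'
#' @param e an [echogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_egram <- function(e, path) {
  stopifnot(inherits(e, "echogram"))
  pt <- e$ping_times
  if (length(pt) > 1) {
    dt <- diff(pt)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop("EGRAM container requires uniform ping spacing")
    interval <- dt[1]
  } else interval <- 1
  rb <- e$range_bins
  step <- if (length(rb) > 1) rb[2] - rb[1] else 1
  hdr <- c(
    sprintf("# ping_epoch_s0: %.6f", pt[1]),
    sprintf("# ping_interval_s: %.6f", interval),
    sprintf("# range_start_m: %.6f", rb[1]),
    sprintf("# range_step_m: %.6f", step),
    sprintf("# transducer_depth_m: %.6f", e$transducer_depth),
    sprintf("# orientation: %s", e$orientation),
    sprintf("# beam_width_3db_deg: %.6f", e$beam_width_3db),
    sprintf("# frequency_khz: %.6f", e$frequency),
    sprintf("# dynamic_range_max_db: %s",
            if (is.na(e$dynamic_range_max)) "NA"
            else sprintf("%.6f", e$dynamic_range_max))
  )
  rows <- apply(e$values, 1L, function(v) paste(sprintf("%.2f", v),
                                                collapse = " "))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read an echogram from the plain-text EGRAM container
#'
#' @param path path to an EGRAM file written by [write_egram()] or conforming
#'   to the documented container layout.
#' @return An [echogram()].
#' @seealso [write_egram()]
#' @export
read_egram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  meta <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*\\S)\\s*$", h))[[1]]
    if (length(m) != 3)
      stop("malformed EGRAM header line: ", h)
    meta[[m[2]]] <- m[3]
  }
  missing_keys <- setdiff(egram_header_keys, names(meta))
  if (length(missing_keys))
    stop("EGRAM header missing keys: ", paste(missing_keys, collapse = ", "))
  num <- function(k) {
    v <- meta[[k]]
    if (identical(v, "NA")) return(NA_real_)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("malformed EGRAM header value for ", k, ": ", v)
    x
  }
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("EGRAM file has no data rows")
  rows <- lapply(body, function(ln)
    suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1)
    stop("EGRAM data rows have inconsistent widths")
  if (anyNA(unlist(rows)))
    stop("EGRAM data rows contain non-numeric values")
  values <- do.call(rbind, rows)
  n_ping <- nrow(values)
  n_bin <- ncol(values)
  echogram(
    values,
    ping_times = num("ping_epoch_s0") + (seq_len(n_ping) - 1) * num("ping_interval_s"),
    range_bins = num("range_start_m") + (seq_len(n_bin) - 1) * num("range_step_m"),
    transducer_depth = num("transducer_depth_m"),
    orientation = meta[["orientation"]],
    beam_width_3db = num("beam_width_3db_deg"),
    frequency = num("frequency_khz"),
    dynamic_range_max = num("dynamic_range_max_db")
  )
}

#' Convert range from the transducer to depth below the surface
#'
#' For an upward-looking transducer, `depth = transducer_depth - range`,
#' clamped at 0 m (surface echoes report 0, never a negative depth). The
#' mapping is its own inverse on `[0, transducer_depth]` (see
#' [depth_to_range()]).
#'
#' @param e an [echogram()] with `orientation = "up"`.
#' @param range_m range(s) from the transducer face (m).
#' @return depth(s) below the surface (m), clamped at 0.
#' @examples
#' e <- echogram(matrix(0, 1, 1), 0, 0, transducer_depth = 24)
#' range_to_depth(e, 12.2)  # 11.8
#' @export
range_to_depth <- function(e, range_m) {
  stopifnot(inherits(e, "echogram"))
  if (e$orientation != "up")
    stop("range_to_depth supports orientation = 'up' only")
  pmax(e$transducer_depth - range_m, 0)
}

#' @rdname range_to_depth
#' @param depth_m depth(s) below the surface (m), in `[0, transducer_depth]`.
#' @export
depth_to_range <- function(e, depth_m) {
  stopifnot(inherits(e, "echogram"))
  if (e$orientation != "up")
    stop("depth_to_range supports orientation = 'up' only")
  if (any(depth_m < 0 | depth_m > e$transducer_depth, na.rm = TRUE))
    stop("depth must lie in [0, transducer_depth]")
  e$transducer_depth - depth_m
}

#' Construct and validate a stimulus event schedule
#'
#' An event schedule is a table with one row per sound emission: its id, start
#' time, duration, source type, nominal frequency (or `NA`) and SPL (dB re
#' 1 uPa). Event windows are half-open `[start, start + duration)` and must
#' not overlap; ids must be unique; `source_type` must be one of
#' [SOURCE_TYPES].
#'
#' @param df data.frame with columns `event_id`, `start_time`, `duration_s`,
#'   `source_type`, `nominal_frequency_hz`, `spl_db`.
#' @return The validated data.frame with class `c("event_schedule",
#'   "data.frame")`.
#' @export
event_schedule <- function(df) {
  req <- c("event_id", "start_time", "duration_s", "source_type",
           "nominal_frequency_hz", "spl_db")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schedule missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$event_id <- as.character(df$event_id)
  bad_type <- setdiff(unique(df$source_type), SOURCE_TYPES)
  if (length(bad_type))
    stop("unknown source_type: ", paste(bad_type, collapse = ", "))
  if (anyDuplicated(df$event_id))
    stop("duplicate event_id: ",
         paste(unique(df$event_id[duplicated(df$event_id)]), collapse = ", "))
  if (any(!is.finite(df$spl_db))) stop("spl_db must be finite")
  if (any(df$duration_s <= 0)) stop("duration_s must be positive")
  if (nrow(df) > 1) {
    o <- order(df$start_time)
    s <- df$start_time[o]; e <- s + df$duration_s[o]; id <- df$event_id[o]
    ov <- which(s[-1] < e[-length(e)])
    if (length(ov))
      stop("overlapping events: ",
           paste(sprintf("(%s,%s)", id[ov], id[ov + 1]), collapse = " "))
  }
  class(df) <- c("event_schedule", "data.frame")
  df
}

#' Read a stimulus event schedule from CSV
#'
#' @param path CSV file with a header row and the columns documented in
#'   [event_schedule()].
#' @return An [event_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_schedule(df)
}

#' Write a result table (or schedule) as CSV
#'
#' Comma-delimited, '.' decimal, header row; the standard exchange format for
#' all package result tables.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}
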
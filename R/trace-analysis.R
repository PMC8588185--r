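# Binary morphology on ping x bin matrices, 3x3 cross structuring element,
# zero padding outside the image.

shift_mat <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  ri <- seq_len(n) - di; ci <- seq_len(p) - dj
  ok_r <- ri >= 1 & ri <= n; ok_c <- ci >= 1 & ci <= p
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

neighbor_count4 <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) +
    shift_mat(m, 0, -1)
}

dilate_cross <- function(m) {
  m | shift_mat(m, 1, 0) | shift_mat(m, -1, 0) | shift_mat(m, 0, 1) |
    shift_mat(m, 0, -1)
}

erode_cross <- function(m) {
  m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) & shift_mat(m, 0, 1) &
    shift_mat(m, 0, -1)
}

#' Binarize an echogram
#'
#' `mask[i, j]` is `TRUE` iff `values[i, j] >= threshold_db`; sentinel
#' (missing) samples are always `FALSE`.
#'
#' @param e an [echogram()].
#' @param threshold_db binarization threshold (dB).
#' @return logical ping x bin matrix.
#' @export
binarize <- function(e, threshold_db = -70) {
  stopifnot(inherits(e, "echogram"), is.finite(threshold_db))
  e$values >= threshold_db & e$values > EGRAM_SENTINEL
}

#' Morphological cleaning of a binary echogram mask
#'
#' Applies, in order: one thickening iteration (compaction fill: background
#' pixels with at least two foreground 4-neighbours are set — regions become
#' more compact but isolated pixels are *not* grown), an opening (erosion
#' then dilation: removes protrusions, isolated noise pixels, and breaks
#' weak connections) and a closing (dilation then erosion: smooths contours
#' and fills small holes). All operators use the 3x3 cross structuring
#' element and 4-connectivity.
#'
#' @param mask logical matrix from [binarize()].
#' @return logical matrix, same shape.
#' @export
clean_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- mask | (neighbor_count4(mask) >= 2)   # thicken (compaction fill)
  m <- dilate_cross(erode_cross(m))          # opening
  m <- erode_cross(dilate_cross(m))          # closing
  m
}

#' Segment a binary mask into 4-connected regions
#'
#' Connected components under 4-connectivity, returned in deterministic
#' order: regions sorted by (first ping index, first bin index), pixels
#' within a region sorted by (ping, bin).
#'
#' @param mask logical matrix.
#' @return list of integer matrices with columns `ping` and `bin`.
#' @export
segment_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  on <- which(mask)
  if (!length(on)) return(list())
  n <- nrow(mask)
  id <- seq_along(on)
  pos <- integer(length(mask)); pos[on] <- id
  ping <- ((on - 1L) %% n) + 1L
  bin <- ((on - 1L) %/% n) + 1L
  # edges to the right and downward neighbours among on-pixels
  e1_from <- id[ping < n & mask[cbind(pmin(ping + 1L, n), bin)]]
  e1_to <- pos[on[e1_from] + 1L]
  down_ok <- bin < ncol(mask) & mask[cbind(ping, pmin(bin + 1L, ncol(mask)))]
  e2_from <- id[down_ok]
  e2_to <- pos[on[e2_from] + n]
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (length(e1_from) + length(e2_from))
    g <- igraph::add_edges(g, c(rbind(e1_from, e1_to), rbind(e2_from, e2_to)))
  memb <- igraph::components(g)$membership
  regs <- split(seq_along(on), memb)
  regs <- lapply(regs, function(ix) {
    m <- cbind(ping = ping[ix], bin = bin[ix])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
  ord <- order(vapply(regs, function(m) m[1, 1], 1L),
               vapply(regs, function(m) m[1, 2], 1L))
  unname(regs[ord])
}

# Build a trace object from a pixel region.
make_trace <- function(region, e) {
  px_vals <- e$values[region]
  pings <- sort(unique(region[, 1]))
  # per-ping maximum-value pixel; ties -> nearest-to-transducer bin
  max_range <- vapply(pings, function(p) {
    sel <- region[, 1] == p
    bins <- region[sel, 2]
    v <- e$values[cbind(p, bins)]
    best <- bins[v == max(v)]
    e$range_bins[min(best)]
  }, numeric(1))
  len <- length(pings)
  slope <- if (len >= 3) {
    xx <- seq_len(len) - (len + 1) / 2          # centered ping index
    sum(xx * (max_range - mean(max_range))) / sum(xx^2)
  } else NA_real_
  structure(list(pixels = region,
                 length_pings = len,
                 ping_indices = pings,
                 max_range = max_range,
                 tilt_slope = slope,
                 mean_level = mean(px_vals),
                 start_time = e$ping_times[pings[1]],
                 end_time = e$ping_times[pings[len]],
                 mean_range = mean(e$range_bins[region[, 2]])),
            class = "fish_trace")
}

#' @export
print.fish_trace <- function(x, ...) {
  cat(sprintf("<fish_trace> %d px, %d pings, mean range %.2f m, level %.1f dB, tilt %s\n",
              nrow(x$pixels), x$length_pings, x$mean_range, x$mean_level,
              if (is.na(x$tilt_slope)) "NA" else sprintf("%+.3f m/ping", x$tilt_slope)))
  invisible(x)
}

#' Filter segmented regions into fish traces
#'
#' Keeps regions with at least `min_size_px` pixels *and* mean echo level at
#' least `min_level_db`, separating fish traces from unwanted targets;
#' survivors become trace objects carrying length (distinct pings), per-ping
#' maximum-backscatter ranges, tilt slope (see [trace_tilt()]), mean echo
#' level, start time and mean range.
#'
#' @param regions list of pixel regions from [segment_mask()].
#' @param e the source [echogram()].
#' @param min_size_px minimum region size (pixels).
#' @param min_level_db minimum mean echo level (dB).
#' @return list of `"fish_trace"` objects.
#' @export
filter_regions <- function(regions, e, min_size_px = 6, min_level_db = -60) {
  stopifnot(is.finite(min_size_px), is.finite(min_level_db))
  out <- list()
  for (r in regions) {
    if (nrow(r) < min_size_px) next
    if (mean(e$values[r]) < min_level_db) next
    out[[length(out) + 1L]] <- make_trace(r, e)
  }
  out
}

#' Tilt indicator of a fish trace
#'
#' For each ping of the trace, takes the range of the maximum-backscatter
#' pixel (ties broken toward the transducer) and fits ordinary least squares
#' of range on ping index; the slope, in m/ping, is the tilt indicator. A
#' positive slope means range increasing per ping, i.e. the fish swimming
#' upward for an up-looking transducer. Undefined (`NA`) for traces shorter
#' than 3 pings.
#'
#' @param trace a `"fish_trace"`.
#' @param e the source [echogram()] (accepted for interface symmetry; the
#'   per-ping maxima are cached on the trace).
#' @return slope in m/ping, or `NA` if the trace spans fewer than 3 pings.
#' @export
trace_tilt <- function(trace, e = NULL) {
  stopifnot(inherits(trace, "fish_trace"))
  if (trace$length_pings < 3) return(NA_real_)
  trace$tilt_slope
}

#' Extract fish traces from an echogram
#'
#' The full pipeline: [binarize()], [clean_mask()], [segment_mask()],
#' [filter_regions()].
#'
#' @inheritParams binarize
#' @inheritParams filter_regions
#' @return list of `"fish_trace"` objects.
#' @export
extract_traces <- function(e, threshold_db = -70, min_size_px = 6,
                           min_level_db = -60) {
  filter_regions(segment_mask(clean_mask(binarize(e, threshold_db))), e,
                 min_size_px, min_level_db)
}

#' One-row-per-trace table
#'
#' @param traces list of `"fish_trace"` objects.
#' @return data.frame with `start_time`, `end_time`, `length_pings`,
#'   `tilt_slope`, `mean_level`, `mean_range`, `n_pixels`.
#' @export
traces_table <- function(traces) {
  if (!length(traces))
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      length_pings = integer(0),
                      tilt_slope = numeric(0), mean_level = numeric(0),
                      mean_range = numeric(0), n_pixels = integer(0)))
  do.call(rbind, lapply(traces, function(t)
    data.frame(start_time = t$start_time, end_time = t$end_time,
               length_pings = t$length_pings,
               tilt_slope = t$tilt_slope, mean_level = t$mean_level,
               mean_range = t$mean_range, n_pixels = nrow(t$pixels))))
}

#' Summarize traces over time windows
#'
#' Per half-open window `[start, end)` (a trace is counted in every window
#' its ping span overlaps, so long traces contribute to each window they
#' cross): mean trace
#' length in pings, mean tilt slope (over traces with a defined tilt), trace
#' count, and the fraction of upward traces (slope > 0). Windows without
#' traces get a row with zero count and `NA` means.
#'
#' @param traces list of `"fish_trace"` objects.
#' @param windows data.frame with `start`, `end` (and optional `window_id`).
#' @return data.frame, one row per window.
#' @export
summarize_traces <- function(traces, windows) {
  tab <- traces_table(traces)
  ids <- if ("window_id" %in% names(windows)) as.character(windows$window_id)
         else as.character(seq_len(nrow(windows)))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- tab$end_time >= windows$start[i] & tab$start_time < windows$end[i]
    n <- sum(sel)
    tilt <- tab$tilt_slope[sel]
    tilt_ok <- tilt[!is.na(tilt)]
    data.frame(window_id = ids[i], start = windows$start[i],
               end = windows$end[i],
               n_traces = n,
               mean_length_pings = if (n) mean(tab$length_pings[sel]) else NA_real_,
               mean_tilt = if (length(tilt_ok)) mean(tilt_ok) else NA_real_,
               frac_upward = if (length(tilt_ok)) mean(tilt_ok > 0) else NA_real_)
  })
  do.call(rbind, rows)
}
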
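# Minimal RIFF/WAVE reader and writer: 16-bit PCM and 32-bit IEEE float,
# mono or multichannel (channels averaged on read). No pre-installed R
# package reads WAV in this stack, and the format subset needed here is
# small and stable.

#' Read a WAV file
#'
#' Supports 16-bit PCM (samples scaled to \[-1, 1\] by 1/32768) and 32-bit
#' IEEE float. Multichannel files are averaged to mono.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, full scale = 1) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk")
      if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits)")
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("WAV file has no data chunk")
  if (fmt$channels > 1) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  list(samples = samples, sample_rate = fmt$rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric vector, full scale = 1 (clipped to \[-1, 1\] for
#'   PCM).
#' @param sample_rate sampling rate (Hz).
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmin(pmax(samples, -1), 32767 / 32768) * 32768))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}

#' Load and calibrate a WAV recording
#'
#' Reads a WAV file plus a sidecar calibration file (plain text `key: value`
#' lines: `sensitivity_db`, `gain_db`, `full_scale_volts`) and returns the
#' calibrated [pressure_series()]:
#' `pressure = samples * full_scale_volts * 10^(-(sensitivity + gain)/20)`.
#'
#' @param wav_path WAV file.
#' @param cal_path sidecar calibration file.
#' @return a [pressure_series()] (uPa).
#' @export
read_calibrated_wav <- function(wav_path, cal_path) {
  w <- read_wav(wav_path)
  lines <- readLines(cal_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cal <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) cal[[m[2]]] <- as.numeric(m[3])
  }
  for (k in c("sensitivity_db", "gain_db", "full_scale_volts"))
    if (is.null(cal[[k]])) stop("calibration file missing key: ", k)
  calibrate(w$samples * cal$full_scale_volts, cal$sensitivity_db,
            cal$gain_db, w$sample_rate, label = basename(wav_path))
}
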
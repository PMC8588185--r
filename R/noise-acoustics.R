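#' Calibrated pressure series
#'
#' A hydrophone recording converted to physical units: pressure samples in
#' micropascal (uPa) at a fixed sample rate.
#'
#' @param samples numeric vector of pressures (uPa), finite.
#' @param sample_rate sampling rate (Hz), > 0.
#' @param label optional source label.
#' @return object of class `"pressure_series"`.
#' @export
pressure_series <- function(samples, sample_rate, label = "") {
  if (!length(samples)) stop("zero-length pressure series")
  if (!all(is.finite(samples))) stop("pressure samples must be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate), label = label),
            class = "pressure_series")
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("<pressure_series> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Calibrate a voltage recording to pressure
#'
#' `pressure_uPa = volts * 10^(-(sensitivity + gain) / 20)`, the standard
#' hydrophone calibration with sensitivity in dB re 1 V/uPa (typically a
#' large negative number, e.g. -194 for an ITC1032, -211 for a B&K 8103)
#' plus any conditioning-amplifier gain in dB.
#'
#' @param volts numeric voltage samples.
#' @param sensitivity_db hydrophone sensitivity, dB re 1 V/uPa.
#' @param gain_db amplifier gain (dB), default 0.
#' @param sample_rate sampling rate (Hz).
#' @param label optional label.
#' @return a [pressure_series()] in uPa.
#' @examples
#' p <- calibrate(1, -194, 0, 44100)
#' p$samples  # ~5.01e9 uPa
#' @export
calibrate <- function(volts, sensitivity_db, gain_db = 0, sample_rate,
                      label = "") {
  if (!length(volts)) stop("zero-length input")
  pressure_series(volts * 10^(-(sensitivity_db + gain_db) / 20), sample_rate,
                  label)
}

#' Sound pressure level with exponential RMS averaging
#'
#' Running mean square with an exponential window:
#' `ms[n] = a * p[n]^2 + (1 - a) * ms[n - 1]`, `a = 1 - exp(-dt / tau)`,
#' reported as `10 * log10(ms)` dB re 1 uPa, plus the overall SPL
#' `10 * log10(mean(p^2))` of the whole series. An all-zero signal reports
#' `-Inf` (missing).
#'
#' @param p a [pressure_series()] (uPa).
#' @param time_constant_s exponential averaging time constant (s), default
#'   1 s.
#' @return list with `spl_series` (per-sample dB) and `spl_overall` (dB).
#' @export
spl_rms <- function(p, time_constant_s = 1) {
  stopifnot(inherits(p, "pressure_series"), time_constant_s > 0)
  x2 <- p$samples^2
  a <- 1 - exp(-1 / (p$sample_rate * time_constant_s))
  ms <- as.numeric(stats::filter(a * x2, 1 - a, method = "recursive",
                                 init = x2[1]))
  overall <- if (all(x2 == 0)) -Inf else 10 * log10(mean(x2))
  list(spl_series = ifelse(ms > 0, 10 * log10(ms), -Inf),
       spl_overall = overall)
}

#' Peak sound pressure level
#'
#' `20 * log10(max(|p|))` dB re 1 uPa; `-Inf` for an all-zero signal.
#'
#' @param p a [pressure_series()] (uPa).
#' @return peak SPL (dB re 1 uPa).
#' @export
peak_spl <- function(p) {
  stopifnot(inherits(p, "pressure_series"))
  mx <- max(abs(p$samples))
  if (mx == 0) -Inf else 20 * log10(mx)
}

# Nominal third-octave center labels (base-10 series), one decade.
TO_NOMINAL <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

# Hann-windowed full-length periodogram: power (uPa^2) per frequency bin,
# normalized so that the sum over all bins estimates the mean square.
periodogram_power <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  X <- stats::fft(x * w)
  pw <- Mod(X)^2 / (n * sum(w^2))
  half <- seq_len(floor(n / 2) + 1)
  p <- pw[half]
  # fold negative frequencies onto positive (except DC and Nyquist)
  inner <- 2:(length(half) - if (n %% 2 == 0) 1 else 0)
  p[inner] <- 2 * p[inner]
  list(freq = (half - 1) * fs / n, power = p)
}

#' Third-octave band levels
#'
#' Band levels (dB re 1 uPa RMS) at the base-10 third-octave centers
#' `10^(n/10)` Hz with edges `fc * 10^(+/-1/20)`, computed by integrating a
#' Hann-windowed periodogram over each band (see the methods vignette for
#' why spectral integration replaces an IIR filter bank here). Bands whose
#' upper edge exceeds Nyquist are omitted with a warning; bands with no
#' power are reported `-Inf`.
#'
#' @param p a [pressure_series()] (uPa).
#' @param f_min,f_max band-center search range (Hz).
#' @return data.frame with `center_hz` (exact), `nominal_hz`, `level_db`.
#' @export
third_octave_levels <- function(p, f_min = 10, f_max = 20000) {
  stopifnot(inherits(p, "pressure_series"), f_min > 0, f_max > f_min)
  nyq <- p$sample_rate / 2
  if (f_max >= nyq) stop("f_max must be below Nyquist (", nyq, " Hz)")
  n_lo <- ceiling(10 * log10(f_min)); n_hi <- floor(10 * log10(f_max))
  idx <- n_lo:n_hi
  centers <- 10^(idx / 10)
  nominal <- TO_NOMINAL[(idx %% 10) + 1] * 10^(idx %/% 10)
  lo <- centers * 10^(-1 / 20); hi <- centers * 10^(1 / 20)
  keep <- hi < nyq
  if (any(!keep)) warning(sum(!keep), " band(s) above Nyquist omitted")
  pg <- periodogram_power(p$samples, p$sample_rate)
  lev <- vapply(which(keep), function(i) {
    pw <- sum(pg$power[pg$freq >= lo[i] & pg$freq < hi[i]])
    if (pw > 0) 10 * log10(pw) else -Inf
  }, numeric(1))
  data.frame(center_hz = centers[keep], nominal_hz = nominal[keep],
             level_db = lev)
}

#' Narrowband (Welch) spectrum
#'
#' Averaged periodogram: Hann window, 50% overlap, segments of `nfft`
#' samples. Returns the per-bin power spectrum scaled so the sum over bins
#' estimates the mean square (uPa^2), as dB levels.
#'
#' @param p a [pressure_series()] (uPa).
#' @param nfft segment length (samples); shortened to the series length if
#'   needed.
#' @return data.frame with `freq_hz`, `level_db` (10*log10 of per-bin
#'   power).
#' @export
narrowband_spectrum <- function(p, nfft = 4096) {
  stopifnot(inherits(p, "pressure_series"))
  x <- p$samples
  nfft <- min(nfft, length(x))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  hop <- max(1, floor(nfft / 2))
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  half <- seq_len(floor(nfft / 2) + 1)
  acc <- numeric(length(half))
  for (s in starts) {
    X <- stats::fft(x[s:(s + nfft - 1)] * w)
    acc <- acc + Mod(X[half])^2
  }
  pw <- acc / (length(starts) * nfft * sum(w^2))
  inner <- 2:(length(half) - if (nfft %% 2 == 0) 1 else 0)
  pw[inner] <- 2 * pw[inner]
  data.frame(freq_hz = (half - 1) * p$sample_rate / nfft,
             level_db = ifelse(pw > 0, 10 * log10(pw), -Inf))
}

#' Harmonic distortion of a tone recording
#'
#' Total harmonic distortion relative to the fundamental:
#' `10 * log10(sum(P_2..P_n) / P_1)` where `P_h` is the spectral power in a
#' small window around harmonic `h * f0` of the Welch spectrum. Quantifies
#' the super-harmonics a driven loudspeaker adds to a nominally pure tone.
#'
#' @param p a [pressure_series()] (uPa).
#' @param f0 fundamental frequency (Hz).
#' @param n_harmonics number of harmonics (>= 2) included, fundamental
#'   excluded; `f0 * n_harmonics` must be below Nyquist.
#' @param nfft Welch segment length.
#' @return distortion ratio (dB; 0 means harmonic power equals fundamental
#'   power).
#' @export
harmonic_distortion <- function(p, f0, n_harmonics = 5, nfft = 4096) {
  stopifnot(inherits(p, "pressure_series"), f0 > 0, n_harmonics >= 2)
  if (f0 * n_harmonics >= p$sample_rate / 2)
    stop("f0 * n_harmonics must be below Nyquist")
  sp <- narrowband_spectrum(p, nfft)
  df <- sp$freq_hz[2] - sp$freq_hz[1]
  band_power <- function(f) {
    sel <- abs(sp$freq_hz - f) <= 2 * df
    sum(10^(sp$level_db[sel] / 10))
  }
  p1 <- band_power(f0)
  if (p1 <= 0) stop("no power at the fundamental frequency bin")
  ph <- sum(vapply(2:n_harmonics, function(h) band_power(h * f0), numeric(1)))
  10 * log10(ph / p1)
}
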
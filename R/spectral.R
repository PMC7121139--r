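#' Standard electrophysiology frequency bands
#'
#' Delta 1-4 Hz, theta 4-12 Hz, beta 12-30 Hz, gamma 30-100 Hz. Band edges
#' are conventions, not model constants, and every function taking bands
#' accepts a custom table.
#'
#' @return Data.frame `name`, `low_hz`, `high_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "beta", "gamma"),
             low_hz = c(1, 4, 12, 30),
             high_hz = c(4, 12, 30, 100))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into
#' `segment_samples` windows with fractional `overlap`, each segment is
#' linearly detrended, tapered (Hann by default) and Fourier transformed;
#' one-sided power densities are averaged over segments. The overall mean
#' is removed first. Scaling is such that the integral of the density over
#' frequency matches the signal variance (Parseval).
#'
#' @param x Numeric signal, or a data.frame with a `time_ms` column (e.g.
#'   the `traces` of a `sim_result`), or a `sim_result`.
#' @param fs_hz Sampling frequency (Hz); inferred from `time_ms` for
#'   data.frame/`sim_result` input.
#' @param column For data.frame/`sim_result` input, which signal to use
#'   (`"vm_sum"`, the default oscillation readout, or `"lfp"`).
#' @param segment_samples Segment length in samples (default 1024, i.e.
#'   1024 ms at dt = 1 ms, about 1 Hz resolution).
#' @param overlap Fractional segment overlap in `[0, 1)`, default 0.5.
#' @param window `"hann"` or `"rect"`.
#' @param detrend `"linear"` (per-segment linear fit removed) or
#'   `"mean"`.
#' @return A `psd` data.frame (`freq_hz`, `power`) with attributes
#'   `fs_hz`, `df_hz`, `n_segments`, `segment_samples`, `window`.
#' @export
estimate_psd <- function(x, fs_hz = NULL, column = "vm_sum",
                         segment_samples = 1024, overlap = 0.5,
                         window = c("hann", "rect"),
                         detrend = c("linear", "mean")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  if (inherits(x, "sim_result")) x <- x$traces
  if (is.data.frame(x)) {
    if (is.null(fs_hz)) {
      dt_ms <- stats::median(diff(x$time_ms))
      fs_hz <- 1000 / dt_ms
    }
    x <- x[[column]]
  }
  if (is.null(fs_hz)) stop("'fs_hz' is required for plain numeric input")
  x <- as.numeric(x)
  nseg <- as.integer(segment_samples)
  if (length(x) < nseg)
    stop("trace shorter than one segment (", nseg, " samples)")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  x <- x - mean(x)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
       else rep(1, nseg)
  u <- sum(w^2)
  tt <- seq_len(nseg)
  acc <- numeric(nseg %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- if (detrend == "linear") stats::lm.fit(cbind(1, tt), seg)$residuals
           else seg - mean(seg)
    ft <- stats::fft(seg * w)[seq_along(acc)]
    p <- Mod(ft)^2 / (fs_hz * u)
    p[-1] <- 2 * p[-1]
    if (nseg %% 2 == 0) p[length(p)] <- p[length(p)] / 2
    acc <- acc + p
  }
  out <- data.frame(freq_hz = (seq_along(acc) - 1) * fs_hz / nseg,
                    power = acc / length(starts))
  attr(out, "fs_hz") <- fs_hz
  attr(out, "df_hz") <- fs_hz / nseg
  attr(out, "n_segments") <- length(starts)
  attr(out, "segment_samples") <- nseg
  attr(out, "window") <- window
  class(out) <- c("psd", "data.frame")
  out
}

# Trapezoidal integral of the density over [low, high], with linear
# interpolation at the band edges.
trapz_band <- function(freq, power, low, high) {
  inside <- freq > low & freq < high
  f <- c(low, freq[inside], high)
  p <- c(stats::approx(freq, power, xout = low, rule = 2)$y,
         power[inside],
         stats::approx(freq, power, xout = high, rule = 2)$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Band power of a spectrum
#'
#' Trapezoidal integral of the power density over a frequency band.
#'
#' @param spectrum A `psd` from [estimate_psd()].
#' @param band Either a band name from `bands`, or `c(low_hz, high_hz)`.
#' @param bands Band definition table (default [default_bands()]).
#' @return Scalar power (signal units squared).
#' @export
band_power <- function(spectrum, band, bands = default_bands()) {
  if (is.character(band)) {
    row <- bands[bands$name == band, ]
    if (nrow(row) != 1) stop("unknown band '", band, "'")
    band <- c(row$low_hz, row$high_hz)
  }
  if (band[1] >= band[2]) stop("'band' must satisfy low < high")
  if (band[1] < min(spectrum$freq_hz) || band[2] > max(spectrum$freq_hz))
    stop("band [", band[1], ", ", band[2], "] Hz outside the spectrum range")
  trapz_band(spectrum$freq_hz, spectrum$power, band[1], band[2])
}

#' Total power of a spectrum
#'
#' Integral of the density over the full frequency axis; approximately the
#' signal variance (Parseval identity).
#'
#' @param spectrum A `psd`.
#' @return Scalar power.
#' @export
total_power <- function(spectrum) {
  trapz_band(spectrum$freq_hz, spectrum$power,
             min(spectrum$freq_hz), max(spectrum$freq_hz))
}

#' Detect the spectral peak in each band
#'
#' For each band, the highest local maximum of the density whose power
#' exceeds `prominence` times the spectrum-wide median density is reported;
#' bands without such a maximum are reported as not detected.
#'
#' @param spectrum A `psd`.
#' @param bands Band table (default [default_bands()]).
#' @param prominence Required ratio of peak power to the median density.
#' @return Data.frame `band`, `freq_hz`, `power`, `detected`.
#' @export
find_band_peaks <- function(spectrum, bands = default_bands(),
                            prominence = 5) {
  p <- spectrum$power
  f <- spectrum$freq_hz
  floor_power <- stats::median(p[f > 0]) * prominence
  local_max <- c(FALSE, diff(sign(diff(p))) < 0, FALSE)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- which(f >= bands$low_hz[i] & f <= bands$high_hz[i] & local_max &
                   p >= floor_power)
    if (!length(sel))
      return(data.frame(band = bands$name[i], freq_hz = NA_real_,
                        power = NA_real_, detected = FALSE))
    j <- sel[which.max(p[sel])]
    data.frame(band = bands$name[i], freq_hz = f[j], power = p[j],
               detected = TRUE)
  })
  do.call(rbind, out)
}
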
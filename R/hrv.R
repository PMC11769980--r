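#' Time-domain heart rate variability indices
#'
#' RMSSD is the square root of the mean of squared successive RR
#' differences; pNN50 is the percentage of successive-difference pairs
#' exceeding 50 ms; heart rate is 60000 divided by the mean RR interval.
#'
#' @param rr Numeric vector of RR intervals in ms (at least 2).
#' @return A tibble (one row) with `mean_rr` (ms), `hr` (min^-1), `rmssd`
#'   (ms), `pnn50` (%).
#' @export
#' @examples
#' time_domain(c(800, 810, 790, 810)) # rmssd = sqrt(900/3)
time_domain <- function(rr) {
  if (length(rr) < 2) {
    cr_abort("time-domain indices need at least 2 intervals",
             class = "cardioresp_error_input")
  }
  d <- diff(rr)
  tibble::tibble(
    mean_rr = mean(rr),
    hr = 60000 / mean(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  )
}

#' Baevsky geometric stress index
#'
#' The RR histogram is built with fixed-width bins (default 50 ms) anchored
#' at zero. The mode Mo is the midpoint of the modal bin (in seconds), AMo
#' the percentage of intervals in the modal bin, MxDMn the interval range
#' (seconds), and the stress index SI = AMo / (2 * Mo * MxDMn) in
#' conventional units. High values indicate sympathetic predominance.
#'
#' @param rr Numeric vector of RR intervals in ms.
#' @param bin_width Histogram bin width in ms.
#' @return A tibble (one row) with `mo` (s), `amo` (%), `mxdmn` (s), `si`
#'   (c.u.).
#' @export
#' @examples
#' stress_index(rnorm(100, 800, 30))
stress_index <- function(rr, bin_width = 50) {
  mxdmn <- (max(rr) - min(rr)) / 1000
  if (mxdmn <= 0) {
    cr_abort("SI undefined: all intervals identical (MxDMn = 0)",
             class = "cardioresp_error_input")
  }
  bins <- floor(rr / bin_width)
  counts <- table(bins)
  modal <- as.numeric(names(counts)[which.max(counts)])
  mo <- (modal * bin_width + bin_width / 2) / 1000
  amo <- 100 * max(counts) / length(rr)
  tibble::tibble(mo = mo, amo = amo, mxdmn = mxdmn,
                 si = amo / (2 * mo * mxdmn))
}

#' Resample a beat-to-beat series onto a uniform grid
#'
#' Cubic-spline interpolation of the tachogram (or beat-to-beat pressure
#' series) onto a uniform grid at `fs` (default 4 Hz), followed by linear
#' detrending -- the standard preprocessing before spectral analysis of
#' unevenly sampled beat series.
#'
#' @param t Beat times in seconds (strictly increasing, span at least 60 s,
#'   at least 30 points).
#' @param value Series values at the beat times (RR in ms or pressure in
#'   mmHg).
#' @param fs Resampling rate in Hz.
#' @return A tibble with columns `t` and `value` (detrended).
#' @export
resample_tachogram <- function(t, value, fs = 4) {
  if (length(t) < 30) {
    cr_abort("resampling needs at least 30 points",
             class = "cardioresp_error_input")
  }
  span <- t[length(t)] - t[1]
  if (span < 60) {
    cr_abort("resampling needs a span of at least 60 s",
             class = "cardioresp_error_input")
  }
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  y <- spline(t, value, xout = grid, method = "fmm")$y
  fit <- lm.fit(cbind(1, grid), y)
  tibble::tibble(t = grid, value = unname(fit$residuals))
}

# Welch power spectral density: Hann window, segments of window_s seconds
# (or the whole series if shorter), 50% overlap, one-sided density
# normalized so that the integral over frequency equals the variance of the
# windowed signal (Parseval).
welch_psd <- function(x, fs, window_s = 100, overlap = 0.5) {
  n <- length(x)
  len <- min(round(window_s * fs), n)
  step <- max(1, floor(len * (1 - overlap)))
  starts <- seq(1, n - len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)) # Hann
  u <- sum(w^2)
  nf <- floor(len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + len - 1)]
    seg <- (seg - mean(seg)) * w
    spec <- Mod(fft(seg)[seq_len(nf)])^2 / (fs * u)
    acc <- acc + spec
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even lengths) Nyquist
  last <- if (len %% 2 == 0) nf - 1 else nf
  psd[2:last] <- 2 * psd[2:last]
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / len, psd = psd)
}

# Trapezoidal band integral with interpolated band edges.
band_integral <- function(freq, psd, lo, hi) {
  f <- c(lo, freq[freq > lo & freq < hi], hi)
  p <- stats::approx(freq, psd, xout = f, rule = 2)$y
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Default spectral band edges (Hz)
#'
#' VLF 0.0033--0.04, LF 0.04--0.15, HF 0.15--0.40 Hz; total power is the
#' integral over 0.0033--0.40 Hz.
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_bands <- function() {
  list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))
}

#' Spectral band powers of a uniformly resampled series
#'
#' Power spectral density by the Welch method (Hann window, segment length
#' `min(window_s, full record)`, 50% overlap) and band powers by trapezoidal
#' integration over the VLF/LF/HF bands. Total power integrates over the
#' union of the bands. Normalized powers use lfn = 100 * lf / (lf + hf).
#'
#' @param series Tibble from [resample_tachogram()] (columns `t`, `value`)
#'   with uniform sampling and span at least 60 s.
#' @param bands Band-edge list as from [default_bands()].
#' @param window_s Welch segment length in seconds.
#' @return A tibble (one row) with `tp`, `vlf`, `lf`, `hf` (squared input
#'   units), `lfn`, `hfn` (%), `lf_hf`.
#' @export
#' @examples
#' tach <- tibble::tibble(t = seq(0, 120, 0.25),
#'                        value = 20 * sin(2 * pi * 0.1 * seq(0, 120, 0.25)))
#' band_powers(tach) # lf close to 200 ms^2
band_powers <- function(series, bands = default_bands(), window_s = 100) {
  t <- series$t
  if (t[length(t)] - t[1] < 60) {
    cr_abort("spectral analysis needs at least 60 s of data",
             class = "cardioresp_error_input")
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) {
    cr_abort("spectral analysis needs uniform sampling; resample first",
             class = "cardioresp_error_input")
  }
  fs <- 1 / dt[1]
  spec <- welch_psd(series$value, fs, window_s = window_s)
  p <- purrr::map_dbl(bands, ~ band_integral(spec$freq, spec$psd,
                                             .x[1], .x[2]))
  tp <- band_integral(spec$freq, spec$psd,
                      min(purrr::map_dbl(bands, 1)),
                      max(purrr::map_dbl(bands, 2)))
  lfn <- 100 * p[["lf"]] / (p[["lf"]] + p[["hf"]])
  tibble::tibble(tp = tp, vlf = p[["vlf"]], lf = p[["lf"]], hf = p[["hf"]],
                 lfn = lfn, hfn = 100 - lfn, lf_hf = p[["lf"]] / p[["hf"]])
}
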
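# Spectral helpers shared by the respiratory-correction methods.

#' Power in a frequency band
#'
#' Periodogram power of `x` (mean removed) summed over `[flo, fhi]` Hz.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param flo,fhi Band edges, Hz.
#' @return Non-negative scalar (arbitrary power units, consistent across
#'   calls of equal length and rate).
#' @export
band_power <- function(x, fs, flo, fhi) {
  x <- x - mean(x)
  n <- length(x)
  # Hann taper suppresses edge leakage; zero-pad to a composite length so
  # the fft stays O(m log m) for awkward n
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  x <- x * w
  m <- stats::nextn(n)
  if (m > n) x <- c(x, numeric(m - n))
  sp <- Mod(fft(x))^2 / sum(w^2)
  freq <- (seq_len(m) - 1) * fs / m
  half <- freq <= fs / 2
  sum(sp[half & freq >= flo & freq <= fhi]) * n / m
}

#' Estimate the respiratory frequency of a pressure signal
#'
#' Decimates the signal by block averaging to about 5 Hz (suppressing the
#' cardiac pulsation), applies a Hann window and locates the periodogram
#' peak inside the plausible respiratory band. The peak must stand clear of
#' the band's median power to count as detected.
#'
#' @param x Pressure series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param band Search band, Hz (default 0.05--1).
#' @param min_prominence Required ratio of peak power to median band power.
#' @return Frequency in Hz.
#' @export
estimate_resp_freq <- function(x, fs, band = c(0.05, 1), min_prominence = 5) {
  if (length(x) < 30 * fs) stop("respiration not detected: signal shorter than 30 s")
  m <- max(1L, round(fs / 5))
  nblk <- floor(length(x) / m)
  if (nblk < 32L) stop("respiration not detected: too few samples")
  y <- colMeans(matrix(x[seq_len(nblk * m)], nrow = m))
  fs_d <- fs / m
  y <- y - mean(y)
  t <- seq_along(y)
  y <- y - stats::lm.fit(cbind(1, t), y)$fitted.values  # remove linear drift
  if (sd(y) < 1e-12) stop("respiration not detected: flat signal")
  n <- length(y)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- Mod(fft(y * w))^2
  freq <- (seq_len(n) - 1) * fs_d / n
  keep <- freq >= band[1] & freq <= band[2] & freq <= fs_d / 2
  if (!any(keep)) stop("respiration not detected: band empty at this rate")
  spb <- sp[keep]; frb <- freq[keep]
  # 3-bin smoothing stabilises the peak location
  if (length(spb) >= 3) {
    spb <- stats::filter(spb, rep(1 / 3, 3), sides = 2)
    spb[is.na(spb)] <- 0
  }
  i <- which.max(spb)
  if (spb[i] < min_prominence * max(median(spb), 1e-300)) {
    stop("respiration not detected: no clear spectral peak in ",
         band[1], "-", band[2], " Hz")
  }
  f_hat <- frb[i]
  # refine with a parabolic interpolation of the raw periodogram peak
  sp_all <- sp
  j <- which.min(abs(freq - f_hat))
  if (j > 1 && j < length(sp_all)) {
    p1 <- sp_all[j - 1]; p2 <- sp_all[j]; p3 <- sp_all[j + 1]
    den <- p1 - 2 * p2 + p3
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (p1 - p3) / den
      if (abs(delta) <= 0.5) f_hat <- freq[j] + delta * (fs_d / n)
    }
  }
  f_hat
}
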
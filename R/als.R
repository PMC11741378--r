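# Asymmetric least squares (Whittaker smoother with asymmetric residual
# weights). The smooth baseline z minimises
#   sum_i w_i (y_i - z_i)^2 + lam * sum_i (delta^2 z_i)^2,
# with w_i = p where y_i > z_i and 1 - p otherwise, iterated to a fixed
# point. With p = 0.5 (default) the smoother tracks the midline of the
# respiratory swing; small p tracks the lower envelope.

#' ALS configuration
#'
#' @param lam Second-difference penalty weight (dimensionless). `NULL`
#'   auto-scales with sampling rate as `1e7 * (fs/250)^4`, placing the
#'   smoother's half-power cutoff near 0.7 Hz -- between the respiratory
#'   (<= 0.5 Hz) and cardiac (>= 1 Hz) bands.
#' @param p Asymmetry weight in (0, 1); 0.5 is symmetric.
#' @param n_iter Reweighting iterations (>= 1).
#' @return List of class `als_config`.
#' @export
als_config <- function(lam = NULL, p = 0.5, n_iter = 10) {
  if (!is.null(lam) && lam <= 0) stop("lam must be > 0")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(lam = lam, p = p, n_iter = as.integer(n_iter)),
            class = "als_config")
}

#' Estimate the respiratory baseline by asymmetric least squares
#'
#' @param x Pressure series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param cfg [als_config()].
#' @param resp_band Respiratory band used for the removed-power summary, Hz.
#' @return A `resp_estimate`: list with `resp_trace` (same length as `x`),
#'   `resp_freq_hz` (estimated from the trace, `NA` if undetectable),
#'   `method = "als"` and `band_power_removed_frac`.
#' @export
estimate_resp_als <- function(x, fs, cfg = als_config(),
                              resp_band = c(0.1, 0.5)) {
  n <- length(x)
  if (n < 10 * fs / resp_band[1]) {
    stop("too short for baseline estimation: need at least ",
         round(10 / resp_band[1]), " s of signal")
  }
  lam <- if (is.null(cfg$lam)) 1e7 * (fs / 250)^4 else cfg$lam
  z <- whittaker_als(x, lam, cfg$p, cfg$n_iter)
  new_resp_estimate(x, z, fs, method = "als", resp_band = resp_band)
}

whittaker_als <- function(y, lam, p, n_iter) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    A <- Matrix::Diagonal(n, w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && it > 1L) break
    w <- w_new
  }
  z
}

new_resp_estimate <- function(x, trace, fs, method, resp_band,
                              resp_freq_hz = NULL, extra = list()) {
  p_before <- band_power(x, fs, resp_band[1], resp_band[2])
  p_after <- band_power(x - trace, fs, resp_band[1], resp_band[2])
  frac <- if (p_before > 0) max(0, min(1, 1 - p_after / p_before)) else 0
  f <- resp_freq_hz
  if (is.null(f)) {
    f <- tryCatch(estimate_resp_freq(trace, fs), error = function(e) NA_real_)
  }
  est <- c(list(resp_trace = trace, resp_freq_hz = f, method = method,
                band_power_removed_frac = frac, resp_band = resp_band),
           extra)
  class(est) <- "resp_estimate"
  est
}

#' @export
print.resp_estimate <- function(x, ...) {
  cat(sprintf("Respiratory estimate (%s): f = %s Hz, band power removed %.1f%%\n",
              toupper(x$method),
              if (is.na(x$resp_freq_hz)) "?" else sprintf("%.3g", x$resp_freq_hz),
              100 * x$band_power_removed_frac))
  invisible(x)
}

#' Subtract a respiratory estimate from a signal
#'
#' Level-preserving subtraction: the mean of the respiratory trace is added
#' back so the absolute mmHg scale of the signal is retained.
#'
#' @param x Pressure series, mmHg.
#' @param est A `resp_estimate` (or a bare numeric trace of equal length).
#' @return Corrected series, same length as `x`.
#' @export
subtract_resp <- function(x, est) {
  trace <- if (inherits(est, "resp_estimate")) est$resp_trace else est
  if (length(trace) != length(x)) {
    stop("length mismatch: signal has ", length(x), " samples, trace has ",
         length(trace))
  }
  x - trace + mean(trace)
}

#' Beats per respiratory cycle
#'
#' Number of beats spanning one respiratory cycle at the paced heart rate:
#' `round(heart_rate_bpm / (60 * resp_freq_hz))`, at least 1. Used for the
#' respiratory-cycle transition-window mode.
#'
#' @param x Pressure series used to estimate the respiratory frequency.
#' @param fs Sampling rate, Hz.
#' @param heart_rate_bpm Paced heart rate.
#' @return Integer beat count >= 1.
#' @export
estimate_resp_cycle_beats <- function(x, fs, heart_rate_bpm) {
  f <- estimate_resp_freq(x, fs)  # errors when respiration is undetectable
  max(1L, as.integer(floor(heart_rate_bpm / (60 * f) + 0.5)))
}
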
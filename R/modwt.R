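# Maximal-overlap discrete wavelet transform (MODWT) and multiresolution
# analysis. The MODWT is used instead of the decimated DWT because it is
# shift-invariant (no alignment artefacts at pacing transitions) and defined
# for any signal length. Boundary handling: the signal is reflected to twice
# its length before the circular transform and the pad is discarded.

# Scaling (low-pass) filters. "la8": Daubechies least-asymmetric 8-tap.
wave_filter <- function(name = c("la8", "haar", "d4")) {
  name <- match.arg(name)
  g <- switch(name,
    haar = c(1, 1) / sqrt(2),
    d4 = c(0.4829629131445341, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604),
    la8 = c(-0.0757657147893407, -0.0296355276459541, 0.4976186676324578,
            0.8037387518052163, 0.2978577956055422, -0.0992195435769354,
            -0.0126039672622612, 0.0322231006040713))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2), L = L, name = name)  # MODWT scaling
}

circ_shift <- function(x, s) {
  # x[(t - s) mod N], vectorised over t
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

modwt_forward_level <- function(v, filt, j) {
  step <- 2^(j - 1)
  W <- numeric(length(v)); V <- numeric(length(v))
  for (l in seq_len(filt$L)) {
    vs <- circ_shift(v, (l - 1) * step)
    W <- W + filt$h[l] * vs
    V <- V + filt$g[l] * vs
  }
  list(W = W, V = V)
}

modwt_inverse_level <- function(W, V, filt, j) {
  step <- 2^(j - 1)
  out <- numeric(length(V))
  for (l in seq_len(filt$L)) {
    sft <- -(l - 1) * step  # x[(t + s) mod N]
    out <- out + filt$h[l] * circ_shift(W, sft) + filt$g[l] * circ_shift(V, sft)
  }
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' Circular MODWT pyramid to `n_levels`. Mostly an internal building block
#' for [estimate_resp_dwt()]; exported for direct use and testing.
#'
#' @param x Numeric series.
#' @param n_levels Decomposition depth.
#' @param wavelet Filter name: `"la8"` (default), `"d4"` or `"haar"`.
#' @return List with `W` (list of wavelet coefficient vectors, one per
#'   level), `V` (final scaling coefficients), `wavelet`, `n_levels`.
#' @export
modwt <- function(x, n_levels, wavelet = "la8") {
  filt <- wave_filter(wavelet)
  v <- x
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    lv <- modwt_forward_level(v, filt, j)
    W[[j]] <- lv$W
    v <- lv$V
  }
  list(W = W, V = v, wavelet = wavelet, n_levels = n_levels)
}

#' MODWT multiresolution detail
#'
#' Reconstructs the level-`j` detail series D_j (the portion of the signal
#' in the nominal band `fs/2^(j+1)` to `fs/2^j`).
#'
#' @param dec Output of [modwt()].
#' @param j Level to reconstruct.
#' @return Numeric series of the original length.
#' @export
modwt_detail <- function(dec, j) {
  filt <- wave_filter(dec$wavelet)
  n <- length(dec$W[[j]])
  v <- modwt_inverse_level(dec$W[[j]], numeric(n), filt, j)
  for (k in rev(seq_len(j - 1))) {
    v <- modwt_inverse_level(numeric(n), v, filt, k)
  }
  v
}

#' Estimate the respiratory component by wavelet subtraction
#'
#' Decomposes the signal with a shift-invariant MODWT and reconstructs the
#' detail levels whose nominal frequency bands overlap the respiratory
#' frequency (estimated from the signal, or supplied as a hint). The
#' reconstruction is the respiratory trace to be subtracted with
#' [subtract_resp()].
#'
#' @param x Pressure series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param resp_freq_hint Optional respiratory frequency, Hz; when `NULL` it
#'   is estimated with [estimate_resp_freq()] (error if undetectable).
#' @param wavelet Filter name (default `"la8"`).
#' @param band_factor A level is selected when its band overlaps
#'   `[f/band_factor, f*band_factor]` (default 1.75).
#' @param resp_band Band used for the removed-power summary, Hz.
#' @return A `resp_estimate` with `method = "dwt"` and the selected
#'   `levels` attached.
#' @export
estimate_resp_dwt <- function(x, fs, resp_freq_hint = NULL, wavelet = "la8",
                              band_factor = 1.75, resp_band = c(0.1, 0.5)) {
  n <- length(x)
  if (n < 4) stop("signal too short for wavelet decomposition")
  if (all(x == x[1])) {
    # constant (incl. all-zero) signal: nothing to remove
    return(new_resp_estimate(x, rep(0, n), fs, method = "dwt",
                             resp_band = resp_band, resp_freq_hz = NA_real_,
                             extra = list(levels = integer())))
  }
  f <- resp_freq_hint
  if (is.null(f)) f <- estimate_resp_freq(x, fs)  # errors if not detected
  # nominal band of level j is [fs/2^(j+1), fs/2^j]
  j_max <- max(1L, ceiling(log2(fs / (f / band_factor))))
  lo <- fs / 2^(seq_len(j_max) + 1)
  hi <- fs / 2^(seq_len(j_max))
  levels <- which(hi > f / band_factor & lo < f * band_factor)
  if (!length(levels)) stop("no wavelet level overlaps the respiratory band")
  mu <- mean(x)
  xp <- c(x, rev(x)) - mu  # reflection pad, circularly smooth
  dec <- modwt(xp, n_levels = max(levels), wavelet = wavelet)
  trace <- numeric(2 * n)
  for (j in levels) trace <- trace + modwt_detail(dec, j)
  trace <- trace[seq_len(n)]
  new_resp_estimate(x, trace, fs, method = "dwt", resp_band = resp_band,
                    resp_freq_hz = f, extra = list(levels = levels))
}
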
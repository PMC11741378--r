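# Beat detection and per-beat feature extraction.

#' Detect beats in a paced pressure signal
#'
#' Finds one beat per pacing cycle by locating the dominant per-cycle peak
#' (after light smoothing) with a minimum peak separation of 70% of the
#' pacing interval, then defines each beat onset at the pulse foot -- the
#' minimum preceding the upstroke. Because the protocol paces at a fixed,
#' known rate, the detected rate is checked against it: a deviation beyond
#' 25% flags the result.
#'
#' @param x Pressure series, mmHg (ABP or CVP; for CVP the dominant a-wave
#'   anchors the cycle).
#' @param fs Sampling rate, Hz.
#' @param pacing_rate_bpm Programmed pacing rate.
#' @return Numeric vector of beat onset times (s), with attributes
#'   `peak_times` (s) and `flag` (`NA`, `"flat"` or `"rate_mismatch"`).
#' @export
detect_beats <- function(x, fs, pacing_rate_bpm) {
  T_beat <- 60 / pacing_rate_bpm
  out_flag <- function(onsets, peaks, flag) {
    structure(onsets, peak_times = peaks, flag = flag)
  }
  rng <- diff(range(x))
  if (rng < 1e-6) {
    warning("flat-line signal: no beats detected")
    return(out_flag(numeric(0), numeric(0), "flat"))
  }
  k <- max(1L, round(0.04 * fs))
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  pk <- pracma::findpeaks(sm,
                          minpeakdistance = max(1L, floor(0.7 * fs * T_beat)),
                          minpeakheight = min(sm) + 0.3 * diff(range(sm)))
  if (is.null(pk) || nrow(pk) == 0) {
    warning("no beats detected")
    return(out_flag(numeric(0), numeric(0), "flat"))
  }
  pk_i <- sort(pk[, 2])
  flag <- NA_character_
  if (length(pk_i) >= 3) {
    med_ibi <- median(diff(pk_i)) / fs
    if (abs(med_ibi - T_beat) > 0.25 * T_beat) {
      warning(sprintf("detected beat rate %.1f bpm deviates >25%% from pacing rate %.1f bpm",
                      60 / med_ibi, pacing_rate_bpm))
      flag <- "rate_mismatch"
    }
  }
  # pulse foot: minimum in the up-to-0.45-cycle window before each peak
  back <- round(0.45 * T_beat * fs)
  onset_i <- vapply(pk_i, function(i) {
    lo <- max(1, i - back)
    lo - 1 + which.min(x[lo:i])
  }, numeric(1))
  keep <- pk_i - back >= 1L  # drop a first beat with truncated foot search
  onset_i <- onset_i[keep]
  out_flag((onset_i - 1) / fs, (pk_i[keep] - 1) / fs, flag)
}

#' Per-beat features
#'
#' For each beat window (onset to next onset), extracts the peak and mean
#' pressure. For CVP the window holds two peaks per cardiac cycle (a- and
#' v-wave); the feature `peak` is the maximum over the up-to-two most
#' prominent local maxima. For ABP it is the single systolic maximum.
#'
#' @param x Pressure series, mmHg.
#' @param beats Beat onset times from [detect_beats()], s.
#' @param fs Sampling rate, Hz.
#' @param channel `"abp"` or `"cvp"`.
#' @return Data frame of class `beat_features`: `beat_time_s`, `channel`,
#'   `peak_mmHg`, `mean_mmHg`, `n_peaks` (local maxima used, <= 2), and
#'   `avd_ms` (`NA` until [attribute_setting()] fills it).
#' @export
beat_features <- function(x, beats, fs, channel = c("abp", "cvp")) {
  channel <- match.arg(channel)
  n_b <- length(beats)
  if (n_b == 0) {
    return(structure(data.frame(beat_time_s = numeric(0), channel = character(0),
                                peak_mmHg = numeric(0), mean_mmHg = numeric(0),
                                n_peaks = integer(0), avd_ms = numeric(0)),
                     class = c("beat_features", "data.frame")))
  }
  ibi <- if (n_b > 1) median(diff(beats)) else 1
  ends <- c(beats[-1], beats[n_b] + ibi)
  peak_v <- rep(NA_real_, n_b); mean_v <- rep(NA_real_, n_b)
  npk_v <- rep(NA_integer_, n_b)
  for (b in seq_len(n_b)) {
    i0 <- floor(beats[b] * fs) + 1L
    i1 <- min(length(x), ceiling(ends[b] * fs))
    if (i1 <= i0) next  # empty beat window: skip
    w <- x[i0:i1]
    if (channel == "cvp" && length(w) >= 5) {
      # up-to-two most prominent local maxima (a- and v-wave)
      core <- w[-c(1, length(w))]
      is_pk <- which(core > w[seq_len(length(w) - 2)] &
                     core >= w[seq.int(3, length(w))]) + 1L
      if (length(is_pk)) {
        top <- head(is_pk[order(w[is_pk], decreasing = TRUE)], 2)
        peak_v[b] <- max(w[top]); npk_v[b] <- length(top)
      } else { peak_v[b] <- max(w); npk_v[b] <- 1L }
    } else { peak_v[b] <- max(w); npk_v[b] <- 1L }
    mean_v[b] <- mean(w)
  }
  keep <- !is.na(peak_v)
  out <- data.frame(beat_time_s = beats[keep], channel = channel,
                    peak_mmHg = peak_v[keep], mean_mmHg = mean_v[keep],
                    n_peaks = npk_v[keep], avd_ms = NA_real_)
  structure(out, class = c("beat_features", "data.frame"))
}

#' Attribute each beat to the pacing setting in force at its onset
#'
#' @param features A `beat_features` data frame.
#' @param events Data frame `time_s`, `avd_ms` (as in a `haemo_record`).
#' @return `features` with `avd_ms` filled; beats before the first event
#'   keep `NA`.
#' @export
attribute_setting <- function(features, events) {
  idx <- findInterval(features$beat_time_s, events$time_s)
  features$avd_ms <- ifelse(idx >= 1, events$avd_ms[pmax(idx, 1L)], NA_real_)
  features
}
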
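# Signal-to-noise and CVP<->ABP agreement statistics.

#' Signal-to-noise ratio of a per-AVD response
#'
#' The signal is the spread between the best and worst observed tested-AVD
#' means; the noise is the arithmetic mean of the per-AVD SEMs.
#'
#' @param resp An `avd_response`.
#' @return List of class `snr_result`: `channel`, `feature`, `signal_mmHg`,
#'   `noise_mmHg`, `snr`. A nonzero signal with zero noise yields `Inf`
#'   (flagged via `noise_mmHg = 0`); zero signal yields `snr = 0`.
#' @export
signal_to_noise <- function(resp) {
  stopifnot(inherits(resp, "avd_response"))
  tab <- resp$table
  if (nrow(tab) < 2) stop("need >= 2 tested AVDs for a signal-to-noise ratio")
  signal <- max(tab$mean_delta_mmHg) - min(tab$mean_delta_mmHg)
  noise <- mean(tab$sem_mmHg, na.rm = TRUE)
  snr <- if (signal == 0) 0 else if (noise > 0) signal / noise else Inf
  structure(list(channel = resp$channel, feature = resp$feature,
                 signal_mmHg = signal, noise_mmHg = noise, snr = snr),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR (%s %s): signal %.2f mmHg / noise %.2f mmHg = %.2f\n",
              toupper(x$channel), x$feature, x$signal_mmHg, x$noise_mmHg,
              x$snr))
  invisible(x)
}

# Spearman rank correlation with midranks for ties; two-sided p-value by
# the t approximation for n >= 10 and exact permutation below that (the
# pressure-delta data are heteroskedastic, hence ranks).
spearman_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n,
                note = "degenerate: a margin is constant (all ties)"))
  }
  r <- cor(rx, ry)
  if (n >= 10) {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    perms <- pracma::perms(seq_len(n))
    rp <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    p <- mean(abs(rp) >= abs(r) - 1e-12)
  }
  list(r = r, p_value = min(p, 1), n = n, note = NA_character_)
}

new_agreement_result <- function(r, p_value, n_pairs, bias = NA_real_,
                                 loa_low = NA_real_, loa_high = NA_real_,
                                 method = "spearman", note = NA_character_) {
  structure(list(r = r, p_value = p_value, n_pairs = n_pairs,
                 bland_bias = bias, loa_low = loa_low, loa_high = loa_high,
                 method = method, note = note),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): r = %s (%s), p = %s\n", x$n_pairs,
              if (is.na(x$r)) "NA" else sprintf("%.3f", x$r), x$method,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  if (!is.na(x$bland_bias)) {
    cat(sprintf("  Bland-Altman bias %.2f, limits of agreement [%.2f, %.2f]\n",
                x$bland_bias, x$loa_low, x$loa_high))
  }
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Per-transition correlation between CVP and ABP changes
#'
#' Pairs the replicate transition deltas of the two channels by (tested
#' AVD, replicate, direction) and computes the Spearman rank correlation.
#' A reliable mirror-image relationship shows as a negative correlation.
#'
#' @param deltas_abp,deltas_cvp `transition_deltas` data frames.
#' @return An `agreement_result`.
#' @export
per_transition_correlation <- function(deltas_abp, deltas_cvp) {
  m <- merge(as.data.frame(deltas_abp)[, c("avd_tested_ms", "replicate_index",
                                           "direction", "delta_mmHg")],
             as.data.frame(deltas_cvp)[, c("avd_tested_ms", "replicate_index",
                                           "direction", "delta_mmHg")],
             by = c("avd_tested_ms", "replicate_index", "direction"),
             suffixes = c("_abp", "_cvp"))
  if (nrow(m) < 5) stop("need >= 5 paired transitions, got ", nrow(m))
  st <- spearman_test(m$delta_mmHg_abp, m$delta_mmHg_cvp)
  new_agreement_result(st$r, st$p_value, st$n, note = st$note)
}

#' SE_opt versus ABP/CVP optimum discrepancy
#'
#' Rank correlation, across subjects, between the vertex standard error and
#' the absolute gap between the ABP- and CVP-derived optima. A positive
#' correlation means SE_opt predicts when the two optimisation targets
#' disagree.
#'
#' @param se_opt_ms Per-subject SE_opt values, ms.
#' @param discrepancy_ms Per-subject `|x_opt_abp - x_opt_cvp|`, ms.
#' @return An `agreement_result` (degenerate inputs -- e.g. a noiseless
#'   cohort with all-zero margins -- are reported as `NA` with a note, not
#'   as a spurious correlation).
#' @export
seopt_vs_discrepancy <- function(se_opt_ms, discrepancy_ms) {
  ok <- is.finite(se_opt_ms) & is.finite(discrepancy_ms)
  if (sum(ok) < 5) stop("need >= 5 subjects, got ", sum(ok))
  st <- spearman_test(se_opt_ms[ok], discrepancy_ms[ok])
  new_agreement_result(st$r, st$p_value, st$n, note = st$note)
}

#' Bland-Altman agreement between paired optima
#'
#' Bias is the mean CVP-minus-ABP difference; limits of agreement are
#' bias +/- 1.96 x SD of the differences. The pairwise Pearson correlation
#' is included.
#'
#' @param optima_abp,optima_cvp Paired optima, ms (or any paired
#'   measurements in common units).
#' @return An `agreement_result` with `bland_bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(optima_abp, optima_cvp) {
  stopifnot(length(optima_abp) == length(optima_cvp))
  ok <- is.finite(optima_abp) & is.finite(optima_cvp)
  a <- optima_abp[ok]; v <- optima_cvp[ok]
  n <- length(a)
  if (n < 3) stop("need >= 3 pairs for Bland-Altman, got ", n)
  d <- v - a
  bias <- mean(d)
  s <- sd(d)
  r <- if (sd(a) > 0 && sd(v) > 0) cor(a, v) else NA_real_
  new_agreement_result(r, NA_real_, n, bias = bias,
                       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                       method = "pearson",
                       note = if (is.na(r)) "correlation undefined (constant margin)" else NA_character_)
}
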
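# End-to-end subject analysis and cohort summaries.

#' Run the full AVD optimisation pipeline on one record
#'
#' Applies the configured respiratory correction to each channel, detects
#' beats, extracts per-beat features, forms replicate transition deltas and
#' per-AVD aggregates, fits the parabolic response per channel, computes
#' vertex standard errors (delta method, plus parametric bootstrap when
#' `bootstrap_reps > 0`), applies the quality-control gate and computes
#' signal-to-noise and the between-channel transition correlation.
#' Deterministic given `config$seed`.
#'
#' When fewer than 3 distinct tested AVDs survive, the parabola fit is
#' refused and QC reports `insufficient_settings` for that channel.
#'
#' @param record A `haemo_record`.
#' @param config An [analysis_config()].
#' @return Object of class `avd_report`: per-channel `response`
#'   (`avd_response`), `fit` (`avd_parabola` or `NULL`), `se_opt`
#'   (delta/bootstrap/gated value used for QC), `snr`, plus `qc`,
#'   `mirror` (per-transition agreement), `window_beats`, `resp_freq_hz`
#'   and the `config`.
#' @export
avd_optimise <- function(record, config = analysis_config()) {
  stopifnot(inherits(record, "haemo_record"))
  fs <- record$sample_rate_hz
  hr <- config$heart_rate_bpm
  ref <- infer_ref_avd(record$events)

  # respiratory correction on the full continuous trace, then beat analysis
  correct <- function(x) {
    switch(config$correction,
      none = list(signal = x, est = NULL),
      als = {
        est <- estimate_resp_als(x, fs, config$als)
        list(signal = subtract_resp(x, est), est = est)
      },
      dwt = {
        est <- estimate_resp_dwt(x, fs, wavelet = config$dwt$wavelet,
                                 band_factor = config$dwt$band_factor)
        list(signal = subtract_resp(x, est), est = est)
      })
  }
  ca <- correct(record$abp)
  cv <- correct(record$cvp)

  # transition window length
  resp_f <- tryCatch(estimate_resp_freq(record$cvp, fs),
                     error = function(e) NA_real_)
  W <- config$window_beats
  if (config$window_mode == "resp_cycle") {
    W <- tryCatch(estimate_resp_cycle_beats(record$cvp, fs, hr),
                  error = function(e) {
                    warning("respiration undetectable; falling back to fixed ",
                            config$window_beats, "-beat window")
                    config$window_beats
                  })
  }

  analyse_channel <- function(signal, channel, feature) {
    beats <- detect_beats(signal, fs, hr)
    if (length(beats) < 2 * W + 2) {
      return(list(response = NULL, fit = NULL, deltas = NULL,
                  reason = "insufficient_settings"))
    }
    feats <- beat_features(signal, beats, fs, channel)
    feats <- attribute_setting(feats, record$events)
    deltas <- transition_deltas(feats, record$events, window_beats = W,
                                ref_avd_ms = ref, feature = feature,
                                directions = config$directions)
    response <- aggregate_response(deltas)
    fit <- tryCatch(fit_parabola(response, weighting = config$weighting),
                    error = function(e) NULL)
    list(response = response, fit = fit, deltas = deltas, reason = NULL)
  }
  abp <- analyse_channel(ca$signal, "abp", "peak")
  cvp <- analyse_channel(cv$signal, "cvp", config$cvp_feature)

  # SE_opt: delta method by default; bootstrap as robust cross-check, used
  # for the QC gate when the two disagree by more than 50%
  se_for <- function(side, sub_seed) {
    if (is.null(side$fit)) return(list(delta = NA_real_, boot = NA_real_, used = NA_real_))
    se_d <- side$fit$se_opt_ms
    se_b <- NA_real_
    used <- se_d
    if (config$bootstrap_reps > 0) {
      se_b <- se_opt_bootstrap(side$response, n_boot = config$bootstrap_reps,
                               seed = config$seed + sub_seed,
                               weighting = config$weighting)
      if (is.finite(se_b) && is.finite(se_d) && se_d > 0 &&
          abs(se_b - se_d) / se_d > 0.5) {
        used <- as.numeric(se_b)
      }
    }
    list(delta = se_d, boot = as.numeric(se_b), used = used)
  }
  se_abp <- se_for(abp, 101L)
  se_cvp <- se_for(cvp, 202L)

  qc <- qc_check(abp$fit, cvp$fit, threshold_ms = config$qc_seopt_threshold_ms,
                 se_override = list(abp = se_abp$used, cvp = se_cvp$used))

  snr <- list(
    abp = if (!is.null(abp$response)) signal_to_noise(abp$response) else NULL,
    cvp = if (!is.null(cvp$response)) signal_to_noise(cvp$response) else NULL)
  mirror <- if (!is.null(abp$deltas) && !is.null(cvp$deltas)) {
    tryCatch(per_transition_correlation(abp$deltas, cvp$deltas),
             error = function(e) NULL)
  } else NULL

  structure(list(
    abp = abp, cvp = cvp, se_opt = list(abp = se_abp, cvp = se_cvp),
    qc = qc, snr = snr, mirror = mirror,
    window_beats = W, resp_freq_hz = resp_f, ref_avd_ms = ref,
    resp_estimates = list(abp = ca$est, cvp = cv$est),
    config = config), class = "avd_report")
}

infer_ref_avd <- function(events) {
  tab <- table(events$avd_ms)
  as.numeric(names(tab)[which.max(tab)])
}

#' @export
print.avd_report <- function(x, ...) {
  cat(sprintf("AVD optimisation report (correction: %s, window: %d beats)\n",
              x$config$correction, x$window_beats))
  for (ch in c("abp", "cvp")) {
    side <- x[[ch]]
    if (is.null(side$fit)) {
      cat(sprintf("  %s: no fit (%s)\n", toupper(ch),
                  paste(x$qc[[ch]]$reasons, collapse = ", ")))
    } else {
      cat(sprintf("  %s: x_opt = %.1f ms, SE_opt = %.1f ms, QC %s\n",
                  toupper(ch), side$fit$x_opt_ms, x$se_opt[[ch]]$used,
                  if (x$qc[[ch]]$passed) "pass"
                  else paste0("fail (", paste(x$qc[[ch]]$reasons, collapse = ", "), ")")))
    }
  }
  if (!is.null(x$mirror)) {
    cat(sprintf("  mirror image: per-transition Spearman r = %.3f (n = %d)\n",
                x$mirror$r, x$mirror$n_pairs))
  }
  invisible(x)
}

#' @export
summary.avd_report <- function(object, ...) {
  row <- function(ch) {
    side <- object[[ch]]
    data.frame(
      channel = ch,
      feature = if (!is.null(side$response)) side$response$feature else NA,
      x_opt_ms = if (!is.null(side$fit)) side$fit$x_opt_ms else NA_real_,
      se_opt_ms = object$se_opt[[ch]]$used,
      se_opt_delta_ms = object$se_opt[[ch]]$delta,
      se_opt_boot_ms = object$se_opt[[ch]]$boot,
      snr = if (!is.null(object$snr[[ch]])) object$snr[[ch]]$snr else NA_real_,
      qc_pass = object$qc[[ch]]$passed,
      qc_reasons = paste(object$qc[[ch]]$reasons, collapse = ";"))
  }
  out <- rbind(row("abp"), row("cvp"))
  out$correction <- object$config$correction
  out$window_beats <- object$window_beats
  rownames(out) <- NULL
  out
}

#' Plot an AVD optimisation report
#'
#' Side-by-side fitted responses for the two channels.
#'
#' @param x An `avd_report`.
#' @param ... Passed to [plot.avd_parabola()].
#' @export
plot.avd_report <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  for (ch in c("abp", "cvp")) {
    if (!is.null(x[[ch]]$fit)) plot(x[[ch]]$fit, main = toupper(ch), ...)
  }
  invisible(x)
}

#' Cohort summary table
#'
#' Binds per-subject report summaries into one data frame (one row per
#' subject x channel), suitable for CSV export and for the cohort-level
#' agreement statistics.
#'
#' @param reports List of `avd_report` objects.
#' @return Data frame with a `subject` column plus [summary.avd_report()]
#'   columns.
#' @export
cohort_table <- function(reports) {
  do.call(rbind, lapply(seq_along(reports), function(i) {
    s <- summary(reports[[i]])
    cbind(subject = i, s)
  }))
}
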
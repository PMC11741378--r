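# Plain-text record I/O: a waveform CSV (time_s, abp_mmhg, cvp_mmhg), an
# annotation CSV (time_s, avd_ms), an optional ground-truth sidecar and a
# plain-text metadata file, all living in one bundle directory.

fmt_num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

#' Write a haemodynamic record to a bundle directory
#'
#' Writes `<prefix>_waveform.csv` (columns `time_s`, `abp_mmhg`,
#' `cvp_mmhg`), `<prefix>_events.csv` (columns `time_s`, `avd_ms`), an
#' optional `<prefix>_truth.csv` sidecar holding the ground-truth
#' respiratory traces, and `<prefix>_meta.txt` with sample rate and, when
#' available, the generator parameters. Numbers are written with 17
#' significant digits so event times and settings survive a round trip
#' bit-exactly.
#'
#' @param record A `haemo_record`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param truth Also write the ground-truth sidecar when the record has one?
#' @return Invisibly, the named character vector of paths written.
#' @export
write_record <- function(record, dir, prefix = "record", truth = FALSE) {
  stopifnot(inherits(record, "haemo_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wf_path <- file.path(dir, paste0(prefix, "_waveform.csv"))
  ev_path <- file.path(dir, paste0(prefix, "_events.csv"))
  wf <- data.table::data.table(time_s = fmt_num(record$time),
                               abp_mmhg = fmt_num(record$abp),
                               cvp_mmhg = fmt_num(record$cvp))
  data.table::fwrite(wf, wf_path, quote = FALSE)
  ev <- data.table::data.table(time_s = fmt_num(record$events$time_s),
                               avd_ms = fmt_num(record$events$avd_ms))
  data.table::fwrite(ev, ev_path, quote = FALSE)
  paths <- c(waveform = wf_path, events = ev_path)
  if (truth && !is.null(record$truth)) {
    tr_path <- file.path(dir, paste0(prefix, "_truth.csv"))
    tr <- data.table::data.table(
      time_s = fmt_num(record$time),
      resp_abp_mmhg = fmt_num(record$truth$resp_trace_abp),
      resp_cvp_mmhg = fmt_num(record$truth$resp_trace_cvp))
    data.table::fwrite(tr, tr_path, quote = FALSE)
    paths <- c(paths, truth = tr_path)
  }
  meta_path <- file.path(dir, paste0(prefix, "_meta.txt"))
  meta <- c(sprintf("sample_rate_hz: %.17g", record$sample_rate_hz),
            sprintf("n_samples: %d", length(record$time)),
            sprintf("n_events: %d", nrow(record$events)))
  if (!is.null(record$params)) {
    p <- record$params
    meta <- c(meta,
              sprintf("seed: %d", p$seed),
              sprintf("heart_rate_bpm: %g", p$heart_rate_bpm),
              sprintf("ref_avd_ms: %g", p$ref_avd_ms),
              sprintf("tested_avds_ms: %s", paste(p$tested_avds_ms, collapse = " ")),
              sprintf("replicates_per_avd: %d", p$replicates_per_avd),
              sprintf("true_optimum_ms: %g", p$true_optimum_ms))
  }
  writeLines(meta, meta_path)
  invisible(c(paths, meta = meta_path))
}

#' Read a haemodynamic record from waveform + annotation CSV files
#'
#' Validates that the time grid is uniform (maximum jitter below half a
#' sample period), that the required columns are present, and that all
#' annotated events fall inside the recording span.
#'
#' @param waveform_path CSV with columns `time_s`, `abp_mmhg`, `cvp_mmhg`.
#' @param annotation_path CSV with columns `time_s`, `avd_ms`.
#' @return A `haemo_record` (without ground truth).
#' @export
read_record <- function(waveform_path, annotation_path) {
  if (!file.exists(waveform_path)) stop("waveform file not found: ", waveform_path)
  if (!file.exists(annotation_path)) stop("annotation file not found: ", annotation_path)
  wf <- data.table::fread(waveform_path, colClasses = "numeric")
  need <- c("time_s", "abp_mmhg", "cvp_mmhg")
  miss <- setdiff(need, names(wf))
  if (length(miss)) stop("waveform file missing column(s): ", paste(miss, collapse = ", "))
  time <- wf$time_s
  n <- length(time)
  if (n < 2L) stop("waveform too short")
  dt <- median(diff(time))
  if (dt <= 0) stop("non-increasing time grid")
  expected <- time[1] + (seq_len(n) - 1) * dt
  jitter <- abs(time - expected)
  bad <- which(jitter >= dt / 2)
  if (length(bad)) {
    stop(sprintf("non-uniform time grid: first offending sample index %d (t = %.6f s, expected %.6f s)",
                 bad[1], time[bad[1]], expected[bad[1]]))
  }
  ev <- data.table::fread(annotation_path, colClasses = "numeric")
  miss <- setdiff(c("time_s", "avd_ms"), names(ev))
  if (length(miss)) stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  ev <- as.data.frame(ev)[order(ev$time_s), , drop = FALSE]
  if (any(duplicated(ev$time_s))) stop("duplicate event times in annotations")
  span <- range(time)
  out <- which(ev$time_s < span[1] | ev$time_s > span[2])
  if (length(out)) {
    stop(sprintf("event outside recording span: t = %g s (index %d)",
                 ev$time_s[out[1]], out[1]))
  }
  new_haemo_record(time = time, abp = wf$abp_mmhg, cvp = wf$cvp_mmhg,
                   sample_rate_hz = 1 / dt,
                   events = data.frame(time_s = ev$time_s, avd_ms = ev$avd_ms))
}
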
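#' Subject-level simulation parameters
#'
#' Collects the physiological and protocol parameters that define one
#' synthetic paced subject. Defaults reproduce the study conditions the
#' analysis is designed for: atrial pacing at 90 bpm, tested AV delays
#' 40--280 ms in 40 ms steps against a 120 ms reference with 8 replicate
#' transitions per setting, a quadratic pressure response with a
#' best-to-worst span of 11.4 mmHg (systolic ABP) mirrored by an inverted
#' 4.15 mmHg span in peak CVP, respiration at 0.25 Hz with peak-to-trough
#' amplitudes 2.5 mmHg (ABP) and 2.3 mmHg (CVP) plus occasional irregular
#' inspiratory spikes, and Gaussian beat-to-beat amplitude noise.
#'
#' Curvatures may be given directly (`abp_curvature`, `cvp_curvature`,
#' mmHg/ms^2; ABP negative, CVP positive) or implied by best-to-worst spans
#' over the tested grid (`abp_span_mmHg`, `cvp_span_mmHg`), in which case the
#' curvature is `span / max((avd - optimum)^2)` over the tested AVDs, so the
#' realised span is invariant to where the optimum sits.
#'
#' @param heart_rate_bpm Paced heart rate, beats/min.
#' @param sample_rate_hz Waveform sampling rate, Hz.
#' @param ref_avd_ms Reference AV delay, ms.
#' @param tested_avds_ms Sorted unique tested AV delays, ms, all in
#'   \[40, 280\].
#' @param replicates_per_avd Number of reference-to-tested transitions per
#'   tested AVD (each is paired with a return transition).
#' @param true_optimum_ms True vertex of the pressure response, ms.
#' @param abp_span_mmHg,cvp_span_mmHg Best-to-worst response spans over the
#'   tested grid, mmHg (ignored when the corresponding curvature is given).
#' @param abp_curvature,cvp_curvature Optional explicit curvatures,
#'   mmHg/ms^2 (ABP < 0, CVP > 0).
#' @param abp_systolic_base_mmHg Systolic ABP at the optimum, mmHg.
#' @param abp_diastolic_mmHg Diastolic ABP level, mmHg (fixed).
#' @param cvp_peak_base_mmHg Peak CVP at the optimum, mmHg.
#' @param cvp_floor_mmHg CVP baseline between beats, mmHg.
#' @param resp_freq_hz Respiratory frequency, Hz; must be slower than the
#'   cardiac rate.
#' @param resp_amp_cvp_mmHg,resp_amp_abp_mmHg Peak-to-trough respiratory
#'   amplitudes, mmHg.
#' @param resp_irregularity Dimensionless >= 0; scales the rate/size of
#'   irregular inspiratory amplitude spikes (0 = perfectly regular
#'   breathing; 1 = about 2 spikes/min at x2.5 amplitude).
#' @param beat_noise_sd_mmHg SD of Gaussian beat-to-beat amplitude noise,
#'   mmHg.
#' @param phase_beats Beats spent in each pacing state between transitions.
#' @param settle_beats Length (beats) of an optional exponential settling
#'   transient after each transition; 0 = instantaneous (default).
#' @param seed Integer seed making the subject reproducible.
#' @return An object of class `subject_params` (a validated list).
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
subject_params <- function(heart_rate_bpm = 90,
                           sample_rate_hz = 250,
                           ref_avd_ms = 120,
                           tested_avds_ms = seq(40, 280, by = 40),
                           replicates_per_avd = 8,
                           true_optimum_ms = 160,
                           abp_span_mmHg = 11.4,
                           cvp_span_mmHg = 4.15,
                           abp_curvature = NULL,
                           cvp_curvature = NULL,
                           abp_systolic_base_mmHg = 120,
                           abp_diastolic_mmHg = 70,
                           cvp_peak_base_mmHg = 12,
                           cvp_floor_mmHg = 2,
                           resp_freq_hz = 0.25,
                           resp_amp_cvp_mmHg = 2.3,
                           resp_amp_abp_mmHg = 2.5,
                           resp_irregularity = 1,
                           beat_noise_sd_mmHg = 2.5,
                           phase_beats = 10,
                           settle_beats = 0,
                           seed = 1L) {
  p <- list(
    heart_rate_bpm = heart_rate_bpm, sample_rate_hz = sample_rate_hz,
    ref_avd_ms = ref_avd_ms, tested_avds_ms = tested_avds_ms,
    replicates_per_avd = as.integer(replicates_per_avd),
    true_optimum_ms = true_optimum_ms,
    abp_systolic_base_mmHg = abp_systolic_base_mmHg,
    abp_diastolic_mmHg = abp_diastolic_mmHg,
    cvp_peak_base_mmHg = cvp_peak_base_mmHg,
    cvp_floor_mmHg = cvp_floor_mmHg,
    resp_freq_hz = resp_freq_hz,
    resp_amp_cvp_mmHg = resp_amp_cvp_mmHg,
    resp_amp_abp_mmHg = resp_amp_abp_mmHg,
    resp_irregularity = resp_irregularity,
    beat_noise_sd_mmHg = beat_noise_sd_mmHg,
    phase_beats = as.integer(phase_beats),
    settle_beats = as.integer(settle_beats),
    seed = as.integer(seed)
  )
  # curvature from span over the tested grid unless given explicitly
  dev2 <- max((tested_avds_ms - true_optimum_ms)^2)
  if (dev2 == 0) dev2 <- 1  # single point at the optimum: span is moot
  p$abp_curvature <- if (is.null(abp_curvature)) -abp_span_mmHg / dev2 else abp_curvature
  p$cvp_curvature <- if (is.null(cvp_curvature)) cvp_span_mmHg / dev2 else cvp_curvature
  class(p) <- "subject_params"
  validate_subject_params(p)
  p
}

validate_subject_params <- function(p) {
  av <- p$tested_avds_ms
  bad <- av[av < 40 | av > 280]
  if (length(bad)) {
    stop("tested AVD outside [40, 280] ms: ", paste(bad, collapse = ", "))
  }
  if (is.unsorted(av, strictly = TRUE)) {
    stop("tested_avds_ms must be strictly increasing; got: ",
         paste(av, collapse = ", "))
  }
  if (p$replicates_per_avd < 1L) stop("replicates_per_avd must be >= 1")
  if (!(p$abp_curvature < 0)) stop("abp_curvature must be negative (concave ABP response)")
  if (!(p$cvp_curvature > 0)) stop("cvp_curvature must be positive (convex CVP response)")
  if (!(p$resp_freq_hz < p$heart_rate_bpm / 60)) {
    stop("resp_freq_hz must be below the cardiac frequency (",
         p$heart_rate_bpm / 60, " Hz)")
  }
  if (p$resp_irregularity < 0) stop("resp_irregularity must be >= 0")
  if (p$beat_noise_sd_mmHg < 0) stop("beat_noise_sd_mmHg must be >= 0")
  if (p$phase_beats < 2L) stop("phase_beats must be >= 2")
  invisible(p)
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Synthetic paced-subject parameters\n")
  cat(sprintf("  pacing: %g bpm, fs = %g Hz, reference AVD %g ms\n",
              x$heart_rate_bpm, x$sample_rate_hz, x$ref_avd_ms))
  cat(sprintf("  tested AVDs (ms): %s  x%d replicates\n",
              paste(x$tested_avds_ms, collapse = " "), x$replicates_per_avd))
  cat(sprintf("  true optimum %g ms; curvature ABP %.3g, CVP %.3g mmHg/ms^2\n",
              x$true_optimum_ms, x$abp_curvature, x$cvp_curvature))
  cat(sprintf("  respiration %g Hz, amp CVP %g / ABP %g mmHg, irregularity %g\n",
              x$resp_freq_hz, x$resp_amp_cvp_mmHg, x$resp_amp_abp_mmHg,
              x$resp_irregularity))
  cat(sprintf("  beat noise SD %g mmHg, seed %d\n",
              x$beat_noise_sd_mmHg, x$seed))
  invisible(x)
}

#' Analysis configuration
#'
#' Settings for the subject-level optimisation pipeline [avd_optimise()].
#'
#' @param window_mode `"fixed_beats"` uses `window_beats` beats either side
#'   of each transition; `"resp_cycle"` sets the window per subject to the
#'   number of beats spanning one respiratory cycle
#'   (see [estimate_resp_cycle_beats()]), falling back to `window_beats`
#'   when respiration cannot be detected.
#' @param window_beats Fixed window length in beats (default 6).
#' @param correction Respiratory correction applied to the continuous trace
#'   before beat extraction: `"none"`, `"als"` or `"dwt"`.
#' @param cvp_feature Per-beat CVP feature entering the analysis: `"peak"`
#'   (the higher of the two per-cycle peaks) or `"mean"`.
#' @param qc_seopt_threshold_ms Quality-control gate on the vertex standard
#'   error, ms (default 50; a fit fails QC when SE_opt exceeds it).
#' @param weighting Parabola fit weighting: `"inverse_variance"` (1/SEM^2)
#'   or `"unweighted"`.
#' @param directions `"both"` uses reference-to-tested and tested-to-reference
#'   transitions (sign-corrected); `"ref_to_test"` restricts to the former.
#' @param bootstrap_reps Parametric-bootstrap replicates for SE_opt
#'   (0 disables the bootstrap and uses the delta method alone).
#' @param heart_rate_bpm Pacing rate assumed for beat detection when the
#'   record does not carry beat times.
#' @param seed Seed for all stochastic steps (bootstrap).
#' @param als Parameter list for [estimate_resp_als()], see [als_config()].
#' @param dwt Parameter list for [estimate_resp_dwt()]: fields `wavelet`
#'   and `band_factor`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(window_mode = c("fixed_beats", "resp_cycle"),
                            window_beats = 6,
                            correction = c("none", "als", "dwt"),
                            cvp_feature = c("peak", "mean"),
                            qc_seopt_threshold_ms = 50,
                            weighting = c("inverse_variance", "unweighted"),
                            directions = c("both", "ref_to_test"),
                            bootstrap_reps = 0,
                            heart_rate_bpm = 90,
                            seed = 1L,
                            als = als_config(),
                            dwt = list(wavelet = "la8", band_factor = 1.75)) {
  cfg <- list(
    window_mode = match.arg(window_mode),
    window_beats = as.integer(window_beats),
    correction = match.arg(correction),
    cvp_feature = match.arg(cvp_feature),
    qc_seopt_threshold_ms = qc_seopt_threshold_ms,
    weighting = match.arg(weighting),
    directions = match.arg(directions),
    bootstrap_reps = as.integer(bootstrap_reps),
    heart_rate_bpm = heart_rate_bpm,
    seed = as.integer(seed),
    als = als, dwt = dwt
  )
  if (cfg$window_beats < 1L) stop("window_beats must be >= 1")
  if (cfg$qc_seopt_threshold_ms <= 0) stop("qc_seopt_threshold_ms must be > 0")
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("AVD analysis configuration\n")
  cat(sprintf("  window: %s (%d beats), correction: %s, CVP feature: %s\n",
              x$window_mode, x$window_beats, x$correction, x$cvp_feature))
  cat(sprintf("  fit weighting: %s, directions: %s\n", x$weighting, x$directions))
  cat(sprintf("  QC SE_opt threshold: %g ms, bootstrap reps: %d, seed: %d\n",
              x$qc_seopt_threshold_ms, x$bootstrap_reps, x$seed))
  invisible(x)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
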
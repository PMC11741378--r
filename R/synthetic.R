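# Synthetic paced-haemodynamics generator.
#
# A subject alternates between the reference AV delay and each tested AVD
# (reference, test, reference, test, ...), spending `phase_beats` beats in
# each state. Per-beat peak pressures are base + quadratic AVD effect +
# respiratory oscillation + Gaussian beat noise; the waveform morphology is
# fixed (single raised-sine pulse for ABP, two-peaked cycle for CVP) and only
# the per-beat amplitude carries the AVD effect.

# Unit-cycle morphologies, u in [0, 1). Peak value is normalised per rendered
# beat so the sampled maximum equals the target amplitude exactly.
morph_abp <- function(u) ifelse(u < 0.6, sin(pi * u / 0.6)^2, 0)

morph_cvp <- function(u) {
  # a-wave (dominant) and v-wave: two peaks per cardiac cycle
  exp(-0.5 * ((u - 0.18) / 0.06)^2) + 0.72 * exp(-0.5 * ((u - 0.55) / 0.09)^2)
}

quad_effect <- function(avd_ms, optimum_ms, curvature) {
  curvature * (avd_ms - optimum_ms)^2
}

# Multiplicative respiratory amplitude envelope: occasional Gaussian-shaped
# spikes emulating sudden irregular inspirations.
resp_envelope <- function(time_s, resp_freq_hz, irregularity) {
  env <- rep(1, length(time_s))
  if (irregularity <= 0) return(env)
  dur_min <- (time_s[length(time_s)] - time_s[1]) / 60
  n_spk <- rpois(1, lambda = 2 * irregularity * dur_min)  # ~2 spikes/min at irregularity 1
  if (n_spk == 0) return(env)
  t_spk <- runif(n_spk, min = time_s[1], max = time_s[length(time_s)])
  width <- 0.35 / resp_freq_hz  # roughly one breath wide
  for (tk in t_spk) env <- env + 1.5 * exp(-0.5 * ((time_s - tk) / width)^2)
  env
}

#' Generate one synthetic paced subject
#'
#' Simulates a two-channel (ABP, CVP) pressure recording during a full AVD
#' optimisation protocol, together with the pacing-event annotations and the
#' ground truth needed to verify every downstream analysis stage.
#'
#' The protocol starts in the reference state and, for each tested AVD in
#' grid order, performs `replicates_per_avd` reference-to-tested transitions
#' each followed by a return to reference. Every pacing phase lasts
#' `phase_beats` beats; the annotated event time falls inside the last beat
#' of the outgoing phase, so that beat straddles two settings and belongs to
#' neither analysis window. Identical seeds give bit-identical output.
#'
#' @param params A [subject_params()] object.
#' @return A `haemo_record`: list with `time` (s), `abp`, `cvp` (mmHg),
#'   `sample_rate_hz`, `events` (data.frame `time_s`, `avd_ms`),
#'   `beat_times` (s, beat onsets), and `truth` (list with true optima,
#'   respiratory traces per channel, per-beat target peaks and realised
#'   sampled peaks).
#' @examples
#' rec <- generate_subject(subject_params(sample_rate_hz = 100,
#'                                        replicates_per_avd = 2, seed = 7))
#' rec
#' @export
generate_subject <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  validate_subject_params(params)
  with_local_seed(params$seed, generate_subject_impl(params))
}

generate_subject_impl <- function(p) {
  fs <- p$sample_rate_hz
  T_beat <- 60 / p$heart_rate_bpm
  ref <- p$ref_avd_ms
  # phase sequence: ref, then (test, ref) x replicates for each tested AVD
  phase_avd <- c(ref, unlist(lapply(p$tested_avds_ms, function(a) {
    rep(c(a, ref), p$replicates_per_avd)
  })))
  n_phase <- length(phase_avd)
  n_beats <- n_phase * p$phase_beats
  beat_phase <- rep(seq_len(n_phase), each = p$phase_beats)
  beat_avd <- phase_avd[beat_phase]
  beat_onset <- (seq_len(n_beats) - 1) * T_beat

  # per-beat target peak pressures (before respiration)
  eff_abp <- quad_effect(beat_avd, p$true_optimum_ms, p$abp_curvature)
  eff_cvp <- quad_effect(beat_avd, p$true_optimum_ms, p$cvp_curvature)
  noise_abp <- rnorm(n_beats, 0, p$beat_noise_sd_mmHg)
  noise_cvp <- rnorm(n_beats, 0, p$beat_noise_sd_mmHg)
  peak_abp <- p$abp_systolic_base_mmHg + eff_abp + noise_abp
  peak_cvp <- p$cvp_peak_base_mmHg + eff_cvp + noise_cvp
  if (p$settle_beats > 0L) {
    within <- (seq_len(n_beats) - 1) %% p$phase_beats  # beat index within phase
    carry <- exp(-(within + 1))
    carry[within >= p$settle_beats] <- 0
    prev_phase <- pmax(beat_phase - 1L, 1L)
    prev_avd <- phase_avd[prev_phase]
    peak_abp <- peak_abp + carry *
      (quad_effect(prev_avd, p$true_optimum_ms, p$abp_curvature) - eff_abp)
    peak_cvp <- peak_cvp + carry *
      (quad_effect(prev_avd, p$true_optimum_ms, p$cvp_curvature) - eff_cvp)
  }
  amp_abp <- peak_abp - p$abp_diastolic_mmHg
  amp_cvp <- peak_cvp - p$cvp_floor_mmHg
  if (any(amp_abp <= 0) || any(amp_cvp <= 0)) {
    stop("beat amplitude became non-positive; reduce noise or effect sizes")
  }

  n_samp <- floor(n_beats * T_beat * fs)
  time <- (seq_len(n_samp) - 1) / fs
  abp <- numeric(n_samp)
  cvp <- numeric(n_samp)
  # first sample index of each beat (1-based), plus end sentinel
  i_start <- pmin(ceiling(beat_onset * fs - 1e-9) + 1L, n_samp + 1L)
  i_end <- c(i_start[-1L] - 1L, n_samp)
  for (k in seq_len(n_beats)) {
    idx <- seq.int(i_start[k], i_end[k])
    if (length(idx) < 4L) next
    u <- (time[idx] - beat_onset[k]) / T_beat
    ma <- morph_abp(u); mc <- morph_cvp(u)
    abp[idx] <- p$abp_diastolic_mmHg + amp_abp[k] * ma / max(ma)
    cvp[idx] <- p$cvp_floor_mmHg + amp_cvp[k] * mc / max(mc)
  }

  phase <- runif(1, 0, 2 * pi)
  env <- resp_envelope(time, p$resp_freq_hz, p$resp_irregularity)
  carrier <- sin(2 * pi * p$resp_freq_hz * time + phase)
  resp_abp <- (p$resp_amp_abp_mmHg / 2) * carrier * env
  resp_cvp <- (p$resp_amp_cvp_mmHg / 2) * carrier * env
  abp <- abp + resp_abp
  cvp <- cvp + resp_cvp

  # realised sampled peaks per beat (include respiration)
  pk_i_abp <- integer(n_beats); pk_i_cvp <- integer(n_beats)
  for (k in seq_len(n_beats)) {
    idx <- seq.int(i_start[k], i_end[k])
    if (length(idx) < 4L) { pk_i_abp[k] <- NA_integer_; pk_i_cvp[k] <- NA_integer_; next }
    pk_i_abp[k] <- idx[which.max(abp[idx])]
    pk_i_cvp[k] <- idx[which.max(cvp[idx])]
  }
  ok <- !is.na(pk_i_abp)
  per_beat_peaks <- rbind(
    data.frame(time_s = time[pk_i_abp[ok]], channel = "abp",
               value = abp[pk_i_abp[ok]]),
    data.frame(time_s = time[pk_i_cvp[ok]], channel = "cvp",
               value = cvp[pk_i_cvp[ok]])
  )

  events <- data.frame(
    time_s = c(0, ((seq_len(n_phase - 1)) * p$phase_beats - 0.35) * T_beat),
    avd_ms = phase_avd
  )
  truth <- list(
    true_optimum_abp_ms = p$true_optimum_ms,
    true_optimum_cvp_ms = p$true_optimum_ms,
    resp_trace_abp = resp_abp,
    resp_trace_cvp = resp_cvp,
    per_beat_peaks = per_beat_peaks,
    beats = data.frame(time_s = beat_onset, avd_ms = beat_avd,
                       peak_abp_target = peak_abp, peak_cvp_target = peak_cvp)
  )
  new_haemo_record(time = time, abp = abp, cvp = cvp, sample_rate_hz = fs,
                   events = events, beat_times = beat_onset,
                   truth = truth, params = p)
}

new_haemo_record <- function(time, abp, cvp, sample_rate_hz, events,
                             beat_times = NULL, truth = NULL, params = NULL) {
  stopifnot(length(time) == length(abp), length(abp) == length(cvp))
  if (is.unsorted(events$time_s, strictly = TRUE)) {
    stop("pacing events must be strictly increasing in time")
  }
  rec <- list(time = time, abp = abp, cvp = cvp,
              sample_rate_hz = sample_rate_hz, events = events,
              beat_times = beat_times, truth = truth, params = params)
  class(rec) <- "haemo_record"
  rec
}

#' @export
print.haemo_record <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("Haemodynamic record: %.1f s at %g Hz (%d samples/channel)\n",
              dur, x$sample_rate_hz, length(x$time)))
  cat(sprintf("  channels: ABP [%.1f, %.1f] mmHg; CVP [%.1f, %.1f] mmHg\n",
              min(x$abp), max(x$abp), min(x$cvp), max(x$cvp)))
  cat(sprintf("  pacing events: %d (settings %s ms)\n", nrow(x$events),
              paste(sort(unique(x$events$avd_ms)), collapse = " ")))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth present (true optimum %g ms)\n",
                x$truth$true_optimum_abp_ms))
  }
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Draws per-subject true optima (and optionally noise levels) from stated
#' spreads around a base parameter set, then simulates each subject with its
#' own sub-seed. Deterministic under `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base_params [subject_params()] shared by the cohort.
#' @param heterogeneity List of spreads: `optimum_range_ms` (length-2 range
#'   for the uniform draw of each subject's true optimum; `NULL` or a
#'   zero-width range means all subjects share the base truth) and
#'   `beat_noise_range_mmHg` (optional uniform range for the beat noise SD).
#' @param seed Integer master seed.
#' @return List of `haemo_record` objects.
#' @export
generate_cohort <- function(n_subjects, base_params = subject_params(),
                            heterogeneity = list(optimum_range_ms = c(100, 320)),
                            seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  stopifnot(inherits(base_params, "subject_params"))
  with_local_seed(seed, {
    opt_rng <- heterogeneity$optimum_range_ms
    opts <- if (is.null(opt_rng) || diff(range(opt_rng)) == 0) {
      rep(base_params$true_optimum_ms, n_subjects)
    } else runif(n_subjects, opt_rng[1], opt_rng[2])
    noise_rng <- heterogeneity$beat_noise_range_mmHg
    noises <- if (is.null(noise_rng)) rep(base_params$beat_noise_sd_mmHg, n_subjects)
              else runif(n_subjects, noise_rng[1], noise_rng[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      p <- base_params
      p$true_optimum_ms <- opts[i]
      p$beat_noise_sd_mmHg <- noises[i]
      p$seed <- seeds[i]
      # curvatures follow the configured span at the subject's own optimum
      dev2 <- max((p$tested_avds_ms - p$true_optimum_ms)^2)
      span_a <- abs(base_params$abp_curvature) *
        max((base_params$tested_avds_ms - base_params$true_optimum_ms)^2)
      span_c <- base_params$cvp_curvature *
        max((base_params$tested_avds_ms - base_params$true_optimum_ms)^2)
      p$abp_curvature <- -span_a / dev2
      p$cvp_curvature <- span_c / dev2
      generate_subject(p)
    })
  })
}

#' Simulate a per-AVD response table directly
#'
#' Response-level shortcut of the full waveform generator: replicate
#' transition deltas are drawn as Normal(quadratic effect, `rep_sd_mmHg`)
#' and aggregated to a per-AVD mean/SEM table. Used for Monte-Carlo
#' calibration studies of the vertex estimator where rendering waveforms
#' would add nothing.
#'
#' @param channel `"abp"` (concave response) or `"cvp"` (convex).
#' @param true_optimum_ms True vertex, ms.
#' @param span_mmHg Best-to-worst response span over `avds`, mmHg.
#' @param ref_avd_ms Reference AVD, ms.
#' @param avds Tested AVD grid, ms.
#' @param replicates Replicate deltas per AVD.
#' @param rep_sd_mmHg SD of a single replicate delta, mmHg (per-AVD SEM is
#'   `rep_sd_mmHg / sqrt(replicates)`).
#' @param seed Optional seed.
#' @return An `avd_response` object (see [aggregate_response()]) with the
#'   true deltas attached as attribute `"truth"`.
#' @export
simulate_response <- function(channel = c("abp", "cvp"),
                              true_optimum_ms = 160, span_mmHg = 11.4,
                              ref_avd_ms = 120, avds = seq(40, 280, by = 40),
                              replicates = 8, rep_sd_mmHg = 2.83,
                              seed = NULL) {
  channel <- match.arg(channel)
  sgn <- if (channel == "abp") -1 else 1
  curv <- sgn * span_mmHg / max((avds - true_optimum_ms)^2)
  eff <- function(x) quad_effect(x, true_optimum_ms, curv)
  delta_true <- eff(avds) - eff(ref_avd_ms)
  draw <- function() {
    tab <- do.call(rbind, lapply(seq_along(avds), function(i) {
      d <- rnorm(replicates, delta_true[i], rep_sd_mmHg)
      data.frame(avd_ms = avds[i], mean_delta_mmHg = mean(d),
                 sem_mmHg = sd(d) / sqrt(replicates),
                 n_replicates = replicates)
    }))
    resp <- new_avd_response(channel = channel, feature = "peak", table = tab)
    attr(resp, "truth") <- list(true_optimum_ms = true_optimum_ms,
                                delta_true = delta_true)
    resp
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
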
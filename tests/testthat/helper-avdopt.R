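# Shared fixtures, all generated in code.

# Small, fast subject: 100 Hz, short phases.
quick_params <- function(...) {
  do.call(subject_params,
          utils::modifyList(list(sample_rate_hz = 100, replicates_per_avd = 2,
                                 seed = 1L),
                            list(...)))
}

# Respiration and noise switched off: per-beat peaks are exactly
# base + quadratic effect.
noiseless_params <- function(...) {
  quick_params(resp_amp_cvp_mmHg = 0, resp_amp_abp_mmHg = 0,
               resp_irregularity = 0, beat_noise_sd_mmHg = 0, ...)
}

# Respiration isolated: cardiac + respiratory component only (near-zero
# curvature so the protocol does not modulate the beat amplitudes).
resp_only_params <- function(...) {
  quick_params(abp_curvature = -1e-12, cvp_curvature = 1e-12,
               beat_noise_sd_mmHg = 0, ...)
}

# Hand-built transition-delta table for unit tests of downstream stages.
make_deltas <- function(avd, delta, channel = "abp", feature = "peak",
                        direction = "ref_to_test") {
  n <- length(delta)
  df <- data.frame(channel = channel, feature = feature,
                   avd_tested_ms = rep_len(avd, n),
                   replicate_index = NA_integer_,
                   direction = rep_len(direction, n),
                   event_time_s = seq_len(n),
                   pre_mean_mmHg = 0, post_mean_mmHg = delta,
                   delta_mmHg = delta, n_pre = 6L, n_post = 6L)
  df$replicate_index <- stats::ave(seq_len(n), df$avd_tested_ms, df$direction,
                                   FUN = seq_along)
  structure(df, class = c("transition_deltas", "data.frame"))
}

# Minimal parabola-fit object with a prescribed coefficient covariance,
# for closed-form SE checks.
fake_fit <- function(a, b, cov_ab, channel = "abp") {
  cov3 <- matrix(0, 3, 3)
  cov3[1:2, 1:2] <- cov_ab
  structure(list(a = a, b = b, c = 0, cov_abc = cov3,
                 x_opt_ms = -b / (2 * a), se_opt_ms = NA_real_,
                 orientation_ok = (channel == "abp") == (a < 0),
                 degenerate = abs(a) < 1e-12, extrapolated = FALSE,
                 channel = channel, weighting = "unweighted",
                 data = data.frame(), fitted = numeric(0), rss = 0),
            class = "avd_parabola")
}
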
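# Synthetic per-beat feature streams with known step effects, built by hand.
step_features <- function(n_cycles = 4, phase_beats = 8, ref = 120, test = 200,
                          effect = 3, base = 100, ibi = 0.5) {
  avd_seq <- c(ref, rep(c(test, ref), n_cycles))
  beat_avd <- rep(avd_seq, each = phase_beats)
  n <- length(beat_avd)
  onset <- (seq_len(n) - 1) * ibi
  val <- base + effect * (beat_avd == test)
  feats <- structure(
    data.frame(beat_time_s = onset, channel = "abp", peak_mmHg = val,
               mean_mmHg = val, n_peaks = 1L, avd_ms = NA_real_),
    class = c("beat_features", "data.frame"))
  events <- data.frame(
    time_s = c(0, (seq_len(length(avd_seq) - 1) * phase_beats - 0.35) * ibi),
    avd_ms = avd_seq)
  list(features = feats, events = events)
}

test_that("a step change gives the step as delta in both directions", {
  s <- step_features(effect = 3)
  d <- transition_deltas(s$features, s$events, window_beats = 6, ref_avd_ms = 120)
  expect_true(all(abs(d$delta_mmHg - 3) < 1e-12))
  expect_setequal(unique(d$direction), c("ref_to_test", "test_to_ref"))
  expect_true(all(d$n_pre == 6 & d$n_post == 6))
  # restricting to ref->test halves the replicates
  d1 <- transition_deltas(s$features, s$events, window_beats = 6,
                          ref_avd_ms = 120, directions = "ref_to_test")
  expect_equal(nrow(d1), nrow(d) / 2)
  expect_true(all(d1$direction == "ref_to_test"))
})

test_that("sign convention: flipping directions while negating the effect is invariant", {
  s <- step_features(effect = 3)
  d1 <- transition_deltas(s$features, s$events, window_beats = 6, ref_avd_ms = 120)
  # negate the signal and call the former tested setting the reference: every
  # transition's direction label flips, and the deltas must be unchanged
  s2 <- s
  s2$features$peak_mmHg <- -s2$features$peak_mmHg
  s2$features$mean_mmHg <- -s2$features$mean_mmHg
  d2 <- transition_deltas(s2$features, s$events, window_beats = 6,
                          ref_avd_ms = 200)
  expect_setequal(unique(d2$direction), c("ref_to_test", "test_to_ref"))
  expect_equal(sort(d2$delta_mmHg), sort(d1$delta_mmHg))
})

test_that("transitions without enough complete beats on one side are dropped", {
  s <- step_features(phase_beats = 5)  # 5-beat phases cannot host 6-beat windows
  expect_error(
    suppressMessages(transition_deltas(s$features, s$events, window_beats = 6,
                                       ref_avd_ms = 120)),
    "no usable transitions")
  s8 <- step_features(phase_beats = 8)
  ev <- s8$events
  ev$time_s[nrow(ev)] <- ev$time_s[nrow(ev) - 1] + 2 * 0.5  # too-close final event
  expect_message(
    d <- transition_deltas(s8$features, ev, window_beats = 6, ref_avd_ms = 120),
    "dropped")
  expect_lt(nrow(d), nrow(ev) - 1)
})

test_that("aggregation computes mean and SEM per AVD", {
  d <- make_deltas(avd = 160, delta = rep(2, 8))
  r <- aggregate_response(d)
  expect_equal(r$table$mean_delta_mmHg, 2)
  expect_equal(r$table$sem_mmHg, 0)
  expect_equal(r$table$n_replicates, 8L)
  d2 <- make_deltas(avd = 160, delta = c(1, 3))
  r2 <- aggregate_response(d2)
  expect_equal(r2$table$mean_delta_mmHg, 2)
  expect_equal(r2$table$sem_mmHg, 1)  # sd = sqrt(2), / sqrt(2)
  # AVDs with fewer than 2 replicates are excluded with a warning
  d3 <- make_deltas(avd = c(160, 160, 200), delta = c(1, 3, 5))
  expect_warning(r3 <- aggregate_response(d3), "200")
  expect_identical(r3$table$avd_ms, 160)
})

test_that("SEM of replicate deltas matches sampling theory on synthetic subjects", {
  # beat noise only (no respiration): delta = mean(6 post) - mean(6 pre),
  # so sd(delta) = sigma * sqrt(2/6); SEM over 16 sign-corrected replicates
  sigma <- 2
  sems <- unlist(lapply(1:6, function(s) {
    rec <- generate_subject(quick_params(replicates_per_avd = 8,
                                         resp_amp_cvp_mmHg = 0, resp_amp_abp_mmHg = 0,
                                         resp_irregularity = 0,
                                         beat_noise_sd_mmHg = sigma,
                                         tested_avds_ms = c(80, 160, 240),
                                         seed = 100 + s))
    r <- avd_optimise(rec, analysis_config(correction = "none"))
    r$abp$response$table$sem_mmHg
  }))
  theory <- sigma * sqrt(2 / 6) / sqrt(16)
  expect_lt(abs(mean(sems) - theory) / theory, 0.35)
})

test_that("reference-vs-reference tested point sits at zero within noise", {
  rec <- generate_subject(quick_params(replicates_per_avd = 8, seed = 31))
  r <- avd_optimise(rec, analysis_config(correction = "dwt"))
  tab <- r$abp$response$table
  row <- tab[tab$avd_ms == 120, ]
  expect_equal(nrow(row), 1L)
  expect_lt(abs(row$mean_delta_mmHg), 3 * row$sem_mmHg)
})

test_that("respiratory-cycle windows beat fixed windows when the cycle is not 6 beats", {
  errs <- sapply(1:2, function(s) {
    p <- quick_params(replicates_per_avd = 4, resp_freq_hz = 0.3,
                      resp_irregularity = 0, beat_noise_sd_mmHg = 0, seed = s)
    rec <- generate_subject(p)
    vapply(c("fixed_beats", "resp_cycle"), function(wm) {
      r <- avd_optimise(rec, analysis_config(window_mode = wm, correction = "none"))
      d <- r$cvp$deltas
      tru <- p$cvp_curvature *
        ((d$avd_tested_ms - p$true_optimum_ms)^2 - (120 - p$true_optimum_ms)^2)
      mean(abs(d$delta_mmHg - tru))
    }, numeric(1))
  })
  expect_true(all(errs["resp_cycle", ] < errs["fixed_beats", ]))
})
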
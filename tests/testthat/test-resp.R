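fs <- 50
tt <- seq(0, 120, by = 1 / fs)

test_that("ALS baseline of a constant signal is the constant", {
  est <- estimate_resp_als(rep(5, length(tt)), fs)
  expect_lt(max(abs(est$resp_trace - 5)), 1e-6)
})

test_that("ALS tracks a pure respiratory sinusoid", {
  x <- 2.3 * sin(2 * pi * 0.25 * tt)
  est <- estimate_resp_als(x, fs)
  expect_gt(cor(est$resp_trace, x), 0.99)
  # smoother than its input: lower second-difference energy
  d2 <- function(z) sum(diff(z, differences = 2)^2)
  xn <- x + rnorm(length(x), 0, 0.5)
  estn <- estimate_resp_als(xn, fs)
  expect_lt(d2(estn$resp_trace), d2(xn))
})

test_that("ALS refuses signals too short to resolve respiration", {
  expect_error(estimate_resp_als(rnorm(3 * fs), fs), "too short")
})

test_that("ALS and DWT recover the true respiratory trace of a synthetic subject", {
  rec <- generate_subject(resp_only_params(seed = 11))
  f <- rec$sample_rate_hz
  truth <- rec$truth$resp_trace_cvp
  ea <- estimate_resp_als(rec$cvp, f)
  ed <- estimate_resp_dwt(rec$cvp, f)
  expect_gt(cor(ea$resp_trace, truth), 0.9)
  expect_gt(cor(ed$resp_trace, truth), 0.9)
})

test_that("DWT separates a two-tone signal into its respiratory component", {
  x <- 2.3 * sin(2 * pi * 0.25 * tt) + 10 * sin(2 * pi * 1.5 * tt)
  est <- estimate_resp_dwt(x, fs)
  core <- est$resp_trace[500:5500]  # away from the edges
  expect_equal((max(core) - min(core)) / 2, 2.3, tolerance = 0.1)
  expect_equal(est$resp_freq_hz, 0.25, tolerance = 0.3)
  # cardiac-band leakage below 5% of the trace's power
  leak <- band_power(est$resp_trace, fs, 1, fs / 2) /
    band_power(est$resp_trace, fs, 0, fs / 2)
  expect_lt(leak, 0.05)
})

test_that("MODWT is an energy-preserving transform with perfect reconstruction", {
  set.seed(8)
  x <- rnorm(512)
  J <- 5
  dec <- modwt(x, J, wavelet = "la8")
  # Parseval: energy is split exactly across levels
  energy <- sum(vapply(dec$W, function(w) sum(w^2), numeric(1))) + sum(dec$V^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-10)
  # details + smooth reconstruct the signal exactly
  details <- Reduce(`+`, lapply(seq_len(J), function(j) modwt_detail(dec, j)))
  filt <- avdopt:::wave_filter("la8")
  smooth <- dec$V
  for (k in rev(seq_len(J))) {
    smooth <- avdopt:::modwt_inverse_level(numeric(512), smooth, filt, k)
  }
  expect_lt(max(abs(x - (details + smooth))), 1e-10)
  # shift invariance: MODWT of a circularly shifted signal is the shifted MODWT
  xs <- c(x[-(1:7)], x[1:7])
  dec_s <- modwt(xs, J, wavelet = "la8")
  expect_equal(dec_s$W[[3]], c(dec$W[[3]][-(1:7)], dec$W[[3]][1:7]),
               tolerance = 1e-12)
  # scaling filter: unit energy, sums to sqrt(2) before MODWT rescaling
  expect_equal(sum((filt$g * sqrt(2))^2), 1, tolerance = 1e-12)
  expect_equal(sum(filt$g * sqrt(2)), sqrt(2), tolerance = 1e-10)
})

test_that("DWT of a zero signal is a zero trace", {
  est <- estimate_resp_dwt(numeric(1000), fs)
  expect_identical(est$resp_trace, numeric(1000))
})

test_that("DWT removes >= 80% of respiratory-band power despite inspiratory spikes", {
  rec <- generate_subject(quick_params(resp_irregularity = 2, seed = 12))
  est <- estimate_resp_dwt(rec$cvp, rec$sample_rate_hz)
  expect_gte(est$band_power_removed_frac, 0.8)
})

test_that("respiration is rejected as undetected on unsuitable input", {
  expect_error(estimate_resp_freq(rep(1, 100 * fs) , fs), "not detected")
  set.seed(1)
  expect_error(estimate_resp_dwt(rnorm(40 * fs), fs), "not detected")
})

test_that("subtract_resp is level-preserving and removes respiratory power", {
  rec <- generate_subject(quick_params(seed = 13))
  f <- rec$sample_rate_hz
  est <- estimate_resp_dwt(rec$cvp, f)
  out <- subtract_resp(rec$cvp, est)
  expect_equal(mean(out), mean(rec$cvp), tolerance = 1e-9)
  expect_lt(band_power(out, f, 0.1, 0.5), 0.2 * band_power(rec$cvp, f, 0.1, 0.5))
  # identities
  expect_equal(subtract_resp(rec$cvp, rec$cvp), rep(mean(rec$cvp), length(rec$cvp)))
  zero <- est; zero$resp_trace <- numeric(length(rec$cvp))
  expect_identical(subtract_resp(rec$cvp, zero), rec$cvp)
  short <- est; short$resp_trace <- est$resp_trace[1:10]
  expect_error(subtract_resp(rec$cvp, short), "length mismatch")
})

test_that("ALS and DWT agree on a sinusoid plus pulse train", {
  pulses <- 8 * pmax(sin(2 * pi * 1.5 * tt), 0)^4
  x <- 2 * sin(2 * pi * 0.25 * tt) + pulses
  ea <- estimate_resp_als(x, fs)
  ed <- estimate_resp_dwt(x, fs, resp_freq_hint = 0.25)
  expect_gt(cor(ea$resp_trace, ed$resp_trace), 0.9)
})

test_that("correction never hurts on in-model data", {
  rec <- generate_subject(quick_params(seed = 14))
  f <- rec$sample_rate_hz
  truth <- rec$truth$resp_trace_cvp
  for (est in list(estimate_resp_als(rec$cvp, f), estimate_resp_dwt(rec$cvp, f))) {
    # error of the estimated trace is smaller than not correcting at all
    expect_lt(var(est$resp_trace - truth), var(truth))
  }
})

test_that("beats per respiratory cycle follow the estimated frequency", {
  for (case in list(list(f = 0.25, beats = 6), list(f = 0.3, beats = 5))) {
    for (s in 1:3) {
      rec <- generate_subject(quick_params(resp_freq_hz = case$f, seed = s))
      expect_identical(
        estimate_resp_cycle_beats(rec$cvp, rec$sample_rate_hz, 90),
        as.integer(case$beats))
    }
  }
  # 0.2 Hz sits exactly on the 7.5-beat rounding boundary: either neighbour
  rec <- generate_subject(quick_params(resp_freq_hz = 0.2, seed = 1))
  expect_true(estimate_resp_cycle_beats(rec$cvp, rec$sample_rate_hz, 90) %in% c(7L, 8L))
  expect_error(estimate_resp_cycle_beats(rep(0, 100 * fs), fs, 90), "not detected")
})
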
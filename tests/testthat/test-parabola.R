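exact_resp <- function(sign = -1, vertex = 160) {
  x <- seq(40, 280, by = 40)
  data.frame(avd_ms = x, mean_delta_mmHg = sign * (x - vertex)^2 / 800,
             sem_mmHg = 0.5)
}

test_that("an exact quadratic is recovered exactly, with mirror symmetry", {
  fit <- fit_parabola(exact_resp(-1), channel = "abp")
  expect_equal(fit$a, -1 / 800, tolerance = 1e-12)
  expect_equal(fit$x_opt_ms, 160, tolerance = 1e-9)
  expect_true(fit$orientation_ok)
  expect_false(fit$extrapolated)
  # mirrored (CVP-like) data
  fitc <- fit_parabola(exact_resp(+1), channel = "cvp")
  expect_equal(fitc$a, +1 / 800, tolerance = 1e-12)
  expect_equal(fitc$x_opt_ms, 160, tolerance = 1e-9)
  expect_true(fitc$orientation_ok)
  # derivative vanishes at the vertex
  expect_lt(abs(2 * fit$a * fit$x_opt_ms + fit$b), 1e-9)
})

test_that("weighted fit matches an independent weighted least-squares oracle", {
  x <- seq(40, 280, by = 40)
  set.seed(7)
  y <- -(x - 170)^2 / 900 + rnorm(7, 0, 0.8)
  sem <- runif(7, 0.3, 1.5)
  fit <- fit_parabola(data.frame(avd_ms = x, mean_delta_mmHg = y, sem_mmHg = sem),
                      channel = "abp")
  orac <- stats::lm(y ~ I(x^2) + x, weights = 1 / sem^2)
  expect_equal(unname(coef(fit)), unname(coef(orac)[c(2, 3, 1)]), tolerance = 1e-10)
})

test_that("unweighted fit equals polynomial least squares on random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 40, 280))
    y <- rnorm(n)
    fit <- fit_parabola(data.frame(avd_ms = x, mean_delta_mmHg = y, sem_mmHg = NA),
                        weighting = "unweighted", channel = "abp")
    orac <- stats::lm(y ~ I(x^2) + x)
    expect_equal(unname(coef(fit)), unname(coef(orac)[c(2, 3, 1)]), tolerance = 1e-8)
  }
})

test_that("vertex SE closed forms from the coefficient covariance", {
  f0 <- fake_fit(a = -0.002, b = 0.64, cov_ab = matrix(0, 2, 2))
  expect_equal(se_opt_delta(f0), 0)
  v <- 0.25
  f1 <- fake_fit(a = -0.002, b = 0.64, cov_ab = diag(c(0, v)))
  expect_equal(se_opt_delta(f1), sqrt(v) / (2 * 0.002), tolerance = 1e-12)
})

test_that("delta-method SE agrees with a large parametric bootstrap", {
  r <- simulate_response("abp", rep_sd_mmHg = sqrt(8), seed = 33)
  fit <- fit_parabola(r)
  se_b <- se_opt_bootstrap(r, n_boot = 10000, seed = 44)
  expect_lt(abs(fit$se_opt_ms - se_b) / se_b, 0.15)
})

test_that("bootstrap SE: zero SEMs give zero, fixed seed reproduces", {
  r0 <- exact_resp(-1); r0$sem_mmHg <- 0
  expect_equal(as.numeric(se_opt_bootstrap(r0, n_boot = 50, seed = 1, channel = "abp")), 0)
  r <- simulate_response("cvp", span_mmHg = 4.15, rep_sd_mmHg = 2, seed = 5)
  b1 <- se_opt_bootstrap(r, n_boot = 200, seed = 9)
  b2 <- se_opt_bootstrap(r, n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  expect_false(isTRUE(attr(b1, "unreliable")))
})

test_that("vertex is shift-equivariant and scale-invariant", {
  set.seed(3)
  x <- seq(40, 280, by = 40)
  y <- -(x - 150)^2 / 700 + rnorm(7, 0, 0.5)
  d <- data.frame(avd_ms = x, mean_delta_mmHg = y, sem_mmHg = 1)
  fit <- fit_parabola(d, channel = "abp")
  for (shift in c(-30, 25)) {
    d2 <- d; d2$avd_ms <- d$avd_ms + shift
    expect_equal(fit_parabola(d2, channel = "abp")$x_opt_ms,
                 fit$x_opt_ms + shift, tolerance = 1e-8)
  }
  k <- 3.7
  d3 <- d; d3$mean_delta_mmHg <- k * d$mean_delta_mmHg; d3$sem_mmHg <- k * d$sem_mmHg
  fit3 <- fit_parabola(d3, channel = "abp")
  expect_equal(fit3$x_opt_ms, fit$x_opt_ms, tolerance = 1e-8)
  expect_equal(fit3$a, k * fit$a, tolerance = 1e-8)
  expect_equal(fit3$b, k * fit$b, tolerance = 1e-8)
})

test_that("degenerate and underdetermined inputs are refused or flagged", {
  x <- seq(40, 280, by = 40)
  lin <- data.frame(avd_ms = x, mean_delta_mmHg = 0.01 * x, sem_mmHg = 1)
  fit <- fit_parabola(lin, channel = "abp")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$x_opt_ms))
  expect_identical(se_opt_delta(fit), Inf)
  qc <- qc_check(fit, NULL)
  expect_false(qc$abp$passed)
  expect_true("degenerate_fit" %in% qc$abp$reasons)
  expect_true("insufficient_settings" %in% qc$cvp$reasons)
  two <- data.frame(avd_ms = c(80, 160), mean_delta_mmHg = c(1, 2), sem_mmHg = 1)
  expect_error(fit_parabola(two, channel = "abp"), "insufficient settings")
})

test_that("QC orientation and SE threshold behave as a gate", {
  good_abp <- fit_parabola(exact_resp(-1), channel = "abp")
  good_cvp <- fit_parabola(exact_resp(+1), channel = "cvp")
  qc <- qc_check(good_abp, good_cvp, threshold_ms = 50)
  expect_true(qc$abp$passed && qc$cvp$passed)
  # wrong orientation: ABP curve opening upward
  bad <- fit_parabola(exact_resp(+1), channel = "abp")
  qc2 <- qc_check(bad, good_cvp, threshold_ms = 50)
  expect_false(qc2$abp$passed)
  expect_identical(qc2$abp$reasons, "wrong_orientation")
  # SE gate is strict at the boundary: fails only above the threshold
  for (case in list(list(se = 49, pass = TRUE), list(se = 50, pass = TRUE),
                    list(se = 50.0001, pass = FALSE))) {
    qc3 <- qc_check(good_abp, good_cvp, threshold_ms = 50,
                    se_override = list(abp = case$se, cvp = 1))
    expect_identical(qc3$abp$passed, case$pass)
    if (!case$pass) expect_identical(qc3$abp$reasons, "seopt_exceeds_threshold")
  }
})

test_that("extrapolated vertices beyond the grid margin are flagged", {
  x <- seq(40, 280, by = 40)
  d <- data.frame(avd_ms = x, mean_delta_mmHg = -(x - 340)^2 / 800, sem_mmHg = 1)
  fit <- fit_parabola(d, channel = "abp")
  expect_equal(fit$x_opt_ms, 340, tolerance = 1e-6)
  expect_true(fit$extrapolated)
})

test_that("model methods are coherent", {
  r <- simulate_response("abp", rep_sd_mmHg = 2, seed = 77)
  fit <- fit_parabola(r)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(residuals(fit), r$table$mean_delta_mmHg - fit$fitted)
  s <- summary(fit)
  expect_s3_class(s, "summary.avd_parabola")
  expect_equal(s$x_opt_ms, fit$x_opt_ms)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(7L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 1), sims)
})
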
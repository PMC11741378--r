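# Parabolic response fit and vertex (optimum) estimation.
#
# The pressure change y at tested AV delay x is modelled as
#   y = a x^2 + b x + c,
# whose stationary point x_opt = -b / (2a) is the haemodynamic optimum.
# The horizontal uncertainty SE_opt is derived from the vertical
# (replicate) uncertainty by first-order propagation of the coefficient
# covariance, with a parametric bootstrap as the robust cross-check.

DEGENERACY_TOL <- 1e-12  # |a| below this (mmHg/ms^2) => vertex undefined

#' Fit a parabola to a per-AVD response
#'
#' Weighted least-squares fit of mean pressure change versus tested AV
#' delay. With `weighting = "inverse_variance"` each point is weighted by
#' 1/SEM^2 (zero or missing SEMs are assigned the smallest nonzero SEM; if
#' every SEM is zero the fit falls back to unweighted) and the coefficient
#' covariance is taken from the weighted normal equations with the SEMs as
#' known standard deviations. Unweighted fits use the residual variance.
#'
#' @param resp An `avd_response` (or a data frame with columns `avd_ms`,
#'   `mean_delta_mmHg`, `sem_mmHg`).
#' @param weighting `"inverse_variance"` (default) or `"unweighted"`.
#' @param channel `"abp"` or `"cvp"`; orientation is judged against it
#'   (concave for ABP, convex for CVP). Default from `resp`.
#' @return Object of class `avd_parabola`: coefficients `a`, `b`, `c`,
#'   3x3 covariance `cov_abc`, vertex `x_opt_ms`, delta-method `se_opt_ms`,
#'   flags `orientation_ok`, `degenerate`, `extrapolated`, and the data.
#' @examples
#' x <- seq(40, 280, by = 40)
#' resp <- data.frame(avd_ms = x, mean_delta_mmHg = -(x - 160)^2 / 800,
#'                    sem_mmHg = 1)
#' fit <- fit_parabola(resp, channel = "abp")
#' coef(fit); fit$x_opt_ms
#' @export
fit_parabola <- function(resp, weighting = c("inverse_variance", "unweighted"),
                         channel = NULL) {
  weighting <- match.arg(weighting)
  tab <- if (inherits(resp, "avd_response")) resp$table else as.data.frame(resp)
  if (is.null(channel)) {
    channel <- if (inherits(resp, "avd_response")) resp$channel else "abp"
  }
  x <- tab$avd_ms; y <- tab$mean_delta_mmHg; sem <- tab$sem_mmHg
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; sem <- sem[ok]
  if (length(unique(x)) < 3) {
    stop("insufficient settings: need >= 3 distinct tested AVDs, got ",
         length(unique(x)))
  }
  w <- rep(1, length(x))
  used_weighting <- "unweighted"
  if (weighting == "inverse_variance") {
    s <- sem
    pos <- is.finite(s) & s > 0
    if (any(pos)) {
      s[!pos] <- min(s[pos])  # zero-SEM points get the smallest nonzero SEM
      w <- 1 / s^2
      used_weighting <- "inverse_variance"
    }
  }
  X <- cbind(x^2, x, 1)
  A <- crossprod(X * sqrt(w))            # X' W X
  beta <- solve(A, crossprod(X, w * y))  # (a, b, c)
  a <- beta[1]; b <- beta[2]; cc <- beta[3]
  fitted <- as.numeric(X %*% beta)
  rss <- sum(w * (y - fitted)^2)
  cov_abc <- if (used_weighting == "inverse_variance") {
    solve(A)  # SEMs treated as known sds
  } else {
    dof <- length(x) - 3
    s2 <- if (dof > 0) rss / dof else 0
    s2 * solve(A)
  }
  degenerate <- abs(a) < DEGENERACY_TOL
  x_opt <- if (degenerate) NA_real_ else -b / (2 * a)
  orientation_ok <- if (degenerate) FALSE
                    else (channel == "abp" && a < 0) || (channel == "cvp" && a > 0)
  extrapolated <- !degenerate &&
    (x_opt < min(x) - 40 || x_opt > max(x) + 40)
  fit <- structure(list(
    a = a, b = b, c = cc, cov_abc = cov_abc,
    x_opt_ms = x_opt, se_opt_ms = NA_real_,
    orientation_ok = orientation_ok, degenerate = degenerate,
    extrapolated = extrapolated, channel = channel,
    weighting = used_weighting,
    data = data.frame(avd_ms = x, mean_delta_mmHg = y, sem_mmHg = sem),
    fitted = fitted, rss = rss), class = "avd_parabola")
  fit$se_opt_ms <- se_opt_delta(fit)
  fit
}

#' Vertex standard error by the delta method
#'
#' First-order propagation of the (a, b) covariance through
#' `x_opt = -b / (2a)`: gradient `(b / (2 a^2), -1 / (2a))`, so
#' `SE = sqrt(g' Sigma_ab g)`.
#'
#' @param fit An `avd_parabola`.
#' @return SE of the optimum, ms (`Inf` for a degenerate fit).
#' @export
se_opt_delta <- function(fit) {
  stopifnot(inherits(fit, "avd_parabola"))
  if (fit$degenerate) return(Inf)
  g <- c(fit$b / (2 * fit$a^2), -1 / (2 * fit$a))
  S <- fit$cov_abc[1:2, 1:2]
  v <- as.numeric(t(g) %*% S %*% g)
  sqrt(max(v, 0))
}

#' Vertex standard error by parametric bootstrap
#'
#' Resamples each per-AVD mean from Normal(mean, SEM), refits the parabola,
#' and takes the standard deviation of the vertices over the replicates
#' that produce a correctly-oriented, non-degenerate fit. More robust than
#' the delta method when the curvature is poorly determined.
#'
#' @param resp An `avd_response` (or data frame as in [fit_parabola()]).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (results are reproducible given it).
#' @param weighting Passed to [fit_parabola()].
#' @param channel Channel for the orientation screen; default from `resp`.
#' @return SE of the optimum, ms, with attributes `discard_frac` (fraction
#'   of replicates discarded by the orientation/degeneracy screen) and
#'   `unreliable` (`TRUE` when more than half were discarded).
#' @export
se_opt_bootstrap <- function(resp, n_boot = 1000, seed = 1L,
                             weighting = "inverse_variance", channel = NULL) {
  tab <- if (inherits(resp, "avd_response")) resp$table else as.data.frame(resp)
  if (is.null(channel)) {
    channel <- if (inherits(resp, "avd_response")) resp$channel else "abp"
  }
  sem <- tab$sem_mmHg
  sem[!is.finite(sem)] <- 0
  with_local_seed(seed, {
    xs <- numeric(0)
    n_bad <- 0L
    for (r in seq_len(n_boot)) {
      tb <- tab
      tb$mean_delta_mmHg <- rnorm(nrow(tab), tab$mean_delta_mmHg, sem)
      f <- tryCatch(fit_parabola(tb, weighting = weighting, channel = channel),
                    error = function(e) NULL)
      if (is.null(f) || f$degenerate || !f$orientation_ok) {
        n_bad <- n_bad + 1L
      } else {
        xs <- c(xs, f$x_opt_ms)
      }
    }
    discard <- n_bad / n_boot
    se <- if (length(xs) >= 2) sd(xs) else NA_real_
    structure(se, discard_frac = discard, unreliable = discard > 0.5,
              n_used = length(xs))
  })
}

#' Quality-control gate for a pair of channel fits
#'
#' Two tests per channel: the parabola must open the physiologically
#' correct way (concave for ABP, convex for CVP), and the vertex standard
#' error must not exceed `threshold_ms` (default 50 ms). QC never raises;
#' it reports a verdict with reasons.
#'
#' @param fit_abp,fit_cvp `avd_parabola` fits (either may be `NULL`, e.g.
#'   refused for insufficient settings).
#' @param threshold_ms SE_opt gate, ms.
#' @param se_override Optional named list (`abp`, `cvp`) of SE_opt values to
#'   gate on instead of the delta-method SE (e.g. bootstrap values).
#' @return List of class `qc_result` with one element per channel, each a
#'   list `passed` / `reasons` (subset of `wrong_orientation`,
#'   `seopt_exceeds_threshold`, `insufficient_settings`, `degenerate_fit`).
#' @export
qc_check <- function(fit_abp, fit_cvp, threshold_ms = 50, se_override = NULL) {
  one <- function(fit, se_ov) {
    reasons <- character(0)
    if (is.null(fit)) {
      reasons <- "insufficient_settings"
    } else {
      if (fit$degenerate) reasons <- c(reasons, "degenerate_fit")
      if (!fit$degenerate && !fit$orientation_ok) {
        reasons <- c(reasons, "wrong_orientation")
      }
      se <- if (!is.null(se_ov) && is.finite(se_ov)) se_ov else fit$se_opt_ms
      if (!is.finite(se) || se > threshold_ms) {
        reasons <- c(reasons, "seopt_exceeds_threshold")
      }
    }
    list(passed = length(reasons) == 0, reasons = reasons)
  }
  structure(list(abp = one(fit_abp, se_override$abp),
                 cvp = one(fit_cvp, se_override$cvp),
                 threshold_ms = threshold_ms),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  for (ch in c("abp", "cvp")) {
    v <- x[[ch]]
    cat(sprintf("QC %s: %s%s\n", toupper(ch),
                if (v$passed) "PASS" else "FAIL",
                if (length(v$reasons)) paste0(" (", paste(v$reasons, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

# ---- methods for the fitted model -----------------------------------------

#' @export
print.avd_parabola <- function(x, ...) {
  cat(sprintf("Parabolic AVD response fit (%s, %s)\n",
              toupper(x$channel), x$weighting))
  cat(sprintf("  y = %.4g x^2 + %.4g x + %.4g  (x in ms, y in mmHg)\n",
              x$a, x$b, x$c))
  if (x$degenerate) {
    cat("  vertex undefined: |a| below degeneracy tolerance\n")
  } else {
    cat(sprintf("  optimum x_opt = %.1f ms, SE_opt = %.1f ms%s%s\n",
                x$x_opt_ms, x$se_opt_ms,
                if (x$orientation_ok) "" else " [WRONG ORIENTATION]",
                if (x$extrapolated) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' @export
coef.avd_parabola <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
predict.avd_parabola <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$avd_ms
       else if (is.data.frame(newdata)) newdata$avd_ms
       else as.numeric(newdata)
  object$a * x^2 + object$b * x + object$c
}

#' @export
residuals.avd_parabola <- function(object, ...) {
  object$data$mean_delta_mmHg - object$fitted
}

#' @export
summary.avd_parabola <- function(object, ...) {
  se <- sqrt(pmax(diag(object$cov_abc), 0))
  out <- list(
    coefficients = cbind(Estimate = c(a = object$a, b = object$b, c = object$c),
                         `Std. Error` = se),
    x_opt_ms = object$x_opt_ms, se_opt_ms = object$se_opt_ms,
    orientation_ok = object$orientation_ok, degenerate = object$degenerate,
    extrapolated = object$extrapolated, channel = object$channel,
    n = nrow(object$data))
  class(out) <- "summary.avd_parabola"
  out
}

#' @export
print.summary.avd_parabola <- function(x, ...) {
  cat(sprintf("Parabolic AVD response fit, channel %s (n = %d settings)\n",
              toupper(x$channel), x$n))
  print(x$coefficients)
  cat(sprintf("x_opt = %.2f ms, SE_opt = %.2f ms, orientation %s\n",
              x$x_opt_ms, x$se_opt_ms,
              if (x$orientation_ok) "ok" else "WRONG"))
  invisible(x)
}

#' Simulate per-AVD responses from a fitted parabola
#'
#' Draws `nsim` parametric replicates of the per-AVD mean response: fitted
#' values plus Normal noise with the observed SEMs. This is the resampling
#' scheme behind [se_opt_bootstrap()].
#'
#' @param object An `avd_parabola`.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with one column per simulation, rows matching
#'   `object$data$avd_ms`.
#' @export
simulate.avd_parabola <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    sem <- object$data$sem_mmHg
    sem[!is.finite(sem)] <- 0
    as.data.frame(replicate(nsim, rnorm(length(sem), object$fitted, sem)))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Plot a fitted parabolic AVD response
#'
#' Observed per-AVD means with SEM error bars, the fitted parabola and the
#' estimated optimum.
#'
#' @param x An `avd_parabola`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.avd_parabola <- function(x, ...) {
  d <- x$data
  xx <- seq(min(d$avd_ms) - 20, max(d$avd_ms) + 20, length.out = 200)
  yy <- predict(x, xx)
  ylim <- range(c(d$mean_delta_mmHg - d$sem_mmHg,
                  d$mean_delta_mmHg + d$sem_mmHg, yy), finite = TRUE)
  plot(d$avd_ms, d$mean_delta_mmHg, ylim = ylim,
       xlab = "AV delay (ms)",
       ylab = sprintf("%s change vs reference (mmHg)", toupper(x$channel)),
       pch = 19, ...)
  segments(d$avd_ms, d$mean_delta_mmHg - d$sem_mmHg,
           d$avd_ms, d$mean_delta_mmHg + d$sem_mmHg)
  lines(xx, yy)
  if (!x$degenerate) abline(v = x$x_opt_ms, lty = 2)
  invisible(x)
}
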
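# Replicate transition deltas and per-AVD aggregation.

# Classify each annotated event as entering the tested or the reference
# state. Values different from the reference are unambiguous; a tested AVD
# equal to the reference (the reference-vs-reference control point) is
# resolved by protocol alternation.
classify_events <- function(events, ref_avd_ms) {
  n <- nrow(events)
  state <- character(n)
  state[1] <- "ref"  # protocol starts in the reference state
  for (i in seq_len(n)[-1]) {
    state[i] <- if (events$avd_ms[i] != ref_avd_ms) "test"
                else if (events$avd_ms[i - 1] != ref_avd_ms) "ref"
                else if (state[i - 1] == "ref") "test" else "ref"
  }
  state
}

#' Per-transition pressure deltas
#'
#' For every pacing transition, compares the mean per-beat feature over a
#' window of `window_beats` complete beats immediately before the event with
#' the window immediately after, and signs the difference as
#' tested-minus-reference. The beat straddling the event instant belongs to
#' neither window. Transitions with fewer than `window_beats` complete beats
#' available on either side (e.g. too-close events) are dropped with a
#' message.
#'
#' @param features A `beat_features` data frame (one channel).
#' @param events Data frame `time_s`, `avd_ms`.
#' @param window_beats Window length in beats (default 6).
#' @param ref_avd_ms Reference AVD; default the most frequent event value.
#' @param feature `"peak"` or `"mean"` beat feature.
#' @param directions `"both"` or `"ref_to_test"` only.
#' @return Data frame of class `transition_deltas`: `channel`, `feature`,
#'   `avd_tested_ms`, `replicate_index`, `direction`, `event_time_s`,
#'   `pre_mean_mmHg`, `post_mean_mmHg`, `delta_mmHg`, `n_pre`, `n_post`.
#' @export
transition_deltas <- function(features, events, window_beats = 6,
                              ref_avd_ms = NULL,
                              feature = c("peak", "mean"),
                              directions = c("both", "ref_to_test")) {
  feature <- match.arg(feature)
  directions <- match.arg(directions)
  stopifnot(nrow(events) >= 2)
  if (is.null(ref_avd_ms)) {
    tab <- table(events$avd_ms)
    ref_avd_ms <- as.numeric(names(tab)[which.max(tab)])
  }
  state <- classify_events(events, ref_avd_ms)
  val <- if (feature == "peak") features$peak_mmHg else features$mean_mmHg
  o <- order(features$beat_time_s)
  val <- val[o]
  onset <- features$beat_time_s[o]
  n_b <- length(onset)
  if (n_b < 2 * window_beats + 2) stop("too few beats for transition analysis")
  ibi <- median(diff(onset))
  ends <- c(onset[-1], onset[n_b] + ibi)
  channel <- as.character(features$channel[1])

  rows <- list()
  dropped <- 0L
  ev_t <- events$time_s
  for (i in seq_len(nrow(events))[-1]) {
    dir <- if (state[i] == "test") "ref_to_test" else "test_to_ref"
    if (directions == "ref_to_test" && dir != "ref_to_test") next
    avd <- if (dir == "ref_to_test") events$avd_ms[i] else events$avd_ms[i - 1]
    t_e <- ev_t[i]
    t_prev <- if (i >= 2) ev_t[i - 1] else -Inf
    t_next <- if (i < nrow(events)) ev_t[i + 1] else Inf
    pre_idx <- which(ends <= t_e & onset >= t_prev)
    post_idx <- which(onset >= t_e & ends <= t_next)
    if (length(pre_idx) < window_beats || length(post_idx) < window_beats) {
      dropped <- dropped + 1L
      next
    }
    pre_idx <- tail(pre_idx, window_beats)
    post_idx <- head(post_idx, window_beats)
    pre_m <- mean(val[pre_idx]); post_m <- mean(val[post_idx])
    delta <- if (dir == "ref_to_test") post_m - pre_m else pre_m - post_m
    rows[[length(rows) + 1L]] <- data.frame(
      channel = channel, feature = feature, avd_tested_ms = avd,
      replicate_index = NA_integer_, direction = dir, event_time_s = t_e,
      pre_mean_mmHg = pre_m, post_mean_mmHg = post_m, delta_mmHg = delta,
      n_pre = window_beats, n_post = window_beats)
  }
  if (dropped > 0) {
    message(dropped, " transition(s) dropped: fewer than ", window_beats,
            " complete beats on one side")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable transitions")
  # replicate index within (tested AVD, direction), in time order
  out <- out[order(out$avd_tested_ms, out$direction, out$event_time_s), ]
  out$replicate_index <- stats::ave(seq_len(nrow(out)),
                                    out$avd_tested_ms, out$direction,
                                    FUN = seq_along)
  rownames(out) <- NULL
  structure(out, class = c("transition_deltas", "data.frame"),
            ref_avd_ms = ref_avd_ms)
}

new_avd_response <- function(channel, feature, table) {
  structure(list(channel = channel, feature = feature, table = table),
            class = "avd_response")
}

#' Aggregate replicate deltas into a per-AVD response
#'
#' Per tested AVD: mean replicate delta, standard error of the mean
#' (sd / sqrt(n)) and replicate count. AVDs with fewer than 2 retained
#' replicates are excluded with a warning.
#'
#' @param deltas A `transition_deltas` data frame.
#' @param channel,feature Labels carried into the response (defaults taken
#'   from `deltas`).
#' @return An `avd_response`: list with `channel`, `feature` and `table`
#'   (data frame `avd_ms`, `mean_delta_mmHg`, `sem_mmHg`, `n_replicates`).
#' @export
aggregate_response <- function(deltas, channel = NULL, feature = NULL) {
  if (is.null(channel)) channel <- as.character(deltas$channel[1])
  if (is.null(feature)) feature <- as.character(deltas$feature[1])
  sp <- split(deltas$delta_mmHg, deltas$avd_tested_ms)
  tab <- do.call(rbind, lapply(names(sp), function(a) {
    d <- sp[[a]]
    data.frame(avd_ms = as.numeric(a), mean_delta_mmHg = mean(d),
               sem_mmHg = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
               n_replicates = length(d))
  }))
  few <- tab$n_replicates < 2
  if (any(few)) {
    warning("AVD(s) excluded with < 2 replicates: ",
            paste(tab$avd_ms[few], collapse = ", "))
    tab <- tab[!few, , drop = FALSE]
  }
  tab <- tab[order(tab$avd_ms), ]
  rownames(tab) <- NULL
  new_avd_response(channel, feature, tab)
}

#' @export
print.avd_response <- function(x, ...) {
  cat(sprintf("Per-AVD response: channel %s, feature %s\n",
              toupper(x$channel), x$feature))
  print(x$table, row.names = FALSE)
  invisible(x)
}
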
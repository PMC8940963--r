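#' Segment perceptual dominance epochs from an OKN trace
#'
#' Automated surrogate for manual marking of dominance periods.  The slow
#' phase of the optokinetic nystagmus tracks the perceived motion direction,
#' so its velocity sign indexes the percept:
#' (i) velocity is estimated from the y coordinate by a centred difference
#' over `span_ms`; (ii) fast phases (|velocity| above `saccade_threshold`)
#' are masked; (iii) the slow-phase velocity sign is majority-filtered over a
#' sliding `sign_window_ms` window; (iv) maximal runs of constant sign
#' lasting at least `min_stable` ms, with mean slow-phase speed of at least
#' `min_speed`, become epochs.  Negative slow-phase velocity (downward
#' pursuit) is labelled percept DOWN.
#'
#' @param trace data.frame(t, x, y), t in ms at uniform 1 kHz sampling.
#' @param min_stable minimum epoch duration, ms.
#' @param saccade_threshold fast-phase velocity threshold, deg/s.
#' @param sign_window_ms sliding majority-vote window, ms.
#' @param span_ms centred-difference span for velocity estimation, ms.
#' @param min_speed minimum mean slow-phase speed (deg/s) for a run to count
#'   as pursuit rather than fixation noise.
#' @return data.frame(onset, offset, percept) in ms; zero rows if the trace
#'   is shorter than `min_stable` or contains no stable pursuit.
#' @export
segment_percepts <- function(trace, min_stable = 300,
                             saccade_threshold = 30, sign_window_ms = 200,
                             span_ms = 20, min_speed = 5) {
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      percept = character(), stringsAsFactors = FALSE)
  n <- nrow(trace)
  dt <- if (n > 1) trace$t[2] - trace$t[1] else 1
  if (n * dt < min_stable) return(empty)
  y <- trace$y
  h <- max(1L, round(span_ms / (2 * dt)))
  ## centred-difference velocity (deg/s), defined on samples (h+1)..(n-h)
  v <- rep(NA_real_, n)
  idx <- (h + 1L):(n - h)
  v[idx] <- (y[idx + h] - y[idx - h]) / (2 * h * dt) * 1000
  v[abs(v) > saccade_threshold] <- NA  # mask fast phases
  ## sliding majority vote on sign; masked samples are neutral
  s <- sign(v); s[is.na(s)] <- 0
  w <- max(1L, round(sign_window_ms / dt))
  cs <- cumsum(c(0, s))
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  hi <- pmin(n, seq_len(n) + (w %/% 2L))
  vote <- sign(cs[hi + 1L] - cs[lo + 1L])
  ## carry last decided sign through undecided samples
  dec <- vote != 0
  if (!any(dec)) return(empty)
  filled <- vote
  last <- 0
  for (i in seq_len(n)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  ## leading zeros take the first decided sign
  first_dec <- which(dec)[1]
  if (first_dec > 1) filled[1:(first_dec - 1)] <- vote[first_dec]
  r <- rle(filled)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- empty
  for (k in seq_along(r$values)) {
    dur <- r$lengths[k] * dt
    if (r$values[k] == 0 || dur < min_stable) next
    run <- starts[k]:ends[k]
    mv <- mean(v[run], na.rm = TRUE)
    if (!is.finite(mv) || abs(mv) < min_speed) next
    out <- rbind(out, data.frame(
      onset = trace$t[starts[k]],
      offset = trace$t[ends[k]] + dt,
      percept = if (r$values[k] < 0) "DOWN" else "UP",
      stringsAsFactors = FALSE))
  }
  out
}

#' Segment all eye traces of a session into perceptual epochs
#'
#' Runs [segment_percepts()] on the requested trials and assigns the phase of
#' each epoch from the trial's event table: epochs before the second-stimulus
#' onset are PA_MONOCULAR, the first epoch at/after it is BFS_DOMINANCE (BR
#' trials), and later epochs are BR_DOMINANCE.  PA trials may alternatively
#' use the stimulus schedule directly via [epochs_from_events()].
#'
#' @param session an `okn_session` (or any list with `trials`, `events`,
#'   `eye` of the same layout).
#' @param paradigms trial types to segment.
#' @param ... passed to [segment_percepts()].
#' @return data.frame(trial_id, onset, offset, percept, phase, source).
#' @export
segment_session <- function(session, paradigms = "BR", ...) {
  tr <- session$trials[session$trials$paradigm %in% paradigms, ]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    tid <- tr$trial_id[i]
    ep <- segment_percepts(session$eye[[as.character(tid)]], ...)
    if (!nrow(ep)) next
    ev <- session$events[session$events$trial_id == tid, ]
    second <- ev$time_ms[ev$type %in% c("FLASH", "STIM_SWITCH")]
    second <- if (length(second)) min(second) else Inf
    ep$phase <- "PA_MONOCULAR"
    if (is.finite(second) && tr$paradigm[i] == "BR") {
      after <- which(ep$onset >= second - 150)  # allow OKN latency jitter
      if (length(after)) {
        ep$phase[after] <- "BR_DOMINANCE"
        ep$phase[after[1]] <- "BFS_DOMINANCE"
      }
    }
    ep$trial_id <- tid
    ep$source <- "OKN_DERIVED"
    out[[length(out) + 1L]] <- ep
  }
  if (!length(out))
    return(data.frame(trial_id = integer(), onset = numeric(),
                      offset = numeric(), percept = character(),
                      phase = character(), source = character()))
  do.call(rbind, out)[, c("trial_id", "onset", "offset", "percept",
                          "phase", "source")]
}

#' Stimulus-derived perceptual epochs
#'
#' Builds the epoch table for trials where perception follows the stimulus
#' schedule (PA and fixation-control trials): each interval between
#' consecutive stimulus events is one epoch with the presented direction.
#'
#' @param session an `okn_session`-like list.
#' @param paradigms trial types to include.
#' @return data.frame(trial_id, onset, offset, percept, phase, source).
#' @export
epochs_from_events <- function(session, paradigms = "PA") {
  tr <- session$trials[session$trials$paradigm %in% paradigms, ]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    tid <- tr$trial_id[i]
    ev <- session$events[session$events$trial_id == tid, ]
    ev <- ev[order(ev$time_ms), ]
    dirs <- ev$direction
    ## fixation trials code direction in degrees; map the vertical ones
    pct <- ifelse(dirs %in% c("UP", "DOWN"), dirs,
                  ifelse(suppressWarnings(as.numeric(dirs)) == 90, "UP",
                         ifelse(suppressWarnings(as.numeric(dirs)) == 270,
                                "DOWN", NA)))
    out[[length(out) + 1L]] <- data.frame(
      trial_id = tid, onset = ev$time_ms,
      offset = c(ev$time_ms[-1], tr$duration_ms[i]),
      percept = pct,
      phase = ifelse(seq_len(nrow(ev)) == 2L & tr$paradigm[i] == "BR",
                     "BFS_DOMINANCE", "PA_MONOCULAR"),
      source = "STIMULUS_DERIVED", stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(trial_id = integer(), onset = numeric(),
                      offset = numeric(), percept = character(),
                      phase = character(), source = character()))
  do.call(rbind, out)
}

#' Maximum-likelihood gamma fit of dominance durations
#'
#' @param durations positive durations, ms; at least 10 values with nonzero
#'   variance.
#' @return object of class `gamma_fit`: list(shape, scale, loglik, n); scale
#'   and log-likelihood on the millisecond scale.
#' @export
fit_dominance_gamma <- function(durations) {
  if (length(durations) < 10) stopf("need at least 10 durations")
  if (any(durations <= 0)) stopf("durations must be positive")
  if (var(durations) == 0)
    stopf("degenerate input: durations have zero variance")
  xs <- durations / 1000  # seconds, for optimizer stability
  fit <- fitdistrplus::fitdist(xs, "gamma")
  shape <- unname(fit$estimate["shape"])
  scale <- 1000 / unname(fit$estimate["rate"])
  out <- list(shape = shape, scale = scale,
              loglik = fit$loglik - length(xs) * log(1000),
              n = length(durations))
  class(out) <- "gamma_fit"
  out
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma fit of %d dominance durations: shape %.3f, scale %.1f ms (mean %.0f ms)\n",
    x$n, x$shape, x$scale, x$shape * x$scale))
  invisible(x)
}

#' Gamma log-likelihood of a duration sample
#' @param durations ms; `shape`, `scale` (ms) gamma parameters.
#' @param shape,scale gamma parameters (scale in ms).
#' @return log-likelihood.
#' @export
gamma_loglik <- function(durations, shape, scale) {
  sum(stats::dgamma(durations, shape = shape, scale = scale, log = TRUE))
}

#' Select trials with reduced eye-position variance
#'
#' For each trial the y coordinate is detrended (straight-line fit removed),
#' low-pass filtered below `cutoff` Hz (zero-phase second-order Butterworth),
#' double-differentiated, and compared against a flat line (slope 0,
#' intercept fitted by least squares, i.e. the baseline of the
#' double-differentiated signal) by the sum of squared errors.  Trials whose
#' error is strictly below the within-condition median are selected.
#'
#' @param traces named list of data.frame(t, x, y).
#' @param condition vector (same length) grouping trials into conditions;
#'   each condition needs at least 2 trials.
#' @param cutoff low-pass cutoff, Hz.
#' @param fs sampling rate, Hz.
#' @return character vector of selected trial names.
#' @export
select_low_em_variance_trials <- function(traces,
                                          condition = rep("all",
                                                          length(traces)),
                                          cutoff = 20, fs = 1000) {
  stopifnot(length(condition) == length(traces))
  if (any(table(condition) < 2))
    stopf("each condition needs at least 2 trials")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  err <- vapply(traces, function(tr) {
    y <- tr$y
    t <- seq_along(y)
    y <- y - stats::fitted(stats::lm(y ~ t))        # detrend
    y <- as.numeric(signal::filtfilt(bf, y))        # < cutoff Hz
    dd <- diff(diff(y))                             # double differential
    # flat line (slope 0) with least-squares intercept: the signal baseline
    sum((dd - mean(dd))^2)
  }, numeric(1))
  ids <- names(traces) %||% as.character(seq_along(traces))
  sel <- logical(length(err))
  for (cond in unique(condition)) {
    i <- condition == cond
    sel[i] <- err[i] < median(err[i])
  }
  ids[sel]
}

#' Standard deviation of eye position in a window
#'
#' Sample SD of the y coordinate within `window` (ms, half-open).
#' @param trace data.frame(t, x, y).
#' @param window length-2 numeric, ms.
#' @return degrees.
#' @export
eye_position_std <- function(trace, window = c(0, 1000)) {
  if (window[1] < min(trace$t) || window[2] > max(trace$t) + 1)
    stopf("window [%g, %g] outside trace", window[1], window[2])
  sd(trace$y[trace$t >= window[1] & trace$t < window[2]])
}
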
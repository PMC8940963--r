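#' Band-pass filter broadband voltage for spike detection
#'
#' Zero-phase second-order Butterworth band-pass, 600-3000 Hz by default,
#' applied forward and backward (filtfilt), preserving signal length.
#'
#' @param x voltage series.
#' @param fs sampling rate, Hz; must exceed twice the upper band edge.
#' @param band length-2 numeric, Hz.
#' @return filtered series, same length as `x`.
#' @export
bandpass_spikes <- function(x, fs, band = c(600, 3000)) {
  if (fs <= 2 * band[2])
    stopf("fs = %g Hz too low for a %g-%g Hz band-pass", fs, band[1], band[2])
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect spike events in a filtered voltage trace
#'
#' Negative-going threshold crossings at -`threshold_mad` times the median
#' absolute deviation (raw MAD, no Gaussian consistency factor).  Events
#' whose trough magnitude exceeds `artifact_factor` times the mean absolute
#' deviation are discarded as artifacts; of any pair of events closer than
#' the refractory period the later one is discarded.  Each surviving event
#' yields a 45-sample snippet (1.5 ms at 30 kHz) aligned to its minimum,
#' `pre` samples before the trough.
#'
#' @param filtered band-passed voltage series.
#' @param fs sampling rate, Hz.
#' @param threshold_mad detection threshold in MADs (default 5).
#' @param artifact_factor artifact rejection threshold (default 50).
#' @param artifact_stat dispersion statistic for the artifact rule: the
#'   literal "mean" absolute deviation (default) or "median".
#' @param refractory_ms minimum inter-event interval (default 0.5 ms).
#' @param snippet_len,pre snippet geometry: `snippet_len` samples total,
#'   `pre` samples before the trough (default 45 and 15; the remaining 30
#'   capture repolarization).
#' @return list(events, snippets): `events` is a data.frame(time_ms,
#'   sample, amplitude); `snippets` an n x `snippet_len` matrix with the
#'   trough at column `pre + 1`.  Events too close to the series edge for a
#'   full snippet are dropped.
#' @export
detect_spikes <- function(filtered, fs = 30000, threshold_mad = 5,
                          artifact_factor = 50,
                          artifact_stat = c("mean", "median"),
                          refractory_ms = 0.5,
                          snippet_len = 45L, pre = 15L) {
  artifact_stat <- match.arg(artifact_stat)
  empty <- list(events = data.frame(time_ms = numeric(), sample = integer(),
                                    amplitude = numeric()),
                snippets = matrix(numeric(), 0, snippet_len))
  m <- median(filtered)
  mad_raw <- median(abs(filtered - m))
  if (mad_raw == 0) {
    warnf("constant signal (MAD = 0): no detections")
    return(empty)
  }
  thr <- -threshold_mad * mad_raw
  below <- filtered < thr
  if (!any(below)) return(empty)
  ## contiguous sub-threshold runs -> trough per run
  d <- diff(c(FALSE, below, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  trough <- mapply(function(a, b) a - 1L + which.min(filtered[a:b]),
                   starts, ends)
  amp <- filtered[trough]
  ## artifact rule: |amplitude| > artifact_factor x (mean|median) abs deviation
  disp <- switch(artifact_stat,
                 mean = mean(abs(filtered - mean(filtered))),
                 median = mad_raw)
  keep <- abs(amp) <= artifact_factor * disp
  trough <- trough[keep]; amp <- amp[keep]
  ## refractory: drop the later of any pair closer than refractory_ms
  if (length(trough) > 1) {
    ref_smp <- refractory_ms * fs / 1000
    keep <- rep(TRUE, length(trough))
    last <- trough[1]
    for (i in 2:length(trough)) {
      if (trough[i] - last < ref_smp) keep[i] <- FALSE else last <- trough[i]
    }
    trough <- trough[keep]; amp <- amp[keep]
  }
  ## snippets: pre samples before the trough, rest after
  lo <- trough - pre; hi <- lo + snippet_len - 1L
  ok <- lo >= 1L & hi <= length(filtered)
  trough <- trough[ok]; amp <- amp[ok]; lo <- lo[ok]
  snip <- if (length(trough))
    t(vapply(lo, function(a) filtered[a:(a + snippet_len - 1L)],
             numeric(snippet_len)))
  else matrix(numeric(), 0, snippet_len)
  list(events = data.frame(time_ms = (trough - 1L) * 1000 / fs,
                           sample = as.integer(trough), amplitude = amp),
       snippets = snip)
}
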
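#' Gaussian-kernel spike density function
#'
#' Sum of unit-mass Gaussians (SD `kernel_sd` ms) centred on the spikes,
#' scaled to Hz.  A single spike peaks at 1000/(kernel_sd * sqrt(2*pi)) Hz.
#'
#' @param spike_times ms.
#' @param kernel_sd ms, > 0.
#' @param grid evaluation grid, ms (default 1 ms steps over the spikes
#'   +/- 4 SD).
#' @return data.frame(time, rate).
#' @export
spike_density <- function(spike_times, kernel_sd = 50, grid = NULL) {
  check_scalar_pos(kernel_sd, "kernel_sd")
  if (is.null(grid)) {
    if (!length(spike_times)) grid <- 0:1000
    else grid <- seq(floor(min(spike_times) - 4 * kernel_sd),
                     ceiling(max(spike_times) + 4 * kernel_sd), by = 1)
  }
  rate <- numeric(length(grid))
  for (s in spike_times) rate <- rate + dnorm(grid, s, kernel_sd)
  data.frame(time = grid, rate = rate * 1000)
}

bin_starts <- function(window, bin_ms) {
  seq(window[1], window[2] - bin_ms, by = bin_ms)
}

## counts matrix units x bins for one alignment; half-open bins [t, t+bin)
aligned_counts <- function(spikes, unit_ids, trial_id, align, starts,
                           bin_ms) {
  sp <- spikes[spikes$trial_id == trial_id, ]
  rel <- sp$time_ms - align
  keep <- rel >= starts[1] & rel < starts[length(starts)] + bin_ms
  sp <- sp[keep, ]; rel <- rel[keep]
  b <- floor((rel - starts[1]) / bin_ms) + 1L
  m <- matrix(0L, length(unit_ids), length(starts),
              dimnames = list(unit_ids, NULL))
  if (nrow(sp)) {
    tab <- table(factor(sp$unit_id, levels = unit_ids),
                 factor(b, levels = seq_along(starts)))
    m[] <- as.integer(tab)
  }
  m
}

#' Conventional population PSTH (preferred vs. nonpreferred)
#'
#' Per unit, the mean response in `bin_ms` bins around each alignment event
#' is computed separately for events where the unit's preferred direction is
#' dominant afterwards and for the opposite events; traces are then averaged
#' across units with equal weight.
#'
#' @param spikes data.frame(unit_id, trial_id, time_ms).
#' @param alignments data.frame(trial_id, time_ms, percept): the percept
#'   dominant after the alignment point.
#' @param preferred named vector, unit_id -> "UP"/"DOWN"; its names define
#'   the unit selection.
#' @param bin_ms bin width (default 50, left-edge labelled, half-open).
#' @param window ms relative to the alignment.
#' @return object of class `psth`: list(time, preferred, nonpreferred,
#'   n_units) with rates in Hz.
#' @export
population_psth <- function(spikes, alignments, preferred, bin_ms = 50,
                            window = c(-1000, 1000)) {
  unit_ids <- names(preferred)
  if (!length(unit_ids)) stopf("empty unit selection")
  starts <- bin_starts(window, bin_ms)
  sum_p <- sum_n <- matrix(0, length(unit_ids), length(starts))
  for (i in seq_len(nrow(alignments))) {
    m <- aligned_counts(spikes, unit_ids, alignments$trial_id[i],
                        alignments$time_ms[i], starts, bin_ms)
    is_pref <- preferred == alignments$percept[i]
    sum_p[is_pref, ] <- sum_p[is_pref, ] + m[is_pref, , drop = FALSE]
    sum_n[!is_pref, ] <- sum_n[!is_pref, ] + m[!is_pref, , drop = FALSE]
  }
  ## per-unit event counts (preferred vs nonpreferred alignments)
  ev_pref <- vapply(unit_ids, function(u)
    sum(alignments$percept == preferred[[u]]), numeric(1))
  ev_non <- nrow(alignments) - ev_pref
  rate <- function(sums, nev) {
    per_unit <- sums / pmax(nev, 1) / (bin_ms / 1000)
    colMeans(per_unit[nev > 0, , drop = FALSE])
  }
  out <- list(time = starts, preferred = rate(sum_p, ev_pref),
              nonpreferred = rate(sum_n, ev_non),
              n_units = length(unit_ids), bin_ms = bin_ms)
  class(out) <- "psth"
  out
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("Population PSTH: %d units, %d bins of %g ms\n",
              x$n_units, length(x$time), x$bin_ms))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$preferred, x$nonpreferred), type = "l",
                    lty = c(1, 2), col = 1, xlab = "time (ms)",
                    ylab = "rate (Hz)", ...)
  graphics::legend("topleft", c("preferred", "nonpreferred"), lty = c(1, 2))
  invisible(x)
}

#' Min-max-normalized ensemble PSTHs around perceptual transitions
#'
#' For each transition and each ensemble (the units sharing a preferred
#' direction), the population-mean rate in `bin_ms` bins forms a population
#' vector; when `normalize` is TRUE each trace has its minimum subtracted
#' and is divided by the maximum of the min-subtracted trace (range [0,1]);
#' traces are then averaged over transitions by transition class (the
#' direction perceived afterwards).  Constant traces cannot be normalized
#' and are skipped with a warning.
#'
#' @param spikes data.frame(unit_id, trial_id, time_ms).
#' @param switches data.frame(trial_id, time_ms, to).
#' @param ensembles list(DOWN = unit ids, UP = unit ids).
#' @param bin_ms,window binning (50 ms bins by default).
#' @param normalize logical.
#' @param norm_max "after_min" (default; maximum taken after min
#'   subtraction, guaranteeing [0,1]) or "raw" (literal pre-subtraction
#'   maximum).
#' @return list(time, traces, n, skipped): `traces[[class]][[ensemble]]` is
#'   the averaged trace; `n` the transition counts per class.
#' @export
ensemble_psth <- function(spikes, switches, ensembles, bin_ms = 50,
                          window = c(-1000, 1000), normalize = TRUE,
                          norm_max = c("after_min", "raw")) {
  norm_max <- match.arg(norm_max)
  starts <- bin_starts(window, bin_ms)
  classes <- unique(switches$to)
  acc <- list(); nn <- setNames(integer(length(classes)), classes)
  skipped <- 0L
  for (cl in classes) acc[[cl]] <-
    lapply(ensembles, function(e) numeric(length(starts)))
  for (i in seq_len(nrow(switches))) {
    cl <- switches$to[i]
    traces <- lapply(ensembles, function(ids) {
      m <- aligned_counts(spikes, ids, switches$trial_id[i],
                          switches$time_ms[i], starts, bin_ms)
      colMeans(m) / (bin_ms / 1000)
    })
    if (normalize) {
      rng_ok <- vapply(traces, function(tr) diff(range(tr)) > 0, logical(1))
      if (!all(rng_ok)) { skipped <- skipped + 1L; next }
      traces <- lapply(traces, function(tr) {
        mx <- if (norm_max == "after_min") max(tr - min(tr)) else max(tr)
        (tr - min(tr)) / mx
      })
    }
    for (e in names(ensembles))
      acc[[cl]][[e]] <- acc[[cl]][[e]] + traces[[e]]
    nn[cl] <- nn[cl] + 1L
  }
  if (skipped) warnf("%d constant-rate transition(s) skipped", skipped)
  for (cl in classes) if (nn[cl] > 0)
    acc[[cl]] <- lapply(acc[[cl]], function(tr) tr / nn[cl])
  list(time = starts, traces = acc, n = nn, skipped = skipped)
}

#' Direction tuning curve of one unit
#'
#' Mean firing rate (Hz) over the stimulus window per motion direction.
#'
#' @param spikes data.frame(unit_id, trial_id, time_ms).
#' @param trials data.frame(trial_id, direction) with directions in degrees.
#' @param unit_id unit to analyse.
#' @param directions direction set (default the eight 45-degree steps).
#' @param window stimulus window, ms.
#' @return named numeric vector of mean rates; directions with no trials
#'   are NA.
#' @export
tuning_curve <- function(spikes, trials, unit_id,
                         directions = seq(0, 315, by = 45),
                         window = c(0, 1000)) {
  if (!any(trials$direction %in% directions))
    stopf("no trials for any requested direction")
  dur_s <- diff(window) / 1000
  out <- setNames(rep(NA_real_, length(directions)), directions)
  for (d in directions) {
    tid <- trials$trial_id[trials$direction == d]
    if (!length(tid)) next
    cnt <- vapply(tid, function(id)
      sum(spikes$unit_id == unit_id & spikes$trial_id == id &
            spikes$time_ms >= window[1] & spikes$time_ms < window[2]),
      numeric(1))
    out[as.character(d)] <- mean(cnt) / dur_s
  }
  out
}
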
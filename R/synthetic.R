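#' Configuration for synthetic no-report rivalry sessions
#'
#' Bundles every knob of the session generator.  Defaults describe a typical
#' recording: a 96-electrode array, trials of 8-10 s, gratings drifting at
#' 12 deg/s inside a +/-8 deg fixation window, gamma-distributed perceptual
#' dominance durations, and an optokinetic nystagmus (OKN) whose polarity
#' flips lag exogenous stimulus changes by 129.4 +/- 36.6 ms.
#'
#' @param n_units number of units.
#' @param baseline_rate firing rate (Hz) for the nonpreferred percept.
#' @param dprime_target_distribution length-2 numeric, mean and SD of the
#'   configured per-unit selectivity d'; draws are truncated at 0.
#' @param preferred_direction_fraction fraction of units preferring DOWN.
#' @param transient_gain multiplicative rate boost applied to all units for
#'   `transient_duration` ms after an exogenous (stimulus-driven) switch,
#'   emulating the feedforward transient that endogenous rivalry switches lack.
#' @param transient_duration ms.
#' @param pa_okn_latency length-2 numeric (mean, SD) in ms of the OKN polarity
#'   flip latency after a physical stimulus change.
#' @param gamma_dominance length-2 numeric (shape, scale in ms) of the
#'   dominance-duration distribution.
#' @param n_trials_per_type trials per paradigm (PA and BR).
#' @param n_trials_per_direction trials per motion direction for the fixation
#'   control paradigms (8 directions each).
#' @param trial_duration ms, must lie in [8000, 10000].
#' @param eye_fs eye-trace sampling rate, Hz.
#' @param raw_fs broadband sampling rate, Hz.
#' @param okn_slow_phase_speed slow-phase speed, deg/s.
#' @param okn_reset_threshold excursion (deg) at which a fast resetting
#'   saccade occurs.
#' @param noise_sd_eye positional noise SD, deg.
#' @param first_stim_duration candidate durations (ms) of the initial
#'   monocular phase, sampled per trial.
#' @param min_dominance ms; gamma draws below this are resampled (dominances
#'   this short are unusable by every downstream inclusion rule).
#' @param fixoff_late_gain rate gain in the 500-1000 ms post-stimulus window
#'   of Fixation-Off trials only (late OKN-linked modulation); 1 disables it.
#' @param seed integer master seed.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_units = 96,
                         baseline_rate = 10,
                         dprime_target_distribution = c(0.5, 0.5),
                         preferred_direction_fraction = 0.5,
                         transient_gain = 2,
                         transient_duration = 200,
                         pa_okn_latency = c(129.4, 36.6),
                         gamma_dominance = c(shape = 3, scale = 800),
                         n_trials_per_type = 20,
                         n_trials_per_direction = 20,
                         trial_duration = 9000,
                         eye_fs = 1000,
                         raw_fs = 30000,
                         okn_slow_phase_speed = 12,
                         okn_reset_threshold = 4,
                         noise_sd_eye = 0.1,
                         first_stim_duration = c(1000, 2000),
                         min_dominance = 300,
                         fixoff_late_gain = 1.25,
                         seed = 1L) {
  check_scalar_pos(n_units, "n_units")
  check_scalar_pos(baseline_rate, "baseline_rate", strict = FALSE)
  check_scalar_pos(gamma_dominance[[1]], "gamma shape")
  check_scalar_pos(gamma_dominance[[2]], "gamma scale")
  check_scalar_pos(transient_gain, "transient_gain")
  check_scalar_pos(okn_slow_phase_speed, "okn_slow_phase_speed")
  check_scalar_pos(okn_reset_threshold, "okn_reset_threshold")
  check_scalar_pos(eye_fs, "eye_fs")
  if (noise_sd_eye < 0) stopf("'noise_sd_eye' must be >= 0")
  if (trial_duration < 8000 || trial_duration > 10000)
    stopf("'trial_duration' must lie in [8000, 10000] ms")
  if (preferred_direction_fraction < 0 || preferred_direction_fraction > 1)
    stopf("'preferred_direction_fraction' must lie in [0, 1]")
  cfg <- list(
    n_units = as.integer(n_units), baseline_rate = baseline_rate,
    dprime_target_distribution = as.numeric(dprime_target_distribution),
    preferred_direction_fraction = preferred_direction_fraction,
    transient_gain = transient_gain, transient_duration = transient_duration,
    pa_okn_latency = as.numeric(pa_okn_latency),
    gamma_dominance = as.numeric(gamma_dominance),
    n_trials_per_type = as.integer(n_trials_per_type),
    n_trials_per_direction = as.integer(n_trials_per_direction),
    trial_duration = trial_duration, eye_fs = eye_fs, raw_fs = raw_fs,
    okn_slow_phase_speed = okn_slow_phase_speed,
    okn_reset_threshold = okn_reset_threshold, noise_sd_eye = noise_sd_eye,
    first_stim_duration = first_stim_duration,
    min_dominance = min_dominance, fixoff_late_gain = fixoff_late_gain,
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Sample perceptual dominance durations from a gamma distribution
#'
#' Dominance durations in multistable perception are well approximated by a
#' gamma distribution; this draws i.i.d. durations, optionally resampling
#' values below a minimum (very short dominances are excluded by every
#' downstream analysis rule and would only waste trial time).
#'
#' @param shape,scale gamma parameters; `scale` in ms.
#' @param n number of draws, >= 1.
#' @param min_duration draws below this (ms) are resampled.
#' @return numeric vector of `n` durations (ms).
#' @export
sample_dominance_durations <- function(shape, scale, n, min_duration = 0) {
  check_scalar_pos(shape, "shape"); check_scalar_pos(scale, "scale")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stopf("'n' must be >= 1")
  n <- as.integer(n)
  out <- rgamma(n, shape = shape, scale = scale)
  for (i in 1:50) {
    short <- out < min_duration
    if (!any(short)) break
    out[short] <- rgamma(sum(short), shape = shape, scale = scale)
  }
  out[out < min_duration] <- min_duration  # pathological configs only
  out
}

#' Preferred-percept firing rate achieving a target d'
#'
#' With the nonpreferred rate fixed at baseline and Poisson count variance in
#' a counting window, the preferred rate solving
#' d' = (mu_p - mu_np) / sqrt((Var_p + Var_np)/2) has the closed form
#' lambda_p = lambda_0 + (k + sqrt(k^2 + 8 k lambda_0)) / 2 with
#' k = d'^2 / (2 w), w the window in seconds.
#'
#' @param dprime target selectivity (>= 0).
#' @param baseline_rate nonpreferred rate, Hz.
#' @param window_ms counting window, ms.
#' @return preferred rate, Hz.
#' @export
rate_for_dprime <- function(dprime, baseline_rate, window_ms = 1000) {
  if (any(dprime < 0)) stopf("'dprime' must be >= 0")
  w <- window_ms / 1000
  k <- dprime^2 / (2 * w)
  baseline_rate + (k + sqrt(k^2 + 8 * k * baseline_rate)) / 2
}

## ---- percept timelines ----------------------------------------------------

## A timeline is a data.frame(onset, offset, percept, phase) tiling [0, dur).
## Switches: data.frame(time_ms, type, from, to, okn_time_ms).

make_trial_timeline <- function(paradigm, cfg, first_dir) {
  dur <- cfg$trial_duration
  other <- function(d) if (d == "UP") "DOWN" else "UP"
  mono <- sample(cfg$first_stim_duration, 1L)
  onsets <- c(0, mono)
  percepts <- c(first_dir, other(first_dir))
  phases <- c("PA_MONOCULAR",
              if (paradigm == "BR") "BFS_DOMINANCE" else "PA_MONOCULAR")
  types <- "EXOGENOUS"
  t <- mono
  repeat {
    d <- sample_dominance_durations(cfg$gamma_dominance[1],
                                    cfg$gamma_dominance[2], 1L,
                                    cfg$min_dominance)
    t <- t + d
    if (t >= dur) break
    onsets <- c(onsets, t)
    percepts <- c(percepts, other(percepts[length(percepts)]))
    phases <- c(phases,
                if (paradigm == "BR") "BR_DOMINANCE" else "PA_MONOCULAR")
    types <- c(types, if (paradigm == "BR") "ENDOGENOUS" else "EXOGENOUS")
  }
  timeline <- data.frame(onset = onsets,
                         offset = c(onsets[-1], dur),
                         percept = percepts, phase = phases,
                         stringsAsFactors = FALSE)
  ## one exogenous OKN latency draw per trial
  lat <- max(0, rnorm(1, cfg$pa_okn_latency[1], cfg$pa_okn_latency[2]))
  sw <- data.frame(time_ms = onsets[-1], type = types,
                   from = percepts[-length(percepts)], to = percepts[-1],
                   stringsAsFactors = FALSE)
  sw$okn_time_ms <- sw$time_ms + ifelse(sw$type == "EXOGENOUS", lat, 0)
  list(timeline = timeline, switches = sw, latency = lat, mono = mono)
}

## OKN-domain timeline: percept boundaries as seen by the eye (latency-shifted)
okn_timeline <- function(timeline, switches, dur) {
  on <- c(0, switches$okn_time_ms)
  on <- pmin(cummax(on), dur - 1)  # guard against a late latency draw
  data.frame(onset = on, offset = c(on[-1], dur),
             percept = timeline$percept[seq_along(on)],
             stringsAsFactors = FALSE)
}

#' Synthesize an OKN eye trace from a percept timeline
#'
#' The y coordinate is a sawtooth: slow phases drift at
#' `okn_slow_phase_speed` in the perceived motion direction (negative slope
#' for DOWN), interrupted by instantaneous fast resets once the excursion
#' reaches `okn_reset_threshold`; Gaussian positional noise is added.  The
#' trace stays inside the +/-8 deg fixation window (excursion is bounded by
#' the reset threshold).
#'
#' @param percept_timeline data.frame with columns onset, offset (ms) and
#'   percept ("UP"/"DOWN"), tiling the trial.  Pass boundaries already shifted
#'   by any OKN latency.
#' @param config a [synth_config()].
#' @param slope_scale optional per-trial multiplier on the slow-phase speed
#'   (used for oblique directions in the fixation paradigms); sign flips the
#'   drift direction, 0 yields a flat (fixation-like) trace.
#' @return data.frame(t, x, y): time in ms at `eye_fs`, position in degrees.
#' @export
synthesize_okn <- function(percept_timeline, config, slope_scale = 1) {
  dur <- max(percept_timeline$offset)
  n <- round(dur * config$eye_fs / 1000)
  t <- (seq_len(n) - 1L) * 1000 / config$eye_fs
  y <- numeric(n)
  theta <- config$okn_reset_threshold
  speed <- config$okn_slow_phase_speed * abs(slope_scale) / 1000  # deg/ms
  e0 <- 0  # excursion accumulated since last reset, carried across epochs
  for (i in seq_len(nrow(percept_timeline))) {
    idx <- t >= percept_timeline$onset[i] & t < percept_timeline$offset[i]
    if (!any(idx)) next
    tt <- t[idx] - percept_timeline$onset[i]
    if (speed == 0) { y[idx] <- 0; next }
    exc <- (e0 + speed * tt) %% theta
    dirn <- percept_timeline$percept[i]
    if (slope_scale < 0) dirn <- if (dirn == "UP") "DOWN" else "UP"
    y[idx] <- if (dirn == "DOWN") theta / 2 - exc else -theta / 2 + exc
    e0 <- (e0 + speed * (percept_timeline$offset[i] -
                           percept_timeline$onset[i])) %% theta
  }
  if (config$noise_sd_eye > 0) {
    y <- y + rnorm(n, 0, config$noise_sd_eye)
    x <- rnorm(n, 0, config$noise_sd_eye)
  } else x <- numeric(n)
  data.frame(t = t, x = x, y = y)
}

#' Synthesize an inhomogeneous-Poisson spike train for one unit
#'
#' The rate is `rate_pref` while the unit's preferred direction is perceived
#' and `rate_nonpref` otherwise; for `transient_duration` ms after every
#' EXOGENOUS switch the rate is multiplied by `transient_gain` (the
#' feedforward transient that accompanies a physical stimulus change but not
#' an endogenous rivalry switch).
#'
#' @param unit_params list/row with fields preferred, rate_pref, rate_nonpref.
#' @param percept_timeline timeline data.frame (onset, offset, percept).
#' @param switch_events data.frame(time_ms, type) (may have zero rows).
#' @param config a [synth_config()].
#' @return sorted numeric vector of spike times (ms).
#' @export
synthesize_spike_train <- function(unit_params, percept_timeline,
                                   switch_events, config) {
  if (unit_params$rate_pref < 0 || unit_params$rate_nonpref < 0)
    stopf("negative firing rate")
  dur <- max(percept_timeline$offset)
  ## piecewise-constant rate: percept boundaries + transient windows
  breaks <- sort(unique(c(0, dur, percept_timeline$onset,
                          percept_timeline$offset)))
  ex <- switch_events$time_ms[switch_events$type == "EXOGENOUS"]
  breaks <- sort(unique(c(breaks, ex, pmin(ex + config$transient_duration,
                                           dur))))
  breaks <- breaks[breaks >= 0 & breaks <= dur]
  a <- breaks[-length(breaks)]; b <- breaks[-1]
  mid <- (a + b) / 2
  seg_percept <- percept_timeline$percept[
    findInterval(mid, percept_timeline$onset)]
  rate <- ifelse(seg_percept == unit_params$preferred,
                 unit_params$rate_pref, unit_params$rate_nonpref)
  if (length(ex)) {
    in_tr <- vapply(mid, function(m)
      any(m >= ex & m < ex + config$transient_duration), logical(1))
    rate[in_tr] <- rate[in_tr] * config$transient_gain
  }
  ns <- rpois(length(a), rate * (b - a) / 1000)
  times <- unlist(mapply(function(k, lo, hi) runif(k, lo, hi),
                         ns, a, b, SIMPLIFY = FALSE), use.names = FALSE)
  sort(times)
}

#' Synthesize broadband voltage from spike times
#'
#' Gaussian noise plus a trough-aligned 45-sample waveform template inserted
#' at each spike time.  Insertions closer than 0.5 ms to the previous kept
#' insertion are rejected with a warning (they would violate the detector's
#' refractory assumption); the kept ground-truth times are returned.
#'
#' @param spike_times ms.
#' @param waveform_template length-45 numeric, trough-aligned (minimum at
#'   `trough_index`); see [default_waveform()].
#' @param noise_sd noise SD, microvolts.
#' @param raw_fs sampling rate, Hz.
#' @param duration_ms length of the output series.
#' @param trough_index sample index of the template trough (default 16).
#' @return list(voltage, fs, inserted_times_ms, inserted_index).
#' @export
synthesize_broadband <- function(spike_times, waveform_template, noise_sd,
                                 raw_fs = 30000,
                                 duration_ms = if (length(spike_times))
                                   max(spike_times) + 10 else 100,
                                 trough_index = 16L) {
  if (length(waveform_template) != 45L)
    stopf("waveform template must have 45 samples")
  n <- ceiling(duration_ms * raw_fs / 1000)
  v <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  st <- sort(spike_times)
  keep <- rep(TRUE, length(st))
  if (length(st) > 1) {
    last <- st[1]
    for (i in 2:length(st)) {
      if (st[i] - last < 0.5) keep[i] <- FALSE else last <- st[i]
    }
    if (any(!keep))
      warnf("%d insertion(s) closer than 0.5 ms rejected", sum(!keep))
  }
  st <- st[keep]
  for (s in st) {
    centre <- round(s * raw_fs / 1000) + 1L
    lo <- centre - (trough_index - 1L); hi <- lo + 44L
    if (lo < 1L || hi > n) next
    v[lo:hi] <- v[lo:hi] + waveform_template
  }
  list(voltage = v, fs = raw_fs, inserted_times_ms = st,
       inserted_index = round(st * raw_fs / 1000) + 1L)
}

#' Canonical extracellular spike waveform template
#'
#' A biphasic (negative trough, small repolarization hump) 45-sample template
#' at 30 kHz with its minimum at sample 16, scaled so that the trough equals
#' `-amplitude`.
#' @param amplitude trough depth, microvolts.
#' @return numeric length 45.
#' @export
default_waveform <- function(amplitude = 50) {
  i <- (1:45) - 16
  w <- -exp(-(i / 4)^2) + 0.35 * exp(-((i - 10) / 8)^2)
  w / max(abs(w)) * amplitude
}

## ---- full session ---------------------------------------------------------

#' Generate a complete synthetic session
#'
#' Produces trials, events, spikes, eye traces and ground truth for the four
#' paradigms.  PA trials carry a physical switch schedule; BR trials have an
#' initial monocular phase, a flash-suppression event, then endogenous
#' switches with gamma-distributed dominance durations.  Fixation-Off/On
#' trials present 1 s of motion in one of eight directions with / without
#' OKN.  Identical `(config, seed)` yields identical output.
#'
#' @param config a [synth_config()].
#' @param paradigms subset of c("PA","BR","FIX_OFF","FIX_ON").
#' @param seed integer; defaults to `config$seed`.
#' @param session_id label stored with the session.
#' @param units optional preset unit table (as in the returned
#'   `ground_truth$units`); used e.g. to model partial unit turnover across
#'   sessions by carrying part of another session's units over.
#' @return object of class `okn_session`: list(trials, events, spikes, eye,
#'   ground_truth, config, seed).  `spikes` is a data.frame(unit_id,
#'   trial_id, time_ms); `eye` a named list of data.frame(t, x, y).
#' @export
generate_session <- function(config = synth_config(),
                             paradigms = c("PA", "BR"),
                             seed = config$seed, session_id = "S1",
                             units = NULL) {
  stopifnot(inherits(config, "synth_config"))
  paradigms <- match.arg(paradigms, c("PA", "BR", "FIX_OFF", "FIX_ON"),
                         several.ok = TRUE)
  with_seed(seed, {
    if (is.null(units)) {
      units <- data.frame(
        unit_id = seq_len(config$n_units),
        electrode = ((seq_len(config$n_units) - 1L) %% 96L) + 1L,
        preferred = ifelse(
          runif(config$n_units) < config$preferred_direction_fraction,
          "DOWN", "UP"),
        dprime_target = pmax(0, rnorm(config$n_units,
                                      config$dprime_target_distribution[1],
                                      config$dprime_target_distribution[2])),
        stringsAsFactors = FALSE)
    }
    units$rate_nonpref <- config$baseline_rate
    units$rate_pref <- rate_for_dprime(units$dprime_target,
                                       config$baseline_rate)

    trials <- list(); events <- list(); spikes <- list(); eye <- list()
    percepts <- list(); switches <- list()
    tid <- 0L

    add_rivalry_trials <- function(paradigm) {
      n <- config$n_trials_per_type
      ## pseudorandomized balanced first direction and eye
      fd <- sample(rep(c("UP", "DOWN"), length.out = n))
      fe <- sample(rep(c("LEFT", "RIGHT"), length.out = n))
      for (k in seq_len(n)) {
        tid <<- tid + 1L
        tl <- make_trial_timeline(paradigm, config, fd[k])
        trials[[length(trials) + 1L]] <<- data.frame(
          trial_id = tid, paradigm = paradigm,
          duration_ms = config$trial_duration,
          first_direction = fd[k], first_eye = fe[k],
          direction = NA_real_, stringsAsFactors = FALSE)
        ev <- data.frame(
          trial_id = tid,
          time_ms = c(0, tl$switches$time_ms),
          type = c("STIM_ON",
                   ifelse(seq_len(nrow(tl$switches)) == 1L &
                            paradigm == "BR", "FLASH", "STIM_SWITCH")),
          direction = c(fd[k], tl$switches$to), stringsAsFactors = FALSE)
        events[[length(events) + 1L]] <<- ev
        pt <- tl$timeline; pt$trial_id <- tid
        percepts[[length(percepts) + 1L]] <<- pt
        sw <- tl$switches; sw$trial_id <- tid
        switches[[length(switches) + 1L]] <<- sw
        okn_tl <- okn_timeline(tl$timeline, tl$switches,
                               config$trial_duration)
        eye[[as.character(tid)]] <<- synthesize_okn(okn_tl, config)
        sp <- lapply(seq_len(nrow(units)), function(u)
          synthesize_spike_train(units[u, ], tl$timeline, tl$switches,
                                 config))
        nsp <- lengths(sp)
        spikes[[length(spikes) + 1L]] <<- data.frame(
          unit_id = rep(units$unit_id, nsp), trial_id = tid,
          time_ms = unlist(sp, use.names = FALSE))
      }
    }

    add_fixation_trials <- function(paradigm) {
      dirs <- rep(seq(0, 315, by = 45), each = config$n_trials_per_direction)
      dirs <- sample(dirs)  # pseudorandomized across trials
      for (d in dirs) {
        tid <<- tid + 1L
        trials[[length(trials) + 1L]] <<- data.frame(
          trial_id = tid, paradigm = paradigm, duration_ms = 1000,
          first_direction = NA_character_, first_eye = NA_character_,
          direction = d, stringsAsFactors = FALSE)
        events[[length(events) + 1L]] <<- data.frame(
          trial_id = tid, time_ms = 0, type = "STIM_ON",
          direction = as.character(d), stringsAsFactors = FALSE)
        ## vertical motion component drives the OKN (y only is analysed)
        vert <- sin(d * pi / 180)   # 90 deg = UP
        if (paradigm == "FIX_ON") vert <- 0
        tl <- data.frame(onset = 0, offset = 1000,
                         percept = if (vert < 0 ||
                                       (vert == 0 && d == 270)) "DOWN"
                         else "UP",
                         stringsAsFactors = FALSE)
        eye[[as.character(tid)]] <<-
          synthesize_okn(tl, config, slope_scale = abs(vert))
        ## cosine tuning between rate_nonpref and rate_pref
        pref_angle <- ifelse(units$preferred == "UP", 90, 270)
        tun <- (1 + cos((d - pref_angle) * pi / 180)) / 2
        rate <- units$rate_nonpref + (units$rate_pref -
                                        units$rate_nonpref) * tun
        gain_late <- if (paradigm == "FIX_OFF") config$fixoff_late_gain else 1
        sp <- lapply(seq_along(rate), function(u) {
          r1 <- rate[u]; r2 <- rate[u] * gain_late
          c(sort(runif(rpois(1, r1 * 0.5), 0, 500)),
            sort(runif(rpois(1, r2 * 0.5), 500, 1000)))
        })
        nsp <- lengths(sp)
        spikes[[length(spikes) + 1L]] <<- data.frame(
          unit_id = rep(units$unit_id, nsp), trial_id = tid,
          time_ms = unlist(sp, use.names = FALSE))
        pt <- data.frame(onset = 0, offset = 1000, percept = tl$percept,
                         phase = "PA_MONOCULAR", trial_id = tid,
                         stringsAsFactors = FALSE)
        percepts[[length(percepts) + 1L]] <<- pt
      }
    }

    for (p in paradigms) {
      if (p %in% c("PA", "BR")) add_rivalry_trials(p)
      else add_fixation_trials(p)
    }

    gt <- list(
      units = units,
      percepts = do.call(rbind, percepts),
      switches = if (length(switches)) do.call(rbind, switches) else
        data.frame(time_ms = numeric(), type = character(),
                   from = character(), to = character(),
                   okn_time_ms = numeric(), trial_id = integer()))
    out <- list(session_id = session_id,
                trials = do.call(rbind, trials),
                events = do.call(rbind, events),
                spikes = do.call(rbind, spikes),
                eye = eye, ground_truth = gt, config = config,
                seed = as.integer(seed))
    class(out) <- "okn_session"
    out
  })
}

#' @export
print.okn_session <- function(x, ...) {
  cat("Synthetic no-report rivalry session", x$session_id, "\n")
  tb <- table(x$trials$paradigm)
  cat("  trials: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  cat("  units:  ", nrow(x$ground_truth$units),
      sprintf(" (mean configured d' = %.2f)",
              mean(x$ground_truth$units$dprime_target)), "\n")
  cat("  spikes: ", nrow(x$spikes), "\n")
  invisible(x)
}
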
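#' Perceptual transitions usable for switch-aligned analyses
#'
#' From an epoch table, keeps transitions between consecutive epochs of a
#' trial whose pre- and post-switch dominances both last at least
#' `min_dominance` ms and whose inter-dominance gap is strictly less than
#' `max_gap` ms; the alignment point is the onset of the forward dominance.
#'
#' @param epochs data.frame(trial_id, onset, offset, percept, ...).
#' @param min_dominance ms (default 1000).
#' @param max_gap ms (default 250).
#' @param phases optional subset of epoch phases the *forward* dominance
#'   must belong to.
#' @return data.frame(trial_id, time_ms, from, to, phase).
#' @export
epoch_switches <- function(epochs, min_dominance = 1000, max_gap = 250,
                           phases = NULL) {
  out <- list()
  for (tid in unique(epochs$trial_id)) {
    ep <- epochs[epochs$trial_id == tid, ]
    ep <- ep[order(ep$onset), ]
    if (nrow(ep) < 2) next
    for (i in 2:nrow(ep)) {
      gap <- ep$onset[i] - ep$offset[i - 1]
      if (gap >= max_gap) next
      if (ep$offset[i - 1] - ep$onset[i - 1] < min_dominance) next
      if (ep$offset[i] - ep$onset[i] < min_dominance) next
      if (ep$percept[i] == ep$percept[i - 1]) next
      if (!is.null(phases) && !is.null(ep$phase) &&
          !(ep$phase[i] %in% phases)) next
      out[[length(out) + 1L]] <- data.frame(
        trial_id = tid, time_ms = ep$onset[i],
        from = ep$percept[i - 1], to = ep$percept[i],
        phase = if (!is.null(ep$phase)) ep$phase[i] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(trial_id = integer(), time_ms = numeric(),
                      from = character(), to = character(),
                      phase = character()))
  do.call(rbind, out)
}

count_spikes_window <- function(spikes, unit_ids, trial_id, lo, hi) {
  sp <- spikes[spikes$trial_id == trial_id &
                 spikes$time_ms >= lo & spikes$time_ms < hi, ]
  tab <- table(factor(sp$unit_id, levels = unit_ids))
  as.integer(tab)
}

#' Spike counts per unit in 1000 ms epoch windows
#'
#' Two modes mirror the two selectivity analyses.  `"dominance"`: every
#' epoch lasting at least `min_dominance` ms contributes one POST window
#' (first 1000 ms of the dominance).  `"switch"`: transitions passing
#' [epoch_switches()] contribute a PRE (-1000..0 ms) and POST (0..1000 ms)
#' window around the onset of the forward dominance, labelled with the
#' percept dominant in that window.
#'
#' @param spikes data.frame(unit_id, trial_id, time_ms).
#' @param epochs epoch table (see [segment_session()]).
#' @param mode "dominance" or "switch".
#' @param unit_ids units to count (default: all in `spikes`).
#' @param min_dominance,max_gap inclusion rules, ms.
#' @param window_ms counting-window length, ms.
#' @return data.frame(unit_id, trial_id, align_ms, window, percept, phase,
#'   count).
#' @export
extract_epoch_counts <- function(spikes, epochs,
                                 mode = c("dominance", "switch"),
                                 unit_ids = sort(unique(spikes$unit_id)),
                                 min_dominance = 1000, max_gap = 250,
                                 window_ms = 1000) {
  mode <- match.arg(mode)
  res <- list()
  add <- function(tid, align, win, lo, hi, percept, phase) {
    cnt <- count_spikes_window(spikes, unit_ids, tid, lo, hi)
    res[[length(res) + 1L]] <<- data.frame(
      unit_id = unit_ids, trial_id = tid, align_ms = align, window = win,
      percept = percept, phase = phase, count = cnt,
      stringsAsFactors = FALSE)
  }
  if (mode == "dominance") {
    keep <- (epochs$offset - epochs$onset) >= min_dominance
    ep <- epochs[keep, ]
    for (i in seq_len(nrow(ep)))
      add(ep$trial_id[i], ep$onset[i], "POST",
          ep$onset[i], ep$onset[i] + window_ms, ep$percept[i],
          if (!is.null(ep$phase)) ep$phase[i] else NA_character_)
  } else {
    sw <- epoch_switches(epochs, min_dominance, max_gap)
    for (i in seq_len(nrow(sw))) {
      add(sw$trial_id[i], sw$time_ms[i], "PRE",
          sw$time_ms[i] - window_ms, sw$time_ms[i], sw$from[i], sw$phase[i])
      add(sw$trial_id[i], sw$time_ms[i], "POST",
          sw$time_ms[i], sw$time_ms[i] + window_ms, sw$to[i], sw$phase[i])
    }
  }
  if (!length(res))
    return(data.frame(unit_id = integer(), trial_id = integer(),
                      align_ms = numeric(), window = character(),
                      percept = character(), phase = character(),
                      count = integer()))
  do.call(rbind, res)
}

#' Wilcoxon rank-sum selectivity between two count samples
#'
#' Two-sided rank-sum test comparing spike counts for DOWN vs UP; the
#' preferred direction is the one with the larger mean count (ties give
#' "NONE").  The exact null distribution is used when both samples have at
#' most `exact_max` values and there are no ties; otherwise the tie-corrected
#' normal approximation.
#'
#' @param counts_down,counts_up non-empty numeric vectors.
#' @param exact_max largest per-group n for the exact test.
#' @return list(p_value, preferred, significant) with alpha = 0.05.
#' @export
rank_sum_selectivity <- function(counts_down, counts_up, exact_max = 20) {
  if (!length(counts_down) || !length(counts_up))
    stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(counts_down, counts_up)) > 0
  use_exact <- !ties && length(counts_down) <= exact_max &&
    length(counts_up) <= exact_max
  p <- suppressWarnings(
    wilcox.test(counts_down, counts_up, exact = use_exact,
                correct = TRUE)$p.value)
  p <- min(1, p)
  md <- mean(counts_down); mu <- mean(counts_up)
  preferred <- if (md > mu) "DOWN" else if (mu > md) "UP" else "NONE"
  list(p_value = p, preferred = preferred, significant = p <= 0.05)
}

#' Selectivity index d'
#'
#' d' = (mu_p - mu_np) / sqrt((Var_p + Var_np) / 2), with sample (n-1)
#' variances by default.  The preferred/nonpreferred designation is fixed
#' upstream (from PA trials), so d' computed on rivalry counts can be
#' negative.
#'
#' @param counts_pref,counts_nonpref numeric vectors with >= 2 values each.
#' @param var_type "sample" (n-1) or "population" (n).
#' @return dimensionless scalar.
#' @export
dprime <- function(counts_pref, counts_nonpref,
                   var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  if (length(counts_pref) < 2 || length(counts_nonpref) < 2)
    stopf("need at least 2 values per sample")
  vfun <- function(x) if (var_type == "sample") var(x)
    else mean((x - mean(x))^2)
  vp <- vfun(counts_pref); vnp <- vfun(counts_nonpref)
  if (vp == 0 && vnp == 0)
    stopf("undefined d': both samples have zero variance")
  (mean(counts_pref) - mean(counts_nonpref)) / sqrt((vp + vnp) / 2)
}

#' Per-unit selectivity records across a sensory and a perceptual condition
#'
#' Combines rank-sum selectivity and d' for each unit from two count tables
#' (typically PA = sensory and BR = perceptual, or Fixation-Off/On).  The
#' preferred/nonpreferred designation for both d' values comes from the
#' first (sensory) condition, so the second d' is negative when the unit's
#' preference reverses.
#'
#' @param counts_a,counts_b data.frames from [extract_epoch_counts()]
#'   (columns unit_id, percept, count); condition A fixes the preference.
#' @param labels length-2 names for the conditions (used in column names).
#' @return data.frame(unit_id, p_a, preferred_a, dprime_a, p_b, preferred_b,
#'   dprime_b, category); see [categorize_units()].
#' @export
selectivity_records <- function(counts_a, counts_b,
                                labels = c("pa", "br")) {
  units <- sort(unique(c(counts_a$unit_id, counts_b$unit_id)))
  one <- function(cc, uid) {
    d <- cc$count[cc$unit_id == uid & cc$percept == "DOWN"]
    u <- cc$count[cc$unit_id == uid & cc$percept == "UP"]
    list(down = d, up = u)
  }
  rows <- lapply(units, function(uid) {
    a <- one(counts_a, uid); b <- one(counts_b, uid)
    ra <- rank_sum_selectivity(a$down, a$up)
    rb <- rank_sum_selectivity(b$down, b$up)
    ## preference designated from condition A; ties fall back to DOWN so a
    ## d' (necessarily ~0) can still be reported
    pref <- if (ra$preferred == "NONE") "DOWN" else ra$preferred
    pick <- function(s) if (pref == "DOWN") list(p = s$down, np = s$up)
      else list(p = s$up, np = s$down)
    da <- tryCatch(do.call(dprime, unname(pick(a))), error = function(e) NA)
    db <- tryCatch(do.call(dprime, unname(pick(b))), error = function(e) NA)
    data.frame(unit_id = uid,
               p_a = ra$p_value, preferred_a = ra$preferred, dprime_a = da,
               p_b = rb$p_value, preferred_b = rb$preferred, dprime_b = db,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  names(rec) <- c("unit_id",
                  paste0(c("p_", "preferred_", "dprime_"), labels[1]),
                  paste0(c("p_", "preferred_", "dprime_"), labels[2]))
  rec$category <- categorize_units(rec, labels)$category
  rec
}

#' Categorize units by sensory vs. perceptual selectivity
#'
#' Each unit falls in exactly one of: BOTH_SAME (significant in both
#' conditions, same preferred direction), SUPPRESSED_PREFERENCE (significant
#' in both with opposite preference, i.e. fires more when its sensory
#' preference is perceptually suppressed), A_ONLY / B_ONLY (significant in
#' one condition), NONE.
#'
#' @param records data.frame as produced by [selectivity_records()].
#' @param labels the two condition labels used in `records` column names.
#' @param alpha significance level (default 0.05).
#' @return list(category = per-unit factor, tally = named counts).
#' @export
categorize_units <- function(records, labels = c("pa", "br"),
                             alpha = 0.05) {
  pa <- records[[paste0("p_", labels[1])]]
  pb <- records[[paste0("p_", labels[2])]]
  fa <- records[[paste0("preferred_", labels[1])]]
  fb <- records[[paste0("preferred_", labels[2])]]
  sa <- pa <= alpha & fa != "NONE"
  sb <- pb <= alpha & fb != "NONE"
  cat_names <- c("BOTH_SAME", "SUPPRESSED_PREFERENCE",
                 paste0(toupper(labels[1]), "_ONLY"),
                 paste0(toupper(labels[2]), "_ONLY"), "NONE")
  category <- ifelse(sa & sb & fa == fb, cat_names[1],
              ifelse(sa & sb, cat_names[2],
              ifelse(sa, cat_names[3],
              ifelse(sb, cat_names[4], cat_names[5]))))
  category <- factor(category, levels = cat_names)
  list(category = category, tally = table(category))
}

#' d' difference between the two fixation-control paradigms
#'
#' For each unit and time window (by default the first and last 500 ms of
#' the stimulus), computes d'(Fixation Off) - d'(Fixation On) and tests the
#' mean difference against zero with a two-sided one-sample t-test.
#'
#' @param counts_off,counts_on data.frames(unit_id, percept, window, count)
#'   with windows "FIRST" and "LAST" (see [fixation_counts()]).
#' @param preferred optional named character vector unit_id -> "UP"/"DOWN";
#'   by default designated from the Fixation-Off mean counts pooled over
#'   windows.
#' @return list(per_unit = data.frame(unit_id, window, dprime_off,
#'   dprime_on, delta), tests = per-window htest list, means = named means).
#' @export
dprime_difference_control <- function(counts_off, counts_on,
                                      preferred = NULL) {
  units <- sort(intersect(unique(counts_off$unit_id),
                          unique(counts_on$unit_id)))
  if (length(units) < 3) stopf("need at least 3 units in both paradigms")
  if (is.null(preferred)) {
    preferred <- vapply(units, function(uid) {
      cc <- counts_off[counts_off$unit_id == uid, ]
      md <- mean(cc$count[cc$percept == "DOWN"])
      mu <- mean(cc$count[cc$percept == "UP"])
      if (md >= mu) "DOWN" else "UP"
    }, character(1))
    names(preferred) <- units
  }
  windows <- intersect(c("FIRST", "LAST"), unique(counts_off$window))
  rows <- list()
  for (w in windows) for (uid in units) {
    dp <- function(cc) {
      cc <- cc[cc$unit_id == uid & cc$window == w, ]
      p <- cc$count[cc$percept == preferred[[as.character(uid)]]]
      np <- cc$count[cc$percept != preferred[[as.character(uid)]]]
      tryCatch(dprime(p, np), error = function(e) NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = uid, window = w,
      dprime_off = dp(counts_off), dprime_on = dp(counts_on),
      stringsAsFactors = FALSE)
  }
  per_unit <- do.call(rbind, rows)
  per_unit$delta <- per_unit$dprime_off - per_unit$dprime_on
  tests <- lapply(setNames(windows, windows), function(w) {
    d <- per_unit$delta[per_unit$window == w]
    d <- d[is.finite(d)]
    t.test(d, mu = 0)
  })
  means <- vapply(tests, function(h) unname(h$estimate), numeric(1))
  list(per_unit = per_unit, tests = tests, means = means)
}

#' Spike counts per direction for the fixation-control paradigms
#'
#' Counts spikes of vertical-motion trials (UP/DOWN) of one fixation
#' paradigm in the requested post-stimulus windows.
#'
#' @param session an `okn_session`-like list.
#' @param paradigm "FIX_OFF" or "FIX_ON".
#' @param windows named list of length-2 ms windows.
#' @param trial_ids optional subset of trials.
#' @return data.frame(unit_id, trial_id, percept, window, count).
#' @export
fixation_counts <- function(session, paradigm,
                            windows = list(FIRST = c(0, 500),
                                           LAST = c(500, 1000),
                                           FULL = c(0, 1000)),
                            trial_ids = NULL) {
  tr <- session$trials[session$trials$paradigm == paradigm &
                         session$trials$direction %in% c(90, 270), ]
  if (!is.null(trial_ids)) tr <- tr[tr$trial_id %in% trial_ids, ]
  unit_ids <- sort(unique(session$spikes$unit_id))
  res <- list()
  for (i in seq_len(nrow(tr))) {
    pct <- if (tr$direction[i] == 90) "UP" else "DOWN"
    for (w in names(windows)) {
      cnt <- count_spikes_window(session$spikes, unit_ids, tr$trial_id[i],
                                 windows[[w]][1], windows[[w]][2])
      res[[length(res) + 1L]] <- data.frame(
        unit_id = unit_ids, trial_id = tr$trial_id[i], percept = pct,
        window = w, count = cnt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
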
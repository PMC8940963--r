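#' Alignment-event (exemplar) tables for decoding
#'
#' Derives the per-session exemplar tables the decoder consumes: one row per
#' usable alignment event with its class label (the direction perceived /
#' presented afterwards).
#'
#' `kind = "switch"` uses perceptual or stimulus transitions passing the
#' inclusion rules (both dominances >= 1000 ms, gap < 250 ms).
#' `kind = "bfs"` uses the onset of flash-suppression dominance epochs of at
#' least 1000 ms.  `kind = "stimulus"` uses the vertical-motion trials of a
#' fixation paradigm, aligned to stimulus onset.
#'
#' @param session an `okn_session`-like list.
#' @param epochs epoch table ([segment_session()] / [epochs_from_events()]);
#'   required for "switch" and "bfs".
#' @param kind exemplar type.
#' @param paradigm for "stimulus": "FIX_OFF" or "FIX_ON".
#' @param min_dominance,max_gap inclusion rules, ms.
#' @param trial_ids optional subset of trials.
#' @return data.frame(trial_id, time_ms, label).
#' @export
make_exemplars <- function(session, epochs = NULL,
                           kind = c("switch", "bfs", "stimulus"),
                           paradigm = "FIX_OFF", min_dominance = 1000,
                           max_gap = 250, trial_ids = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    switch = {
      sw <- epoch_switches(epochs, min_dominance, max_gap)
      data.frame(trial_id = sw$trial_id, time_ms = sw$time_ms,
                 label = sw$to, stringsAsFactors = FALSE)
    },
    bfs = {
      ep <- epochs[epochs$phase == "BFS_DOMINANCE" &
                     (epochs$offset - epochs$onset) >= min_dominance, ]
      data.frame(trial_id = ep$trial_id, time_ms = ep$onset,
                 label = ep$percept, stringsAsFactors = FALSE)
    },
    stimulus = {
      tr <- session$trials[session$trials$paradigm == paradigm &
                             session$trials$direction %in% c(90, 270), ]
      data.frame(trial_id = tr$trial_id, time_ms = 0,
                 label = ifelse(tr$direction == 90, "UP", "DOWN"),
                 stringsAsFactors = FALSE)
    })
  if (!is.null(trial_ids)) out <- out[out$trial_id %in% trial_ids, ]
  out
}
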
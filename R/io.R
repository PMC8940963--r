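#' Write a session to plain-text files
#'
#' Lays a session out as portable text: `trials.csv` (with the trial's
#' events as a JSON column), `spikes.csv` (unit_id, trial_id, time_ms),
#' `eye.csv` (trial_id, t, x, y, long format) and `ground_truth.json`.
#'
#' @param session an `okn_session`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  tr$events <- vapply(tr$trial_id, function(tid)
    as.character(jsonlite::toJSON(
      session$events[session$events$trial_id == tid,
                     c("time_ms", "type", "direction")],
      auto_unbox = FALSE, digits = NA)), character(1))
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(session$spikes, file.path(dir, "spikes.csv"),
            row.names = FALSE)
  eye <- do.call(rbind, lapply(names(session$eye), function(id)
    cbind(trial_id = as.integer(id), session$eye[[id]])))
  write.csv(eye, file.path(dir, "eye.csv"), row.names = FALSE)
  jsonlite::write_json(session$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a session written by [write_session()]
#' @param dir directory.
#' @return an `okn_session`-like list (without the generating config).
#' @export
read_session <- function(dir) {
  tr <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  events <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    ev <- jsonlite::fromJSON(tr$events[i])
    if (!length(ev)) return(NULL)
    cbind(trial_id = tr$trial_id[i], as.data.frame(ev))
  }))
  tr$events <- NULL
  spikes <- read.csv(file.path(dir, "spikes.csv"),
                     stringsAsFactors = FALSE)
  eye_long <- read.csv(file.path(dir, "eye.csv"), stringsAsFactors = FALSE)
  eye <- split(eye_long[, c("t", "x", "y")], eye_long$trial_id)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  gt$units <- as.data.frame(gt$units)
  gt$percepts <- as.data.frame(gt$percepts)
  gt$switches <- as.data.frame(gt$switches)
  out <- list(session_id = basename(dir), trials = tr, events = events,
              spikes = spikes, eye = eye, ground_truth = gt)
  class(out) <- "okn_session"
  out
}
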
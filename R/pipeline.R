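#' Default pipeline configuration
#'
#' Returns the full stage/parameter configuration for [run_pipeline()],
#' which can also be loaded from a YAML or JSON file.  Every stochastic
#' stage has an explicit seed derived from `seed`.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param stages stages to run, in dependency order.
#' @param ... named overrides of any config entry.
#' @return a nested list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("okdrun"),
                               stages = c("simulate", "segment",
                                          "selectivity", "psth", "decode"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    synth = list(n_units = 40, n_trials_per_type = 15,
                 dprime_mean = 1.0, dprime_sd = 0.5),
    segment = list(min_stable = 300),
    decode = list(n_splits = 10, n_resamples = 20, n_perm = 500,
                  window = c(200, 600), run_permutation = FALSE))
  over <- list(...)
  for (nm in names(over)) cfg[[nm] ] <- over[[nm]]
  cfg
}

load_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_run_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate, segment,
#' selectivity, psth, decode — writing machine-readable artifacts (CSV/JSON)
#' and a `manifest.json` listing every artifact with the parameters and
#' seeds that produced it.  Reruns with an unchanged config rewrite
#' identical outputs.
#'
#' @param config a config list from [default_run_config()] or a path to a
#'   YAML/JSON file.
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  stages <- config$stages
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = stages, artifacts = list(),
                   parameters = config[setdiff(names(config), "out_dir")])
  art <- function(name, path, ...) {
    manifest$artifacts[[name]] <<- c(list(path = basename(path)), list(...))
  }
  session <- NULL; epochs_br <- NULL; epochs_pa <- NULL

  if ("simulate" %in% stages) {
    sc <- synth_config(n_units = config$synth$n_units,
                       n_trials_per_type = config$synth$n_trials_per_type,
                       dprime_target_distribution =
                         c(config$synth$dprime_mean, config$synth$dprime_sd),
                       seed = derive_seed(config$seed, 1L))
    session <- generate_session(sc)
    sdir <- file.path(config$out_dir, "session")
    write_session(session, sdir)
    art("session", sdir, n_units = sc$n_units, seed = session$seed)
  }
  if (is.null(session)) stopf("stage 'simulate' is required (no input set)")

  if ("segment" %in% stages) {
    epochs_br <- segment_session(session, "BR",
                                 min_stable = config$segment$min_stable)
    epochs_pa <- epochs_from_events(session, "PA")
    ep <- rbind(epochs_br, epochs_pa)
    p <- file.path(config$out_dir, "epochs.csv")
    write.csv(ep[, c("trial_id", "onset", "offset", "percept", "phase",
                     "source")], p, row.names = FALSE)
    art("epochs", p, n_epochs = nrow(ep))
    dom <- epochs_br[epochs_br$phase == "BR_DOMINANCE", ]
    durs <- dom$offset - dom$onset
    if (length(durs) >= 10 && var(durs) > 0) {
      gf <- fit_dominance_gamma(durs)
      p <- file.path(config$out_dir, "gamma_fit.json")
      jsonlite::write_json(list(shape = gf$shape, scale = gf$scale,
                                loglik = gf$loglik, n = gf$n), p,
                           auto_unbox = TRUE, digits = NA)
      art("gamma_fit", p, shape = gf$shape, scale = gf$scale)
    }
  }

  if ("selectivity" %in% stages) {
    if (is.null(epochs_br)) stopf("stage 'selectivity' requires 'segment'")
    cpa <- extract_epoch_counts(session$spikes, epochs_pa)
    cbr <- extract_epoch_counts(session$spikes, epochs_br[
      epochs_br$phase %in% c("BFS_DOMINANCE", "BR_DOMINANCE"), ])
    rec <- selectivity_records(cpa, cbr)
    p <- file.path(config$out_dir, "selectivity.csv")
    write.csv(rec, p, row.names = FALSE)
    tal <- table(rec$category)
    pj <- file.path(config$out_dir, "unit_categories.json")
    jsonlite::write_json(as.list(tal), pj, auto_unbox = TRUE, digits = NA)
    art("selectivity", p, n_units = nrow(rec))
    art("unit_categories", pj)
  }

  if ("psth" %in% stages) {
    if (is.null(epochs_br)) stopf("stage 'psth' requires 'segment'")
    sw <- epoch_switches(epochs_br)
    if (nrow(sw) > 0) {
      pref <- setNames(session$ground_truth$units$preferred,
                       session$ground_truth$units$unit_id)
      ps <- population_psth(session$spikes,
                            data.frame(trial_id = sw$trial_id,
                                       time_ms = sw$time_ms,
                                       percept = sw$to), pref)
      p <- file.path(config$out_dir, "population_psth.csv")
      write.csv(data.frame(time_ms = ps$time, preferred = ps$preferred,
                           nonpreferred = ps$nonpreferred,
                           n = ps$n_units), p, row.names = FALSE)
      art("population_psth", p, n_units = ps$n_units)
    }
  }

  if ("decode" %in% stages) {
    if (is.null(epochs_br)) stopf("stage 'decode' requires 'segment'")
    dc <- config$decode
    win <- dc$window
    ex_br <- make_exemplars(session, epochs_br, "switch")
    ex_pa <- make_exemplars(session, epochs_pa, "switch")
    res <- list()
    for (tt in c("PA", "BR")) {
      ex <- if (tt == "PA") ex_pa else ex_br
      npc <- min(table(ex$label))
      if (npc < dc$n_splits) next
      pop <- build_pseudopopulation(session, ex,
                                    n_per_class = min(npc, 2L *
                                                        dc$n_splits),
                                    bin_ms = diff(win), step_ms = diff(win),
                                    window = win,
                                    seed = derive_seed(config$seed, 20L))
      if (isTRUE(dc$run_permutation)) {
        r <- permutation_test(pop, n_perm = dc$n_perm,
                              n_splits = dc$n_splits,
                              n_resamples = dc$n_resamples,
                              seed = derive_seed(config$seed, 21L))
        res[[tt]] <- list(accuracy = as.numeric(r$accuracy),
                          sd = as.numeric(r$sd),
                          p_estimate = r$p_estimate,
                          null_mean = mean(r$null_distribution))
        write.csv(data.frame(null_accuracy = r$null_distribution),
                  file.path(config$out_dir,
                            paste0("null_", tt, ".csv")),
                  row.names = FALSE)
      } else {
        r <- cross_validated_accuracy(pop, n_splits = dc$n_splits,
                                      n_resamples = dc$n_resamples,
                                      seed = derive_seed(config$seed, 21L))
        res[[tt]] <- list(accuracy = r$accuracy, sd = r$sd)
      }
    }
    p <- file.path(config$out_dir, "decoding.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    art("decoding", p, n_splits = dc$n_splits,
        n_resamples = dc$n_resamples,
        seed = derive_seed(config$seed, 21L))
  }

  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' @param manifest a manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`; artifact files are read from the same directory.
#' @return character vector of report lines, invisibly; also printed.
#' @export
report <- function(manifest) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  } else dir <- "."
  lines <- c("Pipeline report", sprintf("  seed: %s", manifest$seed),
             sprintf("  stages: %s",
                     paste(unlist(manifest$stages), collapse = ", ")))
  a <- manifest$artifacts
  grab <- function(name) {
    f <- file.path(dir, a[[name]]$path)
    if (!is.null(a[[name]]) && file.exists(f)) f else NULL
  }
  if (!is.null(f <- grab("gamma_fit"))) {
    g <- jsonlite::fromJSON(f)
    lines <- c(lines, sprintf(
      "  dominance gamma fit: shape %.2f, scale %.0f ms (n = %d)",
      g$shape, g$scale, g$n))
  }
  if (!is.null(f <- grab("unit_categories"))) {
    g <- jsonlite::fromJSON(f)
    lines <- c(lines, paste0("  unit categories: ",
                             paste(names(g), unlist(g), sep = "=",
                                   collapse = ", ")))
  }
  if (!is.null(f <- grab("decoding"))) {
    g <- jsonlite::fromJSON(f)
    for (tt in names(g)) {
      ln <- sprintf("  decoding %s: %.1f%% (SD %.1f)", tt,
                    g[[tt]]$accuracy, g[[tt]]$sd)
      if (!is.null(g[[tt]]$p_estimate))
        ln <- paste0(ln, sprintf(", permutation p = %.5f",
                                 g[[tt]]$p_estimate))
      lines <- c(lines, ln)
    }
  }
  if (is.null(a$selectivity) && length(a) > 0 &&
      !("selectivity" %in% unlist(manifest$stages)))
    lines <- c(lines, "  (selectivity stage not run)")
  cat(lines, sep = "\n")
  invisible(lines)
}
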
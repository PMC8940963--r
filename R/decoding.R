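#' Maximum-correlation-coefficient classifier
#'
#' Fits one template per class (the mean training vector) and predicts the
#' class whose template has the maximal Pearson correlation with a test
#' vector.  Ties, and test vectors with zero variance (undefined
#' correlation), resolve to the lexicographically first class label.
#'
#' @param x numeric matrix, exemplars x features (>= 2 features).
#' @param y class labels, one per row.
#' @return object of class `mcc_classifier`.
#' @export
mcc_fit <- function(x, y) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least 2 features")
  y <- factor(y)
  if (any(table(y) < 1)) stopf("need >= 1 training exemplar per class")
  templates <- rowsum(x, y) / as.vector(table(y))
  out <- list(templates = templates, classes = levels(y))
  class(out) <- "mcc_classifier"
  out
}

#' @param object an `mcc_classifier`.
#' @param newdata matrix of test vectors (rows).
#' @param ... unused.
#' @return factor of predicted classes; attribute `"flagged"` marks test
#'   vectors whose correlation was undefined (zero variance).
#' @rdname mcc_fit
#' @export
predict.mcc_classifier <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (is.null(dim(nd)) || ncol(nd) != ncol(object$templates))
    nd <- matrix(nd, ncol = ncol(object$templates))
  r <- suppressWarnings(cor(t(nd), t(object$templates)))
  flagged <- apply(nd, 1, sd) == 0
  r[!is.finite(r)] <- -Inf
  pred <- apply(r, 1, function(z) {
    if (all(!is.finite(z))) 1L else which.max(z)
  })
  pred[flagged] <- 1L  # tie-break: first class
  structure(factor(object$classes[pred], levels = object$classes),
            flagged = flagged)
}

#' @export
print.mcc_classifier <- function(x, ...) {
  cat(sprintf("Maximum-correlation classifier: %d classes, %d features\n",
              nrow(x$templates), ncol(x$templates)))
  invisible(x)
}

## ---- pseudopopulation -----------------------------------------------------

## sub-bin counting: counts in `step`-wide sub-bins, then a sliding sum
## builds the (bin_ms, step) grid.
exemplar_bin_counts <- function(spikes, unit_ids, exemplars, starts,
                                bin_ms, step) {
  nsub <- (starts[length(starts)] + bin_ms - starts[1]) / step
  B <- length(starts); k <- bin_ms / step
  E <- nrow(exemplars)
  out <- array(0L, c(E, length(unit_ids), B))
  for (i in seq_len(E)) {
    sp <- spikes[spikes$trial_id == exemplars$trial_id[i], ]
    rel <- sp$time_ms - exemplars$time_ms[i]
    keep <- rel >= starts[1] & rel < starts[1] + nsub * step
    sp <- sp[keep, ]; rel <- rel[keep]
    sub <- matrix(0L, length(unit_ids), nsub)
    if (nrow(sp)) {
      b <- floor((rel - starts[1]) / step) + 1L
      tab <- table(factor(sp$unit_id, levels = unit_ids),
                   factor(b, levels = seq_len(nsub)))
      sub[] <- as.integer(tab)
    }
    for (b in seq_len(B)) {
      cols <- b:(b + k - 1L)
      out[i, , b] <- rowSums(sub[, cols, drop = FALSE])
    }
  }
  out
}

#' Assemble a pseudopopulation feature stream
#'
#' Combines units recorded in separate sessions into one feature matrix per
#' time bin, pairing exemplars (switches) across sessions by index within
#' class.  Spike counts are taken in sliding bins (`bin_ms` wide, sampled
#' every `step_ms`) around each exemplar's alignment time.  Features with
#' zero variance over all exemplars and bins are dropped at assembly.
#'
#' @param sessions list of `okn_session`-like objects (or a single one).
#' @param exemplars list (one per session) of data.frames(trial_id,
#'   time_ms, label) giving alignment events and their class labels.
#' @param n_per_class exemplars drawn per class per session; default the
#'   largest count available in every session.
#' @param bin_ms,step_ms bin width and step (defaults 150 and 50).
#' @param window ms around the alignment; bins start at
#'   `seq(window[1], window[2] - bin_ms, step_ms)`.
#' @param features "unit" or "electrode" (electrode-summed spikes, for
#'   cross-session correspondence).
#' @param seed RNG seed for the exemplar draw.
#' @return object of class `pseudopopulation`: list(counts = exemplars x
#'   features x bins array, labels, bin_start, session_of_feature,
#'   feature_id).  Rows are class-blocked; counts are raw (z-scoring is done
#'   per decoding fold).
#' @export
build_pseudopopulation <- function(sessions, exemplars, n_per_class = NULL,
                                   bin_ms = 150, step_ms = 50,
                                   window = c(-1000, 1000),
                                   features = c("unit", "electrode"),
                                   seed = 1L) {
  features <- match.arg(features)
  if (inherits(sessions, "okn_session")) sessions <- list(sessions)
  if (is.data.frame(exemplars)) exemplars <- list(exemplars)
  stopifnot(length(sessions) == length(exemplars))
  classes <- sort(unique(unlist(lapply(exemplars, function(e) e$label))))
  avail <- vapply(seq_along(sessions), function(s)
    min(table(factor(exemplars[[s]]$label, levels = classes))), numeric(1))
  if (is.null(n_per_class)) n_per_class <- min(avail)
  short <- which(avail < n_per_class)
  if (length(short))
    stopf("session %s has fewer than %d exemplars in some class",
          paste(short, collapse = ","), n_per_class)
  starts <- seq(window[1], window[2] - bin_ms, by = step_ms)
  with_seed(seed, {
    blocks <- list(); sess_of <- integer(); fid <- character()
    for (s in seq_along(sessions)) {
      ses <- sessions[[s]]
      sp <- ses$spikes
      if (features == "electrode") {
        map <- ses$ground_truth$units
        sp$unit_id <- map$electrode[match(sp$unit_id, map$unit_id)]
      }
      uids <- sort(unique(sp$unit_id))
      ex <- exemplars[[s]]
      pick <- do.call(rbind, lapply(classes, function(cl) {
        rows <- ex[ex$label == cl, ]
        rows[sample(nrow(rows), n_per_class), ]
      }))
      cnt <- exemplar_bin_counts(sp, uids, pick, starts, bin_ms, step_ms)
      blocks[[s]] <- cnt
      sess_of <- c(sess_of, rep(s, length(uids)))
      fid <- c(fid, paste0("s", s, if (features == "electrode") "_e" else
        "_u", uids))
    }
    counts <- do.call(abind_units, blocks)
    labels <- factor(rep(classes, each = n_per_class), levels = classes)
    ## degenerate-feature rule: drop features constant everywhere
    keep <- apply(counts, 2, function(m) var(as.vector(m)) > 0)
    counts <- counts[, keep, , drop = FALSE]
    out <- list(counts = counts, labels = labels, bin_start = starts,
                bin_ms = bin_ms, step_ms = step_ms,
                session_of_feature = sess_of[keep],
                feature_id = fid[keep], classes = classes,
                n_per_class = n_per_class)
    class(out) <- "pseudopopulation"
    out
  })
}

## bind count arrays along the feature dimension
abind_units <- function(...) {
  xs <- list(...)
  E <- dim(xs[[1]])[1]; B <- dim(xs[[1]])[3]
  Fs <- vapply(xs, function(a) dim(a)[2], numeric(1))
  out <- array(0L, c(E, sum(Fs), B))
  at <- 0L
  for (a in xs) {
    out[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  out
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf(
    "Pseudopopulation: %d exemplars (%s), %d features, %d bins (%g ms, step %g ms)\n",
    dim(x$counts)[1],
    paste(levels(x$labels), table(x$labels), sep = "=", collapse = ", "),
    dim(x$counts)[2], dim(x$counts)[3], x$bin_ms, x$step_ms))
  invisible(x)
}

## z-score columns of a train matrix, apply to test; sd 0 -> 0
## (colSums arithmetic instead of apply(.., sd): this sits in the innermost
## cross-validation loop)
zscore_apply <- function(train, test) {
  n <- nrow(train)
  mu <- colMeans(train)
  sdv <- sqrt(pmax(0, (colSums(train * train) - n * mu^2) / (n - 1)))
  inv <- ifelse(sdv > 0, 1 / sdv, 0)
  nt <- nrow(test)
  list(train = (train - rep(mu, each = n)) * rep(inv, each = n),
       test = (test - rep(mu, each = nt)) * rep(inv, each = nt))
}

## centre and L2-normalize each (class/exemplar, bin) vector across features;
## m is rows x (F*B) with feature fastest. Returns same shape.
corr_normalize <- function(m, F, B) {
  out <- m
  for (b in seq_len(B)) {
    cols <- (b - 1L) * F + seq_len(F)
    v <- m[, cols, drop = FALSE]
    v <- v - rowMeans(v)
    nrm <- sqrt(rowSums(v^2))
    nrm[nrm == 0] <- Inf
    out[, cols] <- v / nrm
  }
  out[!is.finite(out)] <- 0
  out
}

#' Cross-validated decoding accuracy of a pseudopopulation
#'
#' The workhorse behind single-window decoding and cross-temporal
#' generalization.  Per resample run, exemplars are re-paired across
#' sessions and re-drawn, split into `n_splits` folds with one exemplar per
#' class per fold in the test set; counts are z-scored with training-fold
#' statistics (by default), class templates are the mean training vectors,
#' and a test vector is assigned to the class with the maximally correlated
#' template (zero-one loss).  Accuracy is reported for every requested pair
#' of train and test bins, averaged over folds and runs.
#'
#' @param pop a [build_pseudopopulation()] object.
#' @param labels class labels (default the population's own; permutation
#'   tests pass shuffled ones).
#' @param n_splits cross-validation splits (15 for rivalry switches, 13 for
#'   flash suppression, 8 for the reduced-eye-movement control, 7 for the
#'   robustness runs).
#' @param n_resamples resample runs (default 50).
#' @param train_bins,test_bins bin indices (default all).
#' @param zscore "fold" (training-fold statistics only; no leakage) or
#'   "global" (statistics over all selected exemplars).
#' @param seed RNG seed.
#' @return object of class `decoding_result`: list(accuracy = train x test
#'   matrix in %, sd = SD over runs, bins, n_splits, n_resamples).
#' @export
cv_decode <- function(pop, labels = pop$labels, n_splits = 15,
                      n_resamples = 50, train_bins = NULL, test_bins = NULL,
                      zscore = c("fold", "global"), seed = 1L) {
  zscore <- match.arg(zscore)
  cnt <- pop$counts
  E <- dim(cnt)[1]; F <- dim(cnt)[2]; B <- dim(cnt)[3]
  labels <- factor(labels, levels = pop$classes)
  C <- length(pop$classes)
  if (min(table(labels)) < n_splits)
    stopf("exemplars per class (%d) < n_splits (%d)",
          min(table(labels)), n_splits)
  train_bins <- train_bins %||% seq_len(B)
  test_bins <- test_bins %||% seq_len(B)
  B1 <- length(train_bins); B2 <- length(test_bins)
  flat <- matrix(cnt, E, F * B)  # feature fastest within bin
  acc_runs <- array(0, c(B1, B2, n_resamples))
  with_seed(seed, {
    multi <- length(unique(pop$session_of_feature)) > 1
    for (run in seq_len(n_resamples)) {
      ## re-pair exemplars across sessions within class (simultaneously
      ## recorded single-session data keeps its true trial pairing)
      fl <- flat
      if (multi) for (s in unique(pop$session_of_feature)) {
        fcols_base <- which(pop$session_of_feature == s)
        cols <- as.vector(outer(fcols_base, (seq_len(B) - 1L) * F, "+"))
        for (cl in pop$classes) {
          rows <- which(labels == cl)
          fl[rows, cols] <- fl[sample(rows), cols]
        }
      }
      ## draw n_splits exemplars per class, random fold assignment
      sel <- unlist(lapply(pop$classes, function(cl)
        sample(which(labels == cl), n_splits)))
      fold_of <- unlist(lapply(seq_len(C), function(i) sample(n_splits)))
      X <- fl[sel, , drop = FALSE]
      y <- labels[sel]
      yi <- as.integer(y)
      if (zscore == "global") {
        z <- zscore_apply(X, X); X <- z$train
      }
      fold_acc <- array(0, c(B1, B2))
      for (f in seq_len(n_splits)) {
        te <- which(fold_of == f); tr <- which(fold_of != f)
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (zscore == "fold") {
          z <- zscore_apply(Xtr, Xte); Xtr <- z$train; Xte <- z$test
        }
        tm <- rowsum(Xtr, y[tr]) / as.vector(table(y[tr]))  # C x (F*B)
        tm <- corr_normalize(tm, F, B)
        vm <- corr_normalize(Xte, F, B)
        ## scores for all (train bin, test bin) pairs via one matmul
        TM <- matrix(0, C * B1, F)
        for (j in seq_len(B1)) {
          cols <- (train_bins[j] - 1L) * F + seq_len(F)
          TM[(j - 1L) * C + seq_len(C), ] <- tm[, cols]
        }
        VM <- matrix(0, F, length(te) * B2)
        for (j in seq_len(B2)) {
          cols <- (test_bins[j] - 1L) * F + seq_len(F)
          VM[, (j - 1L) * length(te) + seq_along(te)] <- t(vm[, cols,
                                                              drop = FALSE])
        }
        S <- TM %*% VM
        dim(S) <- c(C, B1, length(te), B2)
        SS <- aperm(S, c(2, 3, 4, 1))
        dim(SS) <- c(B1 * length(te) * B2, C)
        pred <- max.col(SS, ties.method = "first")
        truth <- aperm(array(yi[te], c(length(te), B1, B2)), c(2, 1, 3))
        correct <- array(pred, c(B1, length(te), B2)) == truth
        fold_acc <- fold_acc + apply(correct, c(1, 3), mean)
      }
      acc_runs[, , run] <- fold_acc / n_splits
    }
  })
  acc <- apply(acc_runs, c(1, 2), mean) * 100
  sdv <- apply(acc_runs, c(1, 2), sd) * 100
  dimnames(acc) <- dimnames(sdv) <-
    list(train = pop$bin_start[train_bins], test = pop$bin_start[test_bins])
  out <- list(accuracy = acc, sd = sdv,
              train_bin_start = pop$bin_start[train_bins],
              test_bin_start = pop$bin_start[test_bins],
              n_splits = n_splits, n_resamples = n_resamples,
              bin_ms = pop$bin_ms)
  class(out) <- "decoding_result"
  out
}

#' Cross-validated accuracy in a single window
#'
#' Convenience wrapper around [cv_decode()] for a single-bin population,
#' returning scalar accuracy and resample SD.
#' @inheritParams cv_decode
#' @return list(accuracy, sd, result).
#' @export
cross_validated_accuracy <- function(pop, n_splits = 15, n_resamples = 50,
                                     seed = 1L, ...) {
  r <- cv_decode(pop, n_splits = n_splits, n_resamples = n_resamples,
                 seed = seed, train_bins = 1L, test_bins = 1L, ...)
  list(accuracy = as.numeric(r$accuracy), sd = as.numeric(r$sd), result = r)
}

#' Cross-temporal generalization matrix
#'
#' Classification accuracy for every pair of train and test time bins
#' (150 ms bins sampled every 50 ms by default); train and test exemplars
#' are never shared within a fold, and both bins use the same fold draw per
#' run.
#' @inheritParams cv_decode
#' @return a `decoding_result` with the full train x test accuracy matrix.
#' @export
cross_temporal_matrix <- function(pop, n_splits = 15, n_resamples = 50,
                                  seed = 1L, ...) {
  cv_decode(pop, n_splits = n_splits, n_resamples = n_resamples,
            seed = seed, ...)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "Decoding result: %d x %d train/test bins, %d splits, %d resamples\n",
    nrow(x$accuracy), ncol(x$accuracy), x$n_splits, x$n_resamples))
  if (length(x$accuracy) == 1)
    cat(sprintf("  accuracy %.1f%% (SD %.1f)\n", x$accuracy, x$sd))
  else
    cat(sprintf("  diagonal mean %.1f%%, matrix range %.1f-%.1f%%\n",
                mean(diag(x$accuracy)), min(x$accuracy), max(x$accuracy)))
  if (!is.null(x$p_estimate))
    cat(sprintf("  permutation p = %.5f (%d shuffles)\n", x$p_estimate,
                length(x$null_distribution)))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  graphics::image(x$train_bin_start, x$test_bin_start, x$accuracy,
                  xlab = "train time (ms)", ylab = "test time (ms)",
                  main = "classification accuracy (%)", ...)
  invisible(x)
}

#' Train on one condition, test on another
#'
#' Assesses invariance of the population code by training the classifier on
#' all exemplars of one condition (e.g. PA switches) in a given window and
#' testing on another (e.g. BR switches), with re-pairing and resample runs.
#' The two populations must share the feature set (same sessions/units and
#' bin grid).
#'
#' @param pop_train,pop_test pseudopopulations with identical features.
#' @param labels_test optional label override for the test set (e.g. for
#'   label-flip controls).
#' @param train_bin,test_bin bin index used in each population.
#' @param n_resamples resample runs.
#' @param zscore as in [cv_decode()]; training-set statistics are applied
#'   to the test condition.
#' @param seed RNG seed.
#' @return list(accuracy %, sd over runs).
#' @export
cross_condition_generalization <- function(pop_train, pop_test,
                                           labels_test = pop_test$labels,
                                           train_bin = 1L, test_bin = 1L,
                                           n_resamples = 50,
                                           zscore = c("fold", "global"),
                                           seed = 1L) {
  zscore <- match.arg(zscore)
  ## reconcile feature sets (each condition drops its own silent features)
  common <- intersect(pop_train$feature_id, pop_test$feature_id)
  if (length(common) < 2) stopf("feature sets differ between conditions")
  itr <- match(common, pop_train$feature_id)
  ite <- match(common, pop_test$feature_id)
  F <- length(common)
  sess_feat <- pop_train$session_of_feature[itr]
  Xtr_all <- matrix(pop_train$counts[, itr, train_bin],
                    dim(pop_train$counts)[1], F)
  Xte_all <- matrix(pop_test$counts[, ite, test_bin],
                    dim(pop_test$counts)[1], F)
  ytr <- pop_train$labels
  yte <- factor(labels_test, levels = pop_train$classes)
  accs <- numeric(n_resamples)
  with_seed(seed, {
    multi <- length(unique(sess_feat)) > 1
    for (run in seq_len(n_resamples)) {
      Xtr <- Xtr_all; Xte <- Xte_all
      if (multi) for (s in unique(sess_feat)) {
        cols <- which(sess_feat == s)
        for (cl in pop_train$classes) {
          r1 <- which(ytr == cl); Xtr[r1, cols] <- Xtr[sample(r1), cols]
          r2 <- which(yte == cl); Xte[r2, cols] <- Xte[sample(r2), cols]
        }
      }
      z <- zscore_apply(Xtr, Xte)
      fit <- mcc_fit(z$train, ytr)
      pred <- predict(fit, z$test)
      accs[run] <- mean(pred == yte)
    }
  })
  list(accuracy = mean(accs) * 100, sd = sd(accs) * 100)
}

#' Permutation test of decoding accuracy
#'
#' Re-runs the decoding with class labels shuffled `n_perm` times (same
#' binning, splits and resample runs) to build a null distribution; the
#' estimated p-value uses the add-one convention
#' p = (k + 1) / (n_perm + 1) with k the number of null accuracies at or
#' above the observed one.  When the observed accuracy exceeds all 500 null
#' values this yields p = 1/501, approximately 0.00199.
#'
#' @param pop a pseudopopulation (typically single-bin).
#' @param n_perm permutations (default 500).
#' @param n_splits,n_resamples,zscore as in [cv_decode()].
#' @param train_bins,test_bins bin indices (default first bin).
#' @param seed RNG seed.
#' @return `decoding_result` with fields `null_distribution` (length
#'   `n_perm`) and `p_estimate` added; accuracy is the observed one.
#' @export
permutation_test <- function(pop, n_perm = 500, n_splits = 15,
                             n_resamples = 50, train_bins = 1L,
                             test_bins = 1L, zscore = "fold", seed = 1L) {
  obs <- cv_decode(pop, n_splits = n_splits, n_resamples = n_resamples,
                   train_bins = train_bins, test_bins = test_bins,
                   zscore = zscore, seed = derive_seed(seed, 1L))
  stat <- mean(obs$accuracy)
  null <- numeric(n_perm)
  with_seed(derive_seed(seed, 2L), {
    perms <- replicate(n_perm, sample(as.character(pop$labels)),
                       simplify = FALSE)
  })
  for (i in seq_len(n_perm)) {
    r <- cv_decode(pop, labels = perms[[i]], n_splits = n_splits,
                   n_resamples = n_resamples, train_bins = train_bins,
                   test_bins = test_bins, zscore = zscore,
                   seed = derive_seed(seed, 2L + i))
    null[i] <- mean(r$accuracy)
  }
  obs$null_distribution <- null
  obs$p_estimate <- (sum(null >= stat) + 1) / (n_perm + 1)
  obs
}

#' Decoding within and generalization across recording sessions
#'
#' Trains the classifier on one session and tests on another, using the
#' spiking activity summed per electrode as features to keep correspondence
#' across sessions.  The diagonal holds within-session cross-validated
#' accuracy; off-diagonal cells hold train-on-i / test-on-j generalization.
#'
#' @param sessions list of `okn_session`-like objects sharing the electrode
#'   grid.
#' @param exemplars list (one per session) of data.frames(trial_id,
#'   time_ms, label).
#' @param window single decoding window, ms (default the 800 ms starting
#'   200 ms after the alignment event).
#' @param n_splits,n_resamples CV parameters for the diagonal.
#' @param seed RNG seed.
#' @return matrix (train session x test session) of accuracies in %.
#' @export
cross_session_generalization <- function(sessions, exemplars,
                                         window = c(200, 1000),
                                         n_splits = 13, n_resamples = 50,
                                         seed = 1L) {
  S <- length(sessions)
  pops <- lapply(seq_len(S), function(s)
    build_pseudopopulation(sessions[[s]], exemplars[[s]],
                           bin_ms = diff(window), step_ms = diff(window),
                           window = window, features = "electrode",
                           seed = derive_seed(seed, 100L + s)))
  elec <- lapply(pops, function(p) p$feature_id)
  common <- Reduce(intersect, lapply(elec, function(e)
    sub("^s\\d+_", "", e)))
  if (!length(common)) stopf("no common electrodes across sessions")
  pops <- lapply(pops, function(p) {
    keep <- sub("^s\\d+_", "", p$feature_id) %in% common
    ord <- order(match(sub("^s\\d+_", "", p$feature_id)[keep], common))
    p$counts <- p$counts[, keep, , drop = FALSE][, ord, , drop = FALSE]
    p$feature_id <- sub("^s\\d+_", "", p$feature_id)[keep][ord]
    p$session_of_feature <- rep(1L, length(p$feature_id))
    p
  })
  acc <- matrix(NA_real_, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) {
      acc[i, j] <- cross_validated_accuracy(
        pops[[i]], n_splits = min(n_splits, pops[[i]]$n_per_class),
        n_resamples = n_resamples,
        seed = derive_seed(seed, 10L * i + j))$accuracy
    } else {
      acc[i, j] <- cross_condition_generalization(
        pops[[i]], pops[[j]], n_resamples = n_resamples,
        seed = derive_seed(seed, 10L * i + j))$accuracy
    }
  }
  dimnames(acc) <- list(train = seq_len(S), test = seq_len(S))
  acc
}

#' Unit selection for the control-paradigm decoding
#'
#' Full mode: units significantly selective (rank-sum p <= 0.05) in either
#' paradigm that prefer the same stimulus in both.  Robustness mode: the
#' selection is recomputed per run from all trials of the training paradigm
#' plus a random half of the testing paradigm's trials; the held-out half is
#' reserved for testing (they are disjoint by construction).  Repeated
#' `n_runs` times.
#'
#' @param counts_train,counts_test data.frames(unit_id, trial_id, percept,
#'   count) of full-window counts for the two paradigms (training paradigm
#'   first).
#' @param mode "full" or "half_trial_robustness".
#' @param n_runs runs in robustness mode (default 10).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return full mode: vector of selected unit ids.  Robustness mode: list
#'   of runs, each list(units, selection_trials, test_trials).
#' @export
control_unit_selection <- function(counts_train, counts_test,
                                   mode = c("full",
                                            "half_trial_robustness"),
                                   n_runs = 10, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  select_units <- function(ca, cb) {
    rec <- selectivity_records(ca, cb, labels = c("a", "b"))
    sel <- (rec$p_a <= alpha | rec$p_b <= alpha) &
      rec$preferred_a == rec$preferred_b & rec$preferred_a != "NONE"
    rec$unit_id[sel]
  }
  if (mode == "full") {
    u <- select_units(counts_train, counts_test)
    if (!length(u)) stopf("no unit passes the selection rule")
    return(u)
  }
  trials <- unique(counts_test$trial_id)
  with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      half <- sample(trials, floor(length(trials) / 2))
      held <- setdiff(trials, half)
      u <- select_units(counts_train,
                        counts_test[counts_test$trial_id %in% half, ])
      if (!length(u)) stopf("no unit passes the selection rule in run %d",
                            run)
      list(units = u, selection_trials = sort(half),
           test_trials = sort(held))
    })
  })
}
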
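test_that("maximum-correlation classifier matches the brute-force oracle", {
  set.seed(61)
  # template exact match and the two-feature centring case
  fit <- mcc_fit(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                 c("A", "A", "B", "B"))
  expect_equal(as.character(predict(fit, rbind(c(1, 0)))), "A")
  expect_equal(as.character(predict(fit, rbind(c(0.9, 0.1)))), "A")
  expect_equal(as.character(predict(fit, rbind(c(0.1, 0.9)))), "B")
  # random problems: identical to the oracle
  for (i in 1:200) {
    n <- sample(6:12, 1); F <- 20
    x <- matrix(rnorm(n * F), n, F)
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("A", "B")
    xt <- matrix(rnorm(5 * F), 5, F)
    fit <- mcc_fit(x, y)
    expect_equal(as.character(predict(fit, xt)), oracle_mcc(x, y, xt))
  }
  # zero-variance test vector: flagged, tie-break to first class
  p <- predict(fit, rbind(rep(1, 20)))
  expect_true(attr(p, "flagged"))
  expect_equal(as.character(p), "A")
  expect_error(mcc_fit(matrix(1:4, 4, 1), c("A", "A", "B", "B")),
               "2 features")
})

test_that("classifier accuracy is invariant to positive affine feature scaling", {
  set.seed(62)
  F <- 15
  x <- matrix(rnorm(40 * F), 40, F)
  y <- rep(c("A", "B"), 20)
  xt <- matrix(rnorm(10 * F), 10, F)
  a <- runif(F, 0.5, 3); b <- rnorm(F)
  scale_it <- function(m) sweep(sweep(m, 2, a, "*"), 2, b, "+")
  p1 <- predict(mcc_fit(x, y), xt)
  p2 <- predict(mcc_fit(scale_it(x), y), scale_it(xt))
  expect_equal(as.character(p1), as.character(p2))
})

test_that("pseudopopulation assembly shapes, pairing and z-scoring", {
  cfg <- synth_config(n_units = 10, n_trials_per_type = 12,
                      dprime_target_distribution = c(1.2, 0.3))
  s1 <- generate_session(cfg, paradigms = "BR", seed = 63,
                         session_id = "A")
  s2 <- generate_session(cfg, paradigms = "BR", seed = 64,
                         session_id = "B")
  ex1 <- make_exemplars(s1, segment_session(s1, "BR"), "switch")
  ex2 <- make_exemplars(s2, segment_session(s2, "BR"), "switch")
  npc <- min(table(ex1$label), table(ex2$label), 15)
  pop <- build_pseudopopulation(list(s1, s2), list(ex1, ex2),
                                n_per_class = npc,
                                bin_ms = 400, step_ms = 400,
                                window = c(200, 600), seed = 2)
  expect_equal(dim(pop$counts)[1], 2 * npc)
  expect_lte(dim(pop$counts)[2], 20)
  expect_equal(as.integer(table(pop$labels)), rep(as.integer(npc), 2))
  # insufficient exemplars error names the session
  expect_error(build_pseudopopulation(list(s1, s2), list(ex1, ex2),
                                      n_per_class = 1000), "session")
  # z-scoring: [2,4,6] -> [-1,0,1] with sample SD
  z <- okndecode:::zscore_apply(matrix(c(2, 4, 6), 3, 1),
                                matrix(8, 1, 1))
  expect_equal(as.numeric(z$train), c(-1, 0, 1))
  expect_equal(as.numeric(z$test), 2)
})

test_that("cross-validated accuracy is perfect for separable data, chance for shuffled labels", {
  set.seed(65)
  mkpop <- function(counts, labels, nbin = 1) {
    structure(list(counts = counts, labels = factor(labels),
                   bin_start = seq_len(nbin) * 50, bin_ms = 150,
                   step_ms = 50,
                   session_of_feature = rep(1L, dim(counts)[2]),
                   feature_id = paste0("u", seq_len(dim(counts)[2])),
                   classes = sort(unique(labels)),
                   n_per_class = min(table(labels))),
              class = "pseudopopulation")
  }
  # separable: opposite firing *patterns* across the feature set (a
  # correlation classifier is blind to uniform rate offsets)
  E <- 30; F <- 12
  cnt <- array(0, c(E, F, 1))
  cnt[1:15, 1:6, 1] <- matrix(rpois(15 * 6, 40), 15, 6)
  cnt[1:15, 7:12, 1] <- matrix(rpois(15 * 6, 2), 15, 6)
  cnt[16:30, 1:6, 1] <- matrix(rpois(15 * 6, 2), 15, 6)
  cnt[16:30, 7:12, 1] <- matrix(rpois(15 * 6, 40), 15, 6)
  pop <- mkpop(cnt, rep(c("DOWN", "UP"), each = 15))
  r <- cross_validated_accuracy(pop, n_splits = 15, n_resamples = 10,
                                seed = 1)
  expect_equal(r$accuracy, 100)
  # random labels over a large exemplar pool: chance level
  E2 <- 10000
  cnt2 <- array(rpois(E2 * F, 10), c(E2, F, 1))
  pop2 <- mkpop(cnt2, sample(rep(c("DOWN", "UP"), each = E2 / 2)))
  r2 <- cross_validated_accuracy(pop2, n_splits = 15, n_resamples = 400,
                                 seed = 2)
  expect_lt(abs(r2$accuracy - 50), 2)
  # exemplars per class below n_splits is an error
  expect_error(cv_decode(pop, n_splits = 20), "n_splits")
})

test_that("cross-temporal matrix is consistent with per-bin decoding and label flips", {
  cfg <- synth_config(n_units = 40, n_trials_per_type = 12,
                      dprime_target_distribution = c(1.5, 0.3))
  s <- generate_session(cfg, paradigms = "BR", seed = 66)
  ex <- make_exemplars(s, segment_session(s, "BR"), "switch")
  pop <- build_pseudopopulation(s, ex, n_per_class = 12, bin_ms = 150,
                                step_ms = 50, window = c(-500, 500),
                                seed = 3)
  B <- length(pop$bin_start)
  m <- cross_temporal_matrix(pop, n_splits = 12, n_resamples = 8, seed = 4)
  # diagonal equals a per-bin run with the same seed
  b <- which.max(pop$bin_start)
  d <- cv_decode(pop, n_splits = 12, n_resamples = 8, seed = 4,
                 train_bins = b, test_bins = b)
  expect_equal(as.numeric(d$accuracy), m$accuracy[b, b], tolerance = 1e-12)
  # post-switch bins decode above chance; train-pre/test-post is inverted
  post <- pop$bin_start >= 200
  pre <- pop$bin_start + pop$bin_ms <= -100
  expect_gt(mean(m$accuracy[post, post]), 85)
  expect_lt(mean(m$accuracy[pre, post]), 25)
  # flipped labels mirror the accuracy around chance
  flip <- ifelse(as.character(pop$labels) == "UP", "DOWN", "UP")
  g <- cross_condition_generalization(pop, pop, train_bin = B,
                                      test_bin = B, n_resamples = 8,
                                      seed = 5)
  gf <- cross_condition_generalization(pop, pop, labels_test = flip,
                                       train_bin = B, test_bin = B,
                                       n_resamples = 8, seed = 5)
  expect_equal(g$accuracy + gf$accuracy, 100, tolerance = 1e-9)
  # training and testing on the same exemplars without CV memorizes
  expect_equal(g$accuracy, 100)
})

test_that("permutation test uses the add-one p-value convention", {
  cfg <- synth_config(n_units = 20, n_trials_per_type = 12,
                      dprime_target_distribution = c(1.8, 0.2))
  s <- generate_session(cfg, paradigms = "BR", seed = 67)
  ex <- make_exemplars(s, segment_session(s, "BR"), "switch")
  pop <- build_pseudopopulation(s, ex, bin_ms = 400, step_ms = 400,
                                window = c(200, 600), seed = 6)
  ns <- min(10, pop$n_per_class)
  r <- permutation_test(pop, n_perm = 40, n_splits = ns, n_resamples = 5,
                        seed = 7)
  expect_length(r$null_distribution, 40)
  k <- sum(r$null_distribution >= mean(r$accuracy))
  expect_equal(r$p_estimate, (k + 1) / 41)
  expect_equal(r$p_estimate, 1 / 41)  # strong code beats every shuffle
  # direct formula check at k = 9, n_perm = 500
  expect_equal((9 + 1) / (500 + 1), 10 / 501)
})

test_that("control-paradigm unit selection follows the significance rules", {
  set.seed(68)
  mk <- function(uid, lam_d, lam_u, n = 12, trials = 1:24)
    data.frame(unit_id = uid, trial_id = trials,
               percept = rep(c("DOWN", "UP"), each = n),
               count = c(rpois(n, lam_d), rpois(n, lam_u)))
  # unit 1: selective in train only, same preference; unit 2: opposite
  # preferences; unit 3: nothing
  ctrain <- rbind(mk(1, 30, 5), mk(2, 30, 5), mk(3, 10, 10))
  ctest <- rbind(mk(1, 20, 8), mk(2, 5, 30), mk(3, 10, 10))
  sel <- control_unit_selection(ctrain, ctest, mode = "full")
  expect_true(1 %in% sel)
  expect_false(2 %in% sel)
  # robustness mode: held-out half disjoint from the selection half
  runs <- control_unit_selection(ctrain, ctest,
                                 mode = "half_trial_robustness",
                                 n_runs = 10, seed = 3)
  expect_length(runs, 10)
  for (r in runs) {
    expect_length(intersect(r$selection_trials, r$test_trials), 0)
    expect_setequal(c(r$selection_trials, r$test_trials), 1:24)
  }
})
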
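test_that("dominance durations follow the configured gamma distribution", {
  set.seed(1)
  x <- sample_dominance_durations(3, 800, 1e4)
  se <- sqrt(3 * 800^2 / 1e4)
  expect_lt(abs(mean(x) - 2400), 3 * se)
  # shape 1 reduces to an exponential
  y <- sample_dominance_durations(1, 500, 1e4)
  ks <- suppressWarnings(ks.test(y, pexp, rate = 1 / 500))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("dominance duration sampling validates its parameters", {
  expect_error(sample_dominance_durations(0, 800, 10), "shape")
  expect_error(sample_dominance_durations(3, -1, 10), "scale")
  expect_error(sample_dominance_durations(3, 800, 0), "n")
  set.seed(2)
  expect_true(all(sample_dominance_durations(3, 100, 500,
                                             min_duration = 300) >= 300))
})

test_that("same seed yields identical sessions; bookkeeping is balanced", {
  cfg <- synth_config(n_units = 5, n_trials_per_type = 6, seed = 7)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
  expect_equal(sum(s1$trials$paradigm == "PA"), 6)
  expect_equal(sum(s1$trials$paradigm == "BR"), 6)
  # pseudorandomized but balanced first stimulus and eye
  for (p in c("PA", "BR")) {
    tr <- s1$trials[s1$trials$paradigm == p, ]
    expect_equal(as.integer(table(tr$first_direction)), c(3L, 3L))
    expect_equal(as.integer(table(tr$first_eye)), c(3L, 3L))
  }
})

test_that("ground-truth percept timelines tile each trial without overlap", {
  gt <- fix_sess$ground_truth$percepts
  for (tid in unique(gt$trial_id)) {
    p <- gt[gt$trial_id == tid, ]
    p <- p[order(p$onset), ]
    expect_true(all(p$offset > p$onset))
    expect_equal(p$onset[1], 0)
    if (nrow(p) > 1) expect_equal(p$onset[-1], p$offset[-nrow(p)])
    dur <- fix_sess$trials$duration_ms[fix_sess$trials$trial_id == tid]
    expect_equal(p$offset[nrow(p)], dur)
  }
  # exogenous switches coincide with stimulus events; endogenous only in BR
  sw <- fix_sess$ground_truth$switches
  ev <- fix_sess$events
  ex <- sw[sw$type == "EXOGENOUS", ]
  for (i in seq_len(nrow(ex)))
    expect_true(any(ev$trial_id == ex$trial_id[i] &
                      ev$time_ms == ex$time_ms[i]))
  endo <- sw[sw$type == "ENDOGENOUS", ]
  br_ids <- fix_sess$trials$trial_id[fix_sess$trials$paradigm == "BR"]
  expect_true(all(endo$trial_id %in% br_ids))
})

test_that("noise-free OKN is a percept-locked sawtooth with exact kinematics", {
  cfg <- synth_config(noise_sd_eye = 0, okn_slow_phase_speed = 12,
                      okn_reset_threshold = 4)
  tl <- data.frame(onset = 0, offset = 3000, percept = "DOWN")
  tr <- synthesize_okn(tl, cfg)
  dy <- diff(tr$y)
  expect_true(all(dy[dy < 0] > -0.02))       # slow phase: -12 deg/s
  expect_true(all(abs(dy[dy > 0] - 4) < 0.1))  # fast resets jump +4 deg
  resets <- which(dy > 1)
  # inter-reset interval = threshold / speed = 4/12 s (1 ms sampling grid)
  expect_lt(abs(mean(diff(resets)) - 4 / 12 * 1000), 1)
  expect_lte(diff(range(diff(resets))), 1)
  expect_true(all(abs(tr$y) <= 8))
})

test_that("OKN polarity flips lag exogenous switches by the configured latency", {
  cfg <- synth_config(noise_sd_eye = 0, seed = 5)
  lat <- replicate(200, {
    tl0 <- data.frame(onset = 0, offset = 6000, percept = c("DOWN"))
    sw_t <- 3000
    l <- max(0, rnorm(1, cfg$pa_okn_latency[1], cfg$pa_okn_latency[2]))
    tl <- data.frame(onset = c(0, sw_t + l), offset = c(sw_t + l, 6000),
                     percept = c("DOWN", "UP"))
    tr <- synthesize_okn(tl, cfg)
    ep <- segment_percepts(tr, min_stable = 500)
    if (nrow(ep) == 2) ep$onset[2] - sw_t else NA
  })
  lat <- lat[!is.na(lat)]
  se <- 36.6 / sqrt(length(lat))
  expect_gt(length(lat), 150)
  expect_lt(abs(mean(lat) - 129.4), 2 * se + 5)  # +5 ms segmentation grid
})

test_that("spike trains realize the configured selectivity", {
  cfg <- synth_config(seed = 3)
  # d' = 0: symmetric rates
  u0 <- list(preferred = "DOWN", rate_pref = 10, rate_nonpref = 10)
  u15 <- list(preferred = "DOWN",
              rate_pref = rate_for_dprime(1.5, 10), rate_nonpref = 10)
  set.seed(42)
  count_epoch <- function(u, pct) {
    tl <- data.frame(onset = 0, offset = 1000, percept = pct)
    length(synthesize_spike_train(u, tl, data.frame(time_ms = numeric(),
                                                    type = character()),
                                  cfg))
  }
  cp0 <- replicate(500, count_epoch(u0, "DOWN"))
  cn0 <- replicate(500, count_epoch(u0, "UP"))
  expect_lt(abs(oracle_dprime(cp0, cn0)), 0.1)
  cp <- replicate(200, count_epoch(u15, "DOWN"))
  cn <- replicate(200, count_epoch(u15, "UP"))
  expect_lt(abs(oracle_dprime(cp, cn) - 1.5), 0.15)
  expect_error(synthesize_spike_train(
    list(preferred = "DOWN", rate_pref = -1, rate_nonpref = 10),
    data.frame(onset = 0, offset = 1000, percept = "DOWN"),
    data.frame(time_ms = numeric(), type = character()), cfg),
    "negative")
})

test_that("the feedforward transient appears at exogenous but not endogenous switches", {
  cfg <- synth_config(transient_gain = 2, transient_duration = 200, seed = 9)
  u <- list(preferred = "DOWN", rate_pref = 20, rate_nonpref = 20)
  tl <- data.frame(onset = c(0, 2000), offset = c(2000, 4000),
                   percept = c("UP", "DOWN"))
  post_rate <- function(type) {
    sw <- data.frame(time_ms = 2000, type = type)
    set.seed(11)
    mean(replicate(300, {
      st <- synthesize_spike_train(u, tl, sw, cfg)
      sum(st >= 2000 & st < 2200)
    }))
  }
  ratio <- post_rate("EXOGENOUS") / post_rate("ENDOGENOUS")
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("broadband synthesis inserts templates at retrievable times", {
  wf <- default_waveform(10)
  expect_length(wf, 45)
  expect_equal(which.min(wf), 16)
  # pure noise: MAD of a unit gaussian is about 0.6745
  set.seed(4)
  bb <- synthesize_broadband(numeric(0), wf, noise_sd = 1,
                             duration_ms = 200)
  expect_lt(abs(median(abs(bb$voltage - median(bb$voltage))) - 0.6745),
            0.02)
  # noiseless single insertion reproduces the template exactly
  bb1 <- synthesize_broadband(5, wf, noise_sd = 0, duration_ms = 20)
  i0 <- bb1$inserted_index - 15
  expect_equal(bb1$voltage[i0:(i0 + 44)], wf)
  expect_equal(sum(bb1$voltage != 0), sum(wf != 0))
  # insertions violating the refractory spacing are rejected with a warning
  expect_warning(
    bb2 <- synthesize_broadband(c(5, 5.2, 8), wf, 0, duration_ms = 20),
    "rejected")
  expect_equal(bb2$inserted_times_ms, c(5, 8))
})

test_that("pooled BR dominance durations recover the configured gamma", {
  cfg <- synth_config(n_units = 1, n_trials_per_type = 50, seed = 77)
  s <- generate_session(cfg, paradigms = "BR")
  gt <- s$ground_truth$percepts
  gt <- gt[gt$phase %in% c("BFS_DOMINANCE", "BR_DOMINANCE"), ]
  # only completed dominances: the trial end right-truncates the last epoch
  gt <- gt[gt$offset < cfg$trial_duration, ]
  f <- fit_dominance_gamma(gt$offset - gt$onset)
  expect_lt(abs(f$shape - 3) / 3, 0.15)
  expect_lt(abs(f$scale - 800) / 800, 0.15)
})
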
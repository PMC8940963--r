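test_that("epoch inclusion rules follow the dominance and gap criteria", {
  epochs <- data.frame(
    trial_id = c(1, 1, 2, 2, 3, 3),
    onset = c(0, 1200, 0, 1300, 0, 1050),
    offset = c(900, 2500, 1200, 2400, 1040, 2000),
    percept = c("DOWN", "UP", "DOWN", "UP", "DOWN", "UP"),
    stringsAsFactors = FALSE)
  # trial 1: first dominance 900 ms -> no usable switch; the 900 ms epoch
  # is also excluded from dominance counts
  spikes <- data.frame(unit_id = 1, trial_id = 1,
                       time_ms = c(100, 200))
  cnt <- extract_epoch_counts(spikes, epochs, mode = "dominance")
  expect_false(any(cnt$trial_id == 1 & cnt$align_ms == 0))
  expect_false(any(cnt$trial_id == 3 & cnt$align_ms == 1050))
  # trial 2: 100 ms gap (< 250) and both dominances >= 1000 -> included
  sw <- epoch_switches(epochs)
  expect_equal(sw$trial_id, 2)
  expect_equal(sw$time_ms, 1300)
  # trial with a 300 ms gap is excluded
  ep3 <- data.frame(trial_id = 9, onset = c(0, 1300),
                    offset = c(1000, 2600), percept = c("DOWN", "UP"))
  expect_equal(nrow(epoch_switches(ep3)), 0)
  # counting: spikes at 100 and 200 ms post-alignment in the POST window
  expect_equal(cnt$count[cnt$trial_id == 1 & cnt$align_ms == 1200], 0)
  c2 <- extract_epoch_counts(spikes,
                             data.frame(trial_id = 1, onset = 0,
                                        offset = 1500, percept = "DOWN"),
                             mode = "dominance")
  expect_equal(c2$count, 2)
})

test_that("rank-sum selectivity matches exact enumeration and tie rules", {
  a <- c(10, 11, 12, 13); b <- c(0, 1, 2, 3)
  r <- rank_sum_selectivity(a, b)
  expect_equal(r$p_value, 2 / 70)
  expect_equal(r$p_value, oracle_ranksum_exact(a, b))
  expect_equal(r$preferred, "DOWN")
  expect_true(r$significant)
  # identical samples: p = 1 and no preference
  r2 <- rank_sum_selectivity(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  expect_equal(r2$preferred, "NONE")
  # preference follows the larger mean regardless of significance
  r3 <- rank_sum_selectivity(c(5, 6), c(6, 7))
  expect_equal(r3$preferred, "UP")
  expect_error(rank_sum_selectivity(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum attains its nominal level under a Poisson null", {
  set.seed(41)
  n_sim <- 10000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    p <- rank_sum_selectivity(rpois(30, 10), rpois(30, 10))$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / n_sim - 0.05), 0.01)
})

test_that("d' matches the closed form and an independent implementation", {
  expect_equal(dprime(c(8, 12, 10, 10), c(8, 12, 10, 10)), 0)
  # mu_p = 10, mu_np = 5, Var = 4 each -> 2.5
  p <- c(8, 10, 12, 10); np <- c(3, 5, 7, 5)
  expect_equal(mean(p), 10); expect_equal(var(p), 8 / 3)
  p2 <- c(8, 12, 10, 10); np2 <- c(3, 7, 5, 5)
  expect_equal(dprime(p2, np2),
               (10 - 5) / sqrt((var(p2) + var(np2)) / 2))
  set.seed(42)
  for (i in 1:50) {
    x <- rpois(20, 12); y <- rpois(15, 8)
    expect_equal(dprime(x, y), oracle_dprime(x, y), tolerance = 1e-12)
    # antisymmetric under swapping the samples
    expect_equal(dprime(x, y), -dprime(y, x), tolerance = 1e-12)
  }
  expect_error(dprime(c(1), c(1, 2)), "at least 2")
  expect_error(dprime(c(5, 5, 5), c(5, 5, 5)), "zero variance")
})

test_that("unit categories are consistent and partition the population", {
  rec <- data.frame(
    unit_id = 1:5,
    p_pa = c(0.01, 0.01, 0.50, 0.60, 0.02),
    preferred_pa = c("DOWN", "DOWN", "DOWN", "UP", "UP"),
    p_br = c(0.02, 0.70, 0.01, 0.80, 0.03),
    preferred_br = c("DOWN", "UP", "DOWN", "DOWN", "DOWN"),
    stringsAsFactors = FALSE)
  cc <- categorize_units(rec)
  expect_equal(as.character(cc$category),
               c("BOTH_SAME", "PA_ONLY", "BR_ONLY", "NONE",
                 "SUPPRESSED_PREFERENCE"))
  expect_equal(sum(cc$tally), nrow(rec))
})

test_that("category rates agree with an independent power simulation", {
  # population: 60% units modulated at d' = 1.5 in both conditions, 40% at 0
  set.seed(43)
  n_units <- 200; n_ep <- 12
  lam0 <- 10; lam1 <- rate_for_dprime(1.5, lam0)
  mod <- rep(c(TRUE, FALSE), times = c(0.6, 0.4) * n_units)
  counts <- function() {
    do.call(rbind, lapply(seq_len(n_units), function(u) {
      lp <- if (mod[u]) lam1 else lam0
      data.frame(unit_id = u,
                 percept = rep(c("DOWN", "UP"), each = n_ep),
                 count = c(rpois(n_ep, lp), rpois(n_ep, lam0)))
    }))
  }
  rec <- selectivity_records(counts(), counts())
  frac_both <- mean(rec$category == "BOTH_SAME")
  # oracle: probability that two independent rank-sum draws are both
  # significant with the modulated direction preferred
  both_sig <- replicate(400, {
    ok <- vapply(1:2, function(k) {
      r <- rank_sum_selectivity(rpois(n_ep, lam1), rpois(n_ep, lam0))
      r$significant && r$preferred == "DOWN"
    }, logical(1))
    all(ok)
  })
  # null units almost never land in BOTH_SAME (alpha^2 scale); compare the
  # modulated fraction against the oracle
  expect_lt(abs(frac_both - 0.6 * mean(both_sig)), 0.05)
})

test_that("fixation-control d' difference isolates a late gain", {
  # identical spike data in both paradigms: every delta is exactly 0
  set.seed(44)
  cnts <- do.call(rbind, lapply(1:10, function(u)
    data.frame(unit_id = u,
               percept = rep(rep(c("DOWN", "UP"), each = 8), 2),
               window = rep(c("FIRST", "LAST"), each = 16),
               count = rpois(32, 10))))
  r0 <- dprime_difference_control(cnts, cnts)
  expect_true(all(r0$per_unit$delta[is.finite(r0$per_unit$delta)] == 0))
  # generator: late gain in Fixation-Off only
  cfg <- synth_config(n_units = 100, n_trials_per_direction = 8,
                      dprime_target_distribution = c(1.0, 0.3),
                      fixoff_late_gain = 1.5, seed = 45)
  s <- generate_session(cfg, paradigms = c("FIX_OFF", "FIX_ON"))
  off <- fixation_counts(s, "FIX_OFF")
  on <- fixation_counts(s, "FIX_ON")
  r <- dprime_difference_control(off, on)
  expect_lt(abs(r$means[["FIRST"]]),
            2 * r$tests$FIRST$stderr + 0.05)
  expect_gt(r$means[["LAST"]], 0)
  expect_lt(r$tests$LAST$p.value, 0.05)
  expect_error(dprime_difference_control(cnts[cnts$unit_id < 3, ],
                                         cnts[cnts$unit_id < 3, ]),
               "at least 3")
})
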
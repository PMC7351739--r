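test_that("binning is half-open, conservative and validates its input", {
  expect_equal(bin_counts(c(0.005, 0.015), 0.01, c(0, 0.05)),
               c(1L, 1L, 0L, 0L, 0L))
  expect_equal(bin_counts(numeric(0), 0.1, c(0, 1)), integer(10))
  expect_error(bin_counts(1:3, -1, c(0, 5)), "positive")
  set.seed(1)
  sp <- sort(runif(500, 0, 100))
  expect_equal(sum(bin_counts(sp, 0.035, c(0, 100))), 500)
})

test_that("the finest default resolution makes 10 ms the smallest nonzero lag", {
  cfg <- scale_config()
  expect_equal(cfg$deltas_s[1] * 1 * 1000, 10)
  expect_true(!is.unsorted(cfg$deltas_s, strictly = TRUE))
  expect_length(cfg$max_lag_bins, length(cfg$deltas_s))
})

test_that("coupled pairs are detected at a positive lag and swapping negates it", {
  pr <- simulate_assembly_pair(unit_spec(baseline_hz = 3),
                               unit_spec(baseline_hz = 3),
                               assembly_coupling_spec(0.2, 0.05, 0.5),
                               t_end = 900, seed = 2)
  set.seed(3)
  pt <- pair_test(pr$src, pr$tgt, 0.12, c(0, 900), max_lag = 10,
                  n_surrogates = 100)
  expect_lt(pt$p_value, 0.05)
  expect_true(pt$best_lag %in% c(1L, 2L))
  set.seed(3)
  pt2 <- pair_test(pr$tgt, pr$src, 0.12, c(0, 900), max_lag = 10,
                   n_surrogates = 100)
  expect_equal(pt2$best_lag, -pt$best_lag)
})

test_that("the coincidence statistic grows monotonically with coupling efficacy", {
  stat_at <- function(eff) {
    pr <- simulate_assembly_pair(unit_spec(baseline_hz = 3),
                                 unit_spec(baseline_hz = 3),
                                 assembly_coupling_spec(0.24, 0.05, max(eff, 1e-9)),
                                 t_end = 600, seed = 4)
    a <- bin_counts(pr$src, 0.12, c(0, 600))
    b <- bin_counts(pr$tgt, 0.12, c(0, 600))
    cc <- vsvta:::coincidence_counts_cpp(a, b, 2L, 13L, length(a) - 12L)
    cc[1]
  }
  s <- vapply(c(0, 0.2, 0.5, 0.8), stat_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("pruning keeps exactly one resolution per significant pair", {
  pr <- simulate_assembly_pair(unit_spec(baseline_hz = 3),
                               unit_spec(baseline_hz = 3),
                               assembly_coupling_spec(0.1, 0.03, 0.5),
                               t_end = 600, seed = 5)
  set.seed(6)
  ind <- sim_poisson_spikes(600, 3)
  cfg <- scale_config(deltas_s = c(0.03, 0.05, 0.12, 0.35),
                      max_lag_bins = c(10, 10, 10, 5))
  set.seed(7)
  det <- detect_assemblies(list(spn = pr$src, dan = pr$tgt, other = ind),
                           labels = c("SPN", "DAN", "FS"), cfg = cfg,
                           n_surrogates = 60, span = c(0, 600))
  keys <- paste(det$pairs$unit_a, det$pairs$unit_b)
  expect_false(any(duplicated(keys)))
  expect_true("spn dan" %in% keys)
  got <- det$pairs[det$pairs$unit_a == "spn" & det$pairs$unit_b == "dan", ]
  expect_lte(got$delta_s, 0.12)   # sharp-scale pattern not absorbed broadly
  expect_gt(got$lag_s, 0)
})

test_that("lag histograms are directional and flip with stored orientation", {
  pairs <- data.frame(unit_a = letters[1:6], unit_b = LETTERS[1:6],
                      label_a = "SPN", label_b = "DAN",
                      delta_s = 0.05, lag_bins = c(3, 2, 4, 3, 1, 2))
  pairs$lag_s <- pairs$lag_bins * pairs$delta_s
  ld <- lag_directionality(pairs, c("SPN", "DAN"))
  expect_lt(ld$sign_test$p.value, 0.05)
  flipped <- pairs
  names(flipped)[1:4] <- c("unit_b", "unit_a", "label_b", "label_a")
  flipped$lag_bins <- -flipped$lag_bins
  flipped$lag_s <- -flipped$lag_s
  ld2 <- lag_directionality(flipped, c("SPN", "DAN"))
  expect_equal(sort(ld2$lags_s), sort(ld$lags_s))
  # half each direction: no directionality
  sym <- pairs; sym$lag_s <- sym$lag_s * c(1, -1)
  lds <- lag_directionality(sym, c("SPN", "DAN"))
  expect_gt(lds$sign_test$p.value, 0.3)
  expect_message(lag_directionality(pairs, c("ChAT", "DAN")), "no assemblies")
})

test_that("assembly activation counts and learning dynamics behave at the nulls", {
  tr <- data.frame(trial = 1:48, t_on = seq(5, by = 10, length.out = 48),
                   cs_plus = rep(c(TRUE, FALSE), 24),
                   phase = rep("original", 48))
  # empty trains: all-zero activation, Wilcoxon degenerate-safe
  ad0 <- assembly_learning_dynamics(numeric(0), numeric(0), 0.05, 2, tr)
  expect_true(all(ad0$counts == 0))
  expect_true(all(ad0$summary$p_value > 0.99))
  # stationary coupled pair: initial ~ late
  ns <- vapply(1:15, function(i) {
    pr <- simulate_assembly_pair(unit_spec(baseline_hz = 4),
                                 unit_spec(baseline_hz = 4),
                                 assembly_coupling_spec(0.1, 0.03, 0.4),
                                 t_end = 500, seed = i + 40)
    ad <- assembly_learning_dynamics(pr$src, pr$tgt, 0.05, 2, tr)
    ad$summary$p_value[ad$summary$stimulus == "CS+"] > 0.05
  }, logical(1))
  expect_gte(mean(ns), 0.8)
})

test_that("value-ramped coupling increases late CS+ activation only", {
  ag <- default_agents()$qph_f
  ss <- simulate_task_session(task_config(), ag, 300, seed = 8)
  v <- ss$traces$value_cs
  kern <- list(A = list(amplitude_hz = 6, latency_s = 0.05, duration_s = 1),
               B = list(amplitude_hz = 6, latency_s = 0.05, duration_s = 1))
  pr <- simulate_assembly_pair(
    unit_spec(baseline_hz = 2, kernels = kern, learning_gain = 0.8),
    unit_spec(baseline_hz = 3),
    assembly_coupling_spec(0.15, 0.04, efficacy = pmin(1, 0.8 * v),
                           window = "cs_plus"),
    trials = ss$trials, value_trace = v,
    t_end = max(ss$trials$t_on) + 10, seed = 9)
  ad <- assembly_learning_dynamics(pr$src, pr$tgt, 0.05, 3, ss$trials)
  cs <- ad$summary[ad$summary$stimulus == "CS+", ]
  expect_true(all(cs$mean_late > cs$mean_initial))
})
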
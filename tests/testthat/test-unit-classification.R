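make_trials <- function(n = 60, iti = 12) {
  data.frame(trial = seq_len(n), t_on = seq(10, by = iti, length.out = n),
             odor = rep(c("A", "B"), length.out = n))
}

test_that("passive-paradigm labels follow the baseline-rate and stability rules", {
  tr <- make_trials()
  span <- max(tr$t_on) + 5
  # deterministic trains (period dividing the baseline window) isolate the
  # rate rule from sampling noise
  spn <- regular_spikes(2, 0, span)
  expect_equal(classify_vs_passive(spn, tr)$label, "SPN")
  fast <- regular_spikes(6, 0, span)
  expect_false(classify_vs_passive(fast, tr)$label == "SPN")
  # stable low-rate unit with a 30% mid-session dip: fluctuation gate fires
  thirds <- c(0, span / 3, 2 * span / 3, span)
  dip <- sort(c(regular_spikes(1, 0, thirds[2]),
                regular_spikes(0.7, thirds[2], thirds[3]),
                regular_spikes(1, thirds[3], span)))
  lab <- classify_vs_passive(dip, tr)
  expect_equal(lab$label, "excluded")
  expect_gt(lab$evidence$fluctuation, 0.2)
  expect_error(classify_vs_passive(spn, tr[0, ]), "baseline")
})

test_that("task-paradigm labels follow rate, ISI CV, burstiness and pause rules", {
  set.seed(2)
  expect_equal(classify_vs_active(sim_poisson_spikes(600, 0.8))$label, "SPN")
  expect_equal(classify_vs_active(sim_poisson_spikes(600, 20))$label, "excluded")
  # regular-ish 4 Hz unit: low CV, few short ISIs -> cholinergic
  chat <- cumsum(pmax(0.08, rnorm(2000, 0.25, 0.05)))
  lab <- classify_vs_active(chat)
  expect_equal(lab$label, "ChAT")
  expect_lt(lab$evidence$isi_cv, 1.2)
  # 5 Hz bursty unit without long pauses -> fast spiking
  isi <- rexp(3000, 5); isi <- pmin(isi, 1.9)
  isi[sample(3000, 600)] <- 0.004          # bursts: high CV, many short ISIs
  fs_unit <- cumsum(isi)
  expect_equal(classify_vs_active(fs_unit)$label, "FS")
  # irregular mid-rate unit with >2 s pauses -> SPN by the pause rule
  expect_equal(classify_vs_active(cumsum(c(rexp(500, 6), 2.5, rexp(500, 6),
                                           2.4, rexp(500, 6))))$label, "SPN")
  expect_equal(classify_vs_active(1:50)$label, "unclassified")
})

test_that("sliding-bin auROC equals the rank-sum statistic and flags separation", {
  set.seed(3)
  for (i in 1:25) {
    x <- rpois(20, sample(1:6, 1)); y <- rpois(40, sample(1:6, 1))
    u <- wilcox.test(x, y, exact = FALSE)$statistic
    expect_equal(vsvta:::.auroc(x, y), unname(u) / (20 * 40), tolerance = 1e-12)
  }
  # identical distributions: trace near 0.5, responsive only at chance rate
  ev <- seq(10, by = 10, length.out = 20)
  sp <- sim_poisson_spikes(215, 3, seed = 4)
  tr0 <- auroc_trace(sp, ev)
  expect_lt(max(abs(tr0$values - 0.5)), 0.25)
  null_rate <- mean(vapply(1:20, function(i)
    auroc_trace(sim_poisson_spikes(215, 3, seed = i + 300), ev)$responsive,
    logical(1)))
  expect_lte(null_rate, 0.2)
  # counts strictly above every baseline count: bin auROC = 1
  resp <- sort(c(sp, unlist(lapply(ev, function(t) t + runif(40, 0, 1)))))
  tr1 <- auroc_trace(resp, ev)
  expect_gt(max(tr1$values), 0.99)
  expect_true(tr1$responsive)
})

test_that("auROC is invariant under strictly monotone count transforms", {
  x <- rpois(15, 4); y <- rpois(30, 2)
  expect_equal(vsvta:::.auroc(x, y), vsvta:::.auroc(x^2 + 3, y^2 + 3))
  expect_equal(vsvta:::.auroc(x, y), vsvta:::.auroc(exp(x), exp(y)))
})

test_that("hierarchical clustering recovers archetypal response types", {
  set.seed(5)
  nb <- 27
  arch <- list(I = c(rep(0.9, nb), rep(0.85, nb)),    # CS+ and US excitation
               II = c(rep(0.5, nb), rep(0.15, nb)),   # US inhibition
               III = c(rep(0.25, nb), rep(0.55, nb)))
  traces <- do.call(rbind, lapply(arch, function(a)
    t(replicate(20, a + rnorm(2 * nb, 0, 0.03)))))
  truth <- rep(c("I", "II", "III"), each = 20)
  cl <- cluster_vta(traces[, 1:nb], traces[, (nb + 1):(2 * nb)])
  expect_equal(as.character(cl$type), truth)
  # duplicating every trace leaves the labels invariant
  cl2 <- cluster_vta(rbind(traces, traces)[, 1:nb],
                     rbind(traces, traces)[, (nb + 1):(2 * nb)])
  expect_equal(as.character(cl2$type), c(truth, truth))
  # synthetic tagged units all drawn from archetype I land in one cluster
  tagged_idx <- which(truth == "I")[1:10]
  expect_gte(mean(cl$type[tagged_idx] == "I"), 0.9)
})

test_that("optogenetic tagging detects locked units and handles edge cases", {
  base <- sim_poisson_spikes(120, 8, seed = 6)
  lb <- simulate_laser_block(base, 0.003, 0.001, 0.8, 10, 400, t_start = 5,
                             seed = 7)
  set.seed(8)
  expect_true(opto_tag(lb$spikes, lb$pulse_times, n_control = 2000)$tagged)
  # long-latency following falls outside the 0-20 ms test window
  lb2 <- simulate_laser_block(base, 0.05, 0.001, 0.8, 10, 400, t_start = 5,
                              seed = 9)
  set.seed(10)
  expect_false(opto_tag(lb2$spikes, lb2$pulse_times, n_control = 2000)$tagged)
  expect_false(opto_tag(numeric(0), lb$pulse_times)$tagged)
  set.seed(11)
  expect_warning(opto_tag(base, c(lb$pulse_times, 1e5), n_control = 500),
                 "trimmed")
})

test_that("response classes follow the rate-gate rules", {
  tr <- data.frame(t_on = seq(10, by = 10, length.out = 40),
                   phase = rep(c("pre", "post"), each = 20))
  # exact mean rates: distribute fractional spikes across alternating trials
  mk <- function(bl_hz, resp_hz) {
    sort(unlist(lapply(seq_len(nrow(tr)), function(i) {
      t0 <- tr$t_on[i]
      nb <- floor(bl_hz) + ((i %% 10) < 10 * (bl_hz %% 1))
      nr <- floor(resp_hz) + ((i %% 10) < 10 * (resp_hz %% 1))
      c(t0 - 1 + seq_len(nb) / (nb + 1), t0 + seq_len(nr) / (nr + 1))
    })))
  }
  expect_equal(response_class(mk(1, 1.3), tr, c("pre", "post"))[1], "excitatory")
  expect_equal(response_class(mk(0.4, 0.1), tr, c("pre", "post"))[1], "none")
  expect_equal(response_class(mk(2, 1.5), tr, c("pre", "post"))[1], "inhibitory")
})
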
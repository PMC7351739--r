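test_that("temporally proximal peaks are pruned keeping the higher, earlier on ties", {
  # direct rule check
  expect_equal(vsvta:::.prune_peaks(c(100, 110), c(5, 5), 20), 100)
  expect_equal(vsvta:::.prune_peaks(c(100, 110), c(5, 6), 20), 110)
  expect_equal(vsvta:::.prune_peaks(c(100, 110, 200), c(5, 4, 3), 20),
               c(100, 200))
  # integration: two identical spikes 0.5 ms apart give exactly one event
  fs <- 20000
  set.seed(1)
  x <- rnorm(fs, 0, 0.5)
  tpl <- vsvta:::.spike_template(fs)
  for (i0 in c(5000, 5010)) x[i0:(i0 + 31)] <- x[i0:(i0 + 31)] + 10 * tpl
  det <- detect_spikes(matrix(x, 1), fs = fs)
  in_window <- det$spikes$time_s > 0.24 & det$spikes$time_s < 0.26
  expect_equal(sum(in_window), 1)
})

test_that("median referencing removes common signals exactly", {
  fs <- 20000
  truth <- list(sort(runif(40, 0.05, 1.95)))
  vs <- simulate_voltage(truth, 1, n_channels = 4, duration_s = 2, fs = fs,
                         noise_sd = 0.5, snr = 12, seed = 3)
  d1 <- detect_spikes(vs)
  # inject an arbitrary large waveform common to all channels
  common <- 30 * sin(2 * pi * 7 * seq_len(ncol(vs$samples)) / fs) *
    rbinom(ncol(vs$samples), 1, 0.3)
  vs$samples <- sweep(vs$samples, 2, common, "+")
  d2 <- detect_spikes(vs)
  expect_equal(d1$spikes$time_s, d2$spikes$time_s)
  expect_equal(d1$spikes$amplitude, d2$spikes$amplitude, tolerance = 1e-9)
})

test_that("detection is translation-equivariant", {
  fs <- 20000
  set.seed(4)
  n <- fs
  x <- rnorm(n, 0, 0.3)
  tpl <- vsvta:::.spike_template(fs)
  for (i0 in c(3000, 9000, 15000)) x[i0:(i0 + 31)] <- x[i0:(i0 + 31)] + 8 * tpl
  k <- 400
  xs <- c(x[(n - k + 1):n], x[1:(n - k)])    # circular shift by k samples
  d0 <- detect_spikes(matrix(x, 1), fs = fs)$spikes$time_s
  d1 <- detect_spikes(matrix(xs, 1), fs = fs)$spikes$time_s
  interior <- d0 > 0.05 & d0 < 0.9
  expect_true(all(vapply(d0[interior] + k / fs, function(t)
    any(abs(d1 - t) < 1e-9), logical(1))))
})

test_that("threshold crossings match an independent brute-force count on noise", {
  fs <- 20000
  set.seed(6)
  x <- rnorm(20 * fs)
  det <- detect_spikes(matrix(x, 1), fs = fs, thresh_mad = 4.5)
  # oracle: count distinct sub-threshold->supra-threshold episodes, merged
  # at 1 ms, on the same filtered trace
  filt <- vsvta:::.bandpass_filter(fs, c(300, 5000))
  fx <- -signal::filtfilt(filt, x)
  thr <- 4.5 * mad(fx, constant = 1)
  above <- fx > thr
  starts <- which(diff(c(FALSE, above)) == 1)
  merged <- starts[c(TRUE, diff(starts) >= 0.001 * fs)]
  expect_equal(nrow(det$spikes), length(merged), tolerance = 0.1)
})

test_that("flat channels and too-low sampling rates are rejected gracefully", {
  expect_warning(d <- detect_spikes(matrix(0, 1, 40000), fs = 20000), "flat")
  expect_equal(nrow(d$spikes), 0)
  expect_error(detect_spikes(matrix(rnorm(1000), 1), fs = 8000), "sampling")
})

test_that("sniff-cycle frequency ratios recover constructed modulations", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)
  on <- c(10, 15, 20)
  # constant 5 Hz breathing: ratio 1
  x <- sin(2 * pi * 5 * tt)
  r1 <- sniff_frequency_change(x, fs, on)
  expect_equal(r1$ratio, rep(1, 3), tolerance = 0.02)
  # frequency step 5 -> 8 Hz at each onset cannot be built globally; use one
  on2 <- 10
  ph <- ifelse(tt < on2, 2 * pi * 5 * tt, 2 * pi * (5 * on2 + 8 * (tt - on2)))
  r2 <- sniff_frequency_change(sin(ph), fs, on2)
  expect_equal(r2$ratio, 1.6, tolerance = 0.02)
  # onset in the last cycle: trial dropped and counted
  expect_message(r3 <- sniff_frequency_change(x, fs, c(10, 29.9)), "dropped")
  expect_equal(attr(r3, "n_dropped"), 1)
  expect_equal(nrow(r3), 1)
})
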
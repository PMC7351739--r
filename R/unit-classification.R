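#' Classify a ventral-striatal unit recorded in the passive paradigm
#'
#' Units with a baseline firing rate below 5 Hz are putative striatal
#' projection neurons (SPN). A stability gate excludes units whose baseline
#' drifts: the start-to-end change of the per-trial baseline rate must stay
#' below 10% of the session mean and intermittent block fluctuations within
#' 20%. The first ten odor trials are excluded from response statistics
#' (initial response habituation).
#'
#' @param spikes Spike-time vector of the unit.
#' @param trials Trial table with onset times `t_on`.
#' @param baseline_window_s Seconds before onset used as baseline (default 1).
#' @param rate_thresh_hz SPN rate threshold (default 5).
#' @param drift_tol,fluct_tol Stability tolerances (default 0.10 / 0.20).
#' @param n_blocks Number of trial blocks for the fluctuation check.
#' @param exclude_first Number of initial trials excluded from response
#'   statistics (default 10).
#' @return Object of class `"unit_label"` with fields `label` ("SPN",
#'   "excluded" or "unclassified") and `evidence` (baseline rate, drift,
#'   fluctuation, indices of analysis trials).
#' @export
classify_vs_passive <- function(spikes, trials, baseline_window_s = 1,
                                rate_thresh_hz = 5, drift_tol = 0.10,
                                fluct_tol = 0.20, n_blocks = 8,
                                exclude_first = 10) {
  if (is.null(trials) || !nrow(trials)) stop("no baseline period definable")
  on <- trials$t_on
  bl <- vapply(on, function(t0)
    sum(spikes >= t0 - baseline_window_s & spikes < t0), numeric(1)) /
    baseline_window_s
  m <- mean(bl)
  blocks <- split(bl, cut(seq_along(bl), n_blocks, labels = FALSE))
  bmeans <- vapply(blocks, mean, numeric(1))
  if (m > 0) {
    drift <- abs(bmeans[length(bmeans)] - bmeans[1]) / m
    fluct <- max(abs(bmeans - m)) / m
  } else {
    drift <- 0; fluct <- 0
  }
  stable <- drift < drift_tol && fluct <= fluct_tol
  label <- if (!stable) "excluded"
           else if (m < rate_thresh_hz) "SPN" else "unclassified"
  structure(list(label = label,
                 evidence = list(baseline_hz = m, drift = drift,
                                 fluctuation = fluct, stable = stable,
                                 analysis_trials =
                                   seq_len(nrow(trials))[-seq_len(
                                     min(exclude_first, nrow(trials)))])),
            class = "unit_label")
}

#' Classify a ventral-striatal unit recorded during task performance
#'
#' Baseline-firing-feature rules for units in behaving animals: rate < 2 Hz
#' gives SPN; rate > 12 Hz excludes the unit as a putative fast-spiking
#' neuron; units in the ambiguous 2-12 Hz range are putative cholinergic
#' interneurons (ChAT) if the ISI coefficient of variation is < 1.2 and ISIs
#' below 60 ms contribute at most 20%, otherwise SPN if the unit ever pauses
#' (fraction of ISIs > 2 s exceeding 1e-4), else fast-spiking.
#'
#' @param spikes Spike-time vector.
#' @param span_s Recording span used for the rate; defaults to the spike
#'   range.
#' @return Object of class `"unit_label"` with `label` in \{"SPN", "ChAT",
#'   "FS", "excluded", "unclassified"\} and the statistics that fired the
#'   rule in `evidence`.
#' @export
classify_vs_active <- function(spikes, span_s = NULL) {
  isi <- diff(spikes)
  if (length(isi) < 100)
    return(structure(list(label = "unclassified",
                          evidence = list(n_isi = length(isi))),
                     class = "unit_label"))
  if (is.null(span_s)) span_s <- diff(range(spikes))
  rate <- length(spikes) / span_s
  cv <- sd(isi) / mean(isi)
  frac_short <- mean(isi < 0.060)
  frac_pause <- mean(isi > 2)
  ev <- list(rate_hz = rate, isi_cv = cv, frac_isi_lt60ms = frac_short,
             frac_isi_gt2s = frac_pause)
  label <- if (rate < 2) "SPN"
    else if (rate > 12) "excluded"
    else if (cv < 1.2 && frac_short <= 0.20) "ChAT"
    else if (frac_pause > 1e-4) "SPN"
    else "FS"
  structure(list(label = label, evidence = ev), class = "unit_label")
}

#' @export
print.unit_label <- function(x, ...) {
  cat("Unit label:", x$label, "\n")
  ev <- x$evidence[vapply(x$evidence, is.numeric, logical(1))]
  ev <- ev[lengths(ev) == 1L]
  if (length(ev))
    cat(" ", paste(names(ev), "=", signif(unlist(ev), 3), collapse = ", "), "\n")
  invisible(x)
}

# auROC of counts x (response) vs y (control) via the rank-sum statistic,
# ties counted half: U/(n1*n2)
.auroc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Sliding-window auROC response trace
#'
#' Characterises a unit's event-locked response: spike counts in 200-ms bins
#' shifted by 50 ms across the window around each event are compared, trial
#' by trial, against a control distribution built by tiling the 2 s before
#' trial onset with 200-ms bins (all baseline bins merged). Each bin yields
#' the area under the ROC between the trial count distribution and the
#' control distribution (0.5 = indistinguishable). Responsiveness is
#' assessed with a Friedman test across trials, with bins (response and
#' baseline) as treatments and trials as blocks.
#'
#' @param spikes Spike-time vector.
#' @param event_times Event (CS or US) times, at least 10.
#' @param window_s Response window around the event (default `c(-0.5, 1)`).
#' @param bin_s,step_s Sliding-bin width and step (defaults 0.2 / 0.05 s).
#' @param baseline_window_s Length of the pre-trial control period
#'   (default 2).
#' @param trial_onsets Trial onset times anchoring the control period;
#'   defaults to the event times.
#' @return Object of class `"auroc_trace"`: `values` per bin (in \[0,1\]),
#'   `bin_times` (bin starts relative to the event), `p_value` of the
#'   Friedman test, and `responsive` flag (p < 0.05).
#' @export
auroc_trace <- function(spikes, event_times, window_s = c(-0.5, 1),
                        bin_s = 0.2, step_s = 0.05, baseline_window_s = 2,
                        trial_onsets = NULL) {
  if (length(event_times) < 10) stop("need at least 10 trials per event")
  if (is.null(trial_onsets)) trial_onsets <- event_times
  starts <- seq(window_s[1], window_s[2] - bin_s + 1e-9, by = step_s)
  nt <- length(event_times)
  counts <- matrix(0L, nt, length(starts))
  for (i in seq_len(nt)) {
    rel <- spikes - event_times[i]
    counts[i, ] <- vapply(starts, function(s0)
      sum(rel >= s0 & rel < s0 + bin_s), integer(1))
  }
  nb <- floor(baseline_window_s / bin_s)
  bl_starts <- -baseline_window_s + (seq_len(nb) - 1) * bin_s
  bl <- matrix(0L, nt, nb)
  for (i in seq_len(nt)) {
    rel <- spikes - trial_onsets[i]
    bl[i, ] <- vapply(bl_starts, function(s0)
      sum(rel >= s0 & rel < s0 + bin_s), integer(1))
  }
  if (!length(bl)) stop("empty control distribution")
  ctrl <- as.vector(bl)
  vals <- apply(counts, 2, .auroc, y = ctrl)
  fr <- friedman.test(cbind(counts, bl))
  structure(list(values = vals, bin_times = starts,
                 p_value = fr$p.value, responsive = fr$p.value < 0.05,
                 n_trials = nt),
            class = "auroc_trace")
}

#' @export
print.auroc_trace <- function(x, ...) {
  cat(sprintf("auROC trace: %d bins, range [%.2f, %.2f], Friedman p = %.3g%s\n",
              length(x$values), min(x$values), max(x$values), x$p_value,
              if (x$responsive) " (responsive)" else ""))
  invisible(x)
}

#' Cluster VTA units into three response types
#'
#' Agglomerative hierarchical clustering (L1 / cityblock metric, average
#' linkage, cut at three clusters) of the concatenated CS+ and US auROC
#' traces of responsive units. The cluster whose mean trace shows the
#' strongest phasic excitation (highest mean auROC over the US segment,
#' breaking ties with the CS+ segment) is labelled type I (putative
#' dopaminergic); of the remaining two, the one with the higher CS+ segment
#' is type II, the other type III.
#'
#' @param cs_traces,us_traces Matrices (units x bins) of auROC values around
#'   CS+ and US.
#' @return Object of class `"vta_clusters"`: `type` (factor "I"/"II"/"III"
#'   per unit), `cluster` (raw cut labels), `hclust` (dendrogram),
#'   `centroids`.
#' @export
cluster_vta <- function(cs_traces, us_traces) {
  stopifnot(nrow(cs_traces) == nrow(us_traces))
  x <- cbind(cs_traces, us_traces)
  if (nrow(x) < 3) stop("need at least 3 units to form 3 clusters")
  hc <- hclust(dist(x, method = "manhattan"), method = "average")
  cl <- cutree(hc, k = 3)
  nc <- ncol(cs_traces)
  us_mean <- tapply(rowMeans(x[, (nc + 1):ncol(x), drop = FALSE]), cl, mean)
  cs_mean <- tapply(rowMeans(x[, seq_len(nc), drop = FALSE]), cl, mean)
  ord <- order(-us_mean, -cs_mean)
  type1 <- as.integer(names(us_mean)[ord[1]])
  rest <- as.integer(names(us_mean)[ord[-1]])
  type2 <- rest[which.max(cs_mean[as.character(rest)])]
  type3 <- setdiff(rest, type2)
  type <- factor(ifelse(cl == type1, "I", ifelse(cl == type2, "II", "III")),
                 levels = c("I", "II", "III"))
  structure(list(type = type, cluster = cl, hclust = hc,
                 centroids = rbind(I = colMeans(x[cl == type1, , drop = FALSE]),
                                   II = colMeans(x[cl == type2, , drop = FALSE]),
                                   III = colMeans(x[cl == type3, , drop = FALSE]))),
            class = "vta_clusters")
}

#' @export
print.vta_clusters <- function(x, ...) {
  cat("VTA unit clustering (L1, average linkage):\n")
  print(table(x$type))
  invisible(x)
}

#' Optogenetic tagging test by jittered cross-correlograms
#'
#' Builds the spike/laser-pulse cross-correlogram (1-ms bins, lags 0-20 ms)
#' and compares it against `n_control` control cross-correlograms in which
#' every pulse is independently jittered uniformly within +/- 30 ms. The
#' unit is tagged if at least two consecutive test bins exceed the 95th
#' percentile of the pooled (global) distribution of all control bins.
#'
#' @param spikes Spike-time vector.
#' @param pulse_times Laser pulse times (>= 100 recommended).
#' @param lag_max_s Maximal tested lag (default 0.020 s).
#' @param bin_s CCG bin width (default 0.001 s).
#' @param jitter_s Control jitter half-width (default 0.030 s).
#' @param n_control Number of control cross-correlograms (default 10000).
#' @param q Control quantile (default 0.95).
#' @return Object of class `"opto_tag"`: `tagged` flag, the test `ccg`,
#'   the control `threshold`, and the bins above threshold.
#' @export
opto_tag <- function(spikes, pulse_times, lag_max_s = 0.020, bin_s = 0.001,
                     jitter_s = 0.030, n_control = 10000, q = 0.95) {
  nbin <- round(lag_max_s / bin_s)
  if (!length(spikes)) {
    return(structure(list(tagged = FALSE, ccg = rep(0L, nbin),
                          threshold = NA_real_, above = logical(nbin)),
                     class = "opto_tag"))
  }
  span <- range(spikes)
  inside <- pulse_times >= span[1] - jitter_s - lag_max_s &
    pulse_times <= span[2] + jitter_s
  if (any(!inside)) {
    warning(sum(!inside), " pulse(s) outside the recording span trimmed")
    pulse_times <- pulse_times[inside]
  }
  np <- length(pulse_times)
  if (!np)
    return(structure(list(tagged = FALSE, ccg = rep(0L, nbin),
                          threshold = NA_real_, above = logical(nbin)),
                     class = "opto_tag"))

  # all spike-pulse lags that could fall in [0, lag_max) under any jitter
  reach <- lag_max_s + jitter_s
  lags <- numeric(0); pulse_of <- integer(0)
  for (i in seq_len(np)) {
    sel <- spikes >= pulse_times[i] - jitter_s & spikes < pulse_times[i] + reach
    if (any(sel)) {
      lags <- c(lags, spikes[sel] - pulse_times[i])
      pulse_of <- c(pulse_of, rep(i, sum(sel)))
    }
  }
  test_bin <- floor(lags / bin_s)
  ccg <- tabulate(test_bin[test_bin >= 0 & test_bin < nbin] + 1L, nbins = nbin)

  if (length(lags)) {
    jit <- matrix(runif(np * n_control, -jitter_s, jitter_s), np, n_control)
    shifted <- matrix(lags, length(lags), n_control) - jit[pulse_of, , drop = FALSE]
    sb <- floor(shifted / bin_s)
    ok <- sb >= 0 & sb < nbin
    idx <- sb[ok] + nbin * (col(sb)[ok] - 1L)   # bin within control CCG
    ctrl_counts <- tabulate(idx + 1L, nbins = nbin * n_control)
  } else {
    ctrl_counts <- rep(0L, nbin * n_control)
  }
  threshold <- quantile(ctrl_counts, q, names = FALSE, type = 1)
  above <- ccg > threshold
  tagged <- any(above[-1] & above[-length(above)])
  structure(list(tagged = tagged, ccg = ccg, threshold = threshold,
                 above = above, n_pulses = np),
            class = "opto_tag")
}

#' @export
print.opto_tag <- function(x, ...) {
  cat("Optogenetic tagging test:", if (x$tagged) "TAGGED" else "not tagged",
      sprintf("(max bin %d, control 95%% = %s)\n",
              if (length(x$ccg)) max(x$ccg) else 0, format(x$threshold)))
  invisible(x)
}

#' Classify a unit's odor response as excitatory, inhibitory or none
#'
#' Excitatory: mean firing rate in the 1-s response window of at least 1 Hz
#' and at least +20% versus the 1-s pre-onset baseline, in either of the two
#' phases. Inhibitory: baseline of at least 0.5 Hz and at least -20% in
#' either phase. Excitation takes precedence if both rules fire.
#'
#' @param spikes Spike-time vector.
#' @param trials Trial table with `t_on` and `phase`.
#' @param phases Two phase labels to evaluate (default the first two levels
#'   present).
#' @param response_window_s,baseline_window_s Window lengths (default 1 s).
#' @param min_excit_hz,min_inhib_baseline_hz Rate gates (1 and 0.5 Hz).
#' @return Character scalar: "excitatory", "inhibitory" or "none"; rates per
#'   phase in attribute `rates`.
#' @export
response_class <- function(spikes, trials, phases = NULL,
                           response_window_s = 1, baseline_window_s = 1,
                           min_excit_hz = 1, min_inhib_baseline_hz = 0.5) {
  if (is.null(phases)) phases <- unique(trials$phase)[1:2]
  rates <- lapply(phases, function(ph) {
    on <- trials$t_on[trials$phase == ph]
    bl <- mean(vapply(on, function(t0)
      sum(spikes >= t0 - baseline_window_s & spikes < t0), numeric(1))) /
      baseline_window_s
    rs <- mean(vapply(on, function(t0)
      sum(spikes >= t0 & spikes < t0 + response_window_s), numeric(1))) /
      response_window_s
    c(baseline = bl, response = rs)
  })
  names(rates) <- phases
  excit <- any(vapply(rates, function(r)
    r["response"] >= min_excit_hz && r["response"] >= 1.2 * r["baseline"],
    logical(1)))
  inhib <- any(vapply(rates, function(r)
    r["baseline"] >= min_inhib_baseline_hz &&
      r["response"] <= 0.8 * r["baseline"], logical(1)))
  out <- if (excit) "excitatory" else if (inhib) "inhibitory" else "none"
  attr(out, "rates") <- rates
  out
}
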
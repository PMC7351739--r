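.bandpass_filter <- function(fs, band, order = 4) {
  if (fs <= 2 * band[2])
    stop("sampling rate too low for the requested band-pass corner (",
         band[2], " Hz)")
  signal::butter(order, band / (fs / 2), type = "pass")
}

# greedy height-based pruning: keep the higher of any two peaks closer than
# min_dist samples; exact ties broken by the earlier sample
.prune_peaks <- function(idx, height, min_dist) {
  if (!length(idx)) return(integer(0))
  ord <- order(-height, idx)
  keep <- logical(length(idx))
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(idx[j] - taken) >= min_dist)) {
      keep[j] <- TRUE
      taken <- c(taken, idx[j])
    }
  }
  sort(idx[keep])
}

#' Detect spikes in a multichannel voltage trace
#'
#' Detection chain: (i) subtraction of the per-sample median across channels
#' (removes any signal common to all channels exactly; applied when at least
#' four channels are present), (ii) 4th-order Butterworth band-pass 300-5000
#' Hz (zero-phase), (iii) per-channel amplitude threshold at `thresh_mad`
#' times the raw median absolute deviation of the filtered trace (no 1.4826
#' scale factor), (iv) peaks closer than 1 ms pruned keeping the higher
#' (earlier wins exact ties), (v) events detected on several channels of a
#' tetrode merged to the timestamp of the highest peak, (vi) waveforms cut
#' -10..+21 samples around the peak.
#'
#' @param samples Channels x time numeric matrix (or a `"voltage_sim"`).
#' @param fs Sampling rate in Hz (>= 20 kHz).
#' @param thresh_mad Threshold multiple of the raw MAD (default 7.5).
#' @param polarity `"negative"` (extracellular convention, default) or
#'   `"positive"`.
#' @param tetrodes Optional list of channel-index groups; by default all
#'   channels form consecutive groups of four (a trailing smaller group is
#'   kept).
#' @param band Band-pass corners in Hz.
#' @param common_ref Subtract the across-channel median (default TRUE; only
#'   applied with >= 4 channels).
#' @return Object of class `"spike_detection"`: `spikes` (data frame with
#'   `time_s`, `group`, `channel`, `amplitude`), `waveforms` (events x 32
#'   matrix of filtered voltage), `threshold` per channel, `fs`.
#' @export
detect_spikes <- function(samples, fs = NULL, thresh_mad = 7.5,
                          polarity = c("negative", "positive"),
                          tetrodes = NULL, band = c(300, 5000),
                          common_ref = TRUE) {
  if (inherits(samples, "voltage_sim")) {
    if (is.null(fs)) fs <- samples$fs
    samples <- samples$samples
  }
  if (is.null(fs)) stop("fs required")
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!all(is.finite(samples))) stop("voltage trace contains non-finite values")
  polarity <- match.arg(polarity)
  nch <- nrow(samples); n <- ncol(samples)
  if (nch >= 4 && common_ref) {
    med <- apply(samples, 2, median)
    samples <- sweep(samples, 2, med, "-")
  }
  filt <- .bandpass_filter(fs, band)
  fx <- t(apply(samples, 1, function(ch) signal::filtfilt(filt, ch)))
  if (nch == 1) fx <- matrix(fx, nrow = 1)

  min_dist <- max(1L, round(0.001 * fs))
  if (is.null(tetrodes))
    tetrodes <- split(seq_len(nch), ceiling(seq_len(nch) / 4))

  thr <- numeric(nch)
  per_ch <- vector("list", nch)
  for (ch in seq_len(nch)) {
    x <- if (polarity == "negative") -fx[ch, ] else fx[ch, ]
    m <- mad(x, constant = 1)
    thr[ch] <- thresh_mad * m
    if (m == 0) {
      warning("channel ", ch, " is flat; zero detections")
      per_ch[[ch]] <- data.frame(idx = integer(0), channel = integer(0),
                                 amplitude = numeric(0))
      next
    }
    # strict left / non-strict right comparison: earliest sample of a
    # plateau is the peak (determinism)
    core <- 2:(n - 1)
    is_peak <- x[core] > thr[ch] & x[core] > x[core - 1] & x[core] >= x[core + 1]
    idx <- core[is_peak]
    idx <- .prune_peaks(idx, x[idx], min_dist)
    per_ch[[ch]] <- data.frame(idx = idx, channel = rep(ch, length(idx)),
                               amplitude = x[idx])
  }

  out <- list()
  for (g in seq_along(tetrodes)) {
    ev <- do.call(rbind, per_ch[tetrodes[[g]]])
    if (is.null(ev) || !nrow(ev)) next
    # merge cross-channel duplicates: keep the highest peak (tie: earlier
    # sample, then lower channel)
    ord <- order(-ev$amplitude, ev$idx, ev$channel)
    keep <- logical(nrow(ev)); taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(ev$idx[j] - taken) >= min_dist)) {
        keep[j] <- TRUE
        taken <- c(taken, ev$idx[j])
      }
    }
    ev <- ev[keep, , drop = FALSE]
    ev$group <- g
    out[[length(out) + 1L]] <- ev
  }
  ev <- if (length(out)) do.call(rbind, out)
        else data.frame(idx = integer(0), channel = integer(0),
                        amplitude = numeric(0), group = integer(0))
  ev <- ev[order(ev$idx), , drop = FALSE]

  wf_ok <- ev$idx - 10 >= 1 & ev$idx + 21 <= n
  wf <- matrix(NA_real_, nrow(ev), 32)
  for (j in which(wf_ok))
    wf[j, ] <- fx[ev$channel[j], (ev$idx[j] - 10):(ev$idx[j] + 21)]

  structure(list(
    spikes = data.frame(time_s = ev$idx / fs, group = ev$group,
                        channel = ev$channel, amplitude = ev$amplitude),
    waveforms = wf, threshold = thr, fs = fs, polarity = polarity),
    class = "spike_detection")
}

#' @export
print.spike_detection <- function(x, ...) {
  cat("Spike detection:", nrow(x$spikes), "events on",
      length(x$threshold), "channel(s), fs =", x$fs, "Hz\n")
  invisible(x)
}

#' Sniff-cycle frequency change around odor onset
#'
#' Band-pass filters the respiration pressure trace (1-50 Hz), anchors sniff
#' cycles at inhalation onsets (negative-going zero crossings by default),
#' and for each odor onset converts the duration of the two full cycles
#' before vs. after onset into frequencies. Trials with fewer than two full
#' cycles on either side are dropped and counted.
#'
#' @param pressure Numeric pressure trace.
#' @param fs Sampling rate in Hz (> 100).
#' @param odor_onsets Odor onset times in seconds.
#' @param phase Optional phase label per onset; per-phase means are then
#'   reported.
#' @param band Filter band in Hz (default `c(1, 50)`).
#' @param anchor `"negative"` (inhalation onset = negative-going zero
#'   crossing, default) or `"positive"`.
#' @return Data frame with per-trial `f_pre`, `f_post` (Hz) and
#'   `ratio = f_post / f_pre`; dropped-trial count in attribute `n_dropped`,
#'   per-phase means in attribute `phase_means`.
#' @export
sniff_frequency_change <- function(pressure, fs, odor_onsets, phase = NULL,
                                   band = c(1, 50), anchor = c("negative",
                                                               "positive")) {
  anchor <- match.arg(anchor)
  stopifnot(fs > 100)
  filt <- .bandpass_filter(fs, band, order = 2)
  x <- signal::filtfilt(filt, pressure)
  if (anchor == "positive") x <- -x
  n <- length(x)
  cross <- which(x[-n] > 0 & x[-1] <= 0)          # negative-going crossings
  # linear interpolation of the crossing time
  ct <- (cross + x[cross] / (x[cross] - x[cross + 1])) / fs

  res <- data.frame(onset = odor_onsets, f_pre = NA_real_, f_post = NA_real_)
  for (i in seq_along(odor_onsets)) {
    on <- odor_onsets[i]
    pre <- ct[ct <= on]
    post <- ct[ct >= on]
    if (length(pre) >= 3) res$f_pre[i] <- 2 / (pre[length(pre)] - pre[length(pre) - 2])
    if (length(post) >= 3) res$f_post[i] <- 2 / (post[3] - post[1])
  }
  res$ratio <- res$f_post / res$f_pre
  dropped <- !is.finite(res$ratio)
  if (any(dropped))
    message(sum(dropped), " trial(s) dropped (fewer than two full sniff cycles)")
  out <- res[!dropped, , drop = FALSE]
  attr(out, "n_dropped") <- sum(dropped)
  if (!is.null(phase)) {
    ph <- phase[!dropped]
    attr(out, "phase_means") <- tapply(out$ratio, ph, mean)
  }
  out
}
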
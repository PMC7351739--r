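#' Specification of a simulated unit
#'
#' Describes one unit's firing model: an inhomogeneous Poisson process with
#' instantaneous rate
#' \deqn{\lambda(t) = [\,b\,(1 + d(t)) + \sum_{trials} k(t)\,(1 + g\,V_{CS+}(t))\,]_+}
#' where `b` is the baseline rate, `d(t)` a slow sinusoidal rate drift,
#' `k(t)` a boxcar odor-response kernel (per-odor amplitude, latency and
#' duration), `g` the learning gain coupling response amplitude to the
#' trial-wise stimulus value, and \eqn{[.]_+} rectification at zero.
#'
#' @param role Cell class label ("SPN", "DAN", "FS", "ChAT").
#' @param baseline_hz Baseline rate in Hz (>= 0).
#' @param kernels Named list per odor (e.g. `list(A = list(amplitude_hz = 4,
#'   latency_s = 0.05, duration_s = 1))`). Negative amplitudes give
#'   inhibitory responses.
#' @param learning_gain Multiplier coupling kernel amplitude to
#'   \eqn{V_{CS+}(t)} (default 0). Applied to CS+ trials only.
#' @param drift_amp Relative amplitude of the slow sinusoidal rate drift
#'   (default 0).
#' @param drift_period_s Drift timescale in seconds (default 300).
#' @param phase_gain Optional named numeric vector of kernel-amplitude
#'   multipliers per task phase (e.g. `c(post = 1.3)`).
#' @return A list of class `"unit_spec"`.
#' @export
unit_spec <- function(role = "SPN", baseline_hz = 1, kernels = list(),
                      learning_gain = 0, drift_amp = 0, drift_period_s = 300,
                      phase_gain = NULL) {
  stopifnot(baseline_hz >= 0, drift_amp >= 0, drift_period_s > 0)
  structure(list(role = role, baseline_hz = baseline_hz, kernels = kernels,
                 learning_gain = learning_gain, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, phase_gain = phase_gain),
            class = "unit_spec")
}

#' Directed coupling between two simulated units
#'
#' Each source spike induces, with probability `efficacy`, one extra target
#' spike at `lag_s` plus Gaussian timing jitter of SD `precision_s`.
#'
#' @param lag_s Induced source-to-target delay in seconds (>= 0).
#' @param precision_s Jitter SD of induced spikes (> 0).
#' @param efficacy Probability in \[0,1\] that a source spike induces a
#'   target spike; may also be a per-trial vector (see `window`).
#' @param window `"all"` couples every source spike; `"cs_plus"` restricts
#'   coupling to source spikes within `window_len_s` after CS+ onsets.
#' @param window_len_s Length of the per-trial coupling window (default 1 s).
#' @return A list of class `"assembly_coupling_spec"`.
#' @export
assembly_coupling_spec <- function(lag_s, precision_s, efficacy,
                                   window = c("all", "cs_plus"),
                                   window_len_s = 1) {
  window <- match.arg(window)
  stopifnot(lag_s >= 0, precision_s > 0,
            all(efficacy >= 0), all(efficacy <= 1))
  structure(list(lag_s = lag_s, precision_s = precision_s,
                 efficacy = efficacy, window = window,
                 window_len_s = window_len_s),
            class = "assembly_coupling_spec")
}

# instantaneous rate of a unit at times tt (uses current RNG only via caller)
.unit_rate <- function(spec, tt, trials, value_trace, drift_phase) {
  rate <- spec$baseline_hz *
    (1 + spec$drift_amp * sin(2 * pi * tt / spec$drift_period_s + drift_phase))
  if (length(spec$kernels) && !is.null(trials) && nrow(trials)) {
    idx <- findInterval(tt, trials$t_on)
    ok <- idx >= 1L
    if (any(ok)) {
      tr <- trials[idx[ok], , drop = FALSE]
      rel <- tt[ok] - tr$t_on
      add <- numeric(sum(ok))
      # phase_gain applies to kernels marked with $phase_gain = TRUE, or to
      # all kernels when none is marked
      marked <- vapply(spec$kernels, function(k) isTRUE(k$phase_gain),
                       logical(1))
      gated <- if (any(marked)) marked else !marked
      for (od in names(spec$kernels)) {
        k <- spec$kernels[[od]]
        hit <- tr$odor == od & rel >= k$latency_s &
          rel < k$latency_s + k$duration_s
        if (!any(hit)) next
        amp <- rep(k$amplitude_hz, sum(hit))
        if (spec$learning_gain != 0 && !is.null(value_trace)) {
          cs <- if ("cs_plus" %in% names(tr)) tr$cs_plus[hit] else rep(TRUE, sum(hit))
          v <- value_trace[tr$trial[hit]]
          amp <- amp * (1 + spec$learning_gain * v * as.numeric(cs))
        }
        if (!is.null(spec$phase_gain) && gated[[od]] &&
            "phase" %in% names(tr)) {
          g <- spec$phase_gain[tr$phase[hit]]
          g[is.na(g)] <- 1
          amp <- amp * g
        }
        add[hit] <- add[hit] + amp
      }
      rate[ok] <- rate[ok] + add
    }
  }
  pmax(rate, 0)
}

.unit_rate_max <- function(spec, value_trace) {
  amp <- 0
  if (length(spec$kernels))
    amp <- max(0, vapply(spec$kernels, function(k) abs(k$amplitude_hz),
                         numeric(1)))
  gain <- 1 + max(0, spec$learning_gain) *
    (if (is.null(value_trace)) 1 else max(0, value_trace, na.rm = TRUE))
  pg <- if (is.null(spec$phase_gain)) 1 else max(1, spec$phase_gain)
  spec$baseline_hz * (1 + spec$drift_amp) + amp * gain * pg
}

# inhomogeneous Poisson by thinning; consumes the current RNG stream
.sim_unit <- function(spec, trials, value_trace, t_end) {
  drift_phase <- runif(1, 0, 2 * pi)
  rmax <- .unit_rate_max(spec, value_trace)
  if (rmax <= 0) return(numeric(0))
  n_cand <- rpois(1, rmax * t_end)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(runif(n_cand, 0, t_end))
  lam <- .unit_rate(spec, tt, trials, value_trace, drift_phase)
  tt[runif(n_cand) < lam / rmax]
}

#' Simulate one unit's spike train
#'
#' Draws spike times from the inhomogeneous Poisson process defined by a
#' [unit_spec()], with the odor-response kernel amplitude modulated by the
#' trial-wise stimulus value when `learning_gain` is non-zero. Rates are
#' rectified at zero, so negative requested rates are never emitted.
#'
#' @param spec A [unit_spec()].
#' @param trials Trial table with columns `trial`, `t_on`, `odor` (and
#'   optionally `cs_plus`, `phase`), e.g. from [simulate_task_session()];
#'   may be `NULL` for a background-only unit.
#' @param value_trace Optional per-trial \eqn{V_{CS+}} vector.
#' @param t_end Recording length in seconds (defaults to 10 s past the last
#'   trial onset).
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
simulate_unit <- function(spec, trials = NULL, value_trace = NULL,
                          t_end = NULL, seed) {
  stopifnot(inherits(spec, "unit_spec"))
  if (!is.null(trials)) {
    if (is.unsorted(trials$t_on, strictly = TRUE))
      stop("trial onset times must be strictly increasing")
    if (is.null(t_end)) t_end <- max(trials$t_on) + 10
  }
  if (is.null(t_end)) stop("t_end required when no trials are given")
  set.seed(seed)
  .sim_unit(spec, trials, value_trace, t_end)
}

#' Simulate a coupled source-target unit pair
#'
#' Generates a source train and an independent target background train, then
#' adds to the target, for each eligible source spike with probability
#' `efficacy`, an induced spike at the source time plus `lag_s` and Gaussian
#' jitter (SD `precision_s`).
#'
#' @param src,tgt [unit_spec()]s for the source (e.g. SPN) and target
#'   (e.g. DAN) unit.
#' @param coupling An [assembly_coupling_spec()]. If `efficacy` is a vector,
#'   it is indexed by the trial containing each source spike (spikes outside
#'   trial windows are not coupled).
#' @param trials Optional trial table (required for `window = "cs_plus"` or
#'   per-trial efficacy).
#' @param value_trace Optional per-trial value trace passed to the units.
#' @param t_end Recording length in seconds.
#' @param seed Integer seed.
#' @return List with sorted spike-time vectors `src` and `tgt`, and
#'   `n_induced`, the number of coupled spikes added.
#' @export
simulate_assembly_pair <- function(src, tgt, coupling, trials = NULL,
                                   value_trace = NULL, t_end = NULL, seed) {
  stopifnot(inherits(coupling, "assembly_coupling_spec"))
  if (is.null(t_end)) {
    if (is.null(trials)) stop("t_end required when no trials are given")
    t_end <- max(trials$t_on) + 10
  }
  set.seed(seed)
  s_src <- .sim_unit(src, trials, value_trace, t_end)
  s_tgt <- .sim_unit(tgt, trials, value_trace, t_end)

  eff <- rep(0, length(s_src))
  if (length(coupling$efficacy) == 1L && coupling$window == "all") {
    eff[] <- coupling$efficacy
  } else {
    if (is.null(trials)) stop("trials required for windowed/per-trial coupling")
    idx <- findInterval(s_src, trials$t_on)
    ok <- idx >= 1L
    rel <- s_src[ok] - trials$t_on[idx[ok]]
    inwin <- rel < coupling$window_len_s
    if (coupling$window == "cs_plus" && "cs_plus" %in% names(trials))
      inwin <- inwin & trials$cs_plus[idx[ok]]
    e <- if (length(coupling$efficacy) == 1L) rep(coupling$efficacy, nrow(trials))
         else coupling$efficacy
    eff[ok][inwin] <- e[idx[ok]][inwin]
  }
  fire <- runif(length(s_src)) < eff
  induced <- s_src[fire] + coupling$lag_s +
    rnorm(sum(fire), 0, coupling$precision_s)
  induced <- induced[induced >= 0 & induced <= t_end]
  list(src = s_src, tgt = sort(c(s_tgt, induced)), n_induced = length(induced))
}

# default extracellular waveform template: biphasic, negative-leading
.spike_template <- function(fs, n = 32) {
  t <- (seq_len(n) - 11) / fs * 1000      # ms, peak at sample 11
  -exp(-(t / 0.15)^2) + 0.35 * exp(-((t - 0.45) / 0.3)^2)
}

#' Simulate a multichannel voltage trace with embedded spikes
#'
#' Gaussian noise on each channel, an optional large common-mode artifact
#' shared by all channels, and a spike waveform template inserted at each
#' unit's ground-truth spike times. The signal-to-noise ratio is defined on
#' the detector's working signal: `snr` is the ratio of the band-pass
#' filtered template peak to the median absolute deviation of the band-pass
#' filtered noise (both computed analytically from the filter's impulse
#' response), so `snr = 10` yields spikes whose filtered peak sits at ten
#' filtered-noise MADs.
#'
#' @param spike_times List of numeric vectors, one per unit (ground truth).
#' @param unit_channels Integer vector assigning each unit to a channel.
#' @param n_channels Number of channels (default 4, one tetrode).
#' @param duration_s Trace length in seconds.
#' @param fs Sampling rate in Hz (>= 20000).
#' @param noise_sd Noise standard deviation in raw units (default 1).
#' @param snr Filtered peak / filtered-noise-MAD ratio of inserted spikes.
#' @param common_mode Optional list `list(amplitude =, rate_hz =,
#'   width_s =)` describing slow artifact bumps added identically to all
#'   channels.
#' @param template Optional custom waveform (numeric vector); must be shorter
#'   than the trace.
#' @param seed Integer seed.
#' @return List of class `"voltage_sim"`: `samples` (channels x time matrix),
#'   `fs`, `spike_times`, `unit_channels`, `template`, `amplitude`.
#' @export
simulate_voltage <- function(spike_times, unit_channels, n_channels = 4,
                             duration_s, fs = 20000, noise_sd = 1, snr = 10,
                             common_mode = NULL, template = NULL, seed) {
  stopifnot(fs >= 20000, length(spike_times) == length(unit_channels))
  n <- round(duration_s * fs)
  if (is.null(template)) template <- .spike_template(fs)
  if (length(template) >= n) stop("template longer than trace")
  set.seed(seed)

  # analytic SNR calibration on the filtered signal
  filt <- .bandpass_filter(fs, c(300, 5000))
  h <- signal::filtfilt(filt, c(rep(0, 256), 1, rep(0, 255)))
  noise_gain <- sqrt(sum(h^2))               # filtered-noise SD per unit SD
  tpl_f <- signal::filtfilt(filt, c(rep(0, 128), template, rep(0, 128)))
  peak_gain <- max(abs(tpl_f)) / max(abs(template))
  mad_f <- 0.6745 * noise_sd * noise_gain    # MAD of filtered Gaussian noise
  amplitude <- snr * mad_f / peak_gain / max(abs(template))

  v <- matrix(rnorm(n_channels * n, 0, noise_sd), n_channels, n)
  if (!is.null(common_mode)) {
    cm <- numeric(n)
    n_ev <- rpois(1, common_mode$rate_hz * duration_s)
    if (n_ev > 0) {
      centers <- runif(n_ev, 0, duration_s)
      w <- common_mode$width_s
      tt <- seq_len(n) / fs
      for (c0 in centers)
        cm <- cm + common_mode$amplitude * exp(-((tt - c0) / w)^2)
    }
    v <- sweep(v, 2, cm, "+")
  }
  pre <- 10L
  for (u in seq_along(spike_times)) {
    ch <- unit_channels[u]
    for (ts in spike_times[[u]]) {
      i0 <- round(ts * fs) - pre
      if (i0 < 1 || i0 + length(template) - 1 > n) next
      idx <- i0:(i0 + length(template) - 1)
      v[ch, idx] <- v[ch, idx] + amplitude * template
    }
  }
  structure(list(samples = v, fs = fs, spike_times = spike_times,
                 unit_channels = unit_channels, template = template,
                 amplitude = amplitude),
            class = "voltage_sim")
}

#' Add laser-pulse-locked spikes to a spike train
#'
#' Models an optogenetic tagging block: a train of brief laser pulses at
#' `pulse_rate_hz`; each pulse adds, with probability `p_follow`, one spike
#' at the pulse time plus `latency_s` and Gaussian jitter `jitter_s`.
#'
#' @param spikes Baseline spike-time vector.
#' @param latency_s Mean spike latency after the pulse (e.g. 0.003 s).
#' @param jitter_s Latency jitter SD.
#' @param p_follow Per-pulse follow probability in \[0,1\].
#' @param pulse_rate_hz Pulse rate (8-12 Hz typical).
#' @param n_pulses Number of pulses.
#' @param t_start Time of the first pulse (default: 1 s after last spike, or
#'   0 for an empty train).
#' @param seed Integer seed.
#' @return List with sorted `spikes` (original plus locked) and `pulse_times`.
#' @export
simulate_laser_block <- function(spikes, latency_s, jitter_s, p_follow,
                                 pulse_rate_hz = 10, n_pulses = 500,
                                 t_start = NULL, seed) {
  stopifnot(p_follow >= 0, p_follow <= 1)
  set.seed(seed)
  if (is.null(t_start))
    t_start <- if (length(spikes)) max(spikes) + 1 else 0
  pulses <- t_start + (seq_len(n_pulses) - 1) / pulse_rate_hz
  fire <- runif(n_pulses) < p_follow
  locked <- pulses[fire] + latency_s + rnorm(sum(fire), 0, jitter_s)
  list(spikes = sort(c(spikes, locked)), pulse_times = pulses)
}

#' Homogeneous or rate-modulated Poisson spike train
#'
#' Convenience generator: constant-rate Poisson spikes, or thinning against a
#' user rate function (used e.g. to build slowly co-modulated null pairs for
#' assembly-detector calibration).
#'
#' @param duration_s Length of the train in seconds.
#' @param rate_hz Mean/maximal rate in Hz.
#' @param rate_fn Optional vectorised function `f(t)` in \[0,1\] multiplying
#'   `rate_hz`.
#' @param seed Optional integer seed.
#' @return Sorted spike-time vector.
#' @export
sim_poisson_spikes <- function(duration_s, rate_hz, rate_fn = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  tt <- sort(runif(n, 0, duration_s))
  if (!is.null(rate_fn)) tt <- tt[runif(n) < rate_fn(tt)]
  tt
}
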
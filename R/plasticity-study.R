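#' Simulate a cohort of passive pDA-pairing recording sessions
#'
#' Generates sessions of the passive paradigm with a mixed population of
#' odor-responsive units and, optionally, a selective plasticity injection:
#' from the 'pairing' phase on, excitatory responses to the paired odor are
#' scaled by `paired_gain` (1 = no plasticity, the control cohort; 1.3
#' emulates dopamine-induced potentiation of excitatory responses).
#'
#' Responsive units are tuned to both odors with a graded preference
#' (non-preferred amplitude a fraction of the preferred one), so the two
#' odor representations overlap and decoding is neither at chance nor at
#' ceiling; inhibitory and unresponsive units complete the mix. Output is
#' ready for [build_population_vectors()].
#'
#' @param n_sessions Number of sessions (default 8).
#' @param n_trials Odor presentations per odor and phase (default 90,
#'   sized so the decoding analysis supports state-space dimensions up
#'   to 6).
#' @param paired_gain Excitatory-response multiplier for the paired odor
#'   after pairing (default 1).
#' @param paired_odor Which odor is paired (default "A").
#' @param overlap Range of the non-preferred/preferred amplitude ratio
#'   (default `c(0.85, 1)`, a strongly overlapping odor code as in sparse
#'   striatal ensembles).
#' @param gain_noise_sd SD of each unit's log-normal per-trial
#'   response-gain fluctuation (default 0.6): supra-Poisson response
#'   variability, which keeps single-trial decoding off ceiling as in real
#'   sparse ensembles.
#' @param params Binning preset (default `pv_params("passive")`).
#' @param seed Integer seed.
#' @return List of sessions, each with `counts` (trials x units x bins,
#'   see [bin_session()]), `odor`, `phase`, and `unit_info` (data frame of
#'   the generating unit types).
#' @export
simulate_passive_cohort <- function(n_sessions = 8, n_trials = 90,
                                    paired_gain = 1, paired_odor = "A",
                                    overlap = c(0.85, 1), gain_noise_sd = 0.6,
                                    params = pv_params("passive"), seed) {
  set.seed(seed)
  session_seeds <- sample.int(1e6, n_sessions)
  lapply(seq_len(n_sessions), function(si) {
    set.seed(session_seeds[si])
    trials <- simulate_passive_session(n_pre = n_trials, n_pairing = n_trials,
                                       n_post = n_trials,
                                       paired_odor = paired_odor,
                                       seed = session_seeds[si] + 1)
    specs <- list(); info <- list()
    add_unit <- function(spec, odor, type) {
      specs[[length(specs) + 1L]] <<- spec
      info[[length(info) + 1L]] <<- data.frame(odor = odor, type = type)
    }
    # excitatory units: strong response to the preferred odor, weaker
    # overlapping response to the other; plasticity targets the units
    # excitatory to (i.e. preferring) the paired odor
    for (pref in rep(c("A", "B"), each = 4)) {
      amp <- runif(1, 4, 10)
      rho <- runif(1, overlap[1], overlap[2])
      amps <- if (pref == "A") c(A = amp, B = amp * rho)
              else c(A = amp * rho, B = amp)
      lat <- runif(1, 0, 0.15)
      dur <- runif(1, 0.9, 1.3)
      gain <- if (paired_gain != 1 && pref == paired_odor)
        c(pairing = paired_gain, post = paired_gain) else NULL
      kern <- list(
        A = list(amplitude_hz = amps[["A"]], latency_s = lat, duration_s = dur),
        B = list(amplitude_hz = amps[["B"]], latency_s = lat, duration_s = dur))
      if (!is.null(gain)) kern[[paired_odor]]$phase_gain <- TRUE
      add_unit(unit_spec(baseline_hz = runif(1, 1.5, 4), kernels = kern,
                         learning_gain = 1, phase_gain = gain),
               pref, "excitatory")
    }
    # inhibitory units (one per odor)
    for (od in c("A", "B")) {
      bl <- runif(1, 1.5, 4)
      add_unit(unit_spec(
        baseline_hz = bl,
        kernels = setNames(list(list(amplitude_hz = -0.7 * bl,
                                     latency_s = runif(1, 0, 0.1),
                                     duration_s = runif(1, 0.9, 1.3))), od)),
        od, "inhibitory")
    }
    # unresponsive units
    for (j in 1:2)
      add_unit(unit_spec(baseline_hz = runif(1, 0.5, 3)), NA, "none")

    unit_seeds <- sample.int(1e6, length(specs))
    trains <- lapply(seq_along(specs), function(u) {
      # per-unit multiplicative response-gain fluctuation, injected through
      # the value-coupling channel
      set.seed(unit_seeds[u])
      gamma <- exp(rnorm(nrow(trials), 0, gain_noise_sd))
      simulate_unit(specs[[u]], trials, value_trace = gamma - 1,
                    t_end = max(trials$t_on) + 5, seed = unit_seeds[u] + 1)
    })
    counts <- bin_session(trains, trials$t_on, params$window_s, params$bin_s)
    list(counts = counts, odor = trials$odor, phase = trials$phase,
         unit_info = do.call(rbind, info))
  })
}
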
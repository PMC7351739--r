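#' Temporal-resolution configuration for assembly detection
#'
#' The detector scans a fixed set of temporal resolutions (bin widths)
#' \eqn{\Delta} with a per-resolution maximal lag. At the finest default
#' resolution (10 ms) the smallest representable non-zero lag is one bin =
#' 10 ms. Resolutions at or below `sharp_cutoff_s` form the "sharp" subset
#' compatible with fast interregional signalling; broader ones capture slow
#' firing-rate coordination.
#'
#' @param deltas_s Strictly increasing resolutions in seconds.
#' @param max_lag_bins Maximal tested lag (in bins) per resolution.
#' @param reference_lag Reference lag offset (bins) used as empirical
#'   contrast in the pair statistic (default -2).
#' @param sharp_cutoff_s Sharp/broad boundary (default 0.25 s).
#' @return List of class `"scale_config"`.
#' @export
scale_config <- function(deltas_s = c(0.01, 0.015, 0.03, 0.05, 0.08, 0.12,
                                      0.25, 0.35, 0.5, 0.6),
                         max_lag_bins = c(20, 20, 20, 20, 20, 10, 7, 5, 5, 5),
                         reference_lag = -2, sharp_cutoff_s = 0.25) {
  stopifnot(length(deltas_s) == length(max_lag_bins),
            !is.unsorted(deltas_s, strictly = TRUE), all(deltas_s > 0),
            all(max_lag_bins >= 1))
  structure(list(deltas_s = deltas_s, max_lag_bins = as.integer(max_lag_bins),
                 reference_lag = as.integer(reference_lag),
                 sharp_cutoff_s = sharp_cutoff_s),
            class = "scale_config")
}

#' Bin a spike train at a temporal resolution
#'
#' Half-open bins `[k*delta, (k+1)*delta)` over `span`; the total count
#' equals the number of spikes in the span.
#'
#' @param spikes Spike-time vector.
#' @param delta_s Bin width (> 0).
#' @param span Two-element time span `[t0, t1)`.
#' @return Integer count vector.
#' @export
bin_counts <- function(spikes, delta_s, span) {
  if (delta_s <= 0) stop("delta_s must be positive")
  nb <- ceiling((span[2] - span[1]) / delta_s)
  sp <- spikes[spikes >= span[1] & spikes < span[2]]
  if (!length(sp)) return(integer(nb))
  tabulate(floor((sp - span[1]) / delta_s) + 1L, nbins = nb)
}

# spike-jitter surrogate: each spike displaced uniformly within +/- half_w
.jitter_spikes <- function(spikes, half_w) {
  spikes + runif(length(spikes), -half_w, half_w)
}

#' Pairwise assembly test at one temporal resolution
#'
#' For every lag \eqn{l \in [-L, L]} the coincidence count
#' \eqn{C(l) = \sum_k \min(a_k, b_{k+l})} is contrasted with the count at a
#' reference offset (`reference_lag` bins away):
#' \eqn{T(l) = C(l) - C(l + l^*)}. A genuine coordination at the tested
#' resolution produces an excess at its lag only, whereas slow co-modulation
#' of the two rates inflates both terms equally. Significance is assessed
#' against surrogates in which every spike of the second train is jittered
#' uniformly within \eqn{\pm 2\Delta} (window \eqn{4\Delta}: destroys
#' coordination at the tested resolution, preserves slower non-stationarity).
#' Per-lag p-values use the pooled surrogate distribution of all lags (the
#' summation window is fixed so all lags have equal length) and are
#' Bonferroni-corrected across lags.
#'
#' @param spikes_a,spikes_b Spike-time vectors (unit a leads at positive
#'   lags of unit b).
#' @param delta_s Temporal resolution in seconds.
#' @param span Time span analysed.
#' @param max_lag Maximal lag in bins.
#' @param reference_lag Reference offset in bins (default -2).
#' @param n_surrogates Number of jitter surrogates (default 100).
#' @return List of class `"pair_test"`: `best_lag` (bins; positive = b
#'   follows a), `p_value` (Bonferroni-corrected), `statistic` per lag,
#'   `counts` per lag, `delta_s`.
#' @export
pair_test <- function(spikes_a, spikes_b, delta_s, span, max_lag = 20,
                      reference_lag = -2, n_surrogates = 100) {
  a <- bin_counts(spikes_a, delta_s, span)
  b <- bin_counts(spikes_b, delta_s, span)
  n <- length(a)
  if (n < 2 * max_lag + 1) stop("series shorter than twice the maximal lag")
  lags <- -max_lag:max_lag
  pad <- max_lag + abs(reference_lag)
  k0 <- pad + 1L; k1 <- n - pad
  if (k1 - k0 < 10) stop("series too short for the requested lags")
  sb <- spikes_b[spikes_b >= span[1] & spikes_b < span[2]]

  stat_of <- function(bb) {
    cc <- coincidence_counts_cpp(a, bb, c(lags, lags + reference_lag), k0, k1)
    cl <- cc[seq_along(lags)]
    list(stat = cl - cc[length(lags) + seq_along(lags)], counts = cl)
  }
  obs <- stat_of(b)
  half_w <- 2 * delta_s
  surr <- matrix(NA_real_, n_surrogates, length(lags))
  for (s in seq_len(n_surrogates)) {
    bs <- .jitter_spikes(sb, half_w)
    bs <- bs[bs >= span[1] & bs < span[2]]
    surr[s, ] <- stat_of(bin_counts(bs, delta_s, span))$stat
  }
  pooled <- as.vector(surr)
  p_lag <- vapply(obs$stat, function(t0)
    (1 + sum(pooled >= t0)) / (1 + length(pooled)), numeric(1))
  # deterministic best lag: smallest p, then largest statistic, then |l|
  ord <- order(p_lag, -obs$stat, abs(lags))
  best <- ord[1]
  structure(list(best_lag = lags[best],
                 p_value = min(1, p_lag[best] * length(lags)),
                 p_per_lag = p_lag, statistic = obs$stat, counts = obs$counts,
                 lags = lags, delta_s = delta_s, span = span,
                 reference_lag = reference_lag,
                 n_surrogates = n_surrogates),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(sprintf(
    "Assembly pair test (delta = %g s): best lag %+d bins (%+.3f s), p = %.4g\n",
    x$delta_s, x$best_lag, x$best_lag * x$delta_s, x$p_value))
  invisible(x)
}

#' Detect and prune pairwise cell assemblies across resolutions
#'
#' Runs [pair_test()] for every unit pair at every resolution of the
#' [scale_config()], corrects across pairs x scales with Benjamini-Hochberg
#' (lags were already Bonferroni-corrected within each test), keeps for each
#' significant pair only the resolution with the smallest detection p-value,
#' and optionally re-runs the pruning restricted to the sharp resolutions
#' (\eqn{\Delta \le} `sharp_cutoff_s`) so that patterns present at both a
#' sharp and a broad scale are not absorbed by the broad one. Detection runs
#' on the whole recording, irrespective of task structure.
#'
#' @param trains Named list of spike-time vectors.
#' @param labels Optional character vector of unit labels (e.g. "SPN",
#'   "DAN"), recycled onto `trains`.
#' @param cfg A [scale_config()].
#' @param alpha Significance level after correction (default 0.05).
#' @param span Analysis span; defaults to the joint spike range.
#' @param n_surrogates Surrogates per test (default 100).
#' @param sharp_rerun Re-run pruning on the sharp subset (default TRUE).
#' @return Object of class `"assembly_set"`: data frame `pairs` with one row
#'   per retained pair (`unit_a`, `unit_b`, labels, `delta_s`, `lag_bins`,
#'   `lag_s`, `p_value`, `p_adj`), the full `tests` table, and the call
#'   parameters.
#' @export
detect_assemblies <- function(trains, labels = NULL, cfg = scale_config(),
                              alpha = 0.05, span = NULL, n_surrogates = 100,
                              sharp_rerun = TRUE) {
  stopifnot(length(trains) >= 2)
  if (is.null(names(trains))) names(trains) <- paste0("u", seq_along(trains))
  if (is.null(labels)) labels <- rep("unit", length(trains))
  labels <- rep_len(labels, length(trains))
  if (is.null(span)) {
    allsp <- unlist(trains)
    span <- c(min(allsp), max(allsp) + 1e-9)
  }
  pairs <- utils::combn(length(trains), 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    for (si in seq_along(cfg$deltas_s)) {
      pt <- tryCatch(
        pair_test(trains[[i1]], trains[[i2]], cfg$deltas_s[si], span,
                  max_lag = cfg$max_lag_bins[si],
                  reference_lag = cfg$reference_lag,
                  n_surrogates = n_surrogates),
        error = function(e) NULL)
      if (is.null(pt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_a = names(trains)[i1], unit_b = names(trains)[i2],
        label_a = labels[i1], label_b = labels[i2],
        delta_s = cfg$deltas_s[si], lag_bins = pt$best_lag,
        lag_s = pt$best_lag * cfg$deltas_s[si], p_value = pt$p_value)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adj <- p.adjust(tests$p_value, "BH")

  prune <- function(tab) {
    sig <- tab[tab$p_adj < alpha, , drop = FALSE]
    if (!nrow(sig)) return(sig)
    key <- paste(sig$unit_a, sig$unit_b)
    keep <- unlist(lapply(split(seq_len(nrow(sig)), key), function(idx) {
      idx[order(sig$p_value[idx], sig$delta_s[idx])][1]
    }))
    sig[sort(keep), , drop = FALSE]
  }
  kept <- prune(tests)
  if (sharp_rerun) {
    sharp <- prune(tests[tests$delta_s <= cfg$sharp_cutoff_s, , drop = FALSE])
    # a pair pruned to a broad scale but also significant at a sharp scale
    # is reassigned to its best sharp scale
    if (nrow(sharp)) {
      key_b <- paste(kept$unit_a, kept$unit_b)
      key_s <- paste(sharp$unit_a, sharp$unit_b)
      broad <- kept$delta_s > cfg$sharp_cutoff_s & key_b %in% key_s
      kept <- rbind(kept[!broad, , drop = FALSE],
                    sharp[key_s %in% key_b[broad], , drop = FALSE])
    }
  }
  rownames(kept) <- NULL
  structure(list(pairs = kept, tests = tests, cfg = cfg, alpha = alpha,
                 span = span, labels = setNames(labels, names(trains)),
                 trains = trains),
            class = "assembly_set")
}

#' @export
print.assembly_set <- function(x, ...) {
  cat("Assembly detection:", nrow(x$pairs), "significant pair(s) of",
      length(unique(paste(x$tests$unit_a, x$tests$unit_b))), "tested\n")
  if (nrow(x$pairs)) print(x$pairs[, c("unit_a", "unit_b", "delta_s",
                                       "lag_bins", "lag_s", "p_value")],
                           row.names = FALSE)
  invisible(x)
}

#' @export
summary.assembly_set <- function(object, ...) {
  cat("Resolutions of retained pairs:\n")
  print(table(object$pairs$delta_s))
  invisible(object)
}

#' Lag directionality of detected assemblies
#'
#' Signed activation lags (seconds) for the requested label combination,
#' oriented so that positive lags mean the second (e.g. VTA) unit follows
#' the first (VS) unit, with an exact sign test on the lag signs.
#'
#' @param assemblies An `"assembly_set"` (or its `pairs` data frame).
#' @param type_filter Optional length-2 character vector of labels
#'   (first = leading region); pairs stored in the opposite orientation are
#'   flipped.
#' @return List with `lags_s`, the `sign_test` (binomial test of positive
#'   vs negative lags) and the selection size; empty selection yields
#'   `NULL` sign test with a message.
#' @export
lag_directionality <- function(assemblies, type_filter = NULL) {
  pairs <- if (inherits(assemblies, "assembly_set")) assemblies$pairs
           else assemblies
  lags <- pairs$lag_s
  if (!is.null(type_filter)) {
    fwd <- pairs$label_a == type_filter[1] & pairs$label_b == type_filter[2]
    rev <- pairs$label_a == type_filter[2] & pairs$label_b == type_filter[1]
    lags <- c(pairs$lag_s[fwd], -pairs$lag_s[rev])
  }
  if (!length(lags)) {
    message("no assemblies match the requested label combination")
    return(list(lags_s = numeric(0), sign_test = NULL, n = 0L))
  }
  nz <- lags[lags != 0]
  st <- if (length(nz)) binom.test(sum(nz > 0), length(nz)) else NULL
  list(lags_s = lags, sign_test = st, n = length(lags))
}

#' Per-trial assembly activation counts
#'
#' Joint-pattern occurrences of a detected pair within a window after each
#' trial onset: with the pair's resolution \eqn{\Delta} and lag `l`, the
#' activation count in a window is \eqn{\sum_k \min(a_k, b_{k+l})} over the
#' bins `k` starting in the window.
#'
#' @param spikes_a,spikes_b The pair's spike trains (a leads at positive
#'   lag).
#' @param delta_s,lag_bins The pair's resolution and lag.
#' @param onsets Trial onset times.
#' @param window_s Window after onset (default `c(0, 0.7)`).
#' @param span Binning span (defaults to cover all spikes and windows).
#' @return Integer vector of per-trial activation counts.
#' @export
assembly_activation_counts <- function(spikes_a, spikes_b, delta_s, lag_bins,
                                       onsets, window_s = c(0, 0.7),
                                       span = NULL) {
  if (is.null(span)) {
    hi <- max(c(spikes_a, spikes_b, onsets + window_s[2])) +
      abs(lag_bins) * delta_s + delta_s
    span <- c(0, hi)
  }
  a <- bin_counts(spikes_a, delta_s, span)
  b <- bin_counts(spikes_b, delta_s, span)
  nb <- length(a)
  joint <- numeric(nb)
  ks <- seq_len(nb)
  kb <- ks + lag_bins
  ok <- kb >= 1 & kb <= nb
  joint[ks[ok]] <- pmin(a[ks[ok]], b[kb[ok]])
  vapply(onsets, function(t0) {
    k <- which((ks - 1) * delta_s + span[1] >= t0 + window_s[1] &
                 (ks - 1) * delta_s + span[1] < t0 + window_s[2])
    sum(joint[k])
  }, numeric(1))
}

#' Learning dynamics of assembly activation
#'
#' Compares assembly activation (counts in the post-CS window) between the
#' first and last `n_each` CS+ (and CS-) trials of each phase with a
#' two-sided Wilcoxon test, and exports the per-trial counts for the value
#' regression.
#'
#' @param spikes_a,spikes_b The pair's spike trains.
#' @param delta_s,lag_bins The pair's resolution and lag.
#' @param trials Trial table with `t_on`, `cs_plus`, `phase`.
#' @param cs_window_s Post-CS window (default `c(0, 0.7)`).
#' @param n_each Trials per end (default 12).
#' @return Object of class `"assembly_dynamics"`: data frame `summary`
#'   (per phase and stimulus: initial/late means and Wilcoxon p), plus
#'   `counts` (per-trial activation, aligned with `trials`).
#' @export
assembly_learning_dynamics <- function(spikes_a, spikes_b, delta_s, lag_bins,
                                       trials, cs_window_s = c(0, 0.7),
                                       n_each = 12) {
  counts <- assembly_activation_counts(spikes_a, spikes_b, delta_s, lag_bins,
                                       trials$t_on, cs_window_s)
  rows <- list()
  for (ph in unique(trials$phase)) {
    for (cs in c(TRUE, FALSE)) {
      idx <- which(trials$phase == ph & trials$cs_plus == cs)
      if (length(idx) < 2 * n_each) {
        warning("fewer than ", 2 * n_each, " trials for phase ", ph,
                ", CS", if (cs) "+" else "-", "; analysis restricted")
      }
      k <- min(n_each, floor(length(idx) / 2))
      if (k < 1) next
      ini <- counts[head(idx, k)]; late <- counts[tail(idx, k)]
      p <- if (all(ini == late)) 1
           else wilcox.test(ini, late, paired = TRUE, exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, stimulus = if (cs) "CS+" else "CS-",
        mean_initial = mean(ini), mean_late = mean(late),
        n = k, p_value = p)
    }
  }
  structure(list(summary = do.call(rbind, rows), counts = counts,
                 window_s = cs_window_s),
            class = "assembly_dynamics")
}

#' @export
print.assembly_dynamics <- function(x, ...) {
  cat("Assembly learning dynamics (window",
      paste(x$window_s, collapse = "-"), "s after CS onset):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
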
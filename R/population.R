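#' Bin a session's spike trains around trial onsets
#'
#' @param spike_list List of spike-time vectors (one per unit).
#' @param onsets Trial onset times in seconds.
#' @param window_s Two-element window around onset, e.g. `c(-2, 2)`.
#' @param bin_s Bin width in seconds.
#' @return Array `trials x units x bins` of spike counts, with attribute
#'   `bin_times` (left bin edges relative to onset).
#' @export
bin_session <- function(spike_list, onsets, window_s, bin_s) {
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nb <- length(edges) - 1L
  out <- array(0L, c(length(onsets), length(spike_list), nb))
  for (u in seq_along(spike_list)) {
    sp <- spike_list[[u]]
    for (i in seq_along(onsets)) {
      rel <- sp[sp >= onsets[i] + window_s[1] & sp < onsets[i] + window_s[2]] -
        onsets[i]
      if (length(rel))
        out[i, u, ] <- tabulate(findInterval(rel, edges), nbins = nb)
    }
  }
  attr(out, "bin_times") <- edges[-length(edges)]
  out
}

#' Analysis presets for the two recording paradigms
#'
#' Bin width, baseline definition, number of tested bins and response window
#' used by the population analyses: behavioral paradigm (go/no-go) bins of
#' 0.4 s, baseline -1.8 to -0.6 s (3 bins), 12 tested post-onset bins,
#' response window 0.6-1.8 s; passive (pDA pairing) paradigm bins of 0.25 s,
#' baseline -1.75 to -0.75 s (4 bins), 7 tested bins, response window
#' 0.5-1.25 s.
#'
#' @param paradigm `"behavioral"` or `"passive"`.
#' @return List of parameters.
#' @export
pv_params <- function(paradigm = c("behavioral", "passive")) {
  paradigm <- match.arg(paradigm)
  if (paradigm == "behavioral")
    list(bin_s = 0.4, n_bl = 3, n_test = 12, baseline_end_s = -0.6,
         response_window_s = c(0.6, 1.8), window_s = c(-1.8, 4.8))
  else
    list(bin_s = 0.25, n_bl = 4, n_test = 7, baseline_end_s = -0.75,
         response_window_s = c(0.5, 1.25), window_s = c(-1.75, 1.75))
}

.group_trials <- function(counts, group_size) {
  nt <- dim(counts)[1]
  ng <- nt %/% group_size
  if (!ng) return(NULL)
  out <- array(0, c(ng, dim(counts)[2], dim(counts)[3]))
  for (g in seq_len(ng)) {
    idx <- ((g - 1) * group_size + 1):(g * group_size)
    out[g, , ] <- apply(counts[idx, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

.front_truncated_phases <- c("pre", "initial")

#' Build across-session population vectors
#'
#' Within each (odor, phase) group, consecutive trials are averaged in
#' non-overlapping groups of `group_size` (remainder dropped from the phase
#' end); sessions are then concatenated unit-wise with the trial-group order
#' preserved (progressive matching) or independently permuted per session.
#' Sessions are truncated to the common minimum number of trial groups:
#' 'pre'/'initial' phases lose their earliest groups, later phases their
#' last groups.
#'
#' @param sessions List of sessions; each a list with `counts` (array
#'   `trials x units x bins`, see [bin_session()]), `odor` and `phase`
#'   (per-trial labels).
#' @param group_size Trials per average (default 3).
#' @param matching `"progressive"` (default) or `"permuted"`.
#' @param n_perm Number of permuted realizations (default 300).
#' @param seed Seed for the permutations.
#' @return Object of class `"population_vectors"`: `groups` is a named list
#'   (`"odor|phase"`) of arrays `group x unit x bin`; with
#'   `matching = "permuted"`, `realizations` is a list of `n_perm` such
#'   group lists.
#' @export
build_population_vectors <- function(sessions, group_size = 3,
                                     matching = c("progressive", "permuted"),
                                     n_perm = 300, seed = 1) {
  matching <- match.arg(matching)
  stopifnot(length(sessions) >= 1)
  n_units <- vapply(sessions, function(s) dim(s$counts)[2], numeric(1))
  if (sum(n_units) == 0) stop("zero eligible units")
  bt <- attr(sessions[[1]]$counts, "bin_times")
  combos <- unique(do.call(rbind, lapply(sessions, function(s)
    unique(data.frame(odor = s$odor, phase = s$phase)))))

  per_session <- lapply(sessions, function(s) {
    g <- list()
    for (i in seq_len(nrow(combos))) {
      sel <- s$odor == combos$odor[i] & s$phase == combos$phase[i]
      g[[paste(combos$odor[i], combos$phase[i], sep = "|")]] <-
        .group_trials(s$counts[sel, , , drop = FALSE], group_size)
    }
    g
  })

  concat <- function(order_fn) {
    groups <- list()
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$odor[i], combos$phase[i], sep = "|")
      tensors <- lapply(per_session, `[[`, key)
      if (any(vapply(tensors, is.null, logical(1))))
        stop("phase/odor group ", key, " missing in some session")
      ng <- min(vapply(tensors, function(x) dim(x)[1], numeric(1)))
      front <- combos$phase[i] %in% .front_truncated_phases
      tensors <- lapply(tensors, function(x) {
        nt <- dim(x)[1]
        keep <- if (front) (nt - ng + 1):nt else seq_len(ng)
        x[keep, , , drop = FALSE]
      })
      tensors <- lapply(tensors, order_fn)
      groups[[key]] <- do.call(function(...) {
        arrs <- list(...)
        out <- array(0, c(ng, sum(vapply(arrs, function(a) dim(a)[2], numeric(1))),
                          dim(arrs[[1]])[3]))
        at <- 0
        for (a in arrs) {
          out[, at + seq_len(dim(a)[2]), ] <- a
          at <- at + dim(a)[2]
        }
        out
      }, tensors)
    }
    groups
  }

  base <- list(bin_times = bt, group_size = group_size, matching = matching,
               combos = combos)
  if (matching == "progressive") {
    base$groups <- concat(identity)
  } else {
    set.seed(seed)
    base$groups <- concat(identity)
    base$realizations <- replicate(n_perm, concat(function(x)
      x[sample(dim(x)[1]), , , drop = FALSE]), simplify = FALSE)
  }
  structure(base, class = "population_vectors")
}

#' @export
print.population_vectors <- function(x, ...) {
  d <- dim(x$groups[[1]])
  cat("Across-session population vectors:", length(x$groups),
      "odor/phase groups,", d[1], "trial-groups x", d[2], "units x", d[3],
      "bins (", x$matching, "matching )\n")
  invisible(x)
}

#' Cosine and normalised Euclidean distance between population vectors
#'
#' \eqn{d^{cos} = 1 - x\cdot y/(\|x\|\|y\|)};
#' \eqn{d^{Euc} = \|x - y\|/l} with `l` the vector length (dimension).
#' Cosine distance is undefined (NA) when either vector has zero norm.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Named vector `c(cosine =, euclidean =)`.
#' @export
pv_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  cosd <- if (nx == 0 || ny == 0) NA_real_ else 1 - sum(x * y) / (nx * ny)
  c(cosine = cosd, euclidean = sqrt(sum((x - y)^2)) / length(x))
}

#' Temporal deviation of the population vector from baseline
#'
#' For each trial group, the baseline vector is the mean of `n_bl` baseline
#' bins; the distance from that baseline is computed at every trial bin
#' (cosine and normalised Euclidean). The first `n_test` post-onset bins are
#' compared between the two phases with two-sided t-tests,
#' Benjamini-Hochberg corrected across bins.
#'
#' @param pv A [build_population_vectors()] object.
#' @param odor Odor label of the group to analyse.
#' @param phases Two phase labels compared (e.g. `c("pre", "post")`).
#' @param params Preset list from [pv_params()].
#' @return Object of class `"pv_deviation"`: `deviation` (long data frame of
#'   per-group per-bin distances) and `tests` (per-bin t-test table with
#'   `p_adj`).
#' @export
deviation_from_baseline <- function(pv, odor, phases, params = pv_params()) {
  bt <- pv$bin_times
  bin_s <- bt[2] - bt[1]
  bl_bins <- utils::tail(which(bt + bin_s <= params$baseline_end_s + 1e-9),
                         params$n_bl)
  if (!length(bl_bins) || max(bt[bl_bins]) >= 0)
    stop("baseline bins must precede onset")
  post_bins <- which(bt >= -1e-9)[seq_len(params$n_test)]

  dev_phase <- function(phase) {
    a <- pv$groups[[paste(odor, phase, sep = "|")]]
    if (is.null(a)) stop("group ", odor, "|", phase, " not present")
    ng <- dim(a)[1]
    do.call(rbind, lapply(seq_len(ng), function(g) {
      baseline <- apply(a[g, , bl_bins, drop = FALSE], 2, mean)
      d <- t(vapply(seq_along(bt), function(b)
        pv_distance(baseline, a[g, , b]), numeric(2)))
      data.frame(phase = phase, group = g, bin = seq_along(bt),
                 bin_time = bt, cosine = d[, 1], euclidean = d[, 2])
    }))
  }
  dev <- do.call(rbind, lapply(phases, dev_phase))
  n_undef <- sum(!is.finite(dev$cosine))
  if (n_undef) message(n_undef, " zero-norm comparison(s) excluded from cosine")

  tests <- do.call(rbind, lapply(post_bins, function(b) {
    do.call(rbind, lapply(c("cosine", "euclidean"), function(metric) {
      x <- dev[dev$phase == phases[1] & dev$bin == b, metric]
      y <- dev[dev$phase == phases[2] & dev$bin == b, metric]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      p <- if (length(x) > 1 && length(y) > 1) t.test(x, y)$p.value else NA_real_
      data.frame(metric = metric, bin = b, bin_time = bt[b],
                 mean_a = mean(x), mean_b = mean(y), p_value = p)
    }))
  }))
  for (metric in c("cosine", "euclidean")) {
    sel <- tests$metric == metric
    tests$p_adj[sel] <- p.adjust(tests$p_value[sel], "BH")
  }
  structure(list(deviation = dev, tests = tests, odor = odor,
                 phases = phases), class = "pv_deviation")
}

#' Odor response vectors (mean over the response window)
#'
#' @param pv A [build_population_vectors()] object.
#' @param response_window_s Two-element window in seconds.
#' @return Named list of matrices (`group x unit`) per `"odor|phase"`.
#' @export
response_vectors <- function(pv, response_window_s) {
  bt <- pv$bin_times
  bin_s <- bt[2] - bt[1]
  bins <- which(bt + bin_s / 2 >= response_window_s[1] &
                  bt + bin_s / 2 <= response_window_s[2])
  lapply(pv$groups, function(a) apply(a[, , bins, drop = FALSE], c(1, 2), mean))
}

#' Response-vector distance distributions
#'
#' Two comparison designs on the response vectors: (a) for each odor, all
#' pairwise distances between phase-1 and phase-2 trial groups versus all
#' pairwise distances within phase 1 (does the phase change exceed
#' trial-by-trial variability?); (b) cross-odor distances between the two
#' odors' responses within each phase.
#'
#' @param pv A [build_population_vectors()] object.
#' @param odors Two odor labels.
#' @param phases Two phase labels (reference phase first).
#' @param params Preset list from [pv_params()].
#' @return List with tidy data frames `within` (columns `odor`,
#'   `comparison` in \{"within_ref", "across_phase"\}, `cosine`,
#'   `euclidean`) and `cross` (columns `phase`, `cosine`, `euclidean`).
#' @export
response_vectors_and_distances <- function(pv, odors, phases,
                                           params = pv_params()) {
  rv <- response_vectors(pv, params$response_window_s)
  pairwise <- function(a, b = NULL) {
    if (is.null(b)) {
      n <- nrow(a)
      if (n < 2) return(NULL)
      cmb <- utils::combn(n, 2)
      t(vapply(seq_len(ncol(cmb)), function(j)
        pv_distance(a[cmb[1, j], ], a[cmb[2, j], ]), numeric(2)))
    } else {
      t(vapply(seq_len(nrow(a) * nrow(b)), function(j) {
        i1 <- (j - 1) %/% nrow(b) + 1; i2 <- (j - 1) %% nrow(b) + 1
        pv_distance(a[i1, ], b[i2, ])
      }, numeric(2)))
    }
  }
  within <- do.call(rbind, lapply(odors, function(od) {
    a1 <- rv[[paste(od, phases[1], sep = "|")]]
    a2 <- rv[[paste(od, phases[2], sep = "|")]]
    rbind(
      data.frame(odor = od, comparison = "within_ref",
                 cosine = pairwise(a1)[, 1], euclidean = pairwise(a1)[, 2]),
      data.frame(odor = od, comparison = "across_phase",
                 cosine = pairwise(a1, a2)[, 1],
                 euclidean = pairwise(a1, a2)[, 2]))
  }))
  cross <- do.call(rbind, lapply(phases, function(ph) {
    a <- rv[[paste(odors[1], ph, sep = "|")]]
    b <- rv[[paste(odors[2], ph, sep = "|")]]
    d <- pairwise(a, b)
    data.frame(phase = ph, cosine = d[, 1], euclidean = d[, 2])
  }))
  list(within = within, cross = cross)
}

# LOOCV QDA accuracy; falls back to a ridge-regularised Gaussian classifier
# when class covariances are singular
.qda_loocv <- function(X, y) {
  res <- tryCatch(MASS::qda(X, grouping = y, CV = TRUE)$class,
                  error = function(e) NULL)
  if (is.null(res)) {
    message("singular class covariance; ridge-regularised QDA fallback")
    n <- nrow(X)
    res <- factor(rep(NA, n), levels = levels(y))
    for (i in seq_len(n)) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      sc <- vapply(levels(y), function(lv) {
        Z <- Xi[yi == lv, , drop = FALSE]
        mu <- colMeans(Z)
        S <- var(Z) + diag(1e-4 * mean(diag(var(Xi))) + 1e-12, ncol(X))
        d <- X[i, ] - mu
        -0.5 * determinant(S)$modulus - 0.5 * drop(t(d) %*% solve(S, d)) +
          log(nrow(Z) / (n - 1))
      }, numeric(1))
      res[i] <- levels(y)[which.max(sc)]
    }
  }
  res
}

#' Odor decoding accuracy by PCA + quadratic discriminant analysis
#'
#' The response vectors of all four (odor x phase) groups are jointly
#' reduced by PCA (so both phases share one space); within each phase a QDA
#' classifier separates the two odors, evaluated by leave-one-out
#' cross-validation. The phase difference in correct/incorrect counts is
#' tested per dimension with Fisher's exact test, BH-corrected across
#' dimensions. Dimensions where the model's total parameter count
#' \eqn{2(D(D-1)/2 + 2D + 1) - 1} reaches the number of data points are
#' refused.
#'
#' @param pv A [build_population_vectors()] object.
#' @param odors Two odor labels (classes).
#' @param phases Two phase labels (reference first).
#' @param dims State-space dimensions to test (default 3:6).
#' @param params Preset list from [pv_params()].
#' @return Object of class `"qda_decoding"`: data frame `accuracy` with
#'   per-phase per-dimension LOOCV accuracies, Fisher p-values and `p_adj`.
#' @export
qda_decode <- function(pv, odors, phases, dims = 3:6, params = pv_params()) {
  rv <- response_vectors(pv, params$response_window_s)
  keys <- as.vector(outer(odors, phases, paste, sep = "|"))
  X <- do.call(rbind, rv[keys])
  lab <- do.call(rbind, lapply(keys, function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(odor = p[1], phase = p[2],
               n = nrow(rv[[k]]))
  }))
  odor_f <- factor(rep(lab$odor, lab$n), levels = odors)
  phase_f <- rep(lab$phase, lab$n)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)

  rows <- list()
  for (D in dims) {
    ok <- TRUE
    for (ph in phases) {
      n_pts <- sum(phase_f == ph)
      df_total <- 2 * (D * (D - 1) / 2 + 2 * D + 1) - 1
      if (df_total >= n_pts || D > ncol(pc$x)) ok <- FALSE
    }
    if (!ok) {
      rows[[length(rows) + 1L]] <-
        data.frame(dim = D, phase = phases, accuracy = NA_real_,
                   n_correct = NA, n_tested = NA, refused = TRUE)
      next
    }
    for (ph in phases) {
      sel <- phase_f == ph
      pred <- .qda_loocv(pc$x[sel, seq_len(D), drop = FALSE], droplevels(odor_f[sel]))
      rows[[length(rows) + 1L]] <-
        data.frame(dim = D, phase = ph,
                   accuracy = mean(pred == odor_f[sel]),
                   n_correct = sum(pred == odor_f[sel]),
                   n_tested = sum(sel), refused = FALSE)
    }
  }
  acc <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(unique(acc$dim[!acc$refused]), function(D) {
    a <- acc[acc$dim == D & acc$phase == phases[1], ]
    b <- acc[acc$dim == D & acc$phase == phases[2], ]
    m <- matrix(c(a$n_correct, a$n_tested - a$n_correct,
                  b$n_correct, b$n_tested - b$n_correct), 2)
    data.frame(dim = D, p_value = fisher.test(m)$p.value)
  }))
  if (!is.null(tests)) tests$p_adj <- p.adjust(tests$p_value, "BH")
  structure(list(accuracy = acc, tests = tests, dims = dims,
                 odors = odors, phases = phases),
            class = "qda_decoding")
}

#' @export
print.qda_decoding <- function(x, ...) {
  cat("PCA + QDA leave-one-out odor decoding\n")
  a <- x$accuracy[!x$accuracy$refused, ]
  if (nrow(a)) {
    w <- stats::reshape(a[, c("dim", "phase", "accuracy")],
                        direction = "wide", idvar = "dim", timevar = "phase")
    print(w, row.names = FALSE)
  }
  if (any(x$accuracy$refused))
    cat("  refused dims (overparameterised):",
        paste(unique(x$accuracy$dim[x$accuracy$refused]), collapse = ", "), "\n")
  invisible(x)
}

#' Delay-embedded low-dimensional population trajectories
#'
#' Trial-averaged per-group trajectories are delay-embedded (`m` copies at
#' `delay`-bin lags) and reduced to `factors` latent dimensions by factor
#' analysis fitted jointly on all groups (shared space). When factor
#' analysis is infeasible (more variables than observations, or a singular
#' fit) the leading principal components are used instead and the result is
#' flagged. Output is for visualisation only.
#'
#' @param pv A [build_population_vectors()] object.
#' @param m Embedding copies (default 3).
#' @param delay Embedding delay in bins (default 1).
#' @param factors Output dimensionality (default 3).
#' @return List of per-group score matrices (`time x factors`), with
#'   attributes `method` ("fa" or "pca") and `degenerate` flag.
#' @export
embed_trajectories <- function(pv, m = 3, delay = 1, factors = 3) {
  traj <- lapply(pv$groups, function(a) {
    # bins x units trial-averaged trajectory
    t(apply(a, c(2, 3), mean))
  })
  nb <- nrow(traj[[1]])
  if (nb < (m - 1) * delay + 1 + 1) stop("need at least 4 time bins")
  emb <- lapply(traj, function(x) {
    rows <- ((m - 1) * delay + 1):nb
    do.call(cbind, lapply(0:(m - 1), function(k) x[rows - k * delay, , drop = FALSE]))
  })
  stacked <- do.call(rbind, emb)
  keep <- apply(stacked, 2, sd) > 0
  degenerate <- sum(keep) < factors
  method <- "fa"
  if (!degenerate) {
    fa <- tryCatch(factanal(stacked[, keep, drop = FALSE], factors = factors,
                            scores = "regression"),
                   error = function(e) NULL)
    if (is.null(fa)) {
      method <- "pca"
      pc <- prcomp(stacked[, keep, drop = FALSE], center = TRUE)
      scores <- pc$x[, seq_len(min(factors, ncol(pc$x))), drop = FALSE]
    } else scores <- fa$scores
  } else {
    method <- "pca"
    scores <- matrix(0, nrow(stacked), factors)
  }
  n_per <- vapply(emb, nrow, numeric(1))
  idx <- split(seq_len(sum(n_per)), rep(seq_along(emb), n_per))
  out <- lapply(idx, function(i) scores[i, , drop = FALSE])
  names(out) <- names(pv$groups)
  attr(out, "method") <- method
  attr(out, "degenerate") <- degenerate
  out
}

#' Multidimensional scaling of odor response vectors
#'
#' Classical MDS of the trial-group response vectors to three dimensions,
#' preserving pairwise distances for visualisation.
#'
#' @param pv A [build_population_vectors()] object.
#' @param params Preset list from [pv_params()].
#' @param k Output dimensionality (default 3).
#' @return List with `points` (rows = trial groups), `labels`
#'   (odor/phase per row) and the `stress` (Kruskal stress-1) of the
#'   configuration.
#' @export
mds_responses <- function(pv, params = pv_params(), k = 3) {
  rv <- response_vectors(pv, params$response_window_s)
  X <- do.call(rbind, rv)
  lab <- rep(names(rv), vapply(rv, nrow, numeric(1)))
  if (nrow(X) < 4) stop("need at least 4 points for MDS")
  d <- dist(X)
  k <- min(k, nrow(X) - 1)
  pts <- cmdscale(d, k = k)
  dhat <- dist(pts)
  stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
  list(points = pts, labels = lab, stress = stress)
}
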
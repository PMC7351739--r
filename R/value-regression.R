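#' Poisson regression of assembly activity on stimulus value
#'
#' Fits the log-link Poisson model
#' \eqn{\log(\mu_t) = \beta_0 + \beta\,V_{CS+}(t)} of per-trial assembly
#' activation counts on the model-derived stimulus value. To pool across
#' assemblies and sessions the coefficient is standardised,
#' \eqn{\bar\beta = \beta\,\sigma(V)/\sigma(\hat\mu)} (SDs over trials,
#' \eqn{\hat\mu} the fitted means), and transformed to
#' \eqn{\beta^* = e^{\bar\beta} - 1}, so positive \eqn{\beta^*} indicates a
#' positive activity-value correlation. Significance is the t-statistic on
#' the raw \eqn{\beta}.
#'
#' @param counts Nonnegative integer activation counts per CS+ trial.
#' @param value Per-trial value trace \eqn{V_{CS+}(t)} (same length), e.g.
#'   from [value_trace()].
#' @param min_trials Minimum number of trials (default 20).
#' @return Object of class `"value_regression"` with `beta0`, `beta`
#'   (raw coefficient), `beta_bar`, `beta_star`, `t_stat`, `p_value`,
#'   `n_trials`, `family`, and a `degenerate` flag for all-zero counts.
#' @export
value_regression <- function(counts, value, min_trials = 20) {
  stopifnot(length(counts) == length(value))
  if (length(counts) < min_trials)
    stop("need at least ", min_trials, " trials")
  if (any(!is.finite(value))) stop("value trace must be finite")
  if (sd(value) == 0) stop("constant value trace: beta undefined")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  degenerate <- all(counts == 0)
  fit <- glm(counts ~ value, family = poisson())
  .vr_result(fit, value, degenerate = degenerate, family = "poisson")
}

.vr_result <- function(fit, value, degenerate, family) {
  sm <- summary(fit)$coefficients
  beta <- unname(coef(fit)[2])
  mu <- fitted(fit)
  s_mu <- sd(mu)
  beta_bar <- if (s_mu > 0) beta * sd(value) / s_mu else 0
  structure(list(beta0 = unname(coef(fit)[1]), beta = beta,
                 beta_bar = beta_bar, beta_star = exp(beta_bar) - 1,
                 t_stat = sm[2, 3], p_value = sm[2, 4],
                 n_trials = length(value), family = family,
                 degenerate = degenerate, fit = fit),
            class = "value_regression")
}

#' @export
print.value_regression <- function(x, ...) {
  cat("Assembly activity ~ V_CS+ regression (", x$family, " family)\n", sep = "")
  cat(sprintf("  beta = %.4f  beta_bar = %.4f  beta* = %.4f\n",
              x$beta, x$beta_bar, x$beta_star))
  cat(sprintf("  t = %.3f, p = %.4g, n = %d trials%s\n", x$t_stat, x$p_value,
              x$n_trials, if (x$degenerate) "  [degenerate: all-zero counts]"
              else ""))
  invisible(x)
}

#' @export
coef.value_regression <- function(object, ...) {
  c(beta0 = object$beta0, beta = object$beta, beta_bar = object$beta_bar,
    beta_star = object$beta_star)
}

#' Baseline-subtracted control regression
#'
#' Repeats the value regression on response counts minus the matched
#' per-trial baseline activity, to exclude that a raw-count correlation is
#' driven by slow drifts of baseline activity. Differences can be negative,
#' which breaks the Poisson likelihood; in that case a Gaussian
#' identity-link regression is used instead (flagged in the result), with
#' \eqn{\bar\beta} and \eqn{\beta^*} computed identically from the fitted
#' means.
#'
#' @param counts Response-window activation counts per trial.
#' @param baseline_counts Matched baseline-window counts per trial.
#' @param value Per-trial value trace.
#' @param min_trials Minimum number of trials (default 20).
#' @return A `"value_regression"` object (family `"poisson"` when all
#'   differences are nonnegative, `"gaussian"` otherwise).
#' @export
baseline_subtracted_control <- function(counts, baseline_counts, value,
                                        min_trials = 20) {
  stopifnot(length(counts) == length(baseline_counts),
            length(counts) == length(value))
  if (length(counts) < min_trials)
    stop("need at least ", min_trials, " trials")
  if (sd(value) == 0) stop("constant value trace: beta undefined")
  d <- counts - baseline_counts
  if (any(d < 0)) {
    message("negative baseline-subtracted counts: Gaussian identity-link fit")
    fit <- lm(d ~ value)
    sm <- summary(fit)$coefficients
    mu <- fitted(fit)
    beta <- unname(coef(fit)[2])
    s_mu <- sd(mu)
    beta_bar <- if (s_mu > 0) beta * sd(value) / s_mu else 0
    return(structure(list(beta0 = unname(coef(fit)[1]), beta = beta,
                          beta_bar = beta_bar, beta_star = exp(beta_bar) - 1,
                          t_stat = sm[2, 3], p_value = sm[2, 4],
                          n_trials = length(value), family = "gaussian",
                          degenerate = all(d == 0), fit = fit),
                     class = "value_regression"))
  }
  value_regression(d, value, min_trials = min_trials)
}

#' Pool value-regression results across assemblies
#'
#' Collects \eqn{\beta^*} coefficients of many assemblies, flags
#' significance of the raw coefficient (optionally BH-corrected), and
#' reports the headline convention: only significant \eqn{\beta^*} values.
#'
#' @param results List of `"value_regression"` objects.
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` (default, matching the headline convention) or
#'   `"BH"`.
#' @return Data frame with one row per assembly (`beta`, `beta_bar`,
#'   `beta_star`, `p_value`, `p_adj`, `significant`).
#' @export
pool_value_regressions <- function(results, alpha = 0.05,
                                   correct = c("none", "BH")) {
  correct <- match.arg(correct)
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(assembly = i, beta = r$beta, beta_bar = r$beta_bar,
               beta_star = r$beta_star, p_value = r$p_value)
  }))
  tab$p_adj <- if (correct == "BH") p.adjust(tab$p_value, "BH") else tab$p_value
  tab$significant <- tab$p_adj < alpha
  tab
}
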
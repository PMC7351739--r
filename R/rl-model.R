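#' Q-learning models with Pearce-Hall associability
#'
#' The package models instrumental licking in the go/no-go task with a family
#' of Q-learning rules built on a hybrid Rescorla-Wagner update whose learning
#' rate is gated by a Pearce-Hall associability variable \eqn{\alpha(t)}: after
#' each trial, \eqn{Q_{s,a} \leftarrow Q_{s,a} + \kappa\,\alpha(t)\,\delta(t)}
#' with prediction error \eqn{\delta(t) = r(t) - Q_{s,a}(t)} and
#' \eqn{\alpha(t+1) = (1-\eta)\alpha(t) + \eta|\delta(t)|}. Three
#' generalisations are available:
#'
#' * `"qph_kappa"` — separate learning rates \eqn{\kappa_1,\kappa_2} for the
#'   two actions (lick / restrain); \eqn{\theta = (\kappa_1,\kappa_2,\eta,\beta)}.
#' * `"qph_eta"` — separate associability rates \eqn{\eta_1,\eta_2} per action;
#'   \eqn{\theta = (\kappa,\eta_1,\eta_2,\beta)}.
#' * `"qph_f"` — a forgetting component that decays the value of the unchosen
#'   action \eqn{a'} of the visited state:
#'   \eqn{Q_{s,a'} \leftarrow Q_{s,a'} - \kappa_F\,\alpha_F(t)\,Q_{s,a'}},
#'   \eqn{\alpha_F(t+1) = (1-\eta)\alpha_F(t) + \eta\,Q_{s,a'}(t)};
#'   \eqn{\theta = (\kappa_L,\kappa_F,\eta,\beta)}. Setting \eqn{\kappa_F = 0}
#'   recovers the plain hybrid model.
#'
#' Actions are selected by a softmax policy with inverse temperature
#' \eqn{\beta}. Initialisation: \eqn{Q_{s,a}(1) = 0.5} for every state-action
#' pair, \eqn{\alpha(1) = \alpha_L(1) = \alpha_F(1) = 0}.
#'
#' @name qph-models
NULL

.qph_models <- c(qph_kappa = 1L, qph_eta = 2L, qph_f = 3L)

.qph_par_names <- function(model) {
  switch(model,
         qph_kappa = c("kappa1", "kappa2", "eta", "beta"),
         qph_eta   = c("kappa", "eta1", "eta2", "beta"),
         qph_f     = c("kappaL", "kappaF", "eta", "beta"))
}

.qph_check_theta <- function(model, theta) {
  nm <- .qph_par_names(model)
  if (length(theta) != 4L)
    stop("theta must have 4 elements (", paste(nm, collapse = ", "), ")")
  theta <- unname(as.numeric(theta))
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(theta[1:3] < 0) || any(theta[1:3] > 1))
    stop("learning/associability rates must lie in [0, 1]")
  if (theta[4] < 0 || theta[4] > 500)
    stop("beta must lie in [0, 500]")
  theta
}

#' Softmax action probabilities
#'
#' \eqn{P(a|s) = \exp(\beta Q_{s,a}) / \sum_l \exp(\beta Q_{s,l})}, computed
#' overflow-safely.
#'
#' @param q Numeric vector of action values for one state.
#' @param beta Inverse temperature (exploitation/exploration trade-off).
#' @return Probability vector summing to one.
#' @examples
#' softmax_prob(c(1, 0), beta = 2)
#' @export
softmax_prob <- function(q, beta) {
  stopifnot(is.finite(beta), all(is.finite(q)))
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' One Q-PH update step
#'
#' Reference (pure R) implementation of a single trial update; the fitting
#' routine uses an equivalent compiled recursion. States and actions are
#' integers in \{1, 2\} (action 1 = lick, action 2 = restrain). Only the
#' visited state's values change.
#'
#' @param model One of `"qph_kappa"`, `"qph_eta"`, `"qph_f"`.
#' @param state,action Integers in \{1, 2\}.
#' @param reward Obtained reward (0 or 1).
#' @param Q 2 x 2 matrix of action values, `Q[state, action]`.
#' @param alpha Current associability (for `"qph_f"` this is \eqn{\alpha_L}).
#' @param alpha_F Current forgetting associability (ignored unless `"qph_f"`).
#' @param theta Parameter vector, see [qph-models].
#' @return List with updated `Q`, `alpha`, `alpha_F` and the prediction error
#'   `delta`.
#' @export
qph_step <- function(model = c("qph_kappa", "qph_eta", "qph_f"),
                     state, action, reward, Q, alpha, alpha_F = 0, theta) {
  model <- match.arg(model)
  theta <- .qph_check_theta(model, theta)
  stopifnot(state %in% 1:2, action %in% 1:2, is.matrix(Q), all(dim(Q) == 2))
  delta <- reward - Q[state, action]
  other <- 3L - action
  if (model == "qph_kappa") {
    kap <- if (action == 1L) theta[1] else theta[2]
    Q[state, action] <- Q[state, action] + kap * alpha * delta
    alpha <- (1 - theta[3]) * alpha + theta[3] * abs(delta)
  } else if (model == "qph_eta") {
    eta <- if (action == 1L) theta[2] else theta[3]
    Q[state, action] <- Q[state, action] + theta[1] * alpha * delta
    alpha <- (1 - eta) * alpha + eta * abs(delta)
  } else {
    eta <- theta[3]
    Q[state, action] <- Q[state, action] + theta[1] * alpha * delta
    alpha <- (1 - eta) * alpha + eta * abs(delta)
    q_old <- Q[state, other]
    Q[state, other] <- q_old - theta[2] * alpha_F * q_old
    alpha_F <- (1 - eta) * alpha_F + eta * q_old
  }
  list(Q = Q, alpha = alpha, alpha_F = alpha_F, delta = delta)
}

.behavior_columns <- function(data) {
  need <- c("state", "action", "reward")
  if (!all(need %in% names(data)))
    stop("behavior data must contain columns: ", paste(need, collapse = ", "))
  s <- data$state
  a <- data$action
  if (!is.numeric(s)) s <- as.integer(factor(s))
  if (!is.numeric(a)) {
    a <- ifelse(as.character(a) %in% c("lick", "go", "1"), 1L, 2L)
  }
  list(s = as.integer(s), a = as.integer(a), r = as.numeric(data$reward))
}

#' Fit a Q-PH reinforcement-learning model by maximum likelihood
#'
#' Maximises the softmax action log-likelihood \eqn{\sum_t \log P(a_t|s_t)}
#' over the model parameters within bounds (rates in \eqn{[0,1]},
#' \eqn{\beta \in [0,500]}) with bounded L-BFGS-B started from `n_starts`
#' random initial conditions (rates uniform, \eqn{\beta} log-uniform on
#' \eqn{[0.1, 50]}). Both task phases (original and reversal) are fit jointly
#' as one series; no reset occurs at reversal. Starts are generated as a
#' nested stream, so increasing `n_starts` can only improve the best
#' log-likelihood.
#'
#' @param data Data frame with columns `state` (1/2 or factor), `action`
#'   (1/2 or "lick"/"no_lick"), `reward` (0/1), e.g. the `$trials` table of
#'   [simulate_task_session()]. At least 50 trials are required.
#' @param model Model name, see [qph-models].
#' @param n_starts Number of random initialisations (default 256).
#' @param seed Optional integer seed for the start stream.
#' @param tol Optimality tolerance passed to the optimiser (default 1e-6).
#' @param fixed Optional named numeric vector of parameters to hold fixed
#'   (e.g. `c(kappaF = 0)` for the nested no-forgetting model).
#' @param cs_state Rewarded (CS+) state per trial, used only to extract the
#'   value trace. Derived from the `state` and `cs_plus` columns when
#'   present (so the trace follows the contingency across the reversal),
#'   otherwise state 1 throughout; a scalar or per-trial vector can be
#'   supplied explicitly.
#' @return An object of class `"qph_fit"`: the estimated parameters,
#'   log-likelihood, BIC (with n = number of trials), and per-trial latent
#'   traces (`Q`, `alpha`, `alpha_F`, `delta`, `value_cs` =
#'   \eqn{\max_a Q_{cs+,a}(t)} for the state given by `cs_state`).
#' @seealso [compare_qph_models()], [value_regression()]
#' @export
qph_fit <- function(data, model = c("qph_f", "qph_kappa", "qph_eta"),
                    n_starts = 256, seed = NULL, tol = 1e-6,
                    fixed = NULL, cs_state = NULL) {
  model <- match.arg(model)
  beh <- .behavior_columns(data)
  n <- length(beh$s)
  if (n < 50) stop("need at least 50 trials to fit")
  code <- .qph_models[[model]]
  nm <- .qph_par_names(model)
  lower <- c(0, 0, 0, 0)
  upper <- c(1, 1, 1, 500)

  free <- rep(TRUE, 4L)
  base <- rep(NA_real_, 4L)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% nm))
      stop("unknown fixed parameter(s): ",
           paste(setdiff(names(fixed), nm), collapse = ", "))
    idx <- match(names(fixed), nm)
    free[idx] <- FALSE
    base[idx] <- as.numeric(fixed)
  }

  negll <- function(par) {
    th <- base
    th[free] <- par
    -qph_loglik_cpp(code, beh$s, beh$a, beh$r, th)
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n_starts <- max(1L, as.integer(n_starts))
  starts <- matrix(NA_real_, n_starts, 4L)
  for (i in seq_len(n_starts)) {   # nested stream: prefix-stable in n_starts
    starts[i, 1:3] <- runif(3)
    starts[i, 4] <- exp(runif(1, log(0.1), log(50)))
  }

  best <- NULL
  failures <- 0L
  for (i in seq_len(n_starts)) {
    p0 <- starts[i, free]
    fit <- tryCatch(
      optim(p0, negll, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free],
            control = list(factr = 1e7, pgtol = tol, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) { failures <- failures + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all ", n_starts, " optimisation starts failed (",
         failures, " errors); check the input series")

  theta <- base
  theta[free] <- best$par
  names(theta) <- nm
  ll <- -best$value
  k <- sum(free)
  if (is.null(cs_state)) {
    cs_state <- if ("cs_plus" %in% names(data))
      ifelse(data$cs_plus, beh$s, 3L - beh$s) else 1L
  }
  cs_state <- rep_len(as.integer(cs_state), n)
  tr <- qph_traces_cpp(code, beh$s, beh$a, beh$r, unname(theta), cs_state)
  colnames(tr$Q) <- c("Q_s1_lick", "Q_s1_restrain", "Q_s2_lick", "Q_s2_restrain")
  structure(list(
    model = model, theta = theta, free = setNames(free, nm),
    logLik = ll, npar = k, n = n, bic = k * log(n) - 2 * ll,
    traces = data.frame(trial = seq_len(n), tr$Q, alpha = tr$alpha,
                        alpha_F = tr$alpha_F, delta = tr$delta,
                        value_cs = tr$value_cs, logp = tr$logp),
    data = data.frame(state = beh$s, action = beh$a, reward = beh$r),
    n_starts = n_starts, convergence = best$convergence,
    cs_state = cs_state),
    class = "qph_fit")
}

#' @export
print.qph_fit <- function(x, ...) {
  cat("Q-PH reinforcement-learning model fit\n")
  cat("  model:", x$model, " trials:", x$n, "\n")
  cat("  theta:\n")
  print(round(x$theta, 4))
  cat(sprintf("  logLik = %.3f   BIC = %.3f   (k = %d, starts = %d)\n",
              x$logLik, x$bic, x$npar, x$n_starts))
  invisible(x)
}

#' @export
coef.qph_fit <- function(object, ...) object$theta

#' @export
logLik.qph_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
summary.qph_fit <- function(object, ...) {
  v <- object$traces$value_cs
  out <- list(fit = object,
              value_range = range(v),
              mean_p_chosen = mean(exp(object$traces$logp)))
  class(out) <- "summary.qph_fit"
  out
}

#' @export
print.summary.qph_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  V_CS+ range: [%.3f, %.3f]   mean P(chosen action) = %.3f\n",
              x$value_range[1], x$value_range[2], x$mean_p_chosen))
  invisible(x)
}

#' Predicted action probabilities of a fitted Q-PH model
#'
#' @param object A [qph_fit()] object.
#' @param ... Unused.
#' @return Matrix with per-trial probabilities of lick and restrain for the
#'   presented state, computed from the pre-update action values.
#' @export
predict.qph_fit <- function(object, ...) {
  tr <- object$traces
  beta <- unname(object$theta[4])
  s <- object$data$state
  q1 <- ifelse(s == 1L, tr$Q_s1_lick, tr$Q_s2_lick)
  q2 <- ifelse(s == 1L, tr$Q_s1_restrain, tr$Q_s2_restrain)
  m <- pmax(q1, q2) * beta
  e1 <- exp(beta * q1 - m); e2 <- exp(beta * q2 - m)
  cbind(lick = e1 / (e1 + e2), restrain = e2 / (e1 + e2))
}

#' Extract the trial-wise CS+ value trace
#'
#' \eqn{V_{CS+}(t) = \max_a Q_{cs+,a}(t)} of the fitted model, the predictor
#' used by [value_regression()].
#'
#' @param fit A [qph_fit()] object.
#' @return Numeric vector of per-trial values.
#' @export
value_trace <- function(fit) {
  stopifnot(inherits(fit, "qph_fit"))
  fit$traces$value_cs
}

#' Compare Q-PH model fits across sessions
#'
#' Computes the Bayesian information criterion per model and session
#' (BIC = k log n - 2 logL, n = trials), tests for systematic BIC differences
#' across sessions with a Friedman test plus pairwise paired Wilcoxon post-hoc
#' tests (BH-corrected), grades the best-vs-rest mean BIC difference on
#' Raftery's qualitative scale, and, when fits of the forgetting model and its
#' nested no-forgetting restriction are supplied, performs the likelihood
#' ratio test (chi-squared, df = 1) per session.
#'
#' @param fits A list of sessions, each a named list of `"qph_fit"` objects
#'   (same data underlying all fits of one session).
#' @param lrt Optional list with elements `full` and `null`, each a list of
#'   `"qph_fit"` objects per session, for the nested LRT.
#' @param alpha Significance level for the LRT (default 0.05).
#' @return An object of class `"qph_comparison"` with the BIC table, test
#'   results, and LRT table if requested.
#' @export
compare_qph_models <- function(fits, lrt = NULL, alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  models <- names(fits[[1]])
  if (is.null(models)) stop("each session must be a *named* list of fits")
  bic <- t(vapply(fits, function(f) {
    ns <- vapply(f, function(x) x$n, numeric(1))
    if (length(unique(ns)) != 1L)
      stop("fits within a session must share the same trial count")
    vapply(f, function(x) x$bic, numeric(1))
  }, numeric(length(models))))
  colnames(bic) <- models
  mean_bic <- colMeans(bic)
  best <- models[which.min(mean_bic)]

  fried <- post <- NULL
  if (nrow(bic) >= 2 && length(models) >= 2) {
    fried <- friedman.test(bic)
    pairs <- utils::combn(models, 2)
    pvals <- apply(pairs, 2, function(pp)
      wilcox.test(bic[, pp[1]], bic[, pp[2]], paired = TRUE, exact = FALSE)$p.value)
    post <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                       p_value = pvals, p_adj = p.adjust(pvals, "BH"))
  }
  dbic <- sort(mean_bic - min(mean_bic))[2] # runner-up gap
  raftery <- if (!is.finite(dbic)) NA_character_
  else if (dbic < 2) "weak" else if (dbic < 6) "positive"
  else if (dbic < 10) "strong" else "very strong"

  lrt_tab <- NULL
  if (!is.null(lrt)) {
    stat <- mapply(function(f0, f1) 2 * (f1$logLik - f0$logLik),
                   lrt$null, lrt$full)
    stat <- pmax(stat, 0)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    lrt_tab <- data.frame(session = seq_along(stat), chisq = stat,
                          p_value = p, reject = p < alpha)
  }
  structure(list(bic = bic, mean_bic = mean_bic, best = best,
                 friedman = fried, posthoc = post, raftery = raftery,
                 lrt = lrt_tab),
            class = "qph_comparison")
}

#' @export
print.qph_comparison <- function(x, ...) {
  cat("Q-PH model comparison across", nrow(x$bic), "sessions\n")
  cat("  mean BIC:\n")
  print(round(x$mean_bic, 2))
  cat("  best model:", x$best, "(evidence vs runner-up:", x$raftery, ")\n")
  if (!is.null(x$friedman))
    cat(sprintf("  Friedman chi-sq = %.2f, p = %.3g\n",
                unname(x$friedman$statistic), x$friedman$p.value))
  if (!is.null(x$lrt))
    cat(sprintf("  LRT (forgetting vs nested): %d/%d sessions reject\n",
                sum(x$lrt$reject), nrow(x$lrt)))
  invisible(x)
}
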
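#' Go/no-go reversal task configuration
#'
#' Parameters of the odor-guided go/no-go task: two odors in pseudorandom
#' order (never more than `max_same_consecutive` identical stimuli in a row),
#' reward retrievable by licking three times within a retrieval window, and a
#' within-session contingency reversal triggered when the running performance
#' reaches `criterion_frac` correct over the trailing `criterion_window`
#' trials of the current phase.
#'
#' @param stim_duration_s Odor presentation length in seconds (sessions used
#'   1, 1.5 or 3 s).
#' @param retrieval_onset_s Delay from odor onset to the start of the
#'   retrieval window (0.75 or 1.5 s).
#' @param retrieval_window_s Length of the retrieval window.
#' @param iti_mean_s,iti_jitter_s Inter-trial interval, drawn uniformly from
#'   `iti_mean_s` +/- `iti_jitter_s` (default 10 +/- 2 s).
#' @param criterion_frac Fraction correct required (default 0.8).
#' @param criterion_window Trailing trial window for the criterion (default 50).
#' @param max_same_consecutive Maximum run length of one odor (default 3).
#' @return A list of class `"task_config"`.
#' @export
task_config <- function(stim_duration_s = 1.5, retrieval_onset_s = 0.75,
                        retrieval_window_s = 2, iti_mean_s = 10,
                        iti_jitter_s = 2, criterion_frac = 0.8,
                        criterion_window = 50, max_same_consecutive = 3) {
  stopifnot(criterion_frac > 0, criterion_frac <= 1,
            max_same_consecutive >= 1,
            stim_duration_s > 0, retrieval_onset_s > 0, retrieval_window_s > 0,
            iti_mean_s > 0, iti_jitter_s >= 0, criterion_window >= 1)
  structure(list(stim_duration_s = stim_duration_s,
                 retrieval_onset_s = retrieval_onset_s,
                 retrieval_window_s = retrieval_window_s,
                 iti_mean_s = iti_mean_s, iti_jitter_s = iti_jitter_s,
                 criterion_frac = criterion_frac,
                 criterion_window = as.integer(criterion_window),
                 max_same_consecutive = as.integer(max_same_consecutive)),
            class = "task_config")
}

#' Specification of a simulated Q-PH agent
#'
#' @param model Model name, see [qph-models].
#' @param theta Parameter vector (rates and eta in \[0,1\], softmax beta in
#'   \[0,500\]), named or in the model's canonical order.
#' @param q_init Initial action value (default 0.5).
#' @param alpha_init Initial associability (default 0).
#' @return A list of class `"agent_spec"`.
#' @export
agent_spec <- function(model = c("qph_f", "qph_kappa", "qph_eta"),
                       theta, q_init = 0.5, alpha_init = 0) {
  model <- match.arg(model)
  theta <- .qph_check_theta(model, theta)
  names(theta) <- .qph_par_names(model)
  structure(list(model = model, theta = theta,
                 q_init = q_init, alpha_init = alpha_init),
            class = "agent_spec")
}

#' Reference agent parameterisations
#'
#' One representative agent per model family, used by the package's
#' simulation studies: regimes in which each family's distinctive mechanism
#' (forgetting of the unchosen action; action-specific learning rates;
#' action-specific associability updating) is clearly expressed in behavior,
#' so that model identification is a meaningful exercise.
#'
#' @return Named list of [agent_spec()]s (`qph_f`, `qph_kappa`, `qph_eta`).
#' @export
default_agents <- function() {
  list(qph_f     = agent_spec("qph_f",     c(0.5, 0.25, 0.3, 5)),
       qph_kappa = agent_spec("qph_kappa", c(0.6, 0.15, 0.3, 5)),
       qph_eta   = agent_spec("qph_eta",   c(0.8, 0.05, 0.9, 5)))
}

# balanced pseudorandom two-odor sequence: exactly n_per of each odor,
# bounded run length; sequential draw weighted by remaining counts
.balanced_odor_sequence <- function(n_per, max_run) {
  n <- 2L * n_per
  rem <- c(n_per, n_per)
  s <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    allowed <- which(rem > 0L)
    if (i > 1L && run >= max_run) allowed <- setdiff(allowed, s[i - 1L])
    if (!length(allowed)) {        # dead end: forced run; restart tail
      return(.balanced_odor_sequence(n_per, max_run))
    }
    s[i] <- if (length(allowed) == 1L) allowed
            else sample(allowed, 1L, prob = rem[allowed])
    rem[s[i]] <- rem[s[i]] - 1L
    run <- if (i > 1L && s[i] == s[i - 1L]) run + 1L else 1L
  }
  s
}

# pseudorandom two-odor sequence with bounded run length
.odor_sequence <- function(n, max_run) {
  s <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && run >= max_run) {
      s[i] <- 3L - s[i - 1L]
    } else {
      s[i] <- sample(1:2, 1L)
    }
    run <- if (i > 1L && s[i] == s[i - 1L]) run + 1L else 1L
  }
  s
}

#' Simulate a go/no-go reversal session with a Q-PH agent
#'
#' Generates the pseudorandom odor sequence, draws actions from the agent's
#' softmax policy, delivers reward on CS+ lick trials, and reverses the
#' contingency at the first trial after the performance criterion is reached
#' (fraction correct >= `criterion_frac` over the trailing `criterion_window`
#' trials of the current phase). The session runs for the full `n_trials_max`
#' trials; it is marked `complete` only if the criterion is reached again in
#' the reversal phase, mirroring the inclusion rule for recorded sessions.
#'
#' @param cfg A [task_config()].
#' @param agent An [agent_spec()].
#' @param n_trials_max Number of trials to simulate (>= `criterion_window`).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return An object of class `"task_session"`: element `trials` is the trial
#'   table (odor state, CS+ flag, action, reward, correct, phase, onset and
#'   reward times), `traces` holds the ground-truth per-trial Q values,
#'   associabilities and \eqn{V_{CS+}(t)}; elements `reversal_trial` and
#'   `complete` describe the phase structure. State 1 is the initially
#'   rewarded odor.
#' @export
simulate_task_session <- function(cfg = task_config(), agent, n_trials_max = 400,
                                  seed) {
  stopifnot(inherits(cfg, "task_config"), inherits(agent, "agent_spec"))
  n <- as.integer(n_trials_max)
  if (n < cfg$criterion_window)
    stop("n_trials_max must be at least criterion_window")
  set.seed(seed)

  s <- .odor_sequence(n, cfg$max_same_consecutive)
  theta <- agent$theta
  model <- agent$model
  Q <- matrix(agent$q_init, 2, 2)
  alpha <- agent$alpha_init
  alpha_F <- agent$alpha_init
  cs_state <- 1L                      # state 1 rewarded in the original phase
  a <- integer(n); r <- numeric(n); correct <- logical(n)
  phase <- character(n)
  Qt <- matrix(NA_real_, n, 4); al <- numeric(n); alF <- numeric(n)
  v <- numeric(n); delta <- numeric(n)
  reversal_trial <- NA_integer_
  phase_start <- 1L
  complete <- FALSE

  for (t in seq_len(n)) {
    Qt[t, ] <- c(Q[1, 1], Q[1, 2], Q[2, 1], Q[2, 2])
    al[t] <- alpha; alF[t] <- alpha_F
    v[t] <- max(Q[cs_state, ])
    p <- softmax_prob(Q[s[t], ], theta[4])
    a[t] <- sample(1:2, 1L, prob = p)
    is_cs <- s[t] == cs_state
    r[t] <- as.numeric(is_cs && a[t] == 1L)
    correct[t] <- (is_cs && a[t] == 1L) || (!is_cs && a[t] == 2L)
    phase[t] <- if (is.na(reversal_trial)) "original" else "reversal"
    up <- qph_step(model, s[t], a[t], r[t], Q, alpha, alpha_F, theta)
    Q <- up$Q; alpha <- up$alpha; alpha_F <- up$alpha_F; delta[t] <- up$delta

    in_phase <- t - phase_start + 1L
    if (in_phase >= cfg$criterion_window) {
      w <- (t - cfg$criterion_window + 1L):t
      if (mean(correct[w]) >= cfg$criterion_frac) {
        if (is.na(reversal_trial)) {
          reversal_trial <- t + 1L
          cs_state <- 3L - cs_state
          phase_start <- t + 1L
        } else if (!complete) {
          complete <- TRUE
        }
      }
    }
  }

  iti <- runif(n, cfg$iti_mean_s - cfg$iti_jitter_s,
               cfg$iti_mean_s + cfg$iti_jitter_s)
  t_on <- cumsum(c(5, head(iti, -1) + cfg$stim_duration_s))
  # reward delivered at the third lick, shortly after the retrieval window opens
  t_rew <- ifelse(r > 0, t_on + cfg$retrieval_onset_s + 0.3, NA_real_)

  cs_plus <- (phase == "original" & s == 1L) | (phase == "reversal" & s == 2L)
  trials <- data.frame(
    trial = seq_len(n), t_on = t_on, state = s,
    odor = c("A", "B")[s], cs_plus = cs_plus,
    action = c("lick", "no_lick")[a], reward = r, correct = correct,
    phase = phase, t_reward = t_rew)
  colnames(Qt) <- c("Q_s1_lick", "Q_s1_restrain", "Q_s2_lick", "Q_s2_restrain")
  traces <- data.frame(trial = seq_len(n), Qt, alpha = al, alpha_F = alF,
                       delta = delta, value_cs = v)
  structure(list(trials = trials, traces = traces, cfg = cfg, agent = agent,
                 reversal_trial = reversal_trial, complete = complete,
                 seed = seed),
            class = "task_session")
}

#' @export
print.task_session <- function(x, ...) {
  n <- nrow(x$trials)
  cat("Simulated go/no-go session:", n, "trials\n")
  if (is.na(x$reversal_trial)) {
    cat("  criterion never reached; session incomplete\n")
  } else {
    cat("  reversal at trial", x$reversal_trial,
        if (x$complete) "(complete)" else "(reversal criterion not reached)", "\n")
  }
  cat(sprintf("  fraction correct: %.3f\n", mean(x$trials$correct)))
  invisible(x)
}

#' Simulate a passive pDA-pairing session layout
#'
#' Trial structure of the awake passive paradigm: two odors presented in
#' pseudorandom order across three phases ('pre', 'pairing', 'post'); during
#' the pairing phase one odor co-occurs with a brief laser train that evokes
#' phasic dopamine release. No actions or rewards are involved. Phase sizes
#' default to 40/30/30 presentations per odor; the first 10 'pre' trials are
#' conventionally dropped from response statistics downstream.
#'
#' @param n_pre,n_pairing,n_post Presentations per odor and phase.
#' @param paired_odor Which odor ("A" or "B") is paired with phasic dopamine.
#' @param stim_duration_s Odor duration (default 0.5 s).
#' @param iti_mean_s,iti_jitter_s Inter-trial interval (default 10 +/- 2 s).
#' @param max_same_consecutive Maximum stimulus run length (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `trial`, `t_on`, `odor`, `phase`,
#'   `paired` (logical), and attribute `paired_odor`.
#' @export
simulate_passive_session <- function(n_pre = 40, n_pairing = 30, n_post = 30,
                                     paired_odor = "A", stim_duration_s = 0.5,
                                     iti_mean_s = 10, iti_jitter_s = 2,
                                     max_same_consecutive = 3, seed) {
  set.seed(seed)
  counts <- c(pre = n_pre, pairing = n_pairing, post = n_post)
  counts <- counts[counts > 0]
  rows <- lapply(names(counts), function(ph) {
    s <- .balanced_odor_sequence(counts[[ph]], max_same_consecutive)
    data.frame(odor = c("A", "B")[s], phase = rep(ph, length(s)))
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  iti <- runif(n, iti_mean_s - iti_jitter_s, iti_mean_s + iti_jitter_s)
  tab <- data.frame(trial = seq_len(n),
                    t_on = cumsum(c(5, head(iti, -1) + stim_duration_s)),
                    tab)
  tab$paired <- tab$odor == paired_odor
  attr(tab, "paired_odor") <- paired_odor
  tab
}
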
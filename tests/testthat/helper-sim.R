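# shared small fixtures, built once per test run

qphf_theta <- c(kappaL = 0.4, kappaF = 0.1, eta = 0.3, beta = 5)

quick_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_task_session(task_config(),
                                      agent_spec("qph_f", qphf_theta),
                                      n_trials_max = 300, seed = 101)
    cache
  }
})

# R reference recursion: independent oracle for the compiled likelihood
r_qph_loglik <- function(model, s, a, r, theta) {
  Q <- matrix(0.5, 2, 2); alpha <- 0; alpha_F <- 0; ll <- 0
  for (t in seq_along(s)) {
    p <- softmax_prob(Q[s[t], ], theta[4])
    ll <- ll + log(p[a[t]])
    up <- qph_step(model, s[t], a[t], r[t], Q, alpha, alpha_F, theta)
    Q <- up$Q; alpha <- up$alpha; alpha_F <- up$alpha_F
  }
  ll
}

# regular spike train at a given rate over [t0, t1)
regular_spikes <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0) return(numeric(0))
  seq(t0, t1 - 1e-9, by = 1 / rate_hz)
}
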
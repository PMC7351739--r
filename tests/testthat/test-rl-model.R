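test_that("softmax policy has the closed form and degenerates to chance", {
  expect_equal(softmax_prob(c(1, 0), beta = 2),
               c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(softmax_prob(c(0.9, 0.1), beta = 0), c(0.5, 0.5))
  expect_equal(softmax_prob(c(0.4, 0.4), beta = 117), c(0.5, 0.5))
  # overflow safety at the beta bound
  expect_equal(sum(softmax_prob(c(1, 0), beta = 500)), 1)
})

test_that("single Q-PH steps match hand-computed updates", {
  Q <- matrix(0.5, 2, 2)
  # zero associability: Q frozen regardless of reward, alpha grows by eta|delta|
  up <- qph_step("qph_f", 1, 1, 1, Q, alpha = 0, alpha_F = 0,
                 theta = c(0.4, 0.1, 0.3, 5))
  expect_equal(up$Q, Q)
  expect_equal(up$alpha, 0.3 * abs(1 - 0.5))
  # forgetting update of the unchosen action, hand-evaluated
  Q2 <- matrix(0.5, 2, 2); Q2[1, 2] <- 0.8
  up2 <- qph_step("qph_f", 1, 1, 1, Q2, alpha = 0.5, alpha_F = 0.2,
                  theta = c(kappaL = 0, kappaF = 0.5, eta = 0.3, beta = 5))
  expect_equal(up2$Q[1, 2], 0.8 - 0.5 * 0.2 * 0.8)
  expect_equal(up2$alpha_F, (1 - 0.3) * 0.2 + 0.3 * 0.8)
})

test_that("forgetting model with kappaF = 0 reproduces the hybrid trajectories", {
  set.seed(5)
  s <- sample(1:2, 200, TRUE); a <- sample(1:2, 200, TRUE)
  r <- as.numeric(s == 1 & a == 1)
  thf <- c(0.6, 0, 0.35, 4)        # kappaF = 0
  thk <- c(0.6, 0.6, 0.35, 4)      # equal action learning rates = hybrid
  llf <- vsvta:::qph_loglik_cpp(3L, s, a, r, thf)
  llk <- vsvta:::qph_loglik_cpp(1L, s, a, r, thk)
  expect_equal(llf, llk, tolerance = 1e-12)
})

test_that("compiled likelihood agrees with the R reference recursion", {
  ss <- quick_session()
  s <- ss$trials$state
  a <- ifelse(ss$trials$action == "lick", 1L, 2L)
  r <- ss$trials$reward
  for (m in c("qph_kappa", "qph_eta", "qph_f")) {
    th <- switch(m, qph_kappa = c(0.5, 0.2, 0.3, 5),
                 qph_eta = c(0.4, 0.5, 0.1, 5),
                 qph_f = c(0.4, 0.1, 0.3, 5))
    expect_equal(vsvta:::qph_loglik_cpp(vsvta:::.qph_models[[m]], s, a, r, th),
                 r_qph_loglik(m, s, a, r, th), tolerance = 1e-10)
  }
})

test_that("action values stay in [0,1] for binary rewards and bounded rates", {
  set.seed(9)
  for (rep in 1:20) {
    m <- sample(c("qph_kappa", "qph_eta", "qph_f"), 1)
    th <- c(runif(3), runif(1, 0, 20))
    Q <- matrix(0.5, 2, 2); alpha <- 0; aF <- 0
    for (t in 1:150) {
      s <- sample(1:2, 1); a <- sample(1:2, 1); r <- rbinom(1, 1, 0.5)
      up <- qph_step(m, s, a, r, Q, alpha, aF, th)
      Q <- up$Q; alpha <- up$alpha; aF <- up$alpha_F
      expect_true(all(Q >= 0 & Q <= 1))
      expect_true(alpha >= 0 && alpha <= 1)
    }
  }
})

test_that("likelihood is invariant to relabeling the two odors", {
  ss <- quick_session()
  s <- ss$trials$state
  a <- ifelse(ss$trials$action == "lick", 1L, 2L)
  r <- ss$trials$reward
  th <- c(0.4, 0.1, 0.3, 5)
  expect_equal(vsvta:::qph_loglik_cpp(3L, s, a, r, th),
               vsvta:::qph_loglik_cpp(3L, 3L - s, a, r, th))
})

test_that("fits recover chance behavior and improve monotonically with restarts", {
  set.seed(31)
  n <- 200
  dat <- data.frame(state = sample(1:2, n, TRUE),
                    action = sample(1:2, n, TRUE))
  dat$reward <- as.numeric(dat$state == 1 & dat$action == 1)
  f <- qph_fit(dat, "qph_f", n_starts = 48, seed = 1)
  # chance data: fitted likelihood cannot beat n log(0.5) by much
  expect_lt(f$logLik - n * log(0.5), qchisq(0.999, df = 4) / 2)
  ss <- quick_session()
  f16 <- qph_fit(ss$trials, "qph_f", n_starts = 16, seed = 7)
  f32 <- qph_fit(ss$trials, "qph_f", n_starts = 32, seed = 7)
  expect_gte(f32$logLik, f16$logLik - 1e-8)
})

test_that("the fitted optimum is locally optimal in every coordinate", {
  ss <- quick_session()
  f <- qph_fit(ss$trials, "qph_f", n_starts = 64, seed = 3, tol = 1e-6)
  beh <- vsvta:::.behavior_columns(ss$trials)
  ll <- function(th) vsvta:::qph_loglik_cpp(3L, beh$s, beh$a, beh$r, th)
  th <- unname(coef(f))
  eps <- 1e-3
  lo <- c(0, 0, 0, 0); hi <- c(1, 1, 1, 500)
  for (j in 1:4) for (d in c(-eps, eps)) {
    th2 <- th; th2[j] <- min(hi[j], max(lo[j], th2[j] + d))
    expect_lte(ll(th2), f$logLik + 1e-4)
  }
})

test_that("value trace follows the contingency across the reversal", {
  ss <- quick_session()
  f <- qph_fit(ss$trials, "qph_f", n_starts = 64, seed = 2)
  expect_gt(cor(value_trace(f), ss$traces$value_cs), 0.9)
})

test_that("comparing identical fits yields zero BIC difference", {
  ss <- quick_session()
  f <- qph_fit(ss$trials, "qph_f", n_starts = 16, seed = 1)
  cmp <- compare_qph_models(list(s1 = list(a = f, b = f),
                                 s2 = list(a = f, b = f)))
  expect_equal(unname(diff(cmp$mean_bic)), 0)
  expect_equal(cmp$bic[, "a"], cmp$bic[, "b"])
})
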
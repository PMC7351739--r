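make_session <- function(n_trials, n_units, n_bins, seed, lambda = 2) {
  set.seed(seed)
  counts <- array(rpois(n_trials * n_units * n_bins, lambda),
                  c(n_trials, n_units, n_bins))
  attr(counts, "bin_times") <- seq(-1.75, by = 0.25, length.out = n_bins)
  list(counts = counts,
       odor = rep(c("A", "B"), length.out = n_trials),
       phase = rep(c("pre", "post"), each = n_trials / 2))
}

test_that("population-vector distances match hand-evaluated values", {
  x <- c(1, 2, 2); y <- c(3, 0, 4)
  d <- pv_distance(x, y)
  expect_equal(unname(d["cosine"]), 1 - 11 / 15, tolerance = 1e-12)
  expect_equal(unname(d["euclidean"]), sqrt(12) / 3, tolerance = 1e-12)
  expect_equal(unname(pv_distance(x, x)), c(0, 0))
  expect_equal(unname(pv_distance(c(1, 0), c(0, 1))["cosine"]), 1)
  expect_true(is.na(pv_distance(c(0, 0, 0), y)["cosine"]))
})

test_that("cosine distance is scale-invariant and Euclidean scales linearly", {
  set.seed(1)
  for (i in 1:20) {
    x <- runif(30); y <- runif(30); a <- runif(1, 0.1, 10)
    expect_equal(pv_distance(a * x, y)["cosine"], pv_distance(x, y)["cosine"],
                 tolerance = 1e-10)
    expect_equal(unname(pv_distance(a * x, a * y)["euclidean"]),
                 unname(a * pv_distance(x, y)["euclidean"]), tolerance = 1e-10)
  }
})

test_that("trial groups concatenate and truncate across sessions as specified", {
  s1 <- make_session(60, 3, 14, 1)           # 15 groups per odor/phase
  pv1 <- build_population_vectors(list(s1))
  # single session: plain trial-group tensor
  own <- vsvta:::.group_trials(s1$counts[s1$odor == "A" & s1$phase == "pre", , ,
                                         drop = FALSE], 3)
  expect_equal(pv1$groups[["A|pre"]], own)
  # sessions with 5 vs 6 trial-groups: truncated to 5; 'post' loses its last
  # group, 'pre' its first
  s2 <- make_session(60, 3, 14, 2)           # 5 groups per odor/phase
  s3 <- make_session(78, 2, 14, 3)           # 6 groups per odor/phase
  pv <- build_population_vectors(list(s2, s3))
  expect_equal(dim(pv$groups[["A|post"]]), c(5, 5, 14))
  g3post <- vsvta:::.group_trials(s3$counts[s3$odor == "A" & s3$phase == "post",
                                            , , drop = FALSE], 3)
  expect_equal(pv$groups[["A|post"]][, 4:5, ], g3post[1:5, , ])
  g3pre <- vsvta:::.group_trials(s3$counts[s3$odor == "A" & s3$phase == "pre",
                                           , , drop = FALSE], 3)
  expect_equal(pv$groups[["A|pre"]][, 4:5, ], g3pre[2:6, , ])
})

test_that("permuted matching yields per-session row permutations", {
  s1 <- make_session(36, 2, 14, 4)
  pv <- build_population_vectors(list(s1), matching = "permuted", n_perm = 5,
                                 seed = 9)
  expect_length(pv$realizations, 5)
  base <- pv$groups[["A|pre"]]
  perm <- pv$realizations[[2]][["A|pre"]]
  # same rows, possibly different order
  key <- function(a) sort(apply(a, 1, function(r) paste(r, collapse = ",")))
  expect_equal(key(base), key(perm))
})

test_that("deviation from baseline is zero for constant tensors", {
  s <- make_session(36, 3, 14, 5)
  s$counts[] <- 3L
  pv <- build_population_vectors(list(s))
  dv <- deviation_from_baseline(pv, "A", c("pre", "post"),
                                pv_params("passive"))
  expect_true(all(dv$deviation$cosine < 1e-12))
  expect_true(all(dv$deviation$euclidean == 0))
})

test_that("decoder refuses overparameterised dimensions via the df rule", {
  # D = 3 needs 2*(3 + 6 + 1) - 1 = 19 < n_points
  df_total <- function(D) 2 * (D * (D - 1) / 2 + 2 * D + 1) - 1
  expect_equal(df_total(3), 19)
  s <- make_session(120, 8, 14, 6)           # 10 groups/odor/phase -> n = 20
  pv <- build_population_vectors(list(s))
  qd <- qda_decode(pv, c("A", "B"), c("pre", "post"), dims = 3:4,
                   params = pv_params("passive"))
  expect_false(any(qd$accuracy$refused[qd$accuracy$dim == 3]))  # 19 < 20
  expect_true(all(qd$accuracy$refused[qd$accuracy$dim == 4]))   # 29 >= 20
})

test_that("decoding accuracy tracks class separation", {
  set.seed(7)
  mk <- function(sep) {
    n <- 30; u <- 8; b <- 14
    counts <- array(rnorm(2 * n * u * b, 5, 1), c(2 * n, u, b))
    odor <- rep(c("A", "B"), n)
    counts[odor == "A", 1:4, ] <- counts[odor == "A", 1:4, ] + sep
    counts <- pmax(counts, 0)
    attr(counts, "bin_times") <- seq(-1.75, by = 0.25, length.out = b)
    list(counts = counts, odor = odor, phase = rep("pre", 2 * n))
  }
  acc <- vapply(c(0, 5), function(sep) {
    pv <- build_population_vectors(list(mk(sep)))
    qd <- qda_decode(pv, c("A", "B"), c("pre", "pre"), dims = 3,
                     params = pv_params("passive"))
    qd$accuracy$accuracy[1]
  }, numeric(1))
  expect_lt(abs(acc[1] - 0.5), 0.3)    # identical classes: chance
  expect_gte(acc[2], 0.95)             # 5-SD separation: near-perfect
})

test_that("MDS preserves known low-dimensional configurations", {
  s <- make_session(36, 6, 14, 8)
  pv <- build_population_vectors(list(s))
  md <- mds_responses(pv, pv_params("passive"))
  expect_equal(ncol(md$points), 3)
  # exact 4-point configuration: distances reproduced, stress ~ 0
  X <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 3))
  pts <- cmdscale(dist(X), k = 2)
  expect_lt(sqrt(sum((dist(X) - dist(pts))^2) / sum(dist(X)^2)), 0.05)
  expect_equal(order(as.vector(dist(pts))), order(as.vector(dist(X))))
  # rigid rotation leaves interpoint distances unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(as.vector(dist(cmdscale(dist(X %*% R), k = 2))),
               as.vector(dist(pts)), tolerance = 1e-8)
})

test_that("trajectory embedding flags degenerate input", {
  s <- make_session(36, 3, 14, 9)
  s$counts[] <- 2L
  pv <- build_population_vectors(list(s))
  emb <- embed_trajectories(pv)
  expect_true(attr(emb, "degenerate"))
  s2 <- make_session(36, 3, 14, 10)
  pv2 <- build_population_vectors(list(s2))
  emb2 <- embed_trajectories(pv2)
  expect_equal(ncol(emb2[[1]]), 3)
  expect_false(attr(emb2, "degenerate"))
})
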
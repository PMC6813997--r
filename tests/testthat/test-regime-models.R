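test_that("AICc formula and guards", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(0, 0, 10), 0)
  expect_error(aicc(0, 5, 6), "n must exceed")
  # independent re-coding on random triples
  set.seed(1)
  for (i in 1:20) {
    ll <- rnorm(1, 0, 10); k <- sample(1:6, 1); n <- k + 2 + sample(1:30, 1)
    expect_equal(aicc(ll, k, n),
                 -2 * ll + 2 * k + (2 * k^2 + 2 * k) / (n - k - 1))
  }
})

test_that("half-life identity t_1/2 * alpha = ln 2", {
  expect_equal(ou_half_life(3.055), 0.227, tolerance = 5e-4)
  a <- exp(seq(-4, 4, length.out = 17))
  expect_equal(ou_half_life(a) * a, rep(log(2), 17))
})

test_that("BM fit matches closed forms and a brute-force density oracle", {
  # two-tip closed form
  f2 <- bm_fit(c(A = 0, B = 2), cherry())
  expect_equal(f2$params$root, 1)
  expect_equal(f2$params$sigma2, 1)
  # degenerate constant trait
  expect_error(bm_fit(c(A = 1, B = 1), cherry()), "degenerate")
  # 6-tip oracle equivalence
  tr <- simulate_tree(6, depth = 4, seed = 2)
  y <- simulate_bm(tr, matrix(0.5), seed = 3)[, 1]
  f <- bm_fit(y, tr)
  C <- brute_vcv(tr)[names(y), names(y)]
  expect_equal(f$params$logLik,
               mvn_logdens(y, rep(f$params$root, 6), f$params$sigma2 * C),
               tolerance = 1e-8)
})

test_that("Hansen likelihood equals a brute-force joint-Gaussian oracle", {
  tr <- tree4()
  p <- regime_painting(tr, shift_edges = 4, shift_regimes = "b")
  y <- c(A = 0.3, B = -0.2, C = 1.1, D = 0.8)
  alpha <- 1; Tt <- 2
  # oracle: enumerate lineage segments by hand for this topology
  wseg <- function(t0, t1) exp(-alpha * (Tt - t1)) - exp(-alpha * (Tt - t0))
  W <- matrix(0, 4, 2, dimnames = list(names(y), c("anc", "b")))
  W["A", "anc"] <- wseg(0, 1) + wseg(1, 2) + exp(-alpha * Tt)
  W["B", "anc"] <- W["A", "anc"]
  W["C", "anc"] <- exp(-alpha * Tt)
  W["C", "b"] <- wseg(0, 1) + wseg(1, 2)
  W["D", ] <- W["C", ]
  expect_equal(unname(rowSums(W)), rep(1, 4), tolerance = 1e-12)
  s <- brute_vcv(tr)[names(y), names(y)]
  d <- outer(diag(s), diag(s), `+`) - 2 * s
  V0 <- exp(-alpha * d) * (1 - exp(-2 * alpha * s)) / (2 * alpha)
  Vi <- solve(V0)
  theta <- solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y)
  r <- y - drop(W %*% theta)
  s2 <- drop(t(r) %*% Vi %*% r) / 4
  ll <- mvn_logdens(y, drop(W %*% theta), s2 * V0)

  got <- hansen_loglik(y, tr, p, alpha = 1)
  expect_equal(got$logLik, ll, tolerance = 1e-8)
  expect_equal(unname(got$theta), unname(drop(theta)), tolerance = 1e-8)
  expect_equal(got$sigma2, s2, tolerance = 1e-8)
})

test_that("Hansen model limits: BM as alpha -> 0, regime means as alpha -> inf", {
  tr <- simulate_tree(8, depth = 4, seed = 5)
  y <- simulate_bm(tr, matrix(0.3), seed = 6)[, 1]
  p1 <- regime_painting(tr)
  expect_equal(hansen_loglik(y, tr, p1, alpha = 1e-8)$logLik,
               bm_fit(y, tr)$params$logLik, tolerance = 1e-4)
  # white-noise limit: optima approach regime means of the tips
  p2 <- paint_random_shifts(tr, 1, seed = 7, min_tips = 3)
  big <- hansen_loglik(y, tr, p2, alpha = 1e3 / tree_depth(tr))
  tr_reg <- tip_regimes(p2)
  means <- tapply(y[names(tr_reg)], tr_reg, mean)
  expect_equal(unname(big$theta[names(means)]), unname(as.numeric(means)),
               tolerance = 1e-3)
})

test_that("OU design rows sum to one and V0 is positive definite", {
  tr <- simulate_tree(16, depth = 12, seed = 8)
  cache <- convergr:::.hansen_cache(tr)
  p <- paint_random_shifts(tr, 3, seed = 9)
  for (a in c(0.01, 0.3, 2, 20)) {
    W <- convergr:::.ou_weights(cache, p$edge_regimes, p$root_regime, a,
                                convergr:::.regime_levels(p))
    expect_equal(unname(rowSums(W)), rep(1, 16), tolerance = 1e-12)
    V0 <- convergr:::.ou_cov0(cache, a)
    expect_equal(V0, t(V0), tolerance = 1e-12)
    expect_gt(min(eigen(V0, symmetric = TRUE)$values), 0)
  }
})

test_that("hansen_fit recovers planted parameters and handles edge cases", {
  # parameter recovery across a handful of seeded replicates
  alphas <- c(); thetas <- c()
  for (s in 1:6) {
    tr <- simulate_tree(48, depth = 12, seed = 300 + s)
    p <- paint_random_shifts(tr, 2, 1, seed = 400 + s, min_tips = 3)
    y <- simulate_hansen(tr, p, alpha = 0.5, sigma2 = 0.05,
                         theta = matrix(c(0, 1), 2, 1,
                                        dimnames = list(c("anc", "a"), NULL)),
                         seed = 500 + s)
    f <- hansen_fit(y, tr, p)
    alphas <- c(alphas, f$params$alpha)
    thetas <- c(thetas, f$theta["a", 1])
  }
  expect_gt(median(alphas), 0.5 / 3)
  expect_lt(median(alphas), 0.5 * 3)
  expect_lt(abs(median(thetas) - 1), 0.25)

  # single-regime painting is exactly the OU1 model
  tr <- simulate_tree(12, depth = 8, seed = 20)
  y <- simulate_bm(tr, matrix(0.1), seed = 21)
  f_ou1 <- hansen_fit(y, tr)
  f_single <- hansen_fit(y, tr, regime_painting(tr))
  expect_equal(f_ou1$AICc, f_single$AICc)
  expect_equal(f_ou1$params$half_life, log(2) / f_ou1$params$alpha)
  # non-ultrametric trees are rejected for OU
  bad <- read_newick("((A:1,B:2):1,C:2);")
  expect_error(hansen_fit(c(A = 1, B = 0, C = 2), bad), "ultrametric")
})

test_that("regime paintings keep their bookkeeping invariants", {
  tr <- tree4()
  p <- regime_painting(tr, shift_edges = c(2, 5), shift_regimes = c("a", "a"))
  cnt <- regime_counts(p)
  expect_equal(cnt$n_shifts, 2)
  expect_equal(cnt$n_convergent_regimes, 1)
  expect_equal(cnt$convergence_fraction, 1)
  expect_equal(unname(tip_regimes(p)[c("A", "C")]), c("a", "a"))
  # a shift that does not change the parent regime is rejected
  expect_error(regime_painting(tr, shift_edges = c(1, 2),
                               shift_regimes = c("anc", "a")),
               "does not change")
  # no shifts: single regime, fraction 0
  cnt0 <- regime_counts(regime_painting(tr))
  expect_equal(cnt0$n_regimes, 1)
  expect_equal(cnt0$convergence_fraction, 0)
})
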
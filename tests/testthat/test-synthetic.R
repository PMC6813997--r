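test_that("simulated trees honour tip count, depth and ultrametry", {
  tr2 <- simulate_tree(2, depth = 7, seed = 1)
  expect_equal(unname(tip_depths(tr2)), c(7, 7))
  tr <- simulate_tree(48, depth = 36, seed = 2)
  expect_equal(length(tr$tip.label), 48)
  expect_equal(tree_depth(tr), 36, tolerance = 1e-9)
  expect_true(is_ultrametric(tr, tol = 1e-9))
})

test_that("tree imbalance is consistent with the pure-birth expectation", {
  # Colless index of simulated trees against a directly simulated Yule
  # envelope (ape's own generator serves as the independent reference)
  colless <- function(tree) {
    b <- ape::balance(tree)   # per-node descendant counts (bifurcating trees)
    sum(abs(b[, 1] - b[, 2]))
  }
  obs <- vapply(1:30, function(s) colless(simulate_tree(32, 10, seed = s)),
                numeric(1))
  set.seed(99)
  ref <- vapply(1:200, function(i) colless(ape::rphylo(32, 1, 0)), numeric(1))
  expect_gt(mean(obs), quantile(ref, 0.005))
  expect_lt(mean(obs), quantile(ref, 0.995))
})

test_that("random paintings satisfy the painting invariants across seeds", {
  tr <- simulate_tree(32, depth = 36, seed = 3)
  expect_equal(regime_counts(paint_random_shifts(tr, 0))$n_shifts, 0)
  p2 <- paint_random_shifts(tr, 2, 1, seed = 4)
  cnt <- regime_counts(p2)
  expect_equal(cnt$n_shifts, 2)
  expect_equal(cnt$n_convergent_regimes, 1)
  expect_equal(cnt$convergence_fraction, 1)
  for (s in 1:25) {
    p <- paint_random_shifts(tr, sample(0:6, 1), seed = s)
    # every branch painted; shifts differ from their parent regime
    expect_equal(length(p$edge_regimes), nrow(tr$edge))
    pe <- convergr:::.parent_edge(tr)
    for (e in p$shift_edges) {
      parent <- pe[tr$edge[e, 1]]
      parent_reg <- if (parent == 0) p$root_regime else p$edge_regimes[parent]
      expect_false(p$edge_regimes[e] == parent_reg)
    }
  }
  expect_error(paint_random_shifts(tr, nrow(tr$edge) + 1), "more shifts")
})

test_that("BM simulation has the analytic first two moments", {
  # zero-length-ish tree: all tips at the root state
  tr0 <- read_newick("(A:1e-12,B:1e-12);")
  expect_lt(max(abs(simulate_bm(tr0, matrix(4), seed = 1))), 1e-4)
  # cherry of depth 1: tip variance ~ sigma2, cross-tip correlation ~ 0
  tr <- cherry()
  reps <- vapply(1:800, function(i) simulate_bm(tr, matrix(0.7), seed = 2000 + i)[, 1],
                 numeric(2))
  expect_gt(var(reps[1, ]), 0.7 * 0.85)
  expect_lt(var(reps[1, ]), 0.7 * 1.15)
  expect_lt(abs(cor(reps[1, ], reps[2, ])), 0.12)
  # multivariate: sample covariance approximates Kronecker(C, R)
  tr6 <- simulate_tree(6, depth = 2, seed = 5)
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  sims <- lapply(1:1500, function(i) simulate_bm(tr6, R, seed = 3000 + i))
  C <- phylo_cov(tr6)[tr6$tip.label, tr6$tip.label]
  # check a handful of cross entries: cov(y_i1, y_j2) = C_ij * R_12
  y11 <- vapply(sims, function(m) m[1, 1], numeric(1))
  y32 <- vapply(sims, function(m) m[3, 2], numeric(1))
  expect_equal(cov(y11, y32), C[1, 3] * R[1, 2],
               tolerance = 0.15 * max(C) + 1e-10)
  expect_error(simulate_bm(tr6, matrix(c(1, 2, 2, 1), 2)), "semidefinite")
})

test_that("Hansen simulation hits its deterministic and stationary limits", {
  tr <- simulate_tree(12, depth = 6, seed = 6)
  p <- paint_random_shifts(tr, 2, 1, seed = 7, min_tips = 2)
  th <- matrix(c(0, 1), 2, 1, dimnames = list(c("anc", "a"), NULL))
  # sigma2 = 0: tips sit exactly on the deterministic mean path
  y0 <- simulate_hansen(tr, p, alpha = 0.8, sigma2 = 0, theta = th, seed = 8)
  y0b <- simulate_hansen(tr, p, alpha = 0.8, sigma2 = 0, theta = th, seed = 99)
  expect_equal(y0, y0b)          # no randomness left
  # strong pull: regime means near their optima
  reps <- vapply(1:200, function(i) {
    simulate_hansen(tr, p, alpha = 2, sigma2 = 0.05, theta = th,
                    seed = 4000 + i)[, 1]
  }, numeric(12))
  regs <- tip_regimes(p)
  m_a <- mean(reps[regs[rownames(reps)] == "a", ])
  m_anc <- mean(reps[regs[rownames(reps)] == "anc", ])
  sd_st <- sqrt(0.05 / 4)
  expect_lt(abs(m_a - 1), 3 * sd_st)
  expect_lt(abs(m_anc - 0), 3 * sd_st)
  expect_error(simulate_hansen(tr, p, 1, 0.1,
                               matrix(0, 1, 1, dimnames = list("anc", NULL))),
               "no optimum")
})

test_that("Hansen simulator and Hansen likelihood agree (cross-module)", {
  # empirical tip covariance over replicates matches the analytic OU
  # covariance used by the likelihood
  tr <- simulate_tree(5, depth = 3, seed = 9)
  p <- regime_painting(tr)
  al <- 0.6; s2 <- 0.4
  th <- matrix(0.3, 1, 1, dimnames = list("anc", NULL))
  sims <- vapply(1:2500, function(i)
    simulate_hansen(tr, p, al, s2, th, seed = 5000 + i)[, 1], numeric(5))
  Vemp <- cov(t(sims))
  cache <- convergr:::.hansen_cache(tr)
  Van <- s2 * convergr:::.ou_cov0(cache, al)
  expect_lt(max(abs(Vemp - Van)) / max(Van), 0.1)

  # the average log-density at the truth beats perturbed parameters
  better <- 0
  for (i in 1:60) {
    y <- simulate_hansen(tr, p, al, s2, th, seed = 6000 + i)[, 1]
    ll_true <- mvn_logdens(y, rep(0.3, 5), Van)
    ll_pert <- mvn_logdens(y, rep(0.3, 5),
                           s2 * 2 * convergr:::.ou_cov0(cache, al / 3))
    if (ll_true > ll_pert) better <- better + 1
  }
  expect_gt(better, 40)
})

test_that("landmark generator honours the scheme and exercises alignment", {
  sch <- default_scheme(4, 5)
  lms <- simulate_landmarks(6, scheme = sch, noise_sd = 0, seed = 10)
  expect_equal(dim(lms)[1], 20)
  al <- gpa(lms)
  for (i in 2:6) {
    expect_lt(procrustes_distance(al$coords[, , 1], al$coords[, , i]), 1e-9)
  }
  # two groups with distinct deformations separate along PC1
  sep <- 0
  for (s in 1:10) {
    g <- rep(1:2, each = 4)
    lg <- simulate_landmarks(8, scheme = sch, groups = g,
                             deformation = c(0.05, 0.3), seed = 100 + s)
    sp <- shape_pca(gpa(lg))
    pc1 <- score_matrix(sp)[, 1]
    gap <- abs(mean(pc1[g == 1]) - mean(pc1[g == 2]))
    spread <- sd(pc1[g == 1]) + sd(pc1[g == 2]) + 1e-12
    if (gap > spread) sep <- sep + 1
  }
  expect_gte(sep, 9)
})

test_that("ecology generator spans independence to determinism", {
  tr <- simulate_tree(24, depth = 36, seed = 11)
  p <- paint_random_shifts(tr, 2, 1, seed = 12, min_tips = 3)
  e1 <- simulate_ecology(p, strength = 1, seed = 13)
  regs <- tip_regimes(p)
  # strength 1: category deterministic within regime
  for (r in unique(regs)) {
    expect_equal(length(unique(e1$habitat[regs[e1$species] == r])), 1)
  }
  e0a <- simulate_ecology(p, strength = 0, seed = 14)
  e0b <- simulate_ecology(p, strength = 0, seed = 14)
  expect_identical(e0a, e0b)
  expect_true(all(e0a$mass_kg > 0))
})

test_that("datasets are bit-reproducible and round-trip through disk", {
  d1 <- simulate_dataset(n_tips = 16, seed = 77, with_landmarks = TRUE,
                         with_ecology = TRUE)
  d2 <- simulate_dataset(n_tips = 16, seed = 77, with_landmarks = TRUE,
                         with_ecology = TRUE)
  expect_identical(d1$traits, d2$traits)
  expect_identical(unclass(d1$landmarks), unclass(d2$landmarks))
  expect_identical(d1$ecology, d2$ecology)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  back <- read_dataset(dir)
  expect_equal(ape::write.tree(back$tree), ape::write.tree(d1$tree))
  # tip numbering may differ after re-reading; compare by label
  expect_equal(back$traits[rownames(d1$traits), ], d1$traits,
               tolerance = 1e-12)
  expect_identical(back$painting$edge_regimes, d1$painting$edge_regimes)
  expect_equal(as.data.frame(back$ecology), as.data.frame(d1$ecology))
  # .pts directories load in filename order; align specimens by label
  expect_equal(unclass(back$landmarks)[, , dimnames(d1$landmarks)[[3]]],
               unclass(d1$landmarks), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$provenance$seed, 77)
})
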
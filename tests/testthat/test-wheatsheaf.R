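test_that("equidistant species on a star tree give w = 1", {
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  # vertices of a regular simplex are mutually equidistant
  y <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1),
             D = c(-1, -1, -1) / 3)
  d <- dist(scale(y))
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(wheatsheaf_index(y, star, c("A", "B")), 1, tolerance = 1e-9)
})

test_that("identical focal phenotypes give an infinite index", {
  tr <- simulate_tree(6, depth = 5, seed = 1)
  y <- simulate_bm(tr, diag(2), seed = 2)
  y[2, ] <- y[1, ]
  expect_warning(
    w <- wheatsheaf_index(y, tr, tr$tip.label[1:2]),
    "identical"
  )
  expect_identical(w, Inf)
})

test_that("the index matches a brute-force enumeration on an 8-tip fixture", {
  tr <- simulate_tree(8, depth = 10, seed = 3)
  set.seed(4)
  y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(tr$tip.label, NULL))
  focal <- tr$tip.label[c(2, 5, 7)]
  # oracle: standardise, enumerate all pairs with the multiplicative kernel
  ys <- scale(y)
  C <- phylo_cov(tr)[tr$tip.label, tr$tip.label]
  Tt <- tree_depth(tr)
  num <- c(); den <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    dd <- sqrt(sum((ys[i, ] - ys[j, ])^2)) * (1 + C[i, j] / Tt)
    num <- c(num, dd)
    if (all(tr$tip.label[c(i, j)] %in% focal)) den <- c(den, dd)
  }
  expect_equal(wheatsheaf_index(y, tr, focal), mean(num) / mean(den),
               tolerance = 1e-10)
  # removing the correction reduces to the plain standardised-distance ratio
  num0 <- c(); den0 <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    dd <- sqrt(sum((ys[i, ] - ys[j, ])^2))
    num0 <- c(num0, dd)
    if (all(tr$tip.label[c(i, j)] %in% focal)) den0 <- c(den0, dd)
  }
  expect_equal(wheatsheaf_index(y, tr, focal, correct = FALSE),
               mean(num0) / mean(den0), tolerance = 1e-10)
})

test_that("the uncorrected index ignores non-focal species labelling", {
  tr <- simulate_tree(10, depth = 8, seed = 5)
  y <- simulate_bm(tr, diag(3), seed = 6)
  focal <- tr$tip.label[1:3]
  # without the relatedness kernel the index depends on phenotypes only, so
  # shuffling which non-focal tip carries which phenotype changes nothing;
  # with the kernel it must change (that is the kernel's whole point)
  w0 <- wheatsheaf_index(y, tr, focal, correct = FALSE)
  others <- setdiff(tr$tip.label, focal)
  y2 <- y
  set.seed(7)
  y2[others, ] <- y[sample(others), ]
  expect_equal(wheatsheaf_index(y2, tr, focal, correct = FALSE), w0,
               tolerance = 1e-12)
})

test_that("two-taxon focal groups yield an infinite upper jackknife CI", {
  tr <- simulate_tree(12, depth = 10, seed = 8)
  y <- simulate_bm(tr, diag(4), seed = 9)
  ci <- wheatsheaf_ci(y, tr, tr$tip.label[c(3, 8)])
  expect_identical(ci$upper, Inf)
  expect_true(is.finite(ci$lower))
  # the two infinite replicates are exactly the focal deletions
  expect_equal(sum(is.infinite(ci$replicates)), 2)
})

test_that("degenerate jackknife distributions give a zero-width interval", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  y <- rbind(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0), C = c(0, 0, 1, 0),
             D = c(0, 0, 0, 1),
             E = (1 - sqrt(5)) / 4 * c(1, 1, 1, 1))
  # mutually equidistant: every leave-one-out replicate equals 1 (raw
  # coordinates; per-replicate restandardisation would break equidistance)
  ci <- wheatsheaf_ci(y, star, c("A", "B", "C"), standardise = FALSE)
  expect_equal(ci$lower, ci$upper, tolerance = 1e-9)
  expect_equal(ci$lower, 1, tolerance = 1e-9)
})

test_that("bootstrap p-values are seeded, floored and respond to planted clusters", {
  tr <- simulate_tree(14, depth = 10, seed = 10)
  y <- simulate_bm(tr, diag(3), seed = 11)
  focal <- tr$tip.label[c(1, 6, 11)]
  p1 <- wheatsheaf_pvalue(y, tr, focal, n_boot = 100, seed = 12)
  p2 <- wheatsheaf_pvalue(y, tr, focal, n_boot = 100, seed = 12)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$p_protected, (sum(p1$boot >= p1$observed) + 1) / 101)
  expect_error(wheatsheaf_pvalue(y, tr, focal, n_boot = 10), "at least 100")

  # planted tight focal cluster among dispersed species
  y2 <- y * 4
  y2[focal, ] <- matrix(rnorm(9, sd = 0.05), 3) + rep(c(5, 5, 5), each = 3)
  res <- wheatsheaf(y2, tr, focal, n_boot = 200, seed = 13)
  expect_gt(res$w, 1)
  expect_lte(res$p_value, 0.05)
  td <- tidy(res)
  expect_named(td, c("w", "ci_lower", "ci_upper", "p_value", "p_protected",
                     "n_boot"))
})

test_that("constant trait columns are dropped with a warning", {
  tr <- simulate_tree(8, depth = 5, seed = 14)
  y <- cbind(simulate_bm(tr, diag(2), seed = 15), 1)
  colnames(y)[3] <- "flat"
  expect_warning(w <- wheatsheaf_index(y, tr, tr$tip.label[1:2]), "flat")
  expect_true(is.finite(w))
})
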
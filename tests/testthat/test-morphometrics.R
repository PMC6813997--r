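# one template-based landmark builder used across the GPA tests
template_config <- function(p = 12, seed = 1) {
  set.seed(seed)
  tt <- seq(0, 2 * pi, length.out = p)
  cbind(cos(tt), sin(tt), 0.2 * tt)
}

apply_similarity <- function(m, seed) {
  set.seed(seed)
  R <- random_rotation(3, seed)
  sweep(m %*% R * exp(runif(1, -0.5, 0.5)), 2, runif(3, -3, 3), `+`)
}

test_that("GPA removes position, scale and orientation", {
  base <- template_config()
  specs <- landmark_set(list(base, apply_similarity(base, 2),
                             apply_similarity(base, 3)))
  al <- gpa(specs)
  # identical shapes align to pairwise distance ~0
  expect_lt(procrustes_distance(al$coords[, , 1], al$coords[, , 2]), 1e-9)
  expect_lt(procrustes_distance(al$coords[, , 1], al$coords[, , 3]), 1e-9)
  # unit centroid size and centred output
  sizes <- apply(al$coords, 3, function(m) sqrt(sum(m^2)))
  expect_equal(unname(sizes), rep(1, 3), tolerance = 1e-9)
  expect_lt(max(abs(apply(al$coords, 3, colMeans))), 1e-12)
  # consensus is the mean of aligned specimens up to its unit-size scaling
  cons <- apply(al$coords, c(1, 2), mean)
  expect_lt(procrustes_distance(cons, al$consensus), 1e-9)
})

test_that("GPA output is invariant to similarity transforms of the input", {
  lms <- simulate_landmarks(6, seed = 10)
  al1 <- gpa(lms)
  moved <- lms
  for (i in seq_len(dim(lms)[3])) moved[, , i] <- apply_similarity(lms[, , i], 100 + i)
  al2 <- gpa(landmark_set(unclass(moved)))
  for (i in seq_len(dim(lms)[3])) {
    expect_lt(procrustes_distance(al1$coords[, , i], al2$coords[, , i]), 1e-8)
  }
})

test_that("mean of noisy copies recovers the template shape", {
  base <- template_config()
  set.seed(4)
  specs <- lapply(1:10, function(i) base + matrix(rnorm(length(base), sd = 0.01),
                                                  nrow(base)))
  al <- gpa(landmark_set(specs))
  # noise sd 0.01 on unit-ish shapes -> consensus error ~ sd/sqrt(n)
  expect_lt(procrustes_distance(al$consensus, base), 0.02)
})

test_that("degenerate specimens are rejected by name", {
  bad <- landmark_set(list(template_config(), matrix(1, 12, 3)))
  expect_error(gpa(bad), "spec2")
})

test_that("sliding reduces arbitrary along-curve placement", {
  # specimens identical -> sliding displaces nothing
  base <- template_config(p = 15)
  same <- landmark_set(list(base, base, base))
  scheme <- semilandmark_scheme(list(1:8, 9:15))
  slid <- slide_semilandmarks(same, scheme, iterations = 1, align = FALSE)
  al <- gpa(same)
  expect_equal(unclass(slid), unclass(al$coords), tolerance = 1e-12)

  # arc-length perturbed copies of a common curve: sliding strictly reduces
  # the summed Procrustes distance to the consensus
  curve_at <- function(tt) cbind(cos(tt), sin(tt), 0.2 * tt)
  t0 <- seq(0, 2 * pi, length.out = 15)
  set.seed(8)
  specs <- lapply(1:6, function(i) {
    jit <- t0 + c(0, rnorm(13, sd = 0.08), 0)   # endpoints untouched
    curve_at(sort(jit))
  })
  lms <- landmark_set(specs)
  scheme1 <- semilandmark_scheme(list(1:15))
  al0 <- gpa(lms)
  d_before <- sum(vapply(1:6, function(i)
    procrustes_distance(al0$coords[, , i], al0$consensus)^2, numeric(1)))
  slid <- slide_semilandmarks(lms, scheme1, iterations = 2)
  al1 <- gpa(slid)
  d_after <- sum(vapply(1:6, function(i)
    procrustes_distance(al1$coords[, , i], al1$consensus)^2, numeric(1)))
  expect_lt(d_after, d_before)
})

test_that("curve endpoints never move during a sliding pass", {
  lms <- simulate_landmarks(5, seed = 6, noise_sd = 0.05)
  scheme <- default_scheme()
  al <- gpa(lms)
  slid <- slide_semilandmarks(al, scheme, iterations = 1, align = FALSE)
  ends <- unlist(lapply(scheme$curves, function(cv) cv[c(1, length(cv))]))
  for (i in seq_len(dim(lms)[3])) {
    expect_identical(unclass(slid)[ends, , i], unclass(al$coords)[ends, , i])
  }
})

test_that("zero tangents are reported with curve and index", {
  base <- template_config(p = 9)
  base[4, ] <- base[2, ]  # neighbours of point 3 coincide
  lms <- landmark_set(list(base, base + 0.01))
  expect_error(slide_semilandmarks(lms, semilandmark_scheme(list(1:9)),
                                   iterations = 1),
               "curve 1 at point 3")
})

test_that("shape PCA conserves variance and reproduces shape distances", {
  lms <- simulate_landmarks(8, groups = rep(1:2, 4), seed = 12)
  al <- gpa(lms)
  sp <- shape_pca(al)
  expect_equal(sum(sp$var_fraction), 100, tolerance = 1e-6)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  scores <- score_matrix(sp)
  expect_lt(max(abs(colMeans(scores))), 1e-12)
  # total variance preserved
  flat <- t(apply(al$coords, 3, as.vector))
  expect_equal(sum(sp$eigenvalues),
               sum(apply(flat, 2, var)), tolerance = 1e-10)
  # pairwise Euclidean distances in full score space equal tangent distances
  expect_equal(as.matrix(dist(scores)),
               as.matrix(dist(flat)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single deformation axis yields PC1 = 100%", {
  base <- template_config()
  dir <- matrix(rnorm(length(base)), nrow(base))
  specs <- lapply(seq(-1, 1, length.out = 5), function(s) base + 0.02 * s * dir)
  al <- gpa(landmark_set(specs))
  sp <- shape_pca(al)
  expect_gt(sp$var_fraction[1], 99.9)
})

test_that(".pts files round-trip with comments and labels", {
  m <- template_config(p = 5)
  rownames(m) <- paste0("p", 1:5)
  f <- withr::local_tempfile(fileext = ".pts")
  write_pts(m, f)
  lines <- readLines(f)
  writeLines(c("# exported landmarks", lines[1:2], "", "# interlude",
               lines[3:5]), f)
  back <- read_pts(f)
  expect_equal(back, m, ignore_attr = TRUE)
  expect_equal(nrow(back), 5)
  writeLines(c(lines, "p6 not a number x"), f)
  expect_error(read_pts(f), "line 6")
})

test_that("pts directories load as a landmark set with expected counts", {
  lms <- simulate_landmarks(3, seed = 20)
  dir <- withr::local_tempdir()
  for (i in 1:3) write_pts(lms[, , i], file.path(dir, sprintf("s%d.pts", i)))
  back <- read_pts_dir(dir)
  expect_equal(dim(back), dim(lms))
  expect_equal(unclass(back)[, , 1], unclass(lms)[, , 1],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(read_pts_dir(dir, n_expected = 99), "expected 99")
})

test_that("scheme JSON round-trips", {
  sch <- default_scheme(3, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, f)
  back <- read_scheme(f)
  expect_equal(back$curves, sch$curves)
})
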
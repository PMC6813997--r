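# Brownian-motion and multi-peak Ornstein-Uhlenbeck (Hansen) model
# likelihoods on a regime-painted ultrametric tree. Traits are modelled
# independently (one alpha, sigma^2 and per-regime theta each); a model's
# AICc is the sum over traits. These likelihoods are the objective of the
# stepwise regime search in surface_forward()/surface_backward().

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`; undefined when
#' `n <= k + 1`.
#'
#' @param logL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @return Numeric scalar.
#' @export
aicc <- function(logL, k, n) {
  if (k > 0 && n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logL + 2 * k + if (k > 0) 2 * k * (k + 1) / (n - k - 1) else 0
}

#' Phylogenetic half-life of an OU process
#'
#' Time to evolve halfway toward a new optimum: `t_1/2 = ln(2) / alpha`.
#'
#' @param alpha Rate of adaptation (1/time units), positive.
#' @return Half-life in the tree's time units.
#' @examples
#' ou_half_life(3.055) # 0.227
#' @export
ou_half_life <- function(alpha) {
  stopifnot(all(alpha > 0))
  log(2) / alpha
}

#' Fit Brownian motion by maximum likelihood
#'
#' GLS root state `a = (1'C^-1 1)^-1 1'C^-1 y`, ML rate
#' `sigma2 = (y - a)' C^-1 (y - a) / N`, and the Gaussian log-likelihood of
#' `y ~ N(a 1, sigma2 C)`. With several traits each is fitted independently
#' and the model AICc is the sum of the per-trait AICc values (k = 2 per
#' trait: root and rate).
#'
#' @param traits Tip-labelled vector/matrix or data frame with a label
#'   column.
#' @param tree A `phylo` object (ultrametricity not required for BM).
#' @return A `bm_fit`: list with per-trait tibble `params` (`trait`, `root`,
#'   `sigma2`, `logLik`, `AICc`), `AICc` (model total), `logLik`, `n`.
#' @export
bm_fit <- function(traits, tree) {
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  N <- nrow(Y)
  C <- phylo_cov(tree)
  R <- .safe_chol(C, "phylogenetic covariance")
  ldet <- 2 * sum(log(diag(R)))
  one <- rep(1, N)
  Cinv_one <- .chol_solve(R, one)
  fit_one <- function(y) {
    a <- sum(Cinv_one * y) / sum(Cinv_one)
    r <- y - a
    s2 <- sum(r * .chol_solve(R, r)) / N
    if (s2 <= .Machine$double.eps * max(1, sum(y^2))) {
      stop("degenerate trait (zero Brownian rate): likelihood unbounded")
    }
    ll <- -0.5 * (N * log(2 * pi) + N * log(s2) + ldet + N)
    c(root = a, sigma2 = s2, logLik = ll,
      AICc = if (N > 3) aicc(ll, 2, N) else NA_real_)
  }
  per <- t(apply(Y, 2, fit_one))
  params <- dplyr::bind_cols(tibble(trait = colnames(Y)), as_tibble(per))
  structure(list(params = params, AICc = sum(per[, "AICc"]),
                 logLik = sum(per[, "logLik"]), n = N, k_per_trait = 2),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("Brownian-motion fit: %d tips, %d trait(s), AICc = %.3f\n",
              x$n, nrow(x$params), x$AICc))
  print(x$params)
  invisible(x)
}

#' @export
#' @method tidy bm_fit
tidy.bm_fit <- function(x, ...) x$params

#' @export
#' @method glance bm_fit
glance.bm_fit <- function(x, ...) {
  tibble(model = "BM", AICc = x$AICc, logLik = x$logLik, n = x$n)
}

# ---- Hansen (multi-peak OU) likelihood -------------------------------------

# Precomputed per-tree quantities reused across every likelihood evaluation
# of a regime search: tree depth, shared-path and patristic matrices, and the
# flattened per-tip lineage segments (tip, edge, start/end times).
.hansen_cache <- function(tree) {
  tree <- validate_tree(tree, require_ultrametric = TRUE)
  segs <- .tip_segments(tree)
  list(tree = tree, N = length(tree$tip.label), T = tree_depth(tree),
       S = phylo_cov(tree), D = patristic(tree), segs = segs,
       stem = .root_stem(tree), alpha_max = 1e3 / tree_depth(tree))
}

# OU design matrix W (tips x regimes): for lineage i and regime r, the sum
# over the lineage's segments painted r of exp(-a(T-t1)) - exp(-a(T-t0)),
# plus the residual weight exp(-aT) assigned to the root-regime column, so
# every row sums to 1.
.ou_weights <- function(cache, edge_regimes, root_regime, alpha, regimes) {
  segs <- cache$segs
  Tt <- cache$T
  w <- exp(-alpha * (Tt - segs$t1)) - exp(-alpha * (Tt - segs$t0))
  ri <- match(edge_regimes[segs$edge], regimes)
  W <- matrix(0, cache$N, length(regimes))
  cell <- (ri - 1L) * cache$N + segs$tip     # linear index into W
  acc <- rowsum(w, cell)
  W[as.integer(rownames(acc))] <- acc
  rr <- match(root_regime, regimes)
  # residual weight before the first painted segment (incl. any root stem
  # retained by pruning) belongs to the root regime
  W[, rr] <- W[, rr] + exp(-alpha * (Tt - cache$stem))
  colnames(W) <- regimes
  W
}

# Stationary-scaled OU covariance V0 = exp(-a d)(1 - exp(-2 a s)) / (2a);
# tip covariance is sigma2 * V0.
.ou_cov0 <- function(cache, alpha) {
  exp(-alpha * cache$D) * (1 - exp(-2 * alpha * cache$S)) / (2 * alpha)
}

#' Profiled log-likelihood of a Hansen model at fixed alpha
#'
#' For one trait on an ultrametric regime-painted tree, evaluates the
#' multi-peak OU model with adaptation rate `alpha`: regime optima `theta`
#' are estimated by GLS against the OU design weights, the diffusion
#' `sigma2` is profiled in closed form, and the Gaussian log-likelihood is
#' returned. The expectation is anchored at the root-regime optimum (the
#' residual root weight `exp(-alpha T)` is assigned to the root regime).
#'
#' @param trait Tip-labelled numeric vector (single trait).
#' @param tree Ultrametric `phylo`.
#' @param painting A `regime_painting` on `tree`.
#' @param alpha Positive adaptation rate, within `[1e-8, 1e3/T]`.
#' @param cache Optional precomputed [.hansen_cache()]-style cache (internal
#'   use by the regime search).
#' @return List with `logLik`, `sigma2`, `theta` (named by regime), `alpha`.
#' @export
hansen_loglik <- function(trait, tree, painting, alpha, cache = NULL) {
  if (is.null(cache)) cache <- .hansen_cache(tree)
  y <- as_trait_matrix(trait, cache$tree)
  if (ncol(y) != 1) stop("hansen_loglik takes a single trait; see hansen_fit()")
  .hansen_ll_core(drop(y), cache, painting, alpha)
}

.hansen_ll_core <- function(y, cache, painting, alpha,
                            regimes = .regime_levels(painting)) {
  if (alpha <= 0) stop("alpha must be positive")
  W <- .ou_weights(cache, painting$edge_regimes, painting$root_regime, alpha, regimes)
  tot <- colSums(abs(W))
  if (any(tot < 1e-12)) {
    stop("regime with zero total weight (rank-deficient design): ",
         paste(regimes[tot < 1e-12], collapse = ", "))
  }
  V0 <- .ou_cov0(cache, alpha)
  R <- .safe_chol(V0, "OU covariance")
  ldet <- 2 * sum(log(diag(R)))
  Vi_W <- .chol_solve(R, W)
  A <- crossprod(W, Vi_W)
  b <- crossprod(Vi_W, y)
  theta <- tryCatch(drop(solve(A, b)), error = function(e) {
    stop("rank-deficient OU design: regimes are not separable")
  })
  r <- y - drop(W %*% theta)
  N <- cache$N
  s2 <- sum(r * .chol_solve(R, r)) / N
  if (s2 <= 0) stop("degenerate trait under OU model (zero residual variance)")
  ll <- -0.5 * (N * log(2 * pi) + N * log(s2) + ldet + N)
  list(logLik = ll, sigma2 = s2, theta = setNames(theta, regimes), alpha = alpha)
}

# deterministic regime ordering: root regime first, then sorted
.regime_levels <- function(painting) {
  others <- setdiff(unique(painting$edge_regimes), painting$root_regime)
  c(painting$root_regime, sort(others))
}

# maximise the profiled likelihood over log(alpha): coarse grid then local
# refinement with optimize(); returns the hansen_loglik() result at the
# optimum.
.hansen_optimise <- function(y_name, y, cache, painting, grid_size = 8,
                             tol = 1e-4, alpha_min = 1e-8) {
  regimes <- .regime_levels(painting)
  lo <- log(alpha_min); hi <- log(cache$alpha_max)
  grid <- exp(seq(lo, hi, length.out = grid_size))
  f <- function(a) {
    out <- tryCatch(.hansen_ll_core(y, cache, painting, a, regimes),
                    error = function(e) NULL)
    if (is.null(out)) -Inf else out$logLik
  }
  ll <- vapply(grid, f, numeric(1))
  if (all(!is.finite(ll))) stop("OU optimiser failure for trait ", y_name)
  # the profiled likelihood can be multimodal in alpha: refine around every
  # local maximum of the restart grid, not just the single best point
  is_peak <- vapply(seq_len(grid_size), function(i) {
    is.finite(ll[i]) &&
      (i == 1 || !is.finite(ll[i - 1]) || ll[i] >= ll[i - 1]) &&
      (i == grid_size || !is.finite(ll[i + 1]) || ll[i] >= ll[i + 1])
  }, logical(1))
  best_a <- grid[which.max(ll)]
  best_ll <- max(ll, na.rm = TRUE)
  for (i in which(is_peak)) {
    lo_b <- log(grid[max(1, i - 1)]); hi_b <- log(grid[min(grid_size, i + 1)])
    opt <- optimize(function(la) f(exp(la)), interval = c(lo_b, hi_b),
                    maximum = TRUE, tol = tol)
    if (opt$objective > best_ll) {
      best_ll <- opt$objective
      best_a <- exp(opt$maximum)
    }
  }
  .hansen_ll_core(y, cache, painting, best_a, regimes)
}

#' Fit a multi-peak Hansen OU model
#'
#' Fits each trait independently: the adaptation rate `alpha` is optimised on
#' the log scale by a bounded search over `[1e-8, 1e3/T]` (coarse grid plus
#' local refinement), with `theta` and `sigma2` profiled at each step. The
#' per-trait parameter count is `k = 2 + R` (alpha, sigma2 and one optimum
#' per regime); the model AICc is the sum of per-trait AICc values. With a
#' single-regime painting this is exactly the one-peak OU (OU1) model.
#'
#' @param traits Tip-labelled matrix or data frame (1-4 traits is typical;
#'   high-dimensional data violate the per-trait independence assumption).
#' @param tree Ultrametric `phylo`.
#' @param painting A `regime_painting`; defaults to the single-regime
#'   painting (OU1).
#' @param grid_size Number of log-spaced alpha restarts.
#' @param alpha_min Lower bound of the alpha search (default `1e-8`; the
#'   regime search narrows this, see [surface_forward()]).
#' @param tol Refinement tolerance on log(alpha).
#' @param cache Internal: precomputed tree cache.
#' @return A `hansen_fit`: `params` tibble (`trait`, `alpha`, `sigma2`,
#'   `half_life`, `logLik`, `AICc`), `theta` matrix (regime x trait),
#'   `AICc` (model total), `n`, `n_regimes`, `painting`.
#' @examples
#' tr <- simulate_tree(16, depth = 10, seed = 1)
#' p <- regime_painting(tr)         # single regime
#' y <- simulate_bm(tr, rate = diag(1), seed = 2)
#' hansen_fit(y, tr, p)             # OU1 fit
#' @export
hansen_fit <- function(traits, tree, painting = NULL, grid_size = 8,
                       tol = 1e-4, alpha_min = 1e-8, cache = NULL) {
  if (is.null(cache)) cache <- .hansen_cache(tree)
  Y <- as_trait_matrix(traits, cache$tree)
  if (is.null(painting)) painting <- regime_painting(cache$tree)
  regimes <- .regime_levels(painting)
  k <- 2 + length(regimes)
  N <- cache$N
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    .hansen_optimise(colnames(Y)[j], Y[, j], cache, painting, grid_size, tol,
                     alpha_min)
  })
  params <- tibble(
    trait = colnames(Y),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
    half_life = ou_half_life(vapply(fits, `[[`, numeric(1), "alpha")),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits, function(f) {
      if (N > k + 1) aicc(f$logLik, k, N) else NA_real_
    }, numeric(1))
  )
  theta <- vapply(fits, `[[`, numeric(length(regimes)), "theta")
  theta <- matrix(theta, nrow = length(regimes),
                  dimnames = list(regimes, colnames(Y)))
  structure(list(params = params, theta = theta, AICc = sum(params$AICc),
                 logLik = sum(params$logLik), n = N,
                 n_regimes = length(regimes), k_per_trait = k,
                 painting = painting),
            class = "hansen_fit")
}

#' @export
print.hansen_fit <- function(x, ...) {
  cat(sprintf("Hansen OU fit: %d tips, %d trait(s), %d regime(s), AICc = %.3f\n",
              x$n, nrow(x$params), x$n_regimes, x$AICc))
  print(x$params)
  invisible(x)
}

#' @export
#' @method tidy hansen_fit
tidy.hansen_fit <- function(x, ...) {
  th <- as_tibble(x$theta, rownames = "regime") |>
    tidyr::pivot_longer(-"regime", names_to = "trait", values_to = "theta")
  dplyr::left_join(th, x$params, by = "trait") |>
    dplyr::select("trait", "regime", "theta", "alpha", "sigma2",
                  "half_life", "logLik", "AICc")
}

#' @export
#' @method glance hansen_fit
glance.hansen_fit <- function(x, ...) {
  tibble(model = if (x$n_regimes == 1) "OU1" else "multipeak OU",
         AICc = x$AICc, logLik = x$logLik, n = x$n,
         n_regimes = x$n_regimes)
}
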
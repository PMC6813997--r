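# Multivariate phylogenetic signal: the K_mult statistic, the multivariate
# generalisation of Blomberg's K built on the equivalence of covariance- and
# distance-based formulations for Euclidean data. Expectation 1 under
# Brownian motion; significance by permuting trait rows across tips.

# statistic only; Y already tip-ordered against C
.kmult_stat <- function(Y, Cinv_chol, trC, one_Cinv_one, w_phylo, N) {
  a <- drop(crossprod(w_phylo, Y))           # GLS phylogenetic mean (1 x p)
  Yc <- sweep(Y, 2, a)
  ss_euclid <- sum(Yc^2)
  if (ss_euclid == 0) return(0)
  q <- sum(Yc * .chol_solve(Cinv_chol, Yc))  # tr((Y-a)' C^-1 (Y-a))
  num <- ss_euclid / q
  denom <- (trC - N / one_Cinv_one) / (N - 1)
  num / denom
}

#' Multivariate phylogenetic signal (K_mult) with permutation test
#'
#' Computes `K_mult` for a tip-by-trait matrix on a phylogeny. With `C` the
#' phylogenetic covariance ([phylo_cov()]) and
#' `a = (1'C^-1 1)^-1 1'C^-1 Y` the phylogenetic mean,
#' \deqn{K = \frac{\sum_i \|y_i - a\|^2 / \mathrm{tr}((Y-a)' C^{-1} (Y-a))}
#'   {(\mathrm{tr}(C) - N/(1'C^{-1}1)) / (N-1)}.}
#' `K = 1` is the Brownian-motion expectation (and holds exactly on a star
#' tree); `K < 1` means less similarity among relatives than BM predicts.
#' Significance is assessed by permuting the assignment of trait rows to tips;
#' the observed statistic is included in the null set, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param traits Tip-by-trait matrix (rownames = tip labels) or data frame
#'   with a label column; typically all non-degenerate PC scores.
#' @param tree A `phylo` object.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility when `n_perm > 0`).
#' @return A `kmult_result`: list with `kmult`, `p_value`, `n_perm`, `seed`,
#'   and the permutation distribution `null`.
#' @examples
#' tr <- simulate_tree(16, depth = 10, seed = 1)
#' y <- simulate_bm(tr, rate = diag(2), seed = 2)
#' kmult(y, tr, n_perm = 99, seed = 3)
#' @export
kmult <- function(traits, tree, n_perm = 999, seed = NULL) {
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  N <- nrow(Y)
  C <- phylo_cov(tree)
  R <- .safe_chol(C, "phylogenetic covariance")
  one <- rep(1, N)
  Cinv_one <- .chol_solve(R, one)
  one_Cinv_one <- sum(Cinv_one)
  w <- Cinv_one / one_Cinv_one
  trC <- sum(diag(C))
  obs <- .kmult_stat(Y, R, trC, one_Cinv_one, w, N)
  null <- numeric(0)
  p <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 99) stop("use at least 99 permutations")
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      .kmult_stat(Y[sample.int(N), , drop = FALSE], R, trC, one_Cinv_one, w, N)
    }, numeric(1))
    p <- (sum(null >= obs) + 1) / (n_perm + 1)
  }
  structure(list(kmult = obs, p_value = p, n_perm = n_perm,
                 seed = seed, null = null),
            class = "kmult_result")
}

#' @export
print.kmult_result <- function(x, ...) {
  cat(sprintf("K_mult = %.4f", x$kmult))
  if (!is.na(x$p_value)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' @export
#' @method tidy kmult_result
tidy.kmult_result <- function(x, ...) {
  tibble(kmult = x$kmult, p_value = x$p_value, n_perm = x$n_perm)
}

#' @export
#' @method glance kmult_result
glance.kmult_result <- function(x, ...) tidy(x)
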
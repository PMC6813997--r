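# Wheatsheaf index of convergence strength: the ratio of the mean
# phylogeny-corrected phenotypic distance over all species pairs to that over
# focal (putatively convergent) pairs. w > 1 means the focal species sit
# tighter in phenotype space than the phylogeny-wide average even after close
# relatives' distances are inflated to discount relatedness-driven
# similarity.

# core on precomputed pieces; returns Inf (the documented guard) when the
# focal pairs have zero mean distance
.wheatsheaf_core <- function(Y, s_over_T, focal_idx, standardise, correct) {
  if (standardise) {
    sds <- apply(Y, 2, sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning("dropping constant trait column(s): ",
              paste(colnames(Y)[!keep], collapse = ", "))
      Y <- Y[, keep, drop = FALSE]
    }
    Y <- scale(Y)
  }
  d <- as.matrix(dist(Y))
  if (correct) d <- d * (1 + s_over_T)
  n <- nrow(d)
  all_mean <- mean(d[upper.tri(d)])
  f <- d[focal_idx, focal_idx, drop = FALSE]
  fv <- f[upper.tri(f)]
  if (length(fv) == 0) return(Inf)
  fm <- mean(fv)
  if (fm == 0) {
    warning("focal species are phenotypically identical: index is infinite")
    return(Inf)
  }
  all_mean / fm
}

#' Wheatsheaf index of convergence strength
#'
#' Traits are standardised per column (zero mean, unit variance across tips;
#' constant columns are dropped with a warning), pairwise Euclidean distances
#' are computed, and each distance is phylogenetically corrected by the
#' multiplicative kernel `d'_ij = d_ij (1 + s_ij / T)` with `s_ij` the shared
#' root-to-MRCA path length and `T` the tree depth — close relatives'
#' distances are inflated (kernel in `[1, 2]`) so that similarity due to
#' relatedness is not mistaken for convergence. The index is
#' `w = mean(d' over all pairs) / mean(d' over focal pairs)`.
#'
#' @param traits Tip-labelled matrix or data frame (typically the leading
#'   shape PCs).
#' @param tree A `phylo` object.
#' @param focal Character vector of focal tip labels (>= 2).
#' @param standardise Standardise trait columns first (recommended: PCs have
#'   wildly different variances).
#' @param correct Apply the phylogenetic correction kernel; with `FALSE` the
#'   index is a plain standardised-distance ratio.
#' @return Numeric scalar (`Inf` when the focal pairs coincide in phenotype).
#' @export
wheatsheaf_index <- function(traits, tree, focal, standardise = TRUE,
                             correct = TRUE) {
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  idx <- match(focal, tree$tip.label)
  if (anyNA(idx)) stop("focal tips not in tree: ",
                       paste(focal[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("at least two focal tips are required")
  S <- phylo_cov(tree)
  .wheatsheaf_core(Y, S / attr(S, "depth"), idx, standardise, correct)
}

#' Jackknife confidence interval for the Wheatsheaf index
#'
#' Leave-one-tip-out recomputation of the index over all tips; the 95%
#' interval is the 2.5/97.5 percentile range of the replicate distribution.
#' Deleting a focal tip from a two-taxon focal group leaves no focal pair, so
#' those replicates are infinite and propagate to an infinite upper bound.
#'
#' @inheritParams wheatsheaf_index
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper` and the `replicates` vector.
#' @export
wheatsheaf_ci <- function(traits, tree, focal, standardise = TRUE,
                          correct = TRUE, level = 0.95) {
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  idx <- match(focal, tree$tip.label)
  S <- phylo_cov(tree)
  sT <- S / attr(S, "depth")
  n <- nrow(Y)
  reps <- vapply(seq_len(n), function(drop_i) {
    keep <- setdiff(seq_len(n), drop_i)
    f2 <- match(setdiff(idx, drop_i), keep)
    if (length(f2) < 2) return(Inf)
    .wheatsheaf_core(Y[keep, , drop = FALSE], sT[keep, keep], f2,
                     standardise, correct)
  }, numeric(1))
  a <- (1 - level) / 2
  q <- suppressWarnings(quantile(reps, c(a, 1 - a), names = FALSE, type = 7))
  list(lower = q[1], upper = q[2], replicates = reps)
}

#' Bootstrap p-value for the Wheatsheaf index
#'
#' Each bootstrap resamples the trait rows with replacement and reassigns
#' them to the tips of the phylogeny, then recomputes the index; the p-value
#' is the proportion of bootstrap indices greater than or equal to the
#' observed one (raw proportion, which can be 0; the protected
#' `(s + 1)/(n + 1)` value is also returned).
#'
#' @inheritParams wheatsheaf_index
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `p_value`, `p_protected`, `observed`, `boot` (the
#'   bootstrap distribution).
#' @export
wheatsheaf_pvalue <- function(traits, tree, focal, n_boot = 1000, seed = NULL,
                              standardise = TRUE, correct = TRUE) {
  if (n_boot < 100) stop("use at least 100 bootstrap replicates")
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  idx <- match(focal, tree$tip.label)
  S <- phylo_cov(tree)
  sT <- S / attr(S, "depth")
  obs <- .wheatsheaf_core(Y, sT, idx, standardise, correct)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)
  boot <- vapply(seq_len(n_boot), function(b) {
    Yb <- Y[sample.int(n, n, replace = TRUE), , drop = FALSE]
    suppressWarnings(.wheatsheaf_core(Yb, sT, idx, standardise, correct))
  }, numeric(1))
  s <- sum(boot >= obs)
  list(p_value = s / n_boot, p_protected = (s + 1) / (n_boot + 1),
       observed = obs, boot = boot)
}

#' Wheatsheaf analysis: index, jackknife CI and bootstrap p-value
#'
#' @inheritParams wheatsheaf_pvalue
#' @return A `wheatsheaf_result`: `w`, `ci_lower`, `ci_upper` (may be `Inf`),
#'   `p_value`, `p_protected`, `n_boot`, `seed`, plus the jackknife
#'   `replicates` and bootstrap distribution `boot`.
#' @examples
#' tr <- simulate_tree(12, depth = 10, seed = 1)
#' y <- simulate_bm(tr, rate = diag(3), seed = 2)
#' wheatsheaf(y, tr, focal = tr$tip.label[1:3], n_boot = 100, seed = 3)
#' @export
wheatsheaf <- function(traits, tree, focal, n_boot = 1000, seed = NULL,
                       standardise = TRUE, correct = TRUE) {
  w <- wheatsheaf_index(traits, tree, focal, standardise, correct)
  ci <- wheatsheaf_ci(traits, tree, focal, standardise, correct)
  pv <- wheatsheaf_pvalue(traits, tree, focal, n_boot, seed, standardise, correct)
  structure(
    list(w = w, ci_lower = ci$lower, ci_upper = ci$upper,
         p_value = pv$p_value, p_protected = pv$p_protected,
         n_boot = n_boot, seed = seed, focal = focal,
         replicates = ci$replicates, boot = pv$boot),
    class = "wheatsheaf_result"
  )
}

#' @export
print.wheatsheaf_result <- function(x, ...) {
  cat(sprintf("Wheatsheaf index w = %.4g, 95%% CI %.4g - %s, p = %.4g (%d bootstraps)\n",
              x$w, x$ci_lower,
              if (is.infinite(x$ci_upper)) "Inf" else sprintf("%.4g", x$ci_upper),
              x$p_value, x$n_boot))
  invisible(x)
}

#' @export
#' @method tidy wheatsheaf_result
tidy.wheatsheaf_result <- function(x, ...) {
  tibble(w = x$w, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         p_value = x$p_value, p_protected = x$p_protected,
         n_boot = x$n_boot)
}

#' @export
#' @method glance wheatsheaf_result
glance.wheatsheaf_result <- function(x, ...) tidy(x)
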
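# Distance-based convergence measures (Stayton's C1-C4) for a focal tip set,
# with significance from Brownian-motion simulation nulls. C1 is the
# proportion of the maximum ancestral phenotypic distance between two focal
# lineages that subsequent evolution has closed; C2 is the unscaled
# difference; C3 and C4 scale C2 by the total phenotypic evolution in the
# focal clade and the whole tree respectively.

#' Ancestral state estimation under Brownian motion
#'
#' GLS/ML reconstruction of every internal node for every trait: with the
#' joint BM covariance over tips and internal nodes, the reconstruction is
#' the conditional expectation of the internal nodes given the tips, with the
#' root anchored at the GLS phylogenetic mean. Deterministic; tip states are
#' the observed values.
#'
#' @param traits Tip-labelled matrix or data frame with a label column.
#' @param tree A `phylo` object.
#' @return An `ancestral_states` object: matrix of `(n_tips + n_nodes) x m`
#'   states, rows named by tip label then internal node number; attribute
#'   `"tree"`.
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' asr_bm(c(A = 0, B = 2), tr)   # root = 1
#' @export
asr_bm <- function(traits, tree) {
  tree <- validate_tree(tree)
  Y <- as_trait_matrix(traits, tree)
  w <- .asr_weights(tree)
  .asr_apply(Y, w)
}

# Precompute the linear map from tip values to ancestral states: internal
# states = a + A (Y - a), root mean a = w' Y.
.asr_weights <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree) + .root_stem(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(depth[M], nn, nn)   # root depth is the stem, so root-coalescing
                                  # pairs share exactly the stem
  Ctt <- S[seq_len(n), seq_len(n), drop = FALSE]
  Cat <- S[(n + 1):nn, seq_len(n), drop = FALSE]
  R <- .safe_chol(Ctt, "phylogenetic covariance")
  Cinv_one <- .chol_solve(R, rep(1, n))
  w <- Cinv_one / sum(Cinv_one)
  A <- t(.chol_solve(R, t(Cat)))
  list(tree = tree, n = n, nn = nn, w = w, A = A, chol_Ctt = R)
}

.asr_apply <- function(Y, wts) {
  a <- drop(crossprod(wts$w, Y))
  Yc <- sweep(Y, 2, a)
  anc <- sweep(wts$A %*% Yc, 2, a, `+`)
  states <- rbind(Y, anc)
  rownames(states) <- c(wts$tree$tip.label,
                        as.character((wts$n + 1):wts$nn))
  structure(states, class = "ancestral_states", tree = wts$tree)
}

# node numbers on the path from `from` (a node) down... up from tip to mrca,
# inclusive of both.
.path_to_ancestor <- function(tree, tip, anc) {
  pe <- .parent_edge(tree)
  node <- tip
  out <- node
  while (node != anc) {
    node <- tree$edge[pe[node], 1]
    out <- c(out, node)
  }
  out
}

# Cache for repeated C-metric evaluation on the same tree/focal set (the
# simulation null recomputes everything per replicate).
.cmetrics_cache <- function(tree, focal) {
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  idx <- match(focal, tree$tip.label)
  if (anyNA(idx)) {
    stop("focal tips not in tree: ", paste(focal[is.na(idx)], collapse = ", "))
  }
  if (length(idx) < 2) stop("at least two focal tips are required")
  wts <- .asr_weights(tree)
  pairs <- utils::combn(idx, 2)
  pair_info <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    m <- ape::getMRCA(tree, c(i1, i2))
    p1 <- .path_to_ancestor(tree, i1, m)
    p2 <- .path_to_ancestor(tree, i2, m)
    # candidate ancestral pairs: all crossings of the two paths except the
    # contemporary tip-vs-tip pair (its exclusion is what lets C1 go negative
    # when lineages have diverged beyond any ancestral separation)
    cand <- expand.grid(u = p1, v = p2)
    cand <- cand[!(cand$u == i1 & cand$v == i2), ]
    # branches of the clade rooted at the MRCA: child edges of m and all
    # their descendants (the MRCA's own subtending branch is outside)
    kid_edges <- which(tree$edge[, 1] == m)
    clade_edges <- sort(unique(unlist(
      lapply(kid_edges, function(e) .descendant_edges(tree, e))
    )))
    list(i = i1, j = i2, mrca = m, u = cand$u, v = cand$v,
         clade_edges = clade_edges)
  })
  list(tree = tree, n = n, focal_idx = idx, wts = wts, pair_info = pair_info,
       edge_parent = tree$edge[, 1], edge_child = tree$edge[, 2])
}

# per-pair metrics on a plain (tips x m) matrix in tree tip order; rows of
# the reconstructed state matrix are indexed directly by node number
.cmetrics_per_pair <- function(Y, cache) {
  rn <- unclass(.asr_apply(Y, cache$wts))
  edge_diff <- rn[cache$edge_child, , drop = FALSE] - rn[cache$edge_parent, , drop = FALSE]
  edge_len_phen <- sqrt(rowSums(edge_diff^2))
  L_tree <- sum(edge_len_phen)
  vapply(cache$pair_info, function(pi_) {
    dtip <- sqrt(sum((rn[pi_$i, ] - rn[pi_$j, ])^2))
    du <- rn[pi_$u, , drop = FALSE] - rn[pi_$v, , drop = FALSE]
    dmax <- sqrt(max(rowSums(du^2)))
    if (dmax <= 0) stop("Dmax = 0: C1 undefined for this focal pair")
    L_clade <- sum(edge_len_phen[pi_$clade_edges])
    c2 <- dmax - dtip
    c(C1 = 1 - dtip / dmax, C2 = c2, C3 = c2 / L_clade, C4 = c2 / L_tree,
      Dtip = dtip, Dmax = dmax, L_clade = L_clade, L_tree = L_tree)
  }, numeric(8))
}

.cmetrics_compute <- function(Y, cache) rowMeans(.cmetrics_per_pair(Y, cache))

#' Stayton's C1-C4 convergence metrics
#'
#' For every unordered pair of focal tips: `Dtip` is the present-day
#' phenotypic distance; `Dmax` is the maximum distance between reconstructed
#' states ([asr_bm()]) along the two lineages back to their MRCA, excluding
#' the contemporary tip-tip pair. Then `C1 = 1 - Dtip/Dmax` (negative when
#' lineages have diverged beyond any ancestral separation),
#' `C2 = Dmax - Dtip`, `C3 = C2 / L_clade` and `C4 = C2 / L_tree`, where the
#' `L` terms sum the phenotypic lengths of all branches of the MRCA's clade
#' and of the whole tree. Metrics are averaged over focal pairs.
#'
#' @param traits Tip-labelled matrix (typically the leading shape PCs — the
#'   components jointly carrying ~95% of the variance).
#' @param tree A `phylo` object.
#' @param focal Character vector of focal tip labels (>= 2), e.g. the tips of
#'   one convergent regime.
#' @return A `cmetrics_result` with `metrics` (one-row tibble `C1..C4`),
#'   `internals` (per-pair Dtip/Dmax/L terms), and empty significance slots.
#' @export
c_metrics <- function(traits, tree, focal) {
  cache <- .cmetrics_cache(tree, focal)
  Y <- as_trait_matrix(traits, cache$tree)
  per_pair <- t(.cmetrics_per_pair(Y, cache))
  vals <- colMeans(per_pair)
  labels <- vapply(cache$pair_info, function(pi_) {
    paste(cache$tree$tip.label[c(pi_$i, pi_$j)], collapse = " vs ")
  }, character(1))
  structure(
    list(
      metrics = as_tibble(as.list(vals[c("C1", "C2", "C3", "C4")])),
      internals = dplyr::bind_cols(tibble(pair = labels),
                                   as_tibble(per_pair)),
      focal = focal, n_sim = 0L, seed = NULL,
      p_values = NULL, null = NULL
    ),
    class = "cmetrics_result"
  )
}

#' C-metrics with Brownian-motion simulation significance
#'
#' The evolutionary rate matrix is estimated from the observed data by GLS
#' (`R_hat = (Y - a)' C^-1 (Y - a) / N`), `n_sim` multivariate BM datasets
#' are simulated on the tree with that rate, and the metrics are recomputed
#' for the same focal set on each. The p-value per metric is the raw
#' proportion of simulated values greater than or equal to the observed one
#' (reproducing the printed convention, which can reach 0); the protected
#' estimate `(s + 1) / (n_sim + 1)` is reported alongside.
#'
#' @inheritParams c_metrics
#' @param n_sim Number of BM simulations (>= 100; 1000 typical).
#' @param seed Integer seed.
#' @return A `cmetrics_result` with `p_values` and `p_protected` (tibbles)
#'   and the simulated null distributions in `null`.
#' @export
c_metrics_significance <- function(traits, tree, focal, n_sim = 1000,
                                   seed = NULL) {
  if (n_sim < 100) stop("use at least 100 simulations")
  cache <- .cmetrics_cache(tree, focal)
  Y <- as_trait_matrix(traits, cache$tree)
  out <- c_metrics(Y, cache$tree, focal)
  N <- nrow(Y)
  # GLS evolutionary rate matrix from the observed data
  a <- drop(crossprod(cache$wts$w, Y))
  Yc <- sweep(Y, 2, a)
  Rhat <- crossprod(Yc, .chol_solve(cache$wts$chol_Ctt, Yc)) / N
  Rhat <- (Rhat + t(Rhat)) / 2
  er <- eigen(Rhat, symmetric = TRUE)
  if (min(er$values) < -1e-8 * max(abs(er$values))) {
    stop("estimated rate matrix is not positive semidefinite")
  }
  sqR <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  Lc <- t(cache$wts$chol_Ctt)                 # C = Lc Lc'
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(Y)
  sims <- matrix(NA_real_, n_sim, 4, dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
  for (b in seq_len(n_sim)) {
    Z <- matrix(rnorm(N * m), N, m)
    Ysim <- Lc %*% Z %*% sqR
    sims[b, ] <- .cmetrics_compute(Ysim, cache)[c("C1", "C2", "C3", "C4")]
  }
  obs <- unlist(out$metrics)
  s <- colSums(sweep(sims, 2, obs, `>=`))
  out$n_sim <- n_sim
  out$seed <- seed
  out$null <- as_tibble(sims)
  out$p_values <- as_tibble(as.list(s / n_sim))
  out$p_protected <- as_tibble(as.list((s + 1) / (n_sim + 1)))
  out
}

#' @export
print.cmetrics_result <- function(x, ...) {
  cat("Convergence metrics for focal set {",
      paste(x$focal, collapse = ", "), "}\n")
  print(x$metrics)
  if (!is.null(x$p_values)) {
    cat(sprintf("p-values (%d BM simulations):\n", x$n_sim))
    print(x$p_values)
  }
  invisible(x)
}

#' @export
#' @method tidy cmetrics_result
tidy.cmetrics_result <- function(x, ...) {
  d <- tidyr::pivot_longer(x$metrics, dplyr::everything(),
                           names_to = "metric", values_to = "value")
  if (!is.null(x$p_values)) {
    p <- tidyr::pivot_longer(x$p_values, dplyr::everything(),
                             names_to = "metric", values_to = "p_value")
    pp <- tidyr::pivot_longer(x$p_protected, dplyr::everything(),
                              names_to = "metric", values_to = "p_protected")
    d <- dplyr::left_join(d, p, by = "metric") |>
      dplyr::left_join(pp, by = "metric")
  }
  d
}

#' @export
#' @method glance cmetrics_result
glance.cmetrics_result <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble(n_pairs = nrow(x$internals), n_sim = x$n_sim))
}

#' Observed metrics against their simulated null
#'
#' @param object A `cmetrics_result` carrying a simulation null.
#' @param ... Unused.
#' @return A ggplot: null histograms with the observed value marked.
#' @export
#' @method autoplot cmetrics_result
autoplot.cmetrics_result <- function(object, ...) {
  if (is.null(object$null)) stop("no simulation null stored; run c_metrics_significance()")
  d <- tidyr::pivot_longer(object$null, dplyr::everything(),
                           names_to = "metric", values_to = "value")
  obs <- tidyr::pivot_longer(object$metrics, dplyr::everything(),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}
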
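# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (explicit matrix construction, dmvnorm-style density
# evaluation) so they stay independent of the package's computational paths.

tree4 <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
cherry <- function() read_newick("(A:1,B:1);")

# log-density of a multivariate normal, written out longhand
mvn_logdens <- function(y, mu, V) {
  k <- length(y)
  ev <- eigen(V, symmetric = TRUE)
  stopifnot(all(ev$values > 0))
  ld <- sum(log(ev$values))
  z <- t(ev$vectors) %*% (y - mu)
  -0.5 * (k * log(2 * pi) + ld + sum(z^2 / ev$values))
}

# brute-force phylogenetic covariance by enumerating all tip pairs' MRCA
# depths through the node path to the root
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  anc_path <- function(tip) {
    pe <- integer(0)
    node <- tip
    repeat {
      pe <- c(pe, node)
      row <- which(tree$edge[, 2] == node)
      if (length(row) == 0) break
      node <- tree$edge[row, 1]
    }
    pe
  }
  paths <- lapply(seq_len(n), anc_path)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- max(depth[shared][depth[shared] <= min(depth[i], depth[j])])
      if (i == j) C[i, j] <- depth[i]
    }
  }
  C
}

# label of the found shift matching a true shift edge: exact edge first, then
# immediate neighbours (parent, siblings, children)
recovered_label <- function(tree, found_shifts, true_edge) {
  if (true_edge %in% found_shifts) {
    return(names(found_shifts)[match(true_edge, found_shifts)])
  }
  pe <- convergr:::.parent_edge(tree)
  nb <- unique(c(pe[tree$edge[true_edge, 1]],
                 which(tree$edge[, 1] == tree$edge[true_edge, 1]),
                 which(tree$edge[, 1] == tree$edge[true_edge, 2])))
  hit <- found_shifts[found_shifts %in% setdiff(nb, true_edge)]
  if (length(hit)) names(hit)[1] else NA_character_
}

# random rotation matrix in m dimensions (QR of a Gaussian matrix)
random_rotation <- function(m, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent oracle: ancestral states as the conditional expectation of the
# joint Gaussian over all nodes, root plugged in by GLS
brute_asr <- function(y, tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(depth[M], nn, nn)
  Ctt <- S[1:n, 1:n]
  a <- drop(solve(t(rep(1, n)) %*% solve(Ctt) %*% rep(1, n),
                  t(rep(1, n)) %*% solve(Ctt) %*% y))
  drop(a + S[(n + 1):nn, 1:n] %*% solve(Ctt, y - a))
}

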
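# Seeded generators for every input the pipeline consumes: ultrametric
# trees, regime paintings, traits under BM and multi-peak OU, landmark sets
# built from a smooth 3-D curve, and ecology tables correlated with regime
# membership. All generators are bit-reproducible under a fixed seed; a
# dataset-level seed spawns deterministic sub-seeds per component.

# deterministic sub-stream: keep derived seeds inside 32-bit integer range
.subseed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483629) + 1L

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree rescaled to exact depth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth Root-to-tip depth in time units (the study system spans
#'   roughly the past 30-36 Myr of diversification; default 36).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, depth = 36, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * (depth / tree_depth(tree))
  validate_tree(tree)
}

#' Paint random regime shifts onto a tree
#'
#' Places `n_shifts` shifts on distinct branches such that no shift sits on
#' an ancestor of another (each shifted regime is a full subtree, so the true
#' painting is unambiguous). The first `n_convergent_pairs` pairs of shifts
#' share a regime label, making those regimes convergent by construction;
#' the two shifts of a pair are placed in distant parts of the tree (their
#' subtrees descend from different children of the root), emulating distant
#' clades pulled to one optimum — adjacent subtrees would be a single
#' connected regime, not convergence.
#'
#' @param tree A `phylo` object.
#' @param n_shifts Number of shifts.
#' @param n_convergent_pairs Number of label-sharing shift pairs
#'   (`2 * n_convergent_pairs <= n_shifts`).
#' @param seed Integer seed.
#' @param min_tips Minimum tips per shifted subtree (default 1).
#' @param min_age Minimum age of a shift's origin (time before present at
#'   the parent node of the shift edge, default 0). Lineages only approach a
#'   new optimum after a few phylogenetic half-lives, so shifts younger than
#'   about `5 / alpha` are unreachable by any regime-detection method;
#'   [simulate_dataset()] uses this to plant detectable shifts.
#' @return A `regime_painting`.
#' @export
paint_random_shifts <- function(tree, n_shifts, n_convergent_pairs = 0,
                                seed = NULL, min_tips = 1, min_age = 0) {
  tree <- validate_tree(tree)
  if (n_shifts == 0) return(regime_painting(tree))
  if (2 * n_convergent_pairs > n_shifts) {
    stop("need at least two shifts per convergent pair")
  }
  ne <- nrow(tree$edge)
  if (n_shifts > ne) stop("more shifts than branches")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  root <- n + 1L
  subtree_tips <- vapply(seq_len(ne), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= n) 1L else length(ape::extract.clade(tree, ch)$tip.label)
  }, integer(1))
  depth <- ape::node.depth.edgelength(tree)
  shift_age <- tree_depth(tree) - depth[tree$edge[, 1]]
  # exclude root edges so the background regime always keeps whole branches
  eligible <- which(subtree_tips >= min_tips & tree$edge[, 1] != root &
                      shift_age >= min_age)
  root_edges <- which(tree$edge[, 1] == root)
  halves <- lapply(root_edges, function(e) {
    intersect(.descendant_edges(tree, e), eligible)
  })
  nested <- function(a, b) {
    a %in% .descendant_edges(tree, b) || b %in% .descendant_edges(tree, a)
  }
  chosen <- NULL
  for (attempt in seq_len(200)) {
    sel <- integer(0)
    ok <- TRUE
    pick <- function(pool) {
      pool <- setdiff(pool, unlist(lapply(sel, function(e) .descendant_edges(tree, e))))
      pool <- pool[!vapply(pool, function(cand)
        any(vapply(sel, nested, logical(1), b = cand)), logical(1))]
      if (length(pool) == 0) return(NA_integer_)
      pool[sample.int(length(pool), 1)]
    }
    root_used <- FALSE
    # distant placement is structurally impossible when all but one root
    # half is too small (e.g. a lone tip against the rest of the tree);
    # fall back to plain non-nested placement after enough failed attempts
    distant <- attempt <= 150
    for (p in seq_len(n_convergent_pairs)) {
      hv <- sample(seq_along(halves))
      grab <- function(h) {
        e <- pick(halves[[h]])
        # a root half may hold no eligible interior branch (e.g. a cherry);
        # shifting the half wholesale is then the only distant placement,
        # allowed for at most one half so the background keeps real branches
        if (is.na(e) && !root_used && subtree_tips[root_edges[h]] >= min_tips) {
          root_used <<- TRUE
          e <- root_edges[h]
        }
        e
      }
      if (distant) {
        e1 <- grab(hv[1])
        if (!is.na(e1)) sel <- c(sel, e1)
        e2 <- if (length(hv) > 1) grab(hv[2]) else NA_integer_
      } else {
        e1 <- pick(eligible)
        if (!is.na(e1)) sel <- c(sel, e1)
        e2 <- pick(eligible)
      }
      if (is.na(e1) || is.na(e2)) { ok <- FALSE; break }
      sel <- c(sel, e2)
    }
    if (ok) {
      for (s in seq_len(n_shifts - 2 * n_convergent_pairs)) {
        e <- pick(eligible)
        if (is.na(e)) { ok <- FALSE; break }
        sel <- c(sel, e)
      }
    }
    if (ok) { chosen <- sel; break }
  }
  if (is.null(chosen)) {
    stop("could not place ", n_shifts, " non-nested shifts (",
         n_convergent_pairs, " distant pairs) on this tree")
  }
  labels <- character(n_shifts)
  lab <- 0
  for (p in seq_len(n_convergent_pairs)) {
    lab <- lab + 1
    labels[c(2 * p - 1, 2 * p)] <- letters[lab]
  }
  for (i in which(labels == "")) {
    lab <- lab + 1
    labels[i] <- letters[lab]
  }
  regime_painting(tree, shift_edges = chosen, shift_regimes = labels)
}

#' Simulate multivariate Brownian motion on a tree
#'
#' Recursive branch-wise Gaussian increments: along each branch of length
#' `t`, the increment is `N(0, t * R)` with `R` the (m x m) evolutionary
#' rate matrix. The root state is 0.
#'
#' @param tree A `phylo` object.
#' @param rate Positive semidefinite rate matrix (scalar accepted for m = 1).
#' @param seed Integer seed.
#' @return Tip-by-trait matrix, rows named by tip label.
#' @export
simulate_bm <- function(tree, rate, seed = NULL) {
  tree <- validate_tree(tree)
  if (length(rate) == 1) rate <- matrix(rate, 1, 1)
  er <- eigen((rate + t(rate)) / 2, symmetric = TRUE)
  if (min(er$values) < -1e-10 * max(abs(er$values), 1)) {
    stop("rate matrix is not positive semidefinite")
  }
  sqR <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  m <- nrow(rate)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  states <- matrix(NA_real_, nn, m)
  states[n + 1L, ] <- 0
  for (e in seq_len(nrow(tree$edge))) {  # cladewise: parents before children
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    inc <- drop(sqR %*% rnorm(m)) * sqrt(tree$edge.length[e])
    states[ch, ] <- states[par, ] + inc
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- paste0("trait", seq_len(m))
  out
}

#' Simulate a multi-peak Ornstein-Uhlenbeck process on a painted tree
#'
#' Exact branch-wise OU transition sampling, per trait: along a branch of
#' length `t` in regime `r`, the child state is Gaussian with mean
#' `theta_r + (parent - theta_r) exp(-alpha t)` and variance
#' `sigma2 (1 - exp(-2 alpha t)) / (2 alpha)`. The root starts at the
#' root regime's optimum.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @param alpha Adaptation rate(s), one per trait (recycled).
#' @param sigma2 Diffusion(s), one per trait (recycled; 0 gives the
#'   deterministic mean path).
#' @param theta Regime optima: named vector (one trait) or regime-by-trait
#'   matrix with regime rownames; every regime of the painting must appear.
#' @param seed Integer seed.
#' @return Tip-by-trait matrix, rows named by tip label.
#' @export
simulate_hansen <- function(tree, painting, alpha, sigma2, theta, seed = NULL) {
  tree <- validate_tree(tree)
  stopifnot(inherits(painting, "regime_painting"))
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1,
                                           dimnames = list(names(theta), NULL))
  regimes <- unique(painting$edge_regimes)
  miss <- setdiff(c(painting$root_regime, regimes), rownames(theta))
  if (length(miss)) stop("no optimum defined for regime(s): ",
                         paste(miss, collapse = ", "))
  m <- ncol(theta)
  alpha <- rep_len(alpha, m); sigma2 <- rep_len(sigma2, m)
  stopifnot(all(alpha > 0), all(sigma2 >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  states <- matrix(NA_real_, n + tree$Nnode, m)
  states[n + 1L, ] <- theta[painting$root_regime, ]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_ <- tree$edge.length[e]
    th <- theta[painting$edge_regimes[e], ]
    mu <- th + (states[par, ] - th) * exp(-alpha * t_)
    vv <- sigma2 * (1 - exp(-2 * alpha * t_)) / (2 * alpha)
    states[ch, ] <- mu + rnorm(m) * sqrt(vv)
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- paste0("trait", seq_len(m))
  out
}

#' Default semilandmark scheme for synthetic landmark sets
#'
#' @param n_curves Number of curves.
#' @param pts_per_curve Points per curve.
#' @return A `semilandmark_scheme` over consecutive landmark indices.
#' @export
default_scheme <- function(n_curves = 4, pts_per_curve = 5) {
  semilandmark_scheme(split(seq_len(n_curves * pts_per_curve),
                            rep(seq_len(n_curves), each = pts_per_curve)))
}

#' Simulate landmark configurations from a smooth 3-D curve
#'
#' Builds a helix-like base curve sampled along the scheme's curves, applies
#' a smooth group-specific deformation field, adds iid Gaussian coordinate
#' noise, and finally applies a random rotation, translation and scaling per
#' specimen so that Procrustes alignment has real work to do.
#'
#' @param n_specimens Number of specimens.
#' @param scheme A `semilandmark_scheme` (default [default_scheme()], 20
#'   landmarks).
#' @param groups Integer group per specimen (recycled; default all 1).
#' @param deformation Deformation magnitude per group (recycled).
#' @param noise_sd Iid coordinate noise standard deviation (shape units).
#' @param seed Integer seed.
#' @return A `landmark_set` with attribute `"groups"`.
#' @export
simulate_landmarks <- function(n_specimens, scheme = default_scheme(),
                               groups = 1L, deformation = 0.15,
                               noise_sd = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- rep_len(as.integer(groups), n_specimens)
  p <- max(unlist(scheme$curves))
  # base curve: one helix arc per scheme curve, offset in z
  base <- matrix(0, p, 3)
  for (ci in seq_along(scheme$curves)) {
    cv <- scheme$curves[[ci]]
    tt <- seq(0, 1.5 * pi, length.out = length(cv))
    r <- 1 - 0.06 * ci
    base[cv, ] <- cbind(r * cos(tt + ci), r * sin(tt + ci), 0.2 * tt + 0.3 * ci)
  }
  defmag <- rep_len(deformation, max(groups))
  out <- array(NA_real_, c(p, 3, n_specimens))
  for (i in seq_len(n_specimens)) {
    g <- groups[i]
    d <- defmag[g]
    x <- base
    # smooth group deformation field (low-frequency trigonometric bend)
    x <- x + d * cbind(sin(g + 2 * base[, 2]), cos(g + 2 * base[, 3]),
                       sin(g + 2 * base[, 1]))
    x <- x + matrix(rnorm(p * 3, sd = noise_sd), p, 3)
    # nuisance similarity transform
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    x <- x %*% R * exp(runif(1, -0.3, 0.3))
    x <- sweep(x, 2, runif(3, -5, 5), `+`)
    out[, , i] <- x
  }
  ls <- landmark_set(out)
  attr(ls, "groups") <- groups
  ls
}

#' Simulate an ecology table correlated with regime membership
#'
#' Each regime has a preferred category per factor (the first shifted regime
#' plays the oceanic, very-deep-diving, suction-feeding role). With
#' probability `strength` a species takes its regime's preferred category,
#' otherwise a uniformly random one; `strength = 0` makes factors independent
#' of regimes, `strength = 1` makes them deterministic (ambiguity is then
#' suppressed). With probability `ambiguity` a species' habitat/dive cell
#' lists a second category (`a|b`), exercising the assignment-variant logic
#' of [chi_square_tests()]. Masses are log-normal per regime.
#'
#' @param painting A `regime_painting` (tip regimes define the groups).
#' @param strength Association strength in `[0, 1]`.
#' @param ambiguity Probability of a multi-valued habitat/dive cell.
#' @param seed Integer seed.
#' @return Ecology tibble (`species`, `habitat`, `diet`, `feeding`, `dive`,
#'   `mass_kg`).
#' @export
simulate_ecology <- function(painting, strength = 0.9, ambiguity = 0.2,
                             seed = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- tip_regimes(painting)
  regimes <- .regime_levels(painting)
  cats <- list(
    habitat = c("riverine", "nearshore", "oceanic"),
    diet = c("generalist", "fish", "cephalopods"),
    feeding = c("raptorial", "suction"),
    dive = c("shallow", "mid", "deep", "very_deep")
  )
  # preferred category per regime and factor: the root regime takes the
  # first level, the first shifted regime plays the oceanic very-deep
  # suction-feeding role, further regimes cycle through the levels
  pref <- lapply(cats, function(cc) {
    p <- cc[1 + (seq_along(regimes) - 1) %% length(cc)]
    p[1] <- cc[1]
    p
  })
  if (length(regimes) > 1) {
    pref$habitat[2] <- "oceanic"; pref$diet[2] <- "cephalopods"
    pref$feeding[2] <- "suction"; pref$dive[2] <- "very_deep"
  }
  ri <- match(tr, regimes)
  n <- length(tr)
  draw <- function(f) {
    cc <- cats[[f]]
    vapply(seq_len(n), function(i) {
      if (runif(1) < strength) pref[[f]][ri[i]] else sample(cc, 1)
    }, character(1))
  }
  hab <- draw("habitat"); diet <- draw("diet")
  feed <- draw("feeding"); dive <- draw("dive")
  if (strength < 1 && ambiguity > 0) {
    for (i in seq_len(n)) {
      if (runif(1) < ambiguity) {
        alt <- sample(setdiff(cats$habitat, hab[i]), 1)
        hab[i] <- paste(hab[i], alt, sep = "|")
      }
      if (runif(1) < ambiguity) {
        alt <- sample(setdiff(cats$dive, dive[i]), 1)
        dive[i] <- paste(dive[i], alt, sep = "|")
      }
    }
  }
  mass <- exp(rnorm(n, mean = log(50) + 0.8 * (ri - 1), sd = 0.4))
  tibble(species = names(tr), habitat = hab, diet = diet,
         feeding = feed, dive = dive, mass_kg = mass)
}

#' Generate a complete synthetic dataset
#'
#' Composes the generators into one reproducible bundle: an ultrametric tree,
#' a true regime painting with convergent shifts, traits evolved under the
#' multi-peak OU model (plus optional extra BM traits emulating trailing PC
#' axes), and optional landmarks and ecology. All component seeds are derived
#' deterministically from `seed`.
#'
#' @param n_tips Tips (default 32).
#' @param depth Tree depth in time units (default 36).
#' @param n_shifts,n_convergent_pairs Painting structure (default 2 shifts
#'   forming 1 convergent pair).
#' @param n_traits OU traits for regime search (default 2).
#' @param alpha,sigma2 OU parameters per trait (recycled). Defaults
#'   `alpha = 1` (half-life 0.69 time units, within the 0.2-1.6 range
#'   typical of fitted cochlear-shape optima on a ~36-Myr tree) and
#'   `sigma2 = 0.04` (stationary sd ~0.14, so unit optima contrasts are
#'   ~7 stationary sd apart).
#' @param theta_contrast Distance of shifted optima from the ancestral 0.
#' @param n_bm_traits Extra independent BM traits (default 0).
#' @param bm_rate Rate of the extra BM traits.
#' @param with_landmarks,with_ecology Generate optional components.
#' @param ecology_strength Association strength for [simulate_ecology()].
#' @param seed Integer seed (required).
#' @return A `synthetic_dataset`: list with `tree`, `painting`, `traits`,
#'   `params`, optional `landmarks`/`ecology`, `seed`, `provenance`.
#' @examples
#' ds <- simulate_dataset(n_tips = 16, seed = 1)
#' ds$painting
#' @export
simulate_dataset <- function(n_tips = 32, depth = 36, n_shifts = 2,
                             n_convergent_pairs = 1, n_traits = 2,
                             alpha = 3, sigma2 = 0.05, theta_contrast = 1,
                             n_bm_traits = 0, bm_rate = 0.01,
                             with_landmarks = FALSE, with_ecology = FALSE,
                             ecology_strength = 0.9, seed) {
  stopifnot(!missing(seed))
  tree <- simulate_tree(n_tips, depth, seed = .subseed(seed, 1))
  # plant only reachable shifts: a lineage needs ~5/alpha time units (about
  # seven half-lives) to arrive at a new optimum
  painting <- paint_random_shifts(tree, n_shifts, n_convergent_pairs,
                                  seed = .subseed(seed, 2), min_tips = 2,
                                  min_age = 5 / max(rep_len(alpha, n_traits)))
  regimes <- .regime_levels(painting)
  alpha <- rep_len(alpha, n_traits); sigma2 <- rep_len(sigma2, n_traits)
  theta <- matrix(0, length(regimes), n_traits,
                  dimnames = list(regimes, NULL))
  if (length(regimes) > 1) {
    shifted <- regimes[-1]
    # convergent labels share a row by construction; alternate signs across
    # distinct shifted regimes so optima are mutually separated
    for (i in seq_along(shifted)) {
      theta[shifted[i], ] <- theta_contrast * (-1)^(i - 1)
    }
  }
  traits <- simulate_hansen(tree, painting, alpha, sigma2, theta,
                            seed = .subseed(seed, 3))
  if (n_bm_traits > 0) {
    extra <- simulate_bm(tree, diag(rep(bm_rate, n_bm_traits)),
                         seed = .subseed(seed, 4))
    colnames(extra) <- paste0("trait", n_traits + seq_len(n_bm_traits))
    traits <- cbind(traits, extra)
  }
  out <- list(
    tree = tree, painting = painting, traits = traits,
    params = list(alpha = alpha, sigma2 = sigma2, theta = theta),
    seed = seed,
    provenance = list(
      n_tips = n_tips, depth = depth, n_shifts = n_shifts,
      n_convergent_pairs = n_convergent_pairs, n_traits = n_traits,
      alpha = alpha, sigma2 = sigma2, theta_contrast = theta_contrast,
      n_bm_traits = n_bm_traits, bm_rate = bm_rate, seed = seed
    )
  )
  if (with_landmarks) {
    tr <- tip_regimes(painting)
    out$landmarks <- simulate_landmarks(
      n_specimens = n_tips, groups = match(tr, regimes),
      seed = .subseed(seed, 5)
    )
    dimnames(out$landmarks)[[3]] <- tree$tip.label
  }
  if (with_ecology) {
    out$ecology <- simulate_ecology(painting, strength = ecology_strength,
                                    seed = .subseed(seed, 6))
  }
  structure(out, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (seed", x$seed, "):",
      length(x$tree$tip.label), "tips,",
      ncol(x$traits), "traits\n")
  print(x$painting)
  invisible(x)
}

#' Write / read a synthetic dataset as a plain-text directory
#'
#' Serialises `tree.nwk`, `painting.csv` (edge table), `traits.csv`,
#' optional `landmarks/*.pts` and `ecology.csv`, and `provenance.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Target directory (created).
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   list with the reloaded components (the painting is reconstructed from
#'   its edge table).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(as_tibble(dataset$painting), file.path(dir, "painting.csv"))
  readr::write_csv(
    dplyr::bind_cols(tibble(species = rownames(dataset$traits)),
                     as_tibble(dataset$traits)),
    file.path(dir, "traits.csv")
  )
  if (!is.null(dataset$ecology)) {
    readr::write_csv(dataset$ecology, file.path(dir, "ecology.csv"))
  }
  if (!is.null(dataset$landmarks)) {
    lmdir <- file.path(dir, "landmarks")
    dir.create(lmdir, showWarnings = FALSE)
    for (i in seq_len(dim(dataset$landmarks)[3])) {
      write_pts(dataset$landmarks[, , i],
                file.path(lmdir, paste0(dimnames(dataset$landmarks)[[3]][i], ".pts")))
    }
  }
  jsonlite::write_json(dataset$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  tree <- read_newick(file = file.path(dir, "tree.nwk"))
  ptab <- readr::read_csv(file.path(dir, "painting.csv"), show_col_types = FALSE)
  root_regime <- ptab$regime[which(!ptab$is_shift)[1]]
  painting <- .painting_from_edges(tree, ptab$regime, root_regime)
  traits <- as_trait_matrix(
    readr::read_csv(file.path(dir, "traits.csv"), show_col_types = FALSE), tree)
  out <- list(tree = tree, painting = painting, traits = traits)
  if (file.exists(file.path(dir, "ecology.csv"))) {
    out$ecology <- read_ecology(file.path(dir, "ecology.csv"))
  }
  if (dir.exists(file.path(dir, "landmarks"))) {
    out$landmarks <- read_pts_dir(file.path(dir, "landmarks"))
  }
  if (file.exists(file.path(dir, "provenance.json"))) {
    out$provenance <- jsonlite::read_json(file.path(dir, "provenance.json"),
                                          simplifyVector = TRUE)
  }
  out
}
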
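# Geometric morphometrics: landmark containers, generalised Procrustes
# alignment with optional sliding semilandmarks, and PCA of the aligned
# shapes. Landmark sets are p x 3 x n arrays (landmarks x coordinates x
# specimens), the layout used throughout landmark-based morphometrics.

#' Build a landmark set
#'
#' @param coords A `p x 3 x n` numeric array (p landmarks, xyz, n specimens),
#'   or a list of `p x 3` matrices.
#' @param labels Specimen labels; defaults to existing dimnames or `spec1..n`.
#' @return A `landmark_set`: the validated array with specimen labels as the
#'   third dimnames.
#' @export
landmark_set <- function(coords, labels = NULL) {
  if (is.list(coords)) {
    p <- nrow(coords[[1]])
    coords <- array(unlist(coords), dim = c(p, 3, length(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("`coords` must be a p x 3 x n array")
  }
  if (dim(coords)[1] < 3) stop("at least 3 landmarks are required")
  if (anyNA(coords)) stop("missing coordinates are not supported")
  if (is.null(labels)) labels <- dimnames(coords)[[3]]
  if (is.null(labels)) labels <- paste0("spec", seq_len(dim(coords)[3]))
  if (anyDuplicated(labels)) stop("duplicate specimen labels")
  dimnames(coords) <- list(NULL, c("x", "y", "z"), labels)
  structure(coords, class = c("landmark_set", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x)
  cat("Landmark set:", d[3], "specimens x", d[1], "landmarks (3-D)\n")
  invisible(x)
}

centroid_size <- function(m) {
  cm <- colMeans(m)
  sqrt(sum(sweep(m, 2, cm)^2))
}

# Optimal rotation (det +1; reflections excluded) of x onto target.
.procrustes_rotation <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Full Procrustes distance between two configurations
#'
#' Centres, optionally scales to unit centroid size, optimally rotates
#' (rotations only, no reflection) and returns the root-sum-of-squares
#' difference.
#'
#' @param x,y `p x 3` landmark matrices.
#' @param scale Scale both to unit centroid size first.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(x, y, scale = TRUE) {
  cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
  if (scale) {
    cx <- cx / sqrt(sum(cx^2)); cy <- cy / sqrt(sum(cy^2))
  }
  R <- .procrustes_rotation(cx, cy)
  sqrt(sum((cx %*% R - cy)^2))
}

#' Generalised Procrustes analysis
#'
#' Iterative superimposition of all specimens: each configuration is centred,
#' scaled to unit centroid size, and optimally rotated (least-squares, proper
#' rotations only — reflections are never introduced) to the current
#' consensus; the consensus is then recomputed. Iteration stops when the
#' root-sum-of-squares change of the consensus falls below `tol`.
#'
#' @param landmarks A `landmark_set` (or `p x 3 x n` array).
#' @param tol Convergence tolerance on the consensus update.
#' @param max_iter Iteration cap.
#' @return An `aligned_shapes` object: list with `coords` (aligned
#'   `landmark_set`, unit centroid size), `consensus` (`p x 3`),
#'   `centroid_sizes` (original units), `iterations` and `trace` (consensus
#'   change per iteration).
#' @examples
#' lms <- simulate_landmarks(n_specimens = 4, seed = 1)
#' al <- gpa(lms)
#' range(apply(al$coords, 3, function(m) sqrt(sum(m^2)))) # all ~1
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 100) {
  x <- landmark_set(unclass(landmarks))
  n <- dim(x)[3]
  labels <- dimnames(x)[[3]]
  sizes <- apply(x, 3, centroid_size)
  if (any(sizes < 1e-12)) {
    stop("degenerate specimen with zero centroid size: ",
         paste(labels[sizes < 1e-12], collapse = ", "))
  }
  for (i in seq_len(n)) {
    m <- sweep(x[, , i], 2, colMeans(x[, , i]))
    x[, , i] <- m / sqrt(sum(m^2))
  }
  consensus <- x[, , 1]
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) x[, , i] <- x[, , i] %*% .procrustes_rotation(x[, , i], consensus)
    new_cons <- apply(x, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    trace <- c(trace, delta)
    consensus <- new_cons
    if (delta < tol) break
  }
  structure(
    list(coords = landmark_set(unclass(x), labels), consensus = consensus,
         centroid_sizes = setNames(sizes, labels),
         iterations = length(trace), trace = trace),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$coords)
  cat("Procrustes-aligned shapes:", d[3], "specimens x", d[1], "landmarks;",
      x$iterations, "iterations (final change",
      format(tail(x$trace, 1), digits = 3), ")\n")
  invisible(x)
}

#' Define a sliding-semilandmark scheme
#'
#' A scheme is a list of curves, each an ordered sequence of landmark indices
#' (length >= 3). Non-endpoint points on each curve are semilandmarks allowed
#' to slide along their local tangent; endpoints are fixed when
#' `fixed_ends` is `TRUE` (per curve or recycled).
#'
#' @param curves List of integer vectors of landmark indices.
#' @param fixed_ends Logical, recycled over curves.
#' @return A `semilandmark_scheme`.
#' @export
semilandmark_scheme <- function(curves, fixed_ends = TRUE) {
  curves <- lapply(curves, as.integer)
  if (any(vapply(curves, length, 1L) < 3)) stop("every curve needs >= 3 points")
  if (any(vapply(curves, anyDuplicated, 1L) > 0)) stop("curve indices must be distinct within a curve")
  interior <- unlist(lapply(curves, function(cv) cv[-c(1, length(cv))]))
  if (anyDuplicated(interior)) stop("curves may share only endpoints")
  fixed_ends <- rep_len(as.logical(fixed_ends), length(curves))
  structure(list(curves = curves, fixed_ends = fixed_ends),
            class = "semilandmark_scheme")
}

#' Read / write a semilandmark scheme as JSON
#'
#' @param path File path.
#' @param scheme A `semilandmark_scheme`.
#' @return `read_scheme()` a `semilandmark_scheme`; `write_scheme()` the path,
#'   invisibly.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  semilandmark_scheme(x$curves, fixed_ends = x$fixed_ends %||% TRUE)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(list(curves = scheme$curves, fixed_ends = scheme$fixed_ends),
                       path, auto_unbox = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One sliding pass of a single specimen toward a reference shape: each
# interior semilandmark moves along the chord between its curve neighbours by
# the closed-form 1-D projection of its offset from the reference.
.slide_specimen <- function(m, ref, scheme) {
  for (ci in seq_along(scheme$curves)) {
    cv <- scheme$curves[[ci]]
    # endpoints have only one curve neighbour, so only interior points slide;
    # fixed_ends is carried for schemes whose endpoints are shared anchors
    idx <- seq_along(cv)[-c(1, length(cv))]
    tangents <- m[cv[idx + 1L], , drop = FALSE] - m[cv[idx - 1L], , drop = FALSE]
    nrm <- sqrt(rowSums(tangents^2))
    if (any(nrm < 1e-12)) {
      k <- idx[which(nrm < 1e-12)[1]]
      stop("zero tangent (coincident neighbours) on curve ", ci, " at point ", k)
    }
    tangents <- tangents / nrm
    disp <- rowSums((ref[cv[idx], , drop = FALSE] - m[cv[idx], , drop = FALSE]) * tangents)
    m[cv[idx], ] <- m[cv[idx], ] + disp * tangents
  }
  m
}

#' Slide semilandmarks along their tangents
#'
#' Alternates Procrustes alignment and tangent sliding: in each outer
#' iteration every interior semilandmark of every specimen is displaced along
#' its local tangent (the chord between its curve neighbours) by the
#' closed-form projection that minimises its Procrustes distance to the
#' consensus; the set is then re-aligned. Curve endpoints never move during
#' sliding. Sliding under the Procrustes-distance criterion reduces the
#' arbitrary along-curve component of semilandmark placement.
#'
#' @param landmarks A `landmark_set` or `aligned_shapes`.
#' @param scheme A `semilandmark_scheme`.
#' @param iterations Outer slide/align iterations.
#' @param align If `TRUE` (default) the returned coordinates are re-aligned
#'   after the final slide; with `FALSE` the last sliding pass is performed in
#'   the current frame against the current consensus and non-sliding
#'   landmarks are returned bit-identical.
#' @return A `landmark_set` of slid (aligned-frame) coordinates.
#' @export
slide_semilandmarks <- function(landmarks, scheme, iterations = 3, align = TRUE) {
  stopifnot(inherits(scheme, "semilandmark_scheme"))
  al <- if (inherits(landmarks, "aligned_shapes")) landmarks else gpa(landmarks)
  p <- dim(al$coords)[1]
  rng <- range(unlist(scheme$curves))
  if (rng[1] < 1 || rng[2] > p) stop("scheme indices out of range for ", p, " landmarks")
  x <- al$coords
  n <- dim(x)[3]
  for (outer in seq_len(iterations)) {
    ref <- al$consensus
    for (i in seq_len(n)) x[, , i] <- .slide_specimen(x[, , i], ref, scheme)
    if (align || outer < iterations) {
      al <- gpa(x)
      x <- al$coords
    }
  }
  landmark_set(unclass(x), dimnames(x)[[3]])
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposes the covariance of the flattened aligned coordinates
#' (tangent-space approximation). Scores are column-centred; at most
#' `min(n - 1, 3p)` components carry variance. For determinism each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param aligned An `aligned_shapes` object (or `landmark_set`, aligned
#'   first).
#' @return A `shape_space`: list with `scores` (tibble: `specimen`,
#'   `PC1..PCk`), `eigenvalues`, `var_fraction` (percent, sums to 100),
#'   `loadings`, `center` (consensus as flat vector), `n`.
#' @examples
#' al <- gpa(simulate_landmarks(n_specimens = 6, seed = 2))
#' sp <- shape_pca(al)
#' sum(sp$var_fraction) # 100
#' @export
shape_pca <- function(aligned) {
  if (inherits(aligned, "landmark_set")) aligned <- gpa(aligned)
  x <- aligned$coords
  n <- dim(x)[3]
  if (n < 2) stop("at least two specimens are required for PCA")
  flat <- t(apply(x, 3, as.vector))  # n x 3p
  pc <- prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(ev > max(ev) * 1e-12)
  ev <- ev[keep]
  scores <- pc$x[, keep, drop = FALSE]
  load <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(load) <- paste0("PC", seq_along(keep))
  structure(
    list(
      scores = dplyr::bind_cols(tibble(specimen = dimnames(x)[[3]]),
                                as_tibble(scores)),
      eigenvalues = ev,
      var_fraction = 100 * ev / sum(ev),
      loadings = load,
      center = pc$center,
      n = n
    ),
    class = "shape_space"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", x$n, "specimens,", length(x$eigenvalues), "components\n")
  k <- min(3, length(x$var_fraction))
  cat("  ", paste(sprintf("PC%d %.2f%%", seq_len(k), x$var_fraction[seq_len(k)]),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Score matrix of a shape space
#'
#' @param space A `shape_space`.
#' @param n_pcs Number of leading components (default all).
#' @return Numeric matrix, rows named by specimen.
#' @export
score_matrix <- function(space, n_pcs = NULL) {
  m <- as.matrix(space$scores[, -1, drop = FALSE])
  rownames(m) <- space$scores$specimen
  if (!is.null(n_pcs)) m <- m[, seq_len(min(n_pcs, ncol(m))), drop = FALSE]
  m
}

#' @export
#' @method tidy shape_space
tidy.shape_space <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    var_fraction = x$var_fraction,
    cumulative = cumsum(x$var_fraction)
  )
}

#' @export
#' @method glance shape_space
glance.shape_space <- function(x, ...) {
  tibble(n = x$n, n_components = length(x$eigenvalues),
         pc1_var = x$var_fraction[1],
         n_pcs_95 = which(cumsum(x$var_fraction) >= 95)[1])
}

#' Scatter of specimens in shape space
#'
#' @param object A `shape_space`.
#' @param x_pc,y_pc Components to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot shape_space
autoplot.shape_space <- function(object, x_pc = 1, y_pc = 2, ...) {
  sc <- object$scores
  xs <- paste0("PC", x_pc); ys <- paste0("PC", y_pc)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xs]], y = .data[[ys]])) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, object$var_fraction[x_pc]),
      y = sprintf("%s (%.1f%%)", ys, object$var_fraction[y_pc])
    ) +
    ggplot2::theme_minimal()
}

# ---- .pts input/output ------------------------------------------------------

#' Read one specimen from a .pts landmark file
#'
#' Dialect: whitespace-separated `label x y z` lines; lines starting with `#`
#' (and blank lines) are skipped. Landmark order in the file defines curve
#' indexing.
#'
#' @param path File path.
#' @return A `p x 3` matrix with landmark labels as rownames.
#' @export
read_pts <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- which(keep)
  out <- matrix(NA_real_, length(lines), 3)
  labs <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tail(parts, 3)))
    if (length(parts) < 4 || anyNA(vals)) {
      stop("malformed .pts line ", lineno[i], " in ", path)
    }
    labs[i] <- paste(head(parts, -3), collapse = " ")
    out[i, ] <- vals
  }
  rownames(out) <- labs
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write one specimen to a .pts file
#'
#' @param coords `p x 3` matrix (rownames used as landmark labels).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pts <- function(coords, path) {
  labs <- rownames(coords) %||% paste0("p", seq_len(nrow(coords)))
  writeLines(sprintf("%s %.17g %.17g %.17g", labs,
                     coords[, 1], coords[, 2], coords[, 3]), path)
  invisible(path)
}

#' Read a directory of .pts files as a landmark set
#'
#' @param dir Directory containing one `.pts` file per specimen.
#' @param n_expected Optional expected landmark count per specimen.
#' @return A `landmark_set`; specimen labels are the file basenames.
#' @export
read_pts_dir <- function(dir, n_expected = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pts$", full.names = TRUE))
  if (length(files) == 0) stop("no .pts files in ", dir)
  mats <- lapply(files, read_pts)
  p <- unique(vapply(mats, nrow, 1L))
  if (length(p) != 1) stop("inconsistent landmark counts across specimens: ",
                           paste(p, collapse = ", "))
  if (!is.null(n_expected) && p != n_expected) {
    stop("expected ", n_expected, " landmarks, found ", p)
  }
  landmark_set(mats, labels = sub("\\.pts$", "", basename(files)))
}
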
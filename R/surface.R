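# Two-phase stepwise detection of convergent adaptive regimes. The forward
# phase greedily adds regime shifts (each introducing a brand-new regime) at
# the origin of whichever branch most improves the summed AICc of the
# per-trait Hansen fits; the backward phase greedily collapses pairs of
# regimes into one shared (convergent) regime while AICc keeps improving.

#' Forward phase: stepwise addition of regime shifts
#'
#' Starts from the single-regime (OU1) model and repeatedly evaluates placing
#' a brand-new regime at the origin of every branch (the shift repaints the
#' branch and all its descendants not already overridden by a more recent
#' shift). The candidate with the largest AICc decrease is accepted; ties are
#' broken toward the branch earliest in preorder. The loop stops when no
#' candidate strictly decreases AICc.
#'
#' @param traits Tip-labelled matrix or data frame; 1-4 traits recommended
#'   (the per-trait OU independence assumption degrades beyond that).
#' @param tree Ultrametric `phylo`.
#' @param max_shifts Optional cap on the number of shifts.
#' @param grid_size,tol Alpha-search settings passed to [hansen_fit()].
#' @param alpha_min Lower bound for the per-trait adaptation rate. The
#'   default (`2 ln 2 / T`, i.e. phylogenetic half-life at most half the
#'   tree depth) keeps the multi-peak search out of the Brownian-motion
#'   limit, where optima are unidentifiable and a degenerate likelihood
#'   ridge (alpha -> 0 with diverging optima) can absorb the very regimes
#'   the backward phase should collapse; that slow-adaptation region is
#'   covered by the separate BM and OU1 comparison fits.
#' @param verbose Print progress.
#' @return List with `painting` (final `regime_painting`), `fit` (its
#'   `hansen_fit`), and `history`, a tibble with one row per accepted step
#'   (`step`, `edge`, `AICc`); step 0 is the single-regime model.
#' @export
surface_forward <- function(traits, tree, max_shifts = Inf, grid_size = 8,
                            tol = 1e-4, alpha_min = NULL, verbose = FALSE) {
  cache <- .hansen_cache(tree)
  Y <- as_trait_matrix(traits, cache$tree)
  if (ncol(Y) > 4) warning("more than 4 traits: per-trait OU independence is doubtful")
  if (is.null(alpha_min)) alpha_min <- 2 * log(2) / cache$T
  painting <- regime_painting(cache$tree)
  fit <- hansen_fit(Y, cache$tree, painting, grid_size, tol, alpha_min, cache = cache)
  history <- tibble(step = 0L, edge = NA_integer_, AICc = fit$AICc)
  ne <- nrow(cache$tree$edge)
  step <- 0L
  while (length(painting$shift_edges) < max_shifts) {
    step <- step + 1L
    new_label <- sprintf("s%02d", step)
    best <- NULL
    for (e in seq_len(ne)) {           # preorder: tie-break by first index
      if (e %in% painting$shift_edges) next
      cand <- .add_shift(painting, e, new_label)
      cf <- tryCatch(
        hansen_fit(Y, cache$tree, cand, grid_size, tol, alpha_min, cache = cache),
        error = function(err) NULL
      )
      if (is.null(cf)) next
      if (is.null(best) || cf$AICc < best$fit$AICc - 1e-12) {
        best <- list(edge = e, painting = cand, fit = cf)
      }
    }
    if (is.null(best) || best$fit$AICc >= fit$AICc) break
    painting <- best$painting
    fit <- best$fit
    history <- dplyr::bind_rows(history,
                                tibble(step = step, edge = best$edge, AICc = fit$AICc))
    if (verbose) {
      message(sprintf("forward step %d: shift on edge %d, AICc %.3f",
                      step, best$edge, fit$AICc))
    }
  }
  list(painting = painting, fit = fit, history = history)
}

# Repaint with an additional shift at `edge`: the new regime covers the edge
# and its descendants up to (not including) existing downstream shifts.
.add_shift <- function(painting, edge, label) {
  er <- painting$edge_regimes
  covered <- .descendant_edges(painting$tree, edge,
                               stop_edges = setdiff(painting$shift_edges, edge))
  er[covered] <- label
  .painting_from_edges(painting$tree, er, painting$root_regime)
}

#' Backward phase: pairwise collapse of regimes into convergent regimes
#'
#' Takes the forward-phase model and repeatedly tries relabelling every
#' unordered pair of regimes as one; the collapse with the best AICc
#' improvement is accepted and the loop repeats until none improves. A regime
#' retained by two or more independent shifts after collapsing is
#' *convergent*. Comparison fits under Brownian motion and single-peak OU are
#' included.
#'
#' @param traits,tree,grid_size,tol,alpha_min,verbose As in
#'   [surface_forward()].
#' @param forward Result of [surface_forward()] (or a list with `painting`).
#' @return A `surface_result`: final `painting` and `fit`, `counts`
#'   ([regime_counts()] row), `forward_history`, `backward_history`,
#'   comparison fits `fit_ou1` and `fit_bm`.
#' @export
surface_backward <- function(traits, tree, forward, grid_size = 8, tol = 1e-4,
                             alpha_min = NULL, verbose = FALSE) {
  cache <- .hansen_cache(tree)
  Y <- as_trait_matrix(traits, cache$tree)
  if (is.null(alpha_min)) alpha_min <- 2 * log(2) / cache$T
  painting <- forward$painting
  fit <- forward$fit %||%
    hansen_fit(Y, cache$tree, painting, grid_size, tol, alpha_min, cache = cache)
  history <- tibble(step = 0L, merged = NA_character_, into = NA_character_,
                    AICc = fit$AICc)
  step <- 0L
  repeat {
    regimes <- .regime_levels(painting)
    if (length(regimes) < 2) break
    best <- NULL
    pairs <- utils::combn(regimes, 2)
    for (j in seq_len(ncol(pairs))) {
      keep_lab <- pairs[1, j]; drop_lab <- pairs[2, j]
      er <- painting$edge_regimes
      er[er == drop_lab] <- keep_lab
      root_lab <- if (painting$root_regime == drop_lab) keep_lab else painting$root_regime
      cand <- .painting_from_edges(painting$tree, er, root_lab)
      cf <- tryCatch(
        hansen_fit(Y, cache$tree, cand, grid_size, tol, alpha_min, cache = cache),
        error = function(err) NULL
      )
      if (is.null(cf)) next
      if (is.null(best) || cf$AICc < best$fit$AICc - 1e-12) {
        best <- list(merged = drop_lab, into = keep_lab, painting = cand, fit = cf)
      }
    }
    if (is.null(best) || best$fit$AICc >= fit$AICc) break
    step <- step + 1L
    painting <- best$painting
    fit <- best$fit
    history <- dplyr::bind_rows(history,
      tibble(step = step, merged = best$merged, into = best$into, AICc = fit$AICc))
    if (verbose) {
      message(sprintf("backward step %d: %s -> %s, AICc %.3f",
                      step, best$merged, best$into, fit$AICc))
    }
  }
  fit_ou1 <- hansen_fit(Y, cache$tree, regime_painting(cache$tree),
                        grid_size, tol, alpha_min, cache = cache)
  fit_bm <- bm_fit(Y, cache$tree)
  structure(
    list(painting = painting, fit = fit, counts = regime_counts(painting),
         forward_history = forward$history %||% tibble(),
         backward_history = history,
         fit_ou1 = fit_ou1, fit_bm = fit_bm),
    class = "surface_result"
  )
}

#' Full two-phase convergent-regime search
#'
#' Convenience wrapper running [surface_forward()] then [surface_backward()].
#'
#' @inheritParams surface_forward
#' @return A `surface_result`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(n_tips = 24, seed = 5)
#' res <- surface_search(ds$traits, ds$tree)
#' glance(res)
#' }
#' @export
surface_search <- function(traits, tree, max_shifts = Inf, grid_size = 8,
                           tol = 1e-4, alpha_min = NULL, verbose = FALSE) {
  fw <- surface_forward(traits, tree, max_shifts, grid_size, tol, alpha_min, verbose)
  surface_backward(traits, tree, fw, grid_size, tol, alpha_min, verbose)
}

#' @export
print.surface_result <- function(x, ...) {
  cnt <- x$counts
  cat("Stepwise OU regime search\n")
  cat(sprintf("  multipeak OU AICc %.3f | OU1 %.3f | BM %.3f\n",
              x$fit$AICc, x$fit_ou1$AICc, x$fit_bm$AICc))
  cat(sprintf("  regimes %d, shifts %d, convergent regimes %d, convergent shifts %d, fraction %.3g\n",
              cnt$n_regimes, cnt$n_shifts, cnt$n_convergent_regimes,
              cnt$n_convergent_shifts, cnt$convergence_fraction))
  invisible(x)
}

#' @export
#' @method tidy surface_result
tidy.surface_result <- function(x, ...) tidy(x$fit)

#' @export
#' @method glance surface_result
glance.surface_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(AICc_multipeak = x$fit$AICc, AICc_ou1 = x$fit_ou1$AICc,
           AICc_bm = x$fit_bm$AICc),
    x$counts
  )
}

#' AICc trace of the stepwise search
#'
#' @param object A `surface_result`.
#' @param ... Unused.
#' @return A ggplot of AICc against accepted step, by phase.
#' @export
#' @method autoplot surface_result
autoplot.surface_result <- function(object, ...) {
  fw <- dplyr::mutate(object$forward_history, phase = "forward")
  bw <- dplyr::mutate(object$backward_history, phase = "backward",
                      step = .data$step + max(fw$step))
  d <- dplyr::bind_rows(
    dplyr::select(fw, "step", "AICc", "phase"),
    dplyr::select(bw[-1, ], "step", "AICc", "phase")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$AICc,
                                  colour = .data$phase)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "accepted step", y = "model AICc") +
    ggplot2::theme_minimal()
}

#' Tips belonging to each convergent regime
#'
#' @param result A `surface_result` (or `regime_painting`).
#' @return Named list of tip-label vectors, one per convergent regime
#'   (regimes reached by two or more shifts).
#' @export
convergent_regime_tips <- function(result) {
  painting <- if (inherits(result, "surface_result")) result$painting else result
  shifts <- painting$shift_edges
  mult <- table(names(shifts))
  conv <- names(mult)[mult >= 2]
  tr <- tip_regimes(painting)
  out <- lapply(conv, function(r) names(tr)[tr == r])
  setNames(out, conv)
}
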
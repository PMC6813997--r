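# Regime paintings: an assignment of every branch of the tree to an adaptive
# regime, plus the shift set (branches at whose origin the regime changes).

#' Paint adaptive regimes onto a tree
#'
#' Builds a `regime_painting`: every edge of the tree carries a regime label.
#' Regimes are defined by shift edges — at the origin of each shift edge a new
#' regime starts and is inherited by all descendant edges until overridden by
#' a more recent shift. Edges above all shifts carry the root regime.
#'
#' @param tree A `phylo` object (edges are indexed in cladewise order).
#' @param shift_edges Integer vector of edge indices where shifts occur.
#' @param shift_regimes Character vector of regime labels, one per shift.
#'   Distinct shifts may share a label: such regimes are *convergent* (reached
#'   by two or more independent shifts).
#' @param root_regime Label of the regime at the root.
#' @return A `regime_painting` object: list with `tree`, `edge_regimes`
#'   (character, one per edge), `root_regime`, and `shift_edges` (named by
#'   regime label).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' p <- regime_painting(tr, shift_edges = c(2, 5), shift_regimes = c("a", "a"))
#' regime_counts(p) # two shifts into one convergent regime: fraction 1
#' @export
regime_painting <- function(tree, shift_edges = integer(0),
                            shift_regimes = character(0),
                            root_regime = "anc") {
  tree <- validate_tree(tree)
  ne <- nrow(tree$edge)
  shift_edges <- as.integer(shift_edges)
  if (length(shift_edges) != length(shift_regimes)) {
    stop("`shift_edges` and `shift_regimes` must have equal length")
  }
  if (anyDuplicated(shift_edges)) stop("duplicate shift edges")
  if (any(shift_edges < 1 | shift_edges > ne)) stop("shift edge index out of range")
  edge_regimes <- rep(root_regime, ne)
  # cladewise order guarantees parents are painted before children
  shift_at <- rep(NA_character_, ne)
  shift_at[shift_edges] <- shift_regimes
  pe <- .parent_edge(tree)
  for (e in seq_len(ne)) {
    parent_reg <- if (pe[tree$edge[e, 1]] == 0) root_regime else edge_regimes[pe[tree$edge[e, 1]]]
    edge_regimes[e] <- if (!is.na(shift_at[e])) shift_at[e] else parent_reg
  }
  .painting_from_edges(tree, edge_regimes, root_regime, validate_shifts = shift_edges)
}

# Construct a painting from a full edge->regime map; shifts are derived as the
# edges whose regime differs from their parent edge's (or the root regime).
.painting_from_edges <- function(tree, edge_regimes, root_regime,
                                 validate_shifts = NULL) {
  pe <- .parent_edge(tree)
  parent_reg <- ifelse(pe[tree$edge[, 1]] == 0, root_regime,
                       edge_regimes[pmax(pe[tree$edge[, 1]], 1L)])
  shifts <- which(edge_regimes != parent_reg)
  if (!is.null(validate_shifts) && !setequal(shifts, validate_shifts)) {
    bad <- setdiff(validate_shifts, shifts)
    stop("shift on edge ", paste(bad, collapse = ", "),
         " does not change the regime of its parent branch")
  }
  names(shifts) <- edge_regimes[shifts]
  structure(
    list(tree = tree, edge_regimes = edge_regimes,
         root_regime = root_regime, shift_edges = shifts),
    class = "regime_painting"
  )
}

#' Regime labels, shift counts and convergence bookkeeping
#'
#' Summarises a painting the way a stepwise regime search reports its final
#' model: the number of regime shifts `k` (the root regime's origin is not a
#' shift), the number of distinct regimes `k_prime`, the number of
#' *convergent* regimes (regimes reached by two or more independent shifts),
#' the number of shifts into convergent regimes `c`, and the convergence
#' fraction `c / k` (`0` when there are no shifts).
#'
#' @param painting A `regime_painting`.
#' @return One-row tibble with columns `n_shifts`, `n_regimes`,
#'   `n_convergent_regimes`, `n_convergent_shifts`, `convergence_fraction`.
#' @export
regime_counts <- function(painting) {
  stopifnot(inherits(painting, "regime_painting"))
  shifts <- painting$shift_edges
  k <- length(shifts)
  mult <- table(names(shifts))
  conv <- names(mult)[mult >= 2]
  c_shifts <- sum(names(shifts) %in% conv)
  tibble(
    n_shifts = k,
    n_regimes = length(unique(painting$edge_regimes)),
    n_convergent_regimes = length(conv),
    n_convergent_shifts = c_shifts,
    convergence_fraction = if (k == 0) 0 else c_shifts / k
  )
}

#' Regime of the terminal branch of every tip
#'
#' @param painting A `regime_painting`.
#' @return Named character vector, tip label -> regime label.
#' @export
tip_regimes <- function(painting) {
  tree <- painting$tree
  n <- length(tree$tip.label)
  pe <- .parent_edge(tree)
  setNames(painting$edge_regimes[pe[seq_len(n)]], tree$tip.label)
}

#' @export
print.regime_painting <- function(x, ...) {
  cnt <- regime_counts(x)
  cat("Regime painting on", length(x$tree$tip.label), "tips:",
      cnt$n_regimes, "regimes,", cnt$n_shifts, "shifts",
      sprintf("(%d convergent shifts, fraction %.3g)\n",
              cnt$n_convergent_shifts, cnt$convergence_fraction))
  invisible(x)
}

#' Tabulate a painting as a branch table
#'
#' @param x A `regime_painting`.
#' @param ... Unused.
#' @return Tibble with one row per edge: `edge`, `parent`, `child`,
#'   `child_label` (tip label or `NA`), `length`, `regime`, `is_shift`.
#' @export
#' @method as_tibble regime_painting
as_tibble.regime_painting <- function(x, ...) {
  tree <- x$tree
  n <- length(tree$tip.label)
  child <- tree$edge[, 2]
  tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = child,
    child_label = ifelse(child <= n, tree$tip.label[pmax(child, 1L)], NA_character_),
    length = tree$edge.length,
    regime = x$edge_regimes,
    is_shift = seq_len(nrow(tree$edge)) %in% x$shift_edges
  )
}
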
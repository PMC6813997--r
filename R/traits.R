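# Trait-matrix plumbing: every model function accepts either a numeric matrix
# with tip-label rownames or a data frame whose first character column labels
# the tips (tidyverse-style input).

#' Coerce trait input to a tip-labelled matrix
#'
#' Accepts a numeric matrix/vector with tip labels as (row)names, or a data
#' frame with one character column of tip labels and numeric trait columns.
#' If a tree is supplied, rows are checked and reordered to match its tip
#' labels exactly.
#'
#' @param x Traits as matrix, named vector, data frame or tibble.
#' @param tree Optional `phylo` object to match against.
#' @return A numeric matrix, rows named by tip.
#' @export
as_trait_matrix <- function(x, tree = NULL) {
  if (is.data.frame(x)) {
    chr <- vapply(x, function(col) is.character(col) || is.factor(col), logical(1))
    if (!any(chr)) stop("data-frame traits need a character column of tip labels")
    lab <- as.character(x[[which(chr)[1]]])
    m <- as.matrix(x[, !chr, drop = FALSE])
    rownames(m) <- lab
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.numeric(x)) {
    m <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  } else {
    stop("cannot interpret `x` as a trait matrix")
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("trait", seq_len(ncol(m)))
  if (!is.null(tree)) {
    if (is.null(rownames(m))) stop("trait rows must be named by tip label")
    missing_tips <- setdiff(tree$tip.label, rownames(m))
    extra <- setdiff(rownames(m), tree$tip.label)
    if (length(missing_tips) || length(extra)) {
      stop("trait/tip label mismatch; missing: [",
           paste(missing_tips, collapse = ", "), "] unmatched: [",
           paste(extra, collapse = ", "), "]")
    }
    m <- m[tree$tip.label, , drop = FALSE]
  }
  m
}

# Solve C x = b through a Cholesky factor; errors on non-PD C.
.chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

.safe_chol <- function(C, what = "covariance matrix") {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out)) stop(what, " is singular or not positive definite")
  out
}
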
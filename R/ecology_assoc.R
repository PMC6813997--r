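# Ecological correlates of regime membership: chi-square tests of
# association between being in a convergent regime and each ecological
# factor (with Bonferroni correction over the realised number of tests), and
# one-way ANOVA of natural-log body mass across groups.

.ecology_factors <- c("habitat", "diet", "feeding", "dive")

#' Read a species ecology table
#'
#' Delimited text with columns `species`, `habitat`, `diet`, `feeding`,
#' `dive`, `mass_kg`; multi-valued cells (species belonging to several
#' categories, e.g. `nearshore|oceanic`) use `|` as separator.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_ecology <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", .ecology_factors, "mass_kg")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("ecology table lacks columns: ", paste(miss, collapse = ", "))
  if (any(x$mass_kg <= 0, na.rm = TRUE)) stop("body masses must be positive")
  x
}

# split multi-valued cells; returns list of category vectors per species
.split_cats <- function(v) strsplit(as.character(v), "|", fixed = TRUE)

#' Chi-square tests of regime membership against ecological factors
#'
#' For one regime, tests membership (in-regime vs all other species) against
#' each ecological factor. Species assigned to several categories of a
#' factor generate assignment variants: variant `k` analyses every ambiguous
#' species as its `k`-th listed category (so a factor with doubly-listed
#' species is tested twice — first-listed, then second-listed — and
#' unambiguous factors once). Each variant builds the membership-by-category
#' contingency table; categories with an empty margin are dropped with a
#' note, and tests with fewer than two remaining categories (or a one-sided
#' membership margin) are recorded as skipped. Pearson chi-square without
#' continuity correction; p-values are Bonferroni-corrected by the total
#' number of tests realised for the regime.
#'
#' @param membership Named character vector, species -> regime label (use
#'   e.g. `"X"` for background species), or a two-column data frame.
#' @param ecology Ecology tibble as from [read_ecology()].
#' @param regime The regime label to test.
#' @param factors Factor columns to test.
#' @return An `association_result` tibble: `regime`, `factor`, `variant`,
#'   `statistic`, `df`, `p_raw`, `p_bonferroni`, `n_tests`, `note`.
#' @export
chi_square_tests <- function(membership, ecology, regime,
                             factors = .ecology_factors) {
  if (is.data.frame(membership)) {
    membership <- setNames(as.character(membership[[2]]),
                           as.character(membership[[1]]))
  }
  sp <- ecology$species
  missing_sp <- setdiff(sp, names(membership))
  if (length(missing_sp)) {
    stop("species without regime membership: ", paste(missing_sp, collapse = ", "))
  }
  member <- factor(ifelse(membership[sp] == regime, "in", "out"),
                   levels = c("in", "out"))
  rows <- list()
  for (fac in factors) {
    cats <- .split_cats(ecology[[fac]])
    n_var <- max(lengths(cats))
    for (k in seq_len(n_var)) {
      assigned <- vapply(cats, function(cc) cc[[min(k, length(cc))]], character(1))
      tab <- table(member, assigned)
      note <- NA_character_
      empty <- colSums(tab) == 0
      if (any(empty)) {
        note <- paste("dropped empty categories:",
                      paste(colnames(tab)[empty], collapse = ", "))
        tab <- tab[, !empty, drop = FALSE]
      }
      if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
        rows[[length(rows) + 1]] <- tibble(
          regime = regime, factor = fac, variant = k,
          statistic = NA_real_, df = NA_integer_, p_raw = NA_real_,
          note = paste(stats::na.omit(c(note, "skipped: degenerate table")),
                       collapse = "; ")
        )
        next
      }
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1]] <- tibble(
        regime = regime, factor = fac, variant = k,
        statistic = unname(ct$statistic), df = as.integer(ct$parameter),
        p_raw = unname(ct$p.value), note = note
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  n_tests <- sum(!is.na(out$p_raw))
  out$n_tests <- n_tests
  out$p_bonferroni <- pmin(1, out$p_raw * n_tests)
  structure(
    dplyr::select(out, "regime", "factor", "variant", "statistic", "df",
                  "p_raw", "p_bonferroni", "n_tests", "note"),
    class = c("association_result", class(out))
  )
}

#' One-way ANOVA of log body mass across groups
#'
#' Natural-log transforms the masses and fits a one-way ANOVA;
#' `F = (SSB/(g-1)) / (SSW/(N-g))`.
#'
#' @param masses Named numeric vector (kg), species -> mass, or a data frame
#'   with species and mass columns.
#' @param groups Named character vector, species -> group label.
#' @return One-row tibble: `F`, `df1`, `df2`, `p_value`, `n`, `n_groups`.
#' @export
body_size_anova <- function(masses, groups) {
  if (is.data.frame(masses)) {
    masses <- setNames(as.numeric(masses[[2]]), as.character(masses[[1]]))
  }
  if (any(masses <= 0)) stop("body masses must be positive")
  sp <- intersect(names(masses), names(groups))
  if (length(sp) < 3) stop("too few species with both mass and group")
  g <- factor(groups[sp])
  if (nlevels(g) < 2) stop("at least two groups are required")
  y <- log(masses[sp])
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (ssw <= 0) stop("zero within-group variance: F undefined")
  fit <- lm(y ~ g)
  a <- anova(fit)
  tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
         p_value = a$`Pr(>F)`[1], n = length(sp), n_groups = nlevels(g))
}
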
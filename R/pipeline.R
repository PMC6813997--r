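# End-to-end orchestration: morphometrics -> phylogenetic signal -> regime
# search -> per-regime convergence metrics and Wheatsheaf -> ecology tests,
# driven by a declarative config, with every output written as plain text
# and every stochastic stage seeded from one dataset seed.

#' Build and validate a pipeline configuration
#'
#' @param tree A `phylo` object or path to a Newick file.
#' @param landmarks Optional `landmark_set` or directory of `.pts` files.
#' @param scores Optional precomputed score matrix (tip-labelled) or CSV path
#'   (first column = specimen); used when no landmarks are given.
#' @param scheme Optional `semilandmark_scheme` (or JSON path) for sliding.
#' @param ecology Optional ecology tibble or CSV path.
#' @param stages Stages to run, a subset of
#'   `c("morphometrics", "signal", "surface", "cmetrics", "wheatsheaf",
#'   "ecology")`.
#' @param n_pcs_surface Leading PCs used as traits in the regime search
#'   (default 2: the per-trait OU independence assumption argues for few).
#' @param n_pcs_metrics Leading PCs for the C-metrics and Wheatsheaf stages
#'   (default 30, roughly the components carrying 95% of shape variance in a
#'   dense landmark set; capped at what the data provide).
#' @param n_sim BM simulations for C-metric significance (default 1000).
#' @param n_perm Permutations for the signal test (default 999).
#' @param n_boot Bootstraps for the Wheatsheaf p-value (default 1000).
#' @param focal_sets Named list of extra tip-label sets to test for
#'   convergence in addition to the detected convergent regimes (e.g. an a
#'   priori ecological guild).
#' @param seed Integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, landmarks = NULL, scores = NULL,
                            scheme = NULL, ecology = NULL,
                            stages = c("morphometrics", "signal", "surface",
                                       "cmetrics", "wheatsheaf", "ecology"),
                            n_pcs_surface = 2, n_pcs_metrics = 30,
                            n_sim = 1000, n_perm = 999, n_boot = 1000,
                            focal_sets = list(), seed = 1,
                            out_dir = tempfile("convergr_run_")) {
  if (is.character(tree)) tree <- read_newick(file = tree)
  if (is.character(landmarks)) landmarks <- read_pts_dir(landmarks)
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  if (is.character(ecology)) ecology <- read_ecology(ecology)
  if (is.character(scores)) {
    scores <- as_trait_matrix(readr::read_csv(scores, show_col_types = FALSE))
  }
  stopifnot(n_pcs_surface >= 1, n_pcs_metrics >= 1,
            n_sim >= 99, n_perm >= 99, n_boot >= 99)
  structure(
    list(tree = tree, landmarks = landmarks, scores = scores, scheme = scheme,
         ecology = ecology, stages = stages, n_pcs_surface = n_pcs_surface,
         n_pcs_metrics = n_pcs_metrics, n_sim = n_sim, n_perm = n_perm,
         n_boot = n_boot, focal_sets = focal_sets, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; file paths
#' (`tree`, `landmarks`, `scores`, `scheme`, `ecology`, `out_dir`) are
#' resolved relative to the YAML file's directory. `focal_sets` is a named
#' mapping of set name to a list of tip labels.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    if (file.exists(p) || dir.exists(p)) return(p)
    file.path(base, p)
  }
  args <- y
  for (f in c("tree", "landmarks", "scores", "scheme", "ecology", "out_dir")) {
    if (!is.null(args[[f]])) args[[f]] <- resolve(args[[f]])
  }
  if (!is.null(args$focal_sets)) {
    args$focal_sets <- lapply(args$focal_sets, unlist)
  }
  do.call(pipeline_config, args)
}

.stage <- function(name, manifest_env, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest_env$completed <- c(manifest_env$completed, name)
  res
}

#' Run the full convergence-detection pipeline
#'
#' Executes the configured stages in order: Procrustes alignment (with
#' optional semilandmark sliding) and shape PCA when landmarks are supplied;
#' the K_mult permutation test on all PC scores; the two-phase stepwise OU
#' regime search on the leading PCs; C-metrics with BM-simulation
#' significance and the Wheatsheaf analysis for every detected convergent
#' regime (plus any user-declared focal sets); and the ecology association
#' tests. Tables are written to `out_dir` as CSV/JSON
#' (`scores.csv`, `signal.csv`, `table1.json`/`table1.csv` model comparison,
#' `table2.csv` C-metrics, `table3.csv` Wheatsheaf, `assoc.csv`,
#' `anova.csv`, `manifest.json`); identical config and seed give
#' byte-identical outputs. A stage failure propagates with the stage name;
#' outputs of completed stages are retained and the manifest records the
#' completion state.
#'
#' @param config A `pipeline_config` (or arguments forwarded to
#'   [pipeline_config()]).
#' @return Invisibly, a list with the stage results (`shape`, `signal`,
#'   `surface`, `cmetrics`, `wheatsheaf`, `assoc`, `anova`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(); env$completed <- character(0)
  seeds <- list(signal = .subseed(config$seed, 11),
                cmetrics = .subseed(config$seed, 12),
                wheatsheaf = .subseed(config$seed, 13))
  results <- list()
  tree <- validate_tree(config$tree)
  on.exit(.write_manifest(config, env, seeds), add = TRUE)

  scores <- config$scores
  if ("morphometrics" %in% config$stages && !is.null(config$landmarks)) {
    results$shape <- .stage("morphometrics", env, {
      lms <- config$landmarks
      if (!is.null(config$scheme)) {
        lms <- slide_semilandmarks(lms, config$scheme)
      }
      shape_pca(gpa(lms))
    })
    scores <- score_matrix(results$shape)
    readr::write_csv(results$shape$scores, file.path(config$out_dir, "scores.csv"))
  } else if (!is.null(scores)) {
    readr::write_csv(
      dplyr::bind_cols(tibble(specimen = rownames(scores)), as_tibble(scores)),
      file.path(config$out_dir, "scores.csv")
    )
  }
  if (is.null(scores)) {
    if (any(c("signal", "surface", "cmetrics", "wheatsheaf") %in% config$stages)) {
      stop("no landmarks or scores supplied for trait-based stages")
    }
    return(invisible(c(results, list(manifest = env$completed))))
  }

  if ("signal" %in% config$stages) {
    results$signal <- .stage("signal", env,
      kmult(scores, tree, n_perm = config$n_perm, seed = seeds$signal))
    readr::write_csv(tidy(results$signal), file.path(config$out_dir, "signal.csv"))
  }

  focal_sets <- config$focal_sets
  if ("surface" %in% config$stages) {
    results$surface <- .stage("surface", env, {
      y <- scores[, seq_len(min(config$n_pcs_surface, ncol(scores))), drop = FALSE]
      surface_search(y, tree)
    })
    .write_table1(results$surface, config$out_dir)
    focal_sets <- c(convergent_regime_tips(results$surface), focal_sets)
  }

  m_scores <- scores[, seq_len(min(config$n_pcs_metrics, ncol(scores))), drop = FALSE]
  if ("cmetrics" %in% config$stages && length(focal_sets) > 0) {
    results$cmetrics <- .stage("cmetrics", env, {
      purrr::imap(focal_sets, function(fs, nm) {
        c_metrics_significance(m_scores, tree, fs, n_sim = config$n_sim,
                               seed = seeds$cmetrics)
      })
    })
    tab2 <- purrr::imap_dfr(results$cmetrics, function(r, nm) {
      dplyr::mutate(tidy(r), regime = nm, .before = 1)
    })
    readr::write_csv(tab2, file.path(config$out_dir, "table2.csv"))
  }

  if ("wheatsheaf" %in% config$stages && length(focal_sets) > 0) {
    results$wheatsheaf <- .stage("wheatsheaf", env, {
      purrr::imap(focal_sets, function(fs, nm) {
        wheatsheaf(m_scores, tree, fs, n_boot = config$n_boot,
                   seed = seeds$wheatsheaf)
      })
    })
    tab3 <- purrr::imap_dfr(results$wheatsheaf, function(r, nm) {
      dplyr::mutate(tidy(r), regime = nm, .before = 1)
    })
    readr::write_csv(tab3, file.path(config$out_dir, "table3.csv"))
  }

  if ("ecology" %in% config$stages && !is.null(config$ecology) &&
      length(focal_sets) > 0) {
    eco <- config$ecology
    membership <- setNames(rep("X", length(tree$tip.label)), tree$tip.label)
    for (nm in names(focal_sets)) membership[focal_sets[[nm]]] <- nm
    results$assoc <- .stage("ecology", env, {
      purrr::map_dfr(names(focal_sets), function(nm) {
        chi_square_tests(membership, eco, regime = nm)
      })
    })
    readr::write_csv(results$assoc, file.path(config$out_dir, "assoc.csv"))
    results$anova <- .stage("ecology_anova", env, {
      masses <- setNames(eco$mass_kg, eco$species)
      body_size_anova(masses, membership)
    })
    readr::write_csv(results$anova, file.path(config$out_dir, "anova.csv"))
  }

  results$manifest <- env$completed
  invisible(results)
}

.write_table1 <- function(surf, out_dir) {
  g <- glance(surf)
  theta <- as_tibble(surf$fit$theta, rownames = "regime")
  tab1 <- list(
    AICc = list(multipeak = surf$fit$AICc, OU1 = surf$fit_ou1$AICc,
                BM = surf$fit_bm$AICc),
    regimes = g$n_regimes, shifts = g$n_shifts,
    convergent_regimes = g$n_convergent_regimes,
    convergent_shifts = g$n_convergent_shifts,
    convergence_fraction = g$convergence_fraction,
    parameters = surf$fit$params,
    theta = theta
  )
  jsonlite::write_json(tab1, file.path(out_dir, "table1.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(tidy(surf), file.path(out_dir, "table1.csv"))
}

.write_manifest <- function(config, env, seeds) {
  manifest <- list(
    completed = env$completed,
    seed = config$seed,
    stage_seeds = seeds,
    n_pcs_surface = config$n_pcs_surface,
    n_pcs_metrics = config$n_pcs_metrics,
    n_sim = config$n_sim, n_perm = config$n_perm, n_boot = config$n_boot,
    package_version = as.character(utils::packageVersion("convergr"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}
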
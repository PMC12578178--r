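# End-to-end driver: quarterly files -> cohort -> signal table -> risk model.

#' Run the full DIMD signal-detection pipeline on a directory of quarters
#'
#' Reads every quarter found under `dir`, builds the deduplicated cohort,
#' scores all drugs with the four disproportionality algorithms, applies the
#' univariate screen, selects covariates by stratified-CV LASSO, fits the
#' multivariable logistic model with Bonferroni correction, and evaluates the
#' ROC AUC. Deterministic given `seed`.
#'
#' @param dir directory of FAERS-format quarterly files.
#' @param quarters optional quarter labels (default: autodetect).
#' @param pts case-defining normalized PTs.
#' @param seed seed for the LASSO fold assignment.
#' @param min_count minimum case count for the combined signal rule.
#' @param screen_min_count,screen_alpha univariate screen cutoffs.
#' @param nfolds LASSO CV folds.
#' @param use_lasso fit the logistic model on the LASSO-selected covariates
#'   (default) or on all screened covariates.
#' @param exclude_outliers passed to [build_cohort()].
#' @return list of class `dimd_pipeline`: `cohort`, `summary`, `signals`,
#'   `volcano`, `screened`, `design`, `lasso`, `fit`, `auc`.
#' @export
run_dimd_pipeline <- function(dir, quarters = NULL, pts = dimd_pts(),
                              seed = 1, min_count = 3,
                              screen_min_count = 100, screen_alpha = 0.01,
                              nfolds = 10, use_lasso = TRUE,
                              exclude_outliers = TRUE) {
  qs <- read_faers_quarters(dir, quarters)
  cohort <- build_cohort(qs, pts = pts, exclude_outliers = exclude_outliers)
  signals <- drug_signals(cohort, min_count = min_count)
  screened <- univariate_screen(signals, min_count = screen_min_count,
                                alpha = screen_alpha)
  design <- build_design(cohort, screened)
  lasso <- lasso_select(design, nfolds = nfolds, seed = seed)
  covs <- if (use_lasso) lasso$selected else design$covariates
  if (!length(covs)) covs <- design$covariates  # LASSO emptied: fall back
  fit <- fit_logistic(design, covs)
  auc <- roc_auc(design$y, fit$fitted)
  structure(list(cohort = cohort,
                 summary = summarize_baseline(cohort),
                 signals = signals,
                 volcano = volcano_table(signals),
                 screened = screened, design = design, lasso = lasso,
                 fit = fit, auc = auc),
            class = "dimd_pipeline")
}

#' @export
print.dimd_pipeline <- function(x, ...) {
  cat(sprintf(
    "<dimd_pipeline> %d reports, %d DIMD cases, %d drugs scored, %d signals\n",
    nrow(x$cohort$reports), sum(x$cohort$reports$is_dimd_case),
    nrow(x$signals), sum(x$signals$is_signal)))
  cat(sprintf("  screen kept %d drug(s); LASSO selected %d covariate(s); AUC %.3f\n",
              length(x$screened), length(x$lasso$selected), x$auc))
  invisible(x)
}
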
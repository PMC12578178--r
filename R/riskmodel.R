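# Sensitivity analysis: complete-case extraction, univariate screening of the
# signal table, LASSO variable selection (glmnet), multivariable logistic
# regression with Bonferroni correction, and ROC/AUC.

#' Complete-case report subset
#'
#' Keeps reports with non-missing sex and age, the covariates the risk model
#' conditions on.
#'
#' @param cohort a `dimd_cohort`.
#' @return data.table of retained report rows.
#' @export
complete_cases <- function(cohort) {
  stopifnot(inherits(cohort, "dimd_cohort"))
  r <- cohort$reports[!is.na(sex) & !is.na(age_years)]
  if (!nrow(r)) stop("no complete-case reports (sex and age)", call. = FALSE)
  r
}

#' Univariate drug screen
#'
#' Retains drugs with `ror_lo > 1`, `a > min_count` and `p_adjust < alpha`
#' (all strict inequalities; a drug with exactly `min_count` cases is
#' excluded).
#'
#' @param signals a `signal_table` from [drug_signals()].
#' @param min_count case-count cutoff (default 100).
#' @param alpha Bonferroni-adjusted p cutoff (default 0.01).
#' @return character vector of screened drug names.
#' @export
univariate_screen <- function(signals, min_count = 100, alpha = 0.01) {
  s <- as.data.table(signals)
  s[!is.na(ror_lo) & ror_lo > 1 & a > min_count &
      !is.na(p_adjust) & p_adjust < alpha]$drug
}

#' Build the binary design matrix for the risk model
#'
#' One row per complete-case report; covariates are male sex, age strictly
#' below the `age_cut` (a report aged exactly `age_cut` scores 0), one
#' prime-suspect exposure indicator per screened drug, and the cohort's
#' comorbidity flags. Constant columns are retained with a warning (the
#' LASSO handles them).
#'
#' @param cohort a `dimd_cohort`.
#' @param drugs character vector of screened (normalized) drug names.
#' @param reports report subset to use; defaults to
#'   [complete_cases()] of the cohort.
#' @param age_cut dichotomization age in years (default 33).
#' @return list of class `dimd_design`: `y` (0/1 outcome), `x` (sparse
#'   binary matrix), `covariates` (column names).
#' @export
build_design <- function(cohort, drugs, reports = complete_cases(cohort),
                         age_cut = 33) {
  stopifnot(inherits(cohort, "dimd_cohort"))
  r <- reports
  y <- as.integer(r$is_dimd_case)
  cols <- list(male = as.integer(r$sex == "M"),
               age_lt33 = as.integer(r$age_years < age_cut))
  exp_tab <- cohort$drugs[drug %in% drugs]
  for (dg in drugs) {
    pid <- exp_tab$primaryid[exp_tab$drug == dg]
    cols[[make.names(dg)]] <- as.integer(r$primaryid %in% pid)
  }
  for (fl in cohort$comorbidity_flags) {
    cols[[fl]] <- as.integer(r[[fl]])
  }
  x <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  colnames(x) <- names(cols)
  const <- which(apply(x, 2, function(col) length(unique(col)) == 1))
  if (length(const))
    warning("constant design column(s) retained: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  structure(list(y = y, x = x, covariates = colnames(x)),
            class = "dimd_design")
}

#' LASSO variable selection with stratified cross-validation
#'
#' L1-penalized logistic path (glmnet: `alpha = 1`, `standardize = TRUE`,
#' `thresh = 1e-6`, `maxit = 1e5`) with outcome-stratified 10-fold
#' cross-validation; the selected set is the covariates with non-zero
#' coefficients at `lambda.min`. Bit-reproducible given the seed.
#'
#' @param design a `dimd_design`.
#' @param nfolds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param type_measure CV loss: `"deviance"` (default, the natural logistic
#'   loss) or `"mse"`.
#' @return list of class `lasso_result`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `selected`, `seed`, `nfolds`, `warnings`, and the
#'   underlying `cv_fit`.
#' @export
lasso_select <- function(design, nfolds = 10, seed = 1,
                         type_measure = c("deviance", "mse")) {
  stopifnot(inherits(design, "dimd_design"))
  type_measure <- match.arg(type_measure)
  y <- design$y
  if (length(unique(y)) < 2)
    stop("outcome has a single class; LASSO undefined", call. = FALSE)
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  warns <- character(0)
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(design$x, y, family = "binomial", alpha = 1,
                      standardize = TRUE, thresh = 1e-6, maxit = 1e5,
                      foldid = foldid, type.measure = type_measure),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- coef(cv, s = "lambda.min")
  nz <- rownames(cf)[as.vector(cf != 0)]
  selected <- setdiff(nz, "(Intercept)")
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = cv$lambda.min, selected = selected,
                 seed = seed, nfolds = nfolds, type_measure = type_measure,
                 warnings = warns, cv_fit = cv),
            class = "lasso_result")
}

#' Multivariable logistic regression with Bonferroni correction
#'
#' Maximum-likelihood logistic fit of the outcome on the selected covariates,
#' with Wald 95% confidence intervals on the odds-ratio scale and Bonferroni
#' correction over the tested covariates. Complete separation raises an
#' error naming the offending covariate.
#'
#' @param design a `dimd_design`.
#' @param covariates covariate names to include (default all).
#' @return list of class `logistic_fit`: `table` (term, estimate, se, or,
#'   or_lo, or_hi, p, p_bonferroni), `intercept`, `fitted`, `converged`, `n`.
#' @export
fit_logistic <- function(design, covariates = design$covariates) {
  stopifnot(inherits(design, "dimd_design"))
  if (!length(covariates)) stop("no covariates selected", call. = FALSE)
  miss <- setdiff(covariates, design$covariates)
  if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(as.matrix(design$x[, covariates, drop = FALSE]))
  df$.y <- design$y
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (sep_warn || any(abs(est[-1]) > 15)) {
    worst <- names(est[-1])[which.max(abs(est[-1]))]
    stop("complete or quasi-complete separation in logistic fit ",
         "(covariate: ", worst, ")", call. = FALSE)
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  k <- length(est) - 1L
  idx <- setdiff(names(est), "(Intercept)")
  tab <- data.frame(
    term = idx, estimate = est[idx], se = se[idx], or = exp(est[idx]),
    or_lo = exp(est[idx] - qnorm(0.975) * se[idx]),
    or_hi = exp(est[idx] + qnorm(0.975) * se[idx]),
    p = p[idx], p_bonferroni = pmin(1, p[idx] * k), row.names = NULL)
  structure(list(table = tab, intercept = unname(est["(Intercept)"]),
                 fitted = fit$fitted.values, converged = fit$converged,
                 n = nrow(df), k = k),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, %d covariates (converged: %s)\n",
              x$n, x$k, x$converged))
  print(x$table, digits = 4)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie correction: the
#' probability a random case outscores a random control, counting ties as
#' one half.
#'
#' @param y 0/1 (or logical) outcome vector.
#' @param scores numeric risk scores or fitted probabilities.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, scores) {
  y <- as.integer(y)
  stopifnot(length(y) == length(scores), all(y %in% 0:1))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
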
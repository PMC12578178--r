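test_that("complete-case extraction keeps reports with sex and age", {
  cohort <- make_cohort(
    primaryid = 1:10, is_dimd_case = rep(c(TRUE, FALSE), 5),
    sex = c(rep("F", 7), NA, "M", NA),
    age_years = c(NA, 20:27, NA))
  cc <- complete_cases(cohort)
  expect_equal(nrow(cc), 7L)   # 3 incomplete dropped
  expect_true(all(!is.na(cc$sex) & !is.na(cc$age_years)))
  empty <- make_cohort(primaryid = 1:2, is_dimd_case = c(TRUE, FALSE),
                       sex = c(NA, NA), age_years = c(NA, NA))
  expect_error(complete_cases(empty), "complete-case")
})

test_that("the univariate screen applies strict cutoffs", {
  s <- data.table::data.table(
    drug = c("keep", "a_at_cut", "weak_ror", "weak_p"),
    a = c(150, 100, 150, 150),
    ror_lo = c(1.2, 1.2, 0.99, 1.2),
    p_adjust = c(0.001, 0.001, 0.001, 0.01))
  expect_identical(univariate_screen(s), "keep")
  s2 <- data.table::copy(s)[drug == "a_at_cut", a := 101]
  expect_setequal(univariate_screen(s2), c("keep", "a_at_cut"))
})

test_that("the design matrix encodes demographics, drugs and flags as 0/1", {
  cohort <- make_cohort(
    primaryid = 1:6, is_dimd_case = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    drugs = data.frame(primaryid = c(1, 2, 5), drug = "X"),
    sex = c("M", "F", "M", "F", "F", "M"),
    age_years = c(30, 33, 32.9, 40, 70, 33.0001),
    flags = list(parkinsons = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)))
  d <- build_design(cohort, drugs = "X")
  expect_s3_class(d, "dimd_design")
  x <- as.matrix(d$x)
  expect_setequal(colnames(x), c("male", "age_lt33", "X", "parkinsons"))
  expect_equal(unname(x[, "male"]), c(1, 0, 1, 0, 0, 1))
  # age exactly 33 scores 0 (strict boundary); 32.9 scores 1
  expect_equal(unname(x[, "age_lt33"]), c(1, 0, 1, 0, 0, 0))
  expect_equal(unname(x[, "X"]), c(1, 1, 0, 0, 1, 0))
  expect_equal(unname(x[, "parkinsons"]), c(1, 0, 0, 1, 0, 0))
  expect_true(all(x %in% 0:1))
  # unexposed-everywhere drug: constant column retained with a warning
  expect_warning(build_design(cohort, drugs = c("X", "ABSENT")), "constant")
})

test_that("LASSO at the heavy-penalty end selects nothing", {
  set.seed(1)
  cohort <- make_cohort(
    primaryid = 1:400, is_dimd_case = runif(400) < 0.3,
    drugs = data.frame(primaryid = sample(1:400, 120), drug = "X"),
    sex = sample(c("F", "M"), 400, TRUE), age_years = sample(20:80, 400, TRUE))
  d <- build_design(cohort, "X")
  fit <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 1,
                        lambda = 10, standardize = TRUE)
  expect_equal(sum(coef(fit)[-1] != 0), 0)
})

test_that("the penalized path converges to the unpenalized logistic fit", {
  set.seed(2)
  n <- 4000
  x1 <- rbinom(n, 1, 0.3); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x1 - 0.5 * x2))
  cohort <- make_cohort(
    primaryid = 1:n, is_dimd_case = y == 1,
    drugs = data.frame(primaryid = which(x1 == 1), drug = "X"),
    sex = ifelse(x2 == 1, "M", "F"), age_years = rep(50, n))
  d <- suppressWarnings(build_design(cohort, "X"))  # age column constant here
  keep <- c("male", "X")
  lfit <- glmnet::glmnet(d$x[, keep], d$y, family = "binomial", alpha = 1,
                         lambda = c(0.1, 0.01, 0), thresh = 1e-12,
                         standardize = TRUE, maxit = 1e6)
  gfit <- glm(d$y ~ as.matrix(d$x[, keep]), family = binomial())
  expect_equal(as.vector(coef(lfit, s = 0))[-1], unname(coef(gfit))[-1],
               tolerance = 1e-3)
})

test_that("LASSO selection is seed-reproducible and stable for a strong effect", {
  set.seed(42)
  n <- 20000; p_null <- 20
  z <- rbinom(n, 1, 0.05)
  y <- rbinom(n, 1, plogis(qlogis(0.05) + log(8) * z))
  nulls <- matrix(rbinom(n * p_null, 1, 0.05), n, p_null)
  x <- Matrix::Matrix(cbind(strong = z, nulls), sparse = TRUE)
  colnames(x) <- c("strong", paste0("null", seq_len(p_null)))
  design <- structure(list(y = y, x = x, covariates = colnames(x)),
                      class = "dimd_design")
  sel1 <- lasso_select(design, seed = 7)
  sel2 <- lasso_select(design, seed = 7)
  expect_identical(sel1$lambda_min, sel2$lambda_min)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$cvm, sel2$cvm)
  hits <- vapply(1:20, function(s)
    "strong" %in% lasso_select(design, seed = s)$selected, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the logistic fit recovers a designed odds ratio and flags nulls", {
  set.seed(9)
  n <- 50000
  z <- rbinom(n, 1, 0.1)
  znull <- rbinom(n, 1, 0.2)
  y <- rbinom(n, 1, plogis(qlogis(0.05) + log(4) * z))
  x <- Matrix::Matrix(cbind(exposed = z, noise = znull), sparse = TRUE)
  design <- structure(list(y = y, x = x, covariates = colnames(x)),
                      class = "dimd_design")
  fit <- fit_logistic(design)
  row <- fit$table[fit$table$term == "exposed", ]
  expect_gt(row$or_hi, 4); expect_lt(row$or_lo, 4)
  nullrow <- fit$table[fit$table$term == "noise", ]
  expect_gt(nullrow$p_bonferroni, 0.2)
  expect_true(all(fit$table$or_lo <= fit$table$or &
                    fit$table$or <= fit$table$or_hi))
  expect_true(all(fit$table$p_bonferroni >= fit$table$p))
})

test_that("a saturated single-covariate logistic equals the 2x2 odds ratio", {
  a <- 20; b <- 30; cc <- 15; d <- 60
  y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  z <- c(rep(1, a + b), rep(0, cc + d))
  design <- structure(list(y = y,
                           x = Matrix::Matrix(cbind(z = z), sparse = TRUE),
                           covariates = "z"), class = "dimd_design")
  fit <- fit_logistic(design)
  expect_equal(fit$table$or, (a * d) / (b * cc), tolerance = 1e-6)
})

test_that("complete separation raises an error naming the covariate", {
  y <- rep(c(1, 0), each = 50)
  z <- y
  design <- structure(list(y = y,
                           x = Matrix::Matrix(cbind(sep_drug = z), sparse = TRUE),
                           covariates = "sep_drug"), class = "dimd_design")
  expect_error(fit_logistic(design), "separation.*sep_drug")
})

test_that("AUC follows the Mann-Whitney formulation with ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.85)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both outcome classes")
  # invariance under strictly monotone transforms
  set.seed(6)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200)
  base <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), base)
  expect_equal(roc_auc(y, 5 * s - 3), base)
  expect_equal(roc_auc(y, plogis(s)), base)
  # independent cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
    expect_equal(base, want, tolerance = 1e-12)
  }
})

test_that("the full pipeline runs end to end on a small synthetic world", {
  cfg <- faers_config(n_reports = 8000, seed = 55)
  dir <- tempfile()
  faers_generate(cfg, dir)
  pl <- run_dimd_pipeline(dir, seed = 55)
  expect_s3_class(pl, "dimd_pipeline")
  expect_true(all(c("ror", "prr", "ic", "ebgm", "fisher_p", "p_adjust",
                    "is_signal") %in% names(pl$signals)))
  expect_true(pl$auc >= 0 && pl$auc <= 1)
  expect_true(is.character(pl$screened))
  expect_output(print(pl), "dimd_pipeline")
})
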
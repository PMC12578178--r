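# Disproportionality statistics on per-drug 2x2 tables.
#
# Table layout, with "the event" = any DIMD preferred term and "the drug" =
# prime-suspect exposure:
#
#                 DIMD      other events
#   target drug     a            b
#   other drugs     c            d
#
# ROR = ad/bc with a Wald CI on the log scale; PRR = [a/(a+b)]/[c/(c+d)] with
# a Pearson chi-squared; the BCPNN information component is the exact
# posterior mean of log2(p11/(p1. p.1)) under independent Beta posteriors;
# EBGM is the DuMouchel gamma-Poisson shrinker with a two-component gamma
# prior fitted by marginal maximum likelihood across all drugs.

#' Per-drug 2x2 contingency table
#'
#' @param cohort a `dimd_cohort`.
#' @param drug normalized drug name; a drug absent from the cohort yields
#'   `a = b = 0` (not an error).
#' @return named integer-ish vector `c(a, b, c, d)`.
#' @export
contingency_table <- function(cohort, drug) {
  ct <- contingency_all(cohort)
  N <- nrow(cohort$reports)
  ncase <- sum(cohort$reports$is_dimd_case)
  i <- match(drug, ct$drug)
  if (is.na(i)) return(c(a = 0, b = 0, c = ncase, d = N - ncase))
  unlist(ct[i, .(a, b, c, d)])
}

#' All per-drug 2x2 tables in a cohort
#'
#' One row per drug appearing in the cohort's exposure table.
#'
#' @param cohort a `dimd_cohort`.
#' @return data.table with columns `drug`, `a`, `b`, `c`, `d`.
#' @export
contingency_all <- function(cohort) {
  stopifnot(inherits(cohort, "dimd_cohort"))
  rep_ <- cohort$reports
  N <- nrow(rep_)
  ncase <- sum(rep_$is_dimd_case)
  dd <- unique(cohort$drugs[, .(primaryid, drug)])
  dd <- dd[rep_[, .(primaryid, is_dimd_case)], on = "primaryid", nomatch = NULL]
  agg <- dd[, .(n_drug = .N, a = sum(is_dimd_case)), by = drug]
  agg[, `:=`(b = n_drug - a, c = ncase - a, d = N - n_drug - (ncase - a))]
  setorder(agg, drug)
  agg[, .(drug, a = as.numeric(a), b = as.numeric(b),
          c = as.numeric(c), d = as.numeric(d))]
}

# Haldane-Anscombe: +0.5 to every cell of tables containing a zero.
# Cells are coerced to double here: full-scale FAERS margins overflow
# 32-bit integer arithmetic in the chi-squared denominator.
haldane <- function(a, b, c, d, zero_policy) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  z <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (zero_policy == "haldane") {
    list(a = a + 0.5 * z, b = b + 0.5 * z, c = c + 0.5 * z, d = d + 0.5 * z,
         corrected = z)
  } else {
    list(a = a, b = b, c = c, d = d, corrected = rep(FALSE, length(a)))
  }
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ror = ad/bc`; CI `exp(log(ror) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Tables containing a zero cell receive the Haldane-Anscombe +0.5 correction
#' (all cells) and are flagged `corrected`.
#'
#' @param a,b,c,d cell counts (vectorized).
#' @param conf_level confidence level for the Wald interval.
#' @param zero_policy `"haldane"` (default) or `"none"` (zero cells then give
#'   non-finite results).
#' @return data.table with `ror`, `ror_lo`, `ror_hi`, `ror_corrected`.
#' @export
ror_stat <- function(a, b, c, d, conf_level = 0.95, zero_policy = "haldane") {
  h <- haldane(a, b, c, d, zero_policy)
  est <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.table(ror = est, ror_lo = exp(log(est) - z * se),
             ror_hi = exp(log(est) + z * se), ror_corrected = h$corrected)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `prr = [a/(a+b)] / [c/(c+d)]`. The chi-squared is the Pearson statistic on
#' the raw 2x2, without continuity correction by default (`yates = TRUE`
#' applies the Yates correction). Zero cells in the ratio are handled by the
#' same continuity policy as [ror_stat()].
#'
#' @inheritParams ror_stat
#' @param yates apply the Yates continuity correction to the chi-squared.
#' @return data.table with `prr`, `chi2`, `prr_corrected`.
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE, zero_policy = "haldane") {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  h <- haldane(a, b, c, d, zero_policy)
  est <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, N * num^2 / denom, NA_real_)
  data.table(prr = est, chi2 = chi2, prr_corrected = h$corrected)
}

#' BCPNN information component with credible bound
#'
#' Exact posterior moments of `IC = log2(p11 / (p1. * p.1))` where the joint
#' and marginal reporting probabilities carry independent Beta posteriors
#' (priors: `Beta(1, gamma - 1)` for the joint cell with `gamma` calibrated
#' so the prior IC expectation is zero, `Beta(1, 1)` updated against
#' `Beta(2, 2)`-style margins, i.e. alpha1 = beta1 = 1, alpha = beta = 2,
#' gamma11 = 1). Moments are computed with digamma/trigamma (exact for
#' log-Beta moments); `ic025 = ic - 1.96 * sd`. Defined for `a = 0`.
#'
#' @inheritParams ror_stat
#' @return data.table with `ic`, `ic025`, `ic_var`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  eic <- (digamma(a + g11) - digamma(N + g) -
            digamma(a + b + a1) + digamma(N + al) -
            digamma(a + c + b1) + digamma(N + be)) / log(2)
  vic <- (trigamma(a + g11) - trigamma(N + g) +
            trigamma(a + b + a1) - trigamma(N + al) +
            trigamma(a + c + b1) - trigamma(N + be)) / log(2)^2
  data.table(ic = eic, ic025 = eic - qnorm(0.975) * sqrt(vic), ic_var = vic)
}

#' Two-sided Fisher exact p-value
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables no more probable than the observed one (with the customary 1e-7
#' relative guard against floating-point ties).
#'
#' @inheritParams ror_stat
#' @return numeric vector of p-values.
#' @export
fisher_exact <- function(a, b, c, d) {
  one <- function(a, b, c, d) {
    k <- a + b          # reports with the drug
    m <- a + c          # event reports
    n2 <- b + d         # non-event reports
    lo <- max(0, k - n2)
    hi <- min(k, m)
    dd <- dhyper(lo:hi, m, n2, k)
    sum(dd[dd <= dd[a - lo + 1] * (1 + 1e-7)])
  }
  pmin(1, mapply(one, a, b, c, d))
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of raw p-values.
#' @param m family size (default the number of p-values).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

# log marginal likelihood of counts under the two-component gamma-Poisson
# mixture prior; lambda ~ p Gamma(a1, b1) + (1-p) Gamma(a2, b2) (shape, rate)
ebgm_negll <- function(theta, a, expected) {
  l1 <- dnbinom(a, size = theta[1], prob = theta[2] / (theta[2] + expected),
                log = TRUE)
  l2 <- dnbinom(a, size = theta[3], prob = theta[4] / (theta[4] + expected),
                log = TRUE)
  w <- theta[5]
  m <- pmax(l1, l2)
  -sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
}

#' Fit the EBGM gamma-mixture prior by marginal maximum likelihood
#'
#' Maximizes the negative-binomial mixture likelihood of the observed counts
#' `a` given their expectations `E = (a+b)(a+c)/N`, using bounded L-BFGS-B
#' from the fixed documented start (1, 1, 1, 1, 0.5) with box constraints
#' `[1e-6, 1e6]` on shapes/rates. Deterministic given the data.
#'
#' @param a observed counts, one per drug (length >= 2).
#' @param expected expected counts under independence, same length.
#' @param mix_p optionally fix the mixture weight (e.g. `1` for a single
#'   gamma prior) instead of estimating it.
#' @param start numeric(5) starting values `(alpha1, beta1, alpha2, beta2,
#'   mix_p)`.
#' @return object of class `ebgm_prior` with elements `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `mix_p`, `negll`, `counts`, `convergence`.
#' @export
ebgm_fit <- function(a, expected, mix_p = NULL,
                     start = c(1, 1, 1, 1, 0.5)) {
  stopifnot(length(a) == length(expected), all(expected > 0))
  if (length(a) < 2)
    stop("ebgm_fit needs at least 2 drug tables", call. = FALSE)
  lower <- c(rep(1e-6, 4), 1e-6)
  upper <- c(rep(1e6, 4), 1 - 1e-6)
  if (!is.null(mix_p)) {
    stopifnot(mix_p >= 0, mix_p <= 1)
    fn <- function(th) ebgm_negll(c(th, mix_p), a, expected)
    opt <- optim(start[1:4], fn, method = "L-BFGS-B",
                 lower = lower[1:4], upper = upper[1:4],
                 control = list(maxit = 500))
    theta <- c(opt$par, mix_p)
  } else {
    opt <- optim(start, ebgm_negll, a = a, expected = expected,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500))
    theta <- opt$par
  }
  if (opt$convergence != 0)
    stop(sprintf(
      "EBGM hyperparameter fit did not converge (code %d after %s evaluations): %s",
      opt$convergence, paste(opt$counts, collapse = "/"),
      if (is.null(opt$message)) "" else opt$message), call. = FALSE)
  structure(list(alpha1 = theta[1], beta1 = theta[2], alpha2 = theta[3],
                 beta2 = theta[4], mix_p = theta[5], negll = opt$value,
                 counts = opt$counts, convergence = opt$convergence),
            class = "ebgm_prior")
}

#' @export
print.ebgm_prior <- function(x, ...) {
  cat(sprintf(
    "<ebgm_prior> mix_p=%.3f  Gamma(%.3g, %.3g) / Gamma(%.3g, %.3g)  negll=%.2f\n",
    x$mix_p, x$alpha1, x$beta1, x$alpha2, x$beta2, x$negll))
  invisible(x)
}

#' EBGM and EB05 posterior summaries
#'
#' Given the fitted prior, the posterior over the rate ratio lambda for a
#' drug with count `a` and expectation `E` is the two-component gamma mixture
#' with components `Gamma(alpha_j + a, beta_j + E)` and updated weights.
#' `ebgm = 2^(E[log2 lambda | a]) = exp(E[log lambda | a])`; `eb05` is the
#' posterior 5th percentile, found by root-finding on the mixture CDF.
#' Rows with `E = 0` yield `NA` (undefined).
#'
#' @param a observed counts.
#' @param expected expected counts.
#' @param prior an `ebgm_prior`.
#' @return data.table with `ebgm`, `eb05`.
#' @export
ebgm_score <- function(a, expected, prior) {
  stopifnot(inherits(prior, "ebgm_prior"))
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  p <- prior$mix_p
  ok <- is.finite(expected) & expected > 0
  E <- ifelse(ok, expected, 1)  # placeholder, masked below
  lw1 <- log(p) + dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  lw2 <- log1p(-p) + dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  mx <- pmax(lw1, lw2)
  q1 <- exp(lw1 - mx) / (exp(lw1 - mx) + exp(lw2 - mx))
  if (p == 1) q1 <- rep(1, length(a))
  if (p == 0) q1 <- rep(0, length(a))
  meanlog <- q1 * (digamma(a1 + a) - log(b1 + E)) +
    (1 - q1) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- exp(meanlog)
  eb05 <- vapply(seq_along(a), function(i) {
    if (!ok[i]) return(NA_real_)
    cdf <- function(x) {
      q1[i] * pgamma(x, a1 + a[i], rate = b1 + E[i]) +
        (1 - q1[i]) * pgamma(x, a2 + a[i], rate = b2 + E[i]) - 0.05
    }
    lo <- min(qgamma(1e-4, a1 + a[i], rate = b1 + E[i]),
              qgamma(1e-4, a2 + a[i], rate = b2 + E[i]))
    hi <- max(qgamma(0.9, a1 + a[i], rate = b1 + E[i]),
              qgamma(0.9, a2 + a[i], rate = b2 + E[i]))
    uniroot(cdf, lower = lo, upper = hi, extendInt = "upX",
            tol = 1e-10)$root
  }, numeric(1))
  data.table(ebgm = ifelse(ok, ebgm, NA_real_), eb05 = eb05)
}

#' Apply the combined four-algorithm signal rule
#'
#' Flags: `flag_ror = ror_lo > 1 & a >= min_count`; `flag_prr = prr >= 2 &
#' chi2 >= 4 & a >= min_count`; `flag_bcpnn = ic025 > 0`; `flag_ebgm = ebgm >
#' ebgm_threshold` (or `eb05` if `ebgm_metric = "eb05"`). A drug is a signal
#' only when all four flags hold and it has at least `min_count` co-reported
#' cases.
#'
#' @param stats data.table holding at least `a`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm` (and `eb05` if used).
#' @param min_count minimum co-reported case count (default 3).
#' @param ebgm_threshold threshold on the EBGM metric (default 2).
#' @param ebgm_metric `"ebgm"` (default) or `"eb05"`.
#' @return the input with `flag_ror`, `flag_prr`, `flag_bcpnn`, `flag_ebgm`,
#'   `is_signal` columns added.
#' @export
classify_signals <- function(stats, min_count = 3, ebgm_threshold = 2,
                             ebgm_metric = c("ebgm", "eb05")) {
  ebgm_metric <- match.arg(ebgm_metric)
  s <- as.data.table(stats)
  ebgm_val <- s[[ebgm_metric]]
  s[, flag_ror := !is.na(ror_lo) & ror_lo > 1 & a >= min_count]
  s[, flag_prr := !is.na(prr) & !is.na(chi2) & prr >= 2 & chi2 >= 4 &
      a >= min_count]
  s[, flag_bcpnn := !is.na(ic025) & ic025 > 0]
  s[, flag_ebgm := !is.na(ebgm_val) & ebgm_val > ebgm_threshold]
  s[, is_signal := flag_ror & flag_prr & flag_bcpnn & flag_ebgm &
      a >= min_count]
  s[]
}

#' Score every drug in a cohort with all four algorithms
#'
#' Builds the per-drug 2x2 tables, computes ROR (Wald CI), PRR + chi-squared,
#' the BCPNN information component, EBGM/EB05 under a prior fitted across all
#' drugs, Fisher exact p-values with Bonferroni correction (family size = the
#' number of drugs with `a >= 1`), and the combined signal flags.
#'
#' @param cohort a `dimd_cohort`.
#' @param min_count minimum case count for a valid signal (default 3).
#' @param ebgm_threshold,ebgm_metric see [classify_signals()].
#' @param conf_level Wald CI level for the ROR.
#' @param yates use the Yates-corrected chi-squared.
#' @return data.table of class `signal_table`, one row per drug.
#' @export
drug_signals <- function(cohort, min_count = 3, ebgm_threshold = 2,
                         ebgm_metric = "ebgm", conf_level = 0.95,
                         yates = FALSE) {
  ct <- contingency_all(cohort)
  if (!nrow(ct)) stop("cohort has no drug exposure rows", call. = FALSE)
  N <- ct$a + ct$b + ct$c + ct$d
  res <- cbind(
    ct,
    ror_stat(ct$a, ct$b, ct$c, ct$d, conf_level = conf_level),
    prr_stat(ct$a, ct$b, ct$c, ct$d, yates = yates),
    bcpnn_ic(ct$a, ct$b, ct$c, ct$d))
  res[, expected := (a + b) * (a + c) / N]
  prior <- ebgm_fit(res$a, res$expected)
  res <- cbind(res, ebgm_score(res$a, res$expected, prior))
  res[, fisher_p := fisher_exact(a, b, c, d)]
  m <- sum(res$a >= 1)
  res[, p_adjust := bonferroni_adjust(fisher_p, m)]
  res <- classify_signals(res, min_count = min_count,
                          ebgm_threshold = ebgm_threshold,
                          ebgm_metric = ebgm_metric)
  setattr(res, "ebgm_prior", prior)
  setattr(res, "bonferroni_m", m)
  setattr(res, "class", c("signal_table", class(res)))
  res[]
}

#' Volcano-plot coordinate table
#'
#' Plot-ready coordinates for the signal volcano: log10 ROR, -log10 of the
#' Bonferroni-adjusted Fisher p, and log10 case count for the colour scale.
#' Adjusted p-values of exactly zero are replaced by the smallest positive
#' double and flagged. The published description assigns the axes both ways
#' round; `ror_axis` records the intended orientation without changing the
#' columns.
#'
#' @param signals a `signal_table` from [drug_signals()].
#' @param ror_axis `"x"` (default) or `"y"`: which axis carries log10 ROR.
#' @return data.table with `drug`, `log_ror`, `neg_log10_p_adjust`,
#'   `log10_case_count`, `p_zero_replaced`; the axis choice is stored in the
#'   `ror_axis` attribute.
#' @export
volcano_table <- function(signals, ror_axis = c("x", "y")) {
  ror_axis <- match.arg(ror_axis)
  s <- as.data.table(signals)
  p <- s$p_adjust
  zero <- !is.na(p) & p == 0
  p[zero] <- .Machine$double.xmin
  out <- data.table(drug = s$drug, log_ror = log10(s$ror),
                    neg_log10_p_adjust = -log10(p),
                    log10_case_count = log10(pmax(s$a, 1)),
                    p_zero_replaced = zero)
  setattr(out, "ror_axis", ror_axis)
  out[]
}
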
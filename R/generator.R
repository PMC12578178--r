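# Synthetic FAERS world with known ground truth.
#
# Reports are generated one case at a time (vectorised): demographics with
# configurable missingness, prime-suspect exposures to a set of "signal" drugs
# whose DIMD odds multipliers are exact by construction (logistic link), a
# background of null drugs, MedDRA-style reaction/indication terms, and
# injected duplicate report versions sharing a caseid.

#' Default signal-drug specification
#'
#' Four drugs spanning designed odds multipliers 8, 4, 2 and 1 (the last being
#' a null control). Exposure probabilities are graded so that, in a world of
#' 200,000 reports, every non-null drug clears 100 co-reported cases while
#' odds-ratio non-collapsibility across co-exposures stays far inside the
#' sampling error of the marginal 2x2 odds ratio.
#'
#' @return data.frame with columns `drug`, `exposure_prob`,
#'   `dimd_odds_multiplier`.
#' @export
default_drug_specs <- function() {
  data.frame(
    drug = c("METOCLOPRAMIDE", "HALOPERIDOL", "RISPERIDONE", "OMEPRAZOLE"),
    exposure_prob = c(0.008, 0.012, 0.025, 0.020),
    dimd_odds_multiplier = c(8, 4, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' Default comorbidity specification
#'
#' Seven comorbidity flags, each tied to one indication preferred term and a
#' marginal prevalence. Prevalences are independent of the DIMD outcome, so
#' these covariates are true nulls in the risk model.
#'
#' @return data.frame with columns `flag`, `indication_pt`, `prob`.
#' @export
default_comorbidity_specs <- function() {
  data.frame(
    flag = c("parkinsons", "schizophrenia", "affective", "epilepsy",
             "gerd", "nausea_vomiting", "other_cns"),
    indication_pt = c("Parkinson's disease", "Schizophrenia", "Depression",
                      "Epilepsy", "Gastrooesophageal reflux disease",
                      "Nausea", "Migraine"),
    prob = c(0.04, 0.05, 0.10, 0.04, 0.06, 0.10, 0.05),
    stringsAsFactors = FALSE
  )
}

# null background drugs; never associated with the outcome
bg_drug_pool <- function() {
  c("ASPIRIN", "PARACETAMOL", "IBUPROFEN", "METFORMIN", "LISINOPRIL",
    "ATORVASTATIN", "AMLODIPINE", "SIMVASTATIN", "LEVOTHYROXINE",
    "AMOXICILLIN", "PREDNISONE", "WARFARIN", "FUROSEMIDE", "SERTRALINE",
    "ALBUTEROL", "INSULIN GLARGINE", "HYDROCHLOROTHIAZIDE", "CLOPIDOGREL",
    "MONTELUKAST", "RANITIDINE")
}

# non-DIMD reaction preferred terms (natural MedDRA-style case)
bg_pt_pool <- function() {
  c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash", "Vomiting",
    "Diarrhoea", "Insomnia", "Pruritus", "Pyrexia", "Dyspnoea",
    "Arthralgia", "Anxiety", "Constipation", "Oedema peripheral")
}

#' Configure the synthetic FAERS generator
#'
#' All probabilities are validated; the same config + seed always yields
#' byte-identical output files.
#'
#' @param n_reports number of distinct safety reports (duplicate versions are
#'   extra rows on top of these).
#' @param drug_specs data.frame with columns `drug`, `exposure_prob`
#'   (probability of prime-suspect exposure) and `dimd_odds_multiplier`
#'   (multiplier on the DIMD odds; 1 means no association).
#' @param baseline_dimd_prob probability of a DIMD reaction for a report with
#'   no signal-drug exposure.
#' @param duplicate_rate fraction of caseids emitted with more than one
#'   report version.
#' @param sex_probs named numeric over `F`, `M`, `missing`; must sum to 1.
#' @param age_distribution list with `median` (years), `iqr` (length-2 years)
#'   and `missing_rate`.
#' @param weight_distribution list with `median` (kg), `iqr` (length-2 kg) and
#'   `missing_rate`.
#' @param outlier_rate probability a report carries an implausible age
#'   (>= 120 y) or weight (>= 400 kg), split evenly between the two.
#' @param role_probs named numeric over the FAERS role codes `PS`, `SS`, `C`,
#'   `I` used for background drug entries.
#' @param comorbidity_specs data.frame with columns `flag`, `indication_pt`,
#'   `prob` (see [default_comorbidity_specs()]).
#' @param age_unit_probs named numeric over the emitted age unit codes `YR`,
#'   `MON`, `DEC`.
#' @param concomitant_rate probability each signal drug additionally appears
#'   with role `C` on an unexposed report (exercises the prime-suspect
#'   filter; no effect on outcome).
#' @param quarters character vector of quarter labels (`"2024Q1"` style) the
#'   base reports are spread over.
#' @param seed integer RNG seed.
#' @return object of class `faers_config`.
#' @export
faers_config <- function(n_reports = 50000,
                         drug_specs = default_drug_specs(),
                         baseline_dimd_prob = 0.025,
                         duplicate_rate = 0.1,
                         sex_probs = c(F = 0.50, M = 0.40, missing = 0.10),
                         age_distribution = list(median = 53, iqr = c(33, 67),
                                                 missing_rate = 0.43),
                         weight_distribution = list(median = 70, iqr = c(57.2, 85),
                                                    missing_rate = 0.74),
                         outlier_rate = 0.002,
                         role_probs = c(PS = 0.35, SS = 0.20, C = 0.40, I = 0.05),
                         comorbidity_specs = default_comorbidity_specs(),
                         age_unit_probs = c(YR = 0.8, MON = 0.1, DEC = 0.1),
                         concomitant_rate = 0.005,
                         quarters = c("2024Q1", "2024Q2", "2024Q3", "2024Q4"),
                         seed = 1L) {
  stopifnot(is.data.frame(drug_specs),
            all(c("drug", "exposure_prob", "dimd_odds_multiplier") %in%
                  names(drug_specs)))
  chk_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("invalid probability for ", what, ": must be in [0, 1]", call. = FALSE)
  }
  chk_prob(drug_specs$exposure_prob, "drug exposure_prob")
  chk_prob(baseline_dimd_prob, "baseline_dimd_prob")
  chk_prob(duplicate_rate, "duplicate_rate")
  chk_prob(outlier_rate, "outlier_rate")
  chk_prob(concomitant_rate, "concomitant_rate")
  chk_prob(comorbidity_specs$prob, "comorbidity prob")
  chk_prob(age_distribution$missing_rate, "age missing_rate")
  chk_prob(weight_distribution$missing_rate, "weight missing_rate")
  if (any(drug_specs$dimd_odds_multiplier <= 0))
    stop("dimd_odds_multiplier must be > 0", call. = FALSE)
  for (nm in c("sex_probs", "role_probs", "age_unit_probs")) {
    p <- get(nm)
    chk_prob(p, nm)
    if (abs(sum(p) - 1) > 1e-8)
      stop(nm, " must sum to 1", call. = FALSE)
  }
  if (n_reports < 1) stop("n_reports must be >= 1", call. = FALSE)
  if (!grepl("^\\d{4}Q[1-4]$", quarters[1]) || any(!grepl("^\\d{4}Q[1-4]$", quarters)))
    stop("quarters must look like '2024Q1'", call. = FALSE)
  structure(list(
    n_reports = as.integer(n_reports), drug_specs = drug_specs,
    baseline_dimd_prob = baseline_dimd_prob, duplicate_rate = duplicate_rate,
    sex_probs = sex_probs, age_distribution = age_distribution,
    weight_distribution = weight_distribution, outlier_rate = outlier_rate,
    role_probs = role_probs, comorbidity_specs = comorbidity_specs,
    age_unit_probs = age_unit_probs, concomitant_rate = concomitant_rate,
    quarters = quarters, seed = as.integer(seed)
  ), class = "faers_config")
}

quarter_start <- function(q) {
  yr <- as.integer(substr(q, 1, 4))
  qn <- as.integer(substr(q, 6, 6))
  as.Date(sprintf("%04d-%02d-01", yr, (qn - 1L) * 3L + 1L))
}

date_quarter <- function(d) {
  sprintf("%04dQ%d", as.integer(format(d, "%Y")),
          (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
}

yyyymmdd <- function(d) as.integer(format(d, "%Y%m%d"))

# random case variation of drug names so downstream normalization is exercised
mangle_name <- function(x) {
  m <- runif(length(x)) < 0.3
  y <- x
  lower <- tolower(x[m])
  y[m] <- paste0(" ", toupper(substr(lower, 1, 1)), substr(lower, 2, nchar(lower)), " ")
  y
}

# Full in-memory simulation: tables (one data.table per FAERS file type, with
# a `quarter` column) plus ground truth. Deterministic given config.
simulate_faers <- function(config) {
  stopifnot(inherits(config, "faers_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_reports
  specs <- config$drug_specs
  K <- nrow(specs)

  caseid <- 1000000L + seq_len(n)
  base_q <- sample(config$quarters, n, replace = TRUE)
  fda_date <- quarter_start(base_q) + (sample.int(89L, n, replace = TRUE) - 1L)
  event_date <- fda_date - sample.int(120L, n, replace = TRUE)
  event_missing <- runif(n) < 0.2

  ## demographics
  sexp <- config$sex_probs
  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = sexp[c("F", "M", "missing")])
  ad <- config$age_distribution
  age_true <- rnorm(n, ad$median, diff(range(ad$iqr)) / 1.349)
  age_true <- round(pmin(pmax(age_true, 1), 100))
  age_missing <- runif(n) < ad$missing_rate
  unit <- sample(names(config$age_unit_probs), n, replace = TRUE,
                 prob = config$age_unit_probs)
  age_val <- ifelse(unit == "YR", age_true,
                    ifelse(unit == "MON", round(age_true * 12), age_true / 10))
  wd <- config$weight_distribution
  wt <- round(pmin(pmax(rnorm(n, wd$median, diff(range(wd$iqr)) / 1.349), 30), 200), 1)
  wt_missing <- runif(n) < wd$missing_rate

  ## implausible-value outliers, half on age (forces unit YR), half on weight
  u_out <- runif(n)
  out_age <- u_out < config$outlier_rate / 2
  out_wt <- u_out >= config$outlier_rate / 2 & u_out < config$outlier_rate
  age_val[out_age] <- sample(120:139, sum(out_age), replace = TRUE)
  unit[out_age] <- "YR"
  age_missing[out_age] <- FALSE
  wt[out_wt] <- sample(400:500, sum(out_wt), replace = TRUE)
  wt_missing[out_wt] <- FALSE

  occp <- sample(c("CN", "MD", "LW", "OT", "HP", "PH", "RN", ""), n, replace = TRUE,
                 prob = c(0.40, 0.18, 0.14, 0.11, 0.075, 0.043, 0.0004, 0.0516))
  country <- sample(c("US", "GB", "CA", "FR", "DE", "JP", "IT", "NL", "BR", "CN", "ZZ"),
                    n, replace = TRUE,
                    prob = c(0.62, 0.062, 0.044, 0.033, 0.024, 0.022, 0.013,
                             0.012, 0.011, 0.010, 0.149))

  ## prime-suspect exposures and logistic outcome: odds multiplied per PS drug
  expo <- matrix(runif(n * K) < rep(specs$exposure_prob, each = n), n, K)
  eta <- qlogis(config$baseline_dimd_prob) +
    as.vector(expo %*% log(specs$dimd_odds_multiplier))
  is_dimd <- runif(n) < plogis(eta)
  conc <- matrix(runif(n * K) < config$concomitant_rate, n, K) & !expo

  ## comorbidity indications (independent of outcome)
  cs <- config$comorbidity_specs
  com <- matrix(runif(n * nrow(cs)) < rep(cs$prob, each = n), n, nrow(cs))

  ## drug rows: signal PS + signal concomitant + 1-3 background drugs
  sig_ps <- data.table(caseid = caseid[row(expo)[expo]],
                       drugname = specs$drug[col(expo)[expo]], role_cod = "PS")
  sig_c <- data.table(caseid = caseid[row(conc)[conc]],
                      drugname = specs$drug[col(conc)[conc]], role_cod = "C")
  nbg <- sample.int(3L, n, replace = TRUE)
  bg <- data.table(caseid = rep(caseid, nbg),
                   drugname = sample(bg_drug_pool(), sum(nbg), replace = TRUE),
                   role_cod = sample(names(config$role_probs), sum(nbg),
                                     replace = TRUE, prob = config$role_probs))
  sig_ps[, is_bg := FALSE]; sig_c[, is_bg := FALSE]; bg[, is_bg := TRUE]
  drugdt <- rbind(sig_ps, sig_c, bg)
  setorder(drugdt, caseid)
  # every report must carry at least one prime-suspect drug; only a null
  # background row may be promoted, never a signal drug's concomitant row
  # (promoting those would create PS exposures the outcome draw never saw)
  drugdt[, has_ps := any(role_cod == "PS"), by = caseid]
  drugdt[, bg_row := cumsum(is_bg), by = caseid]
  drugdt[has_ps == FALSE & is_bg & bg_row == 1L, role_cod := "PS"]
  drugdt[, c("has_ps", "bg_row", "is_bg") := NULL]
  drugdt[, drug_seq := seq_len(.N), by = caseid]
  drugdt[, drugname := mangle_name(drugname)]

  ## reaction rows: DIMD cases get one DIMD PT + 0-2 background PTs
  dimd <- dimd_pt_natural()
  n_case <- sum(is_dimd)
  rx_case <- data.table(caseid = caseid[is_dimd],
                        pt = dimd[sample.int(length(dimd), n_case, replace = TRUE)])
  nex <- sample(0:2, n_case, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  rx_case_bg <- data.table(caseid = rep(caseid[is_dimd], nex),
                           pt = sample(bg_pt_pool(), sum(nex), replace = TRUE))
  nrx <- sample.int(3L, n - n_case, replace = TRUE)
  rx_ctrl <- data.table(caseid = rep(caseid[!is_dimd], nrx),
                        pt = sample(bg_pt_pool(), sum(nrx), replace = TRUE))
  reacdt <- rbind(rx_case, rx_case_bg, rx_ctrl)
  setorder(reacdt, caseid)

  ## indications from comorbidities
  indidt <- data.table(caseid = caseid[row(com)[com]],
                       indi_drug_seq = 1L,
                       indi_pt = cs$indication_pt[col(com)[com]])
  setorder(indidt, caseid)

  ## outcomes
  has_outc <- runif(n) < 0.65
  outcdt <- data.table(
    caseid = caseid[has_outc],
    outc_cod = sample(c("HO", "OT", "DS", "LT", "DE", "CA", "RI"),
                      sum(has_outc), replace = TRUE,
                      prob = c(0.35, 0.30, 0.12, 0.08, 0.10, 0.02, 0.03)))

  ## therapy dates (not used analytically; present for format fidelity)
  therdt <- drugdt[, .(caseid, dsg_drug_seq = drug_seq)]
  ther_base <- fda_date[match(therdt$caseid, caseid)]
  therdt[, start_dt := yyyymmdd(ther_base - sample.int(400L, nrow(therdt),
                                                       replace = TRUE))]

  rpsrdt <- data.table(caseid = caseid,
                       rpsr_cod = sample(c("FGN", "HP", "CSM", "OTH"), n,
                                         replace = TRUE))

  ## duplicate report versions: same caseid, larger primaryid; fda_dt strictly
  ## larger with probability 0.5 per extra version, else tied (tie-break path)
  vt <- data.table(caseid = caseid, version = 1L, fda_date = fda_date)
  dup <- runif(n) < config$duplicate_rate
  if (any(dup)) {
    d1 <- data.table(caseid = caseid[dup], version = 2L, base = fda_date[dup])
    d1[, fda_date := base + ifelse(runif(.N) < 0.5,
                                   sample.int(60L, .N, replace = TRUE), 0L)]
    extra2 <- runif(nrow(d1)) < 0.25
    d2 <- d1[extra2, .(caseid, version = 3L, base = fda_date)]
    if (nrow(d2))
      d2[, fda_date := base + ifelse(runif(.N) < 0.5,
                                     sample.int(60L, .N, replace = TRUE), 0L)]
    vt <- rbind(vt, d1[, .(caseid, version, fda_date)],
                d2[, .(caseid, version, fda_date)])
  }
  vt[, primaryid := caseid * 100L + version]
  setorder(vt, caseid, version)

  ## demographic base table keyed by caseid, expanded to all versions
  demo_base <- data.table(
    caseid = caseid,
    event_dt = ifelse(event_missing, NA_integer_, yyyymmdd(event_date)),
    sex = sex,
    age = ifelse(age_missing, NA_real_, age_val),
    age_cod = ifelse(age_missing, "", unit),
    wt = ifelse(wt_missing, NA_real_, wt),
    wt_cod = ifelse(wt_missing, "", "KG"),
    occp_cod = occp, reporter_country = country)
  demo <- demo_base[vt, on = "caseid"]
  demo[, `:=`(fda_dt = yyyymmdd(fda_date), caseversion = version,
              quarter = date_quarter(fda_date))]
  demo <- demo[, .(primaryid, caseid, caseversion, fda_dt, event_dt, sex, age,
                   age_cod, wt, wt_cod, occp_cod, reporter_country, quarter)]

  expand <- function(dt) {
    out <- dt[vt, on = "caseid", allow.cartesian = TRUE, nomatch = NULL]
    out[, quarter := date_quarter(fda_date)]
    out[, c("version", "fda_date") := NULL]
    setcolorder(out, "primaryid")
    out
  }
  tables <- list(
    demo = demo,
    drug = expand(drugdt)[, .(primaryid, caseid, drug_seq, role_cod, drugname, quarter)],
    reac = expand(reacdt)[, .(primaryid, caseid, pt, quarter)],
    outc = expand(outcdt)[, .(primaryid, caseid, outc_cod, quarter)],
    ther = expand(therdt)[, .(primaryid, caseid, dsg_drug_seq, start_dt, quarter)],
    indi = expand(indidt)[, .(primaryid, caseid, indi_drug_seq, indi_pt, quarter)],
    rpsr = expand(rpsrdt)[, .(primaryid, caseid, rpsr_cod, quarter)]
  )

  truth_reports <- vt[, .(caseid, primaryid, version, fda_dt = yyyymmdd(fda_date))]
  truth_reports[, dup_cluster := truth_reports$caseid]
  truth_reports$is_dimd <- is_dimd[match(truth_reports$caseid, caseid)]
  truth_drugs <- data.table(
    drug = specs$drug, exposure_prob = specs$exposure_prob,
    dimd_odds_multiplier = specs$dimd_odds_multiplier,
    designed_or = specs$dimd_odds_multiplier)

  list(tables = tables,
       truth = structure(list(drugs = truth_drugs, reports = truth_reports),
                         class = "faers_truth"),
       config = config)
}

#' Designed ground truth of a generator configuration
#'
#' Returns the per-drug designed odds ratio (equal to the configured odds
#' multiplier, exact under the generator's logistic exposure-to-outcome link)
#' and the per-report duplicate cluster membership, without writing any files.
#'
#' @param config a [faers_config()].
#' @return list of class `faers_truth` with elements `drugs` (drug,
#'   exposure_prob, dimd_odds_multiplier, designed_or) and `reports` (caseid,
#'   primaryid, version, fda_dt, dup_cluster, is_dimd).
#' @export
faers_truth <- function(config) simulate_faers(config)$truth

#' Generate synthetic FAERS quarterly files
#'
#' Writes one "$"-delimited ASCII file per table per quarter (e.g.
#' `DEMO24Q1.txt`) in the dialect accepted by [read_faers_quarter()], plus
#' tab-delimited ground-truth sidecars (`ground_truth_drugs.tsv`,
#' `ground_truth_reports.tsv`). Identical config + seed yields byte-identical
#' files.
#'
#' @param config a [faers_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `files` (paths written), `truth` and `dir`.
#' @export
faers_generate <- function(config, out_dir) {
  sim <- simulate_faers(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (tbl in names(sim$tables)) {
    dt <- sim$tables[[tbl]]
    for (q in sort(unique(dt$quarter))) {
      suffix <- paste0(substr(q, 3, 4), substr(q, 5, 6))
      path <- file.path(out_dir, paste0(toupper(tbl), suffix, ".txt"))
      out <- dt[quarter == q][, quarter := NULL]
      fwrite(out, path, sep = "$", quote = FALSE, na = "")
      files <- c(files, path)
    }
  }
  fwrite(sim$truth$drugs, file.path(out_dir, "ground_truth_drugs.tsv"), sep = "\t")
  fwrite(sim$truth$reports, file.path(out_dir, "ground_truth_reports.tsv"), sep = "\t")
  invisible(list(files = files, truth = sim$truth, dir = out_dir))
}
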
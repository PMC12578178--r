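# DIMD case definition (28 MedDRA preferred terms), cohort construction and
# Table-1-style descriptive summaries.

#' The 28 DIMD preferred terms
#'
#' Normalized (uppercase, space-free) MedDRA preferred terms defining a
#' drug-induced movement disorder case: a report is a case iff at least one
#' of its reaction PTs normalizes into this set.
#'
#' @return character vector of 28 normalized preferred terms.
#' @export
dimd_pts <- function() {
  c("MUSCLETWITCHING", "TIC", "TARDIVEDYSKINESIA", "DROOLING", "DYSKINESIA",
    "CHOREOATHETOSIS", "MOVEMENTDISORDER", "GRIMACING", "MOTORDYSFUNCTION",
    "EXTRAPYRAMIDALDISORDER", "DYSKINESIANEONATAL", "CHOREA",
    "BUCCOGLOSSALSYNDROME", "ATHETOSIS", "BALLISMUS", "DYSKINESIAOESOPHAGEAL",
    "RESPIRATORYDYSKINESIA", "OCULOGYRICCRISIS",
    "DOPAMINEDYSREGULATIONSYNDROME", "PROTRUSIONTONGUE", "RABBITSYNDROME",
    "PHARYNGEALDYSKINESIA", "ABNORMALINVOLUNTARYMOVEMENTSCALE",
    "CHRONICTICDISORDER", "SECONDARYTIC", "PROVISIONALTICDISORDER",
    "OCULOGYRATION", "REDUCEDDEXTERITY")
}

#' Natural-case MedDRA spellings of the 28 DIMD preferred terms
#'
#' Aligned element-wise with [dimd_pts()]; the synthetic generator emits
#' these so that PT normalization is genuinely exercised downstream.
#'
#' @return character vector of 28 preferred terms in natural case.
#' @export
dimd_pt_natural <- function() {
  c("Muscle twitching", "Tic", "Tardive dyskinesia", "Drooling", "Dyskinesia",
    "Choreoathetosis", "Movement disorder", "Grimacing", "Motor dysfunction",
    "Extrapyramidal disorder", "Dyskinesia neonatal", "Chorea",
    "Buccoglossal syndrome", "Athetosis", "Ballismus",
    "Dyskinesia oesophageal", "Respiratory dyskinesia", "Oculogyric crisis",
    "Dopamine dysregulation syndrome", "Protrusion tongue", "Rabbit syndrome",
    "Pharyngeal dyskinesia", "Abnormal involuntary movement scale",
    "Chronic tic disorder", "Secondary tic", "Provisional tic disorder",
    "Oculogyration", "Reduced dexterity")
}

#' Default comorbidity flag map
#'
#' Maps each of the seven comorbidity flags used by the risk model to a small
#' set of normalized indication preferred terms. The per-flag PT lists
#' (notably `other_cns`) are illustrative defaults and meant to be replaced
#' by the user's own MedDRA curation.
#'
#' @return named list: flag name -> character vector of normalized PTs.
#' @export
default_comorbidity_map <- function() {
  list(
    parkinsons = c("PARKINSONSDISEASE", "PARKINSONISM"),
    schizophrenia = c("SCHIZOPHRENIA", "SCHIZOAFFECTIVEDISORDER"),
    affective = c("DEPRESSION", "MAJORDEPRESSION", "BIPOLARDISORDER",
                  "DEPRESSEDMOOD"),
    epilepsy = c("EPILEPSY", "SEIZURE", "PARTIALSEIZURES"),
    gerd = c("GASTROOESOPHAGEALREFLUXDISEASE", "REFLUXOESOPHAGITIS"),
    nausea_vomiting = c("NAUSEA", "VOMITING"),
    other_cns = c("MIGRAINE", "MULTIPLESCLEROSIS", "RESTLESSLEGSSYNDROME")
  )
}

#' Flag DIMD case reports
#'
#' @param reac data.frame/data.table of reaction rows with `primaryid` and
#'   `pt` (raw preferred terms; normalized internally).
#' @param pts character vector of normalized case-defining PTs.
#' @return character vector of unique case `primaryid`s.
#' @export
flag_dimd <- function(reac, pts = dimd_pts()) {
  if (length(pts) == 0) stop("empty PT set", call. = FALSE)
  r <- as.data.table(reac)
  unique(r$primaryid[normalize_pt(r$pt) %in% pts])
}

#' Build the analysis cohort from ingested quarters
#'
#' Pools all quarters, applies the two-stage deduplication across the whole
#' span, normalizes demographics, flags DIMD cases by preferred term, and
#' attaches prime-suspect drug exposure, outcome codes and comorbidity flags.
#'
#' @param quarters a `faers_quarter` or list of them (see
#'   [read_faers_quarters()]).
#' @param pts normalized case-defining PTs (default the 28 DIMD terms).
#' @param comorbidity_map named list mapping flag names to normalized
#'   indication PTs.
#' @param exclude_outliers drop reports with age >= 120 years or weight >=
#'   400 kg (default TRUE, applied to all analyses).
#' @param role_filter drug role(s) defining exposure; default `"PS"` (prime
#'   suspect only).
#' @param drug_synonyms optional synonym map passed to
#'   [normalize_drugname()].
#' @return object of class `dimd_cohort`: `reports` (one row per retained
#'   report with demographics, `is_dimd_case` and one logical column per
#'   comorbidity flag), `drugs` (long table of exposure rows: `primaryid`,
#'   `drug`, `role`), `outcomes` (`primaryid`, `outc_cod`), plus bookkeeping
#'   counts.
#' @export
build_cohort <- function(quarters, pts = dimd_pts(),
                         comorbidity_map = default_comorbidity_map(),
                         exclude_outliers = TRUE, role_filter = "PS",
                         drug_synonyms = NULL) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  if (length(pts) == 0) stop("empty PT set", call. = FALSE)
  demo <- rbindlist(lapply(quarters, `[[`, "demo"), fill = TRUE)
  drug <- rbindlist(lapply(quarters, `[[`, "drug"), fill = TRUE)
  reac <- rbindlist(lapply(quarters, `[[`, "reac"), fill = TRUE)
  outc <- rbindlist(lapply(quarters, `[[`, "outc"), fill = TRUE)
  indi <- rbindlist(lapply(quarters, `[[`, "indi"), fill = TRUE)
  if (!nrow(demo)) stop("empty cohort: no DEMO rows in any quarter", call. = FALSE)

  retained <- dedup_reports(demo)
  reports <- build_report_records(retained)
  n_outliers <- 0L
  if (exclude_outliers) {
    out <- (!is.na(reports$age_years) & reports$age_years >= 120) |
      (!is.na(reports$weight_kg) & reports$weight_kg >= 400)
    n_outliers <- sum(out)
    reports <- reports[!out]
  }
  if (!nrow(reports)) stop("empty cohort after deduplication/exclusion", call. = FALSE)
  keep_pid <- reports$primaryid

  case_pid <- flag_dimd(reac, pts)
  reports[, is_dimd_case := primaryid %in% case_pid]

  drugs <- drug[primaryid %in% keep_pid & toupper(trimws(role_cod)) %in% role_filter,
                .(primaryid, drug = normalize_drugname(drugname, drug_synonyms),
                  role = toupper(trimws(role_cod)))]
  drugs <- unique(drugs)

  outcomes <- if (nrow(outc) && "outc_cod" %in% names(outc)) {
    unique(outc[primaryid %in% keep_pid, .(primaryid, outc_cod)])
  } else data.table(primaryid = character(0), outc_cod = character(0))

  if (nrow(indi) && "indi_pt" %in% names(indi)) {
    ipt <- indi[primaryid %in% keep_pid, .(primaryid, pt_norm = normalize_pt(indi_pt))]
    for (fl in names(comorbidity_map)) {
      pid_fl <- unique(ipt$primaryid[ipt$pt_norm %in% comorbidity_map[[fl]]])
      reports[, (fl) := primaryid %in% pid_fl]
    }
  } else {
    for (fl in names(comorbidity_map)) reports[, (fl) := FALSE]
  }

  structure(list(reports = reports, drugs = drugs, outcomes = outcomes,
                 pts = pts, comorbidity_flags = names(comorbidity_map),
                 n_outliers_excluded = n_outliers,
                 n_raw_demo_rows = nrow(demo)),
            class = "dimd_cohort")
}

#' @export
print.dimd_cohort <- function(x, ...) {
  cat(sprintf("<dimd_cohort> %d reports (%d DIMD cases), %d exposure rows\n",
              nrow(x$reports), sum(x$reports$is_dimd_case), nrow(x$drugs)))
  cat(sprintf("  %d outlier reports excluded; %d raw DEMO rows before dedup\n",
              x$n_outliers_excluded, x$n_raw_demo_rows))
  invisible(x)
}

# counts + percentages for one categorical vector (NA -> "Unknown")
cat_summary <- function(x, top_k = Inf) {
  x <- ifelse(is.na(x), "Unknown", as.character(x))
  tab <- sort(table(x), decreasing = TRUE)
  if (is.finite(top_k) && length(tab) > top_k) {
    keep <- names(tab)[seq_len(top_k)]
    other <- sum(tab[!names(tab) %in% keep])
    tab <- c(tab[keep], Other = other)
  }
  data.frame(level = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / sum(tab), 2),
             row.names = NULL)
}

# median and type-7 quartiles over present values, plus missingness
num_summary <- function(x) {
  n_missing <- sum(is.na(x))
  present <- x[!is.na(x)]
  data.frame(
    median = if (length(present)) median(present) else NA_real_,
    q1 = if (length(present)) unname(quantile(present, 0.25, type = 7)) else NA_real_,
    q3 = if (length(present)) unname(quantile(present, 0.75, type = 7)) else NA_real_,
    n_present = length(present), n_missing = n_missing,
    pct_missing = round(100 * n_missing / length(x), 2))
}

#' Baseline descriptive summary of the cohort
#'
#' Median and type-7 quartiles for age and weight (present values only, with
#' the missing fraction reported alongside), counts and percentages for sex,
#' reporter occupation, reporting country (top-k plus Other) and outcome
#' codes, case counts per calendar year, and counts per configurable age
#' band.
#'
#' @param cohort a `dimd_cohort`.
#' @param cases_only restrict to DIMD case reports (default TRUE).
#' @param top_k number of countries listed individually before pooling into
#'   Other.
#' @param age_breaks cut points (years) for the age-band tally.
#' @return named list of data.frames.
#' @export
summarize_baseline <- function(cohort, cases_only = TRUE, top_k = 10,
                               age_breaks = c(33, 53, 67)) {
  stopifnot(inherits(cohort, "dimd_cohort"))
  r <- cohort$reports
  if (cases_only) r <- r[is_dimd_case == TRUE]
  if (!nrow(r)) stop("no reports to summarize", call. = FALSE)
  pid <- r$primaryid
  oc <- cohort$outcomes[primaryid %in% pid]
  bands <- cut(r$age_years, breaks = c(-Inf, age_breaks, Inf),
               labels = c(paste0("<", age_breaks[1]),
                          paste(head(age_breaks, -1), age_breaks[-1], sep = "-"),
                          paste0(">", age_breaks[length(age_breaks)])),
               right = FALSE)
  list(
    n_reports = nrow(r),
    age = num_summary(r$age_years),
    weight = num_summary(r$weight_kg),
    sex = cat_summary(r$sex),
    occupation = cat_summary(r$reporter_occupation),
    country = cat_summary(r$country, top_k = top_k),
    outcomes = if (nrow(oc)) cat_summary(oc$outc_cod) else
      data.frame(level = character(0), n = integer(0), pct = numeric(0)),
    yearly = {
      yr <- cat_summary(r$event_year)
      yr$level <- suppressWarnings(as.integer(yr$level))
      yr[order(yr$level), ]
    },
    age_bands = cat_summary(bands)
  )
}
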
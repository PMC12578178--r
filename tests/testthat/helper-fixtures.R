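# Fixtures are built in code at test time; nothing binary is stored.

# write "$"-delimited FAERS-style files into a fresh temp dir
write_fixture_dir <- function(files) {
  dir <- tempfile("faersfix")
  dir.create(dir)
  for (nm in names(files)) writeLines(files[[nm]], file.path(dir, nm))
  dir
}

# a small hand-written quarter: 3 reports, mixed age units, lbs weight,
# missing fields, one concomitant-only drug
fixture_quarter_files <- function() {
  list(
    "DEMO24Q1.txt" = c(
      "primaryid$caseid$caseversion$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occp_cod$reporter_country",
      "101$1$1$20240105$20231201$F$53$YR$70$KG$MD$US",
      "201$2$1$20240110$$M$600$MON$154.324$LBS$CN$GB",
      "301$3$1$20240115$20240101$$5$DEC$$$$"),
    "DRUG24Q1.txt" = c(
      "primaryid$caseid$drug_seq$role_cod$drugname",
      "101$1$1$PS$Metoclopramide",
      "101$1$2$C$ASPIRIN",
      "201$2$1$PS$HALOPERIDOL",
      "301$3$1$PS$Carbidopa  Levodopa"),
    "REAC24Q1.txt" = c(
      "primaryid$caseid$pt",
      "101$1$Tardive dyskinesia",
      "101$1$Nausea",
      "201$2$Oculogyric crisis",
      "301$3$Headache"),
    "OUTC24Q1.txt" = c(
      "primaryid$caseid$outc_cod",
      "101$1$HO",
      "201$2$DS"))
}

# assemble a dimd_cohort directly from plain vectors (bypasses ingestion)
make_cohort <- function(primaryid, is_dimd_case,
                        drugs = NULL,            # data.frame(primaryid, drug)
                        sex = rep("F", length(primaryid)),
                        age_years = rep(50, length(primaryid)),
                        weight_kg = rep(NA_real_, length(primaryid)),
                        flags = list()) {
  reports <- data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(primaryid),
    fda_dt = 20240101L, sex = sex, age_years = age_years,
    weight_kg = weight_kg, reporter_occupation = NA_character_,
    country = NA_character_, event_year = 2024L,
    is_dimd_case = as.logical(is_dimd_case))
  flag_names <- names(flags)
  if (is.null(flag_names)) flag_names <- character(0)
  for (fl in flag_names) reports[[fl]] <- flags[[fl]]
  dr <- if (is.null(drugs)) {
    data.table::data.table(primaryid = character(0), drug = character(0),
                           role = character(0))
  } else {
    data.table::data.table(primaryid = as.character(drugs$primaryid),
                           drug = drugs$drug, role = "PS")
  }
  structure(list(reports = reports, drugs = dr,
                 outcomes = data.table::data.table(primaryid = character(0),
                                                   outc_cod = character(0)),
                 pts = dimd_pts(), comorbidity_flags = flag_names,
                 n_outliers_excluded = 0L, n_raw_demo_rows = nrow(reports)),
            class = "dimd_cohort")
}

# independent enumeration oracle for the two-sided Fisher p (lchoose route)
fisher_oracle <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n2 <- b + d
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  lp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  pr <- exp(lp)
  sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)])
}

# numeric-integration oracle for the BCPNN posterior moments of IC
bcpnn_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  g <- (N + 2) * (N + 2) / ((a + b + 1) * (a + c + 1))
  mom <- function(u, v) {
    m <- stats::integrate(function(x) log(x) * stats::dbeta(x, u, v), 0, 1,
                          rel.tol = 1e-12)$value
    s2 <- stats::integrate(function(x) (log(x) - m)^2 * stats::dbeta(x, u, v),
                           0, 1, rel.tol = 1e-10)$value
    c(m, s2)
  }
  m11 <- mom(1 + a, g - 1 + N - a)
  m1. <- mom(1 + a + b, 1 + N - a - b)
  m.1 <- mom(1 + a + c, 1 + N - a - c)
  ic <- (m11[1] - m1.[1] - m.1[1]) / log(2)
  v <- (m11[2] + m1.[2] + m.1[2]) / log(2)^2
  c(ic = ic, var = v)
}
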
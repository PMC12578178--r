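# Parsing of FAERS quarterly ASCII extracts ("$"-delimited, one header line)
# and the two-stage case deduplication recommended for FAERS analyses.

#' Normalize a reaction/indication preferred term
#'
#' Uppercases and strips whitespace, apostrophes and hyphens, matching the
#' space-free PT spelling used by the DIMD case list (e.g. `"Tardive
#' dyskinesia"` -> `"TARDIVEDYSKINESIA"`).
#'
#' @param x character vector of raw MedDRA preferred terms.
#' @return character vector of normalized terms.
#' @export
normalize_pt <- function(x) {
  gsub("[\\s'’-]+", "", toupper(as.character(x)), perl = TRUE)
}

#' Normalize a drug name
#'
#' Uppercase, trimmed, internal whitespace collapsed to single spaces; an
#' optional synonym map (named character vector, names = raw normalized form,
#' values = replacement) is applied afterwards.
#'
#' @param x character vector of raw drug names.
#' @param synonyms optional named character vector, e.g.
#'   `c(REGLAN = "METOCLOPRAMIDE")`.
#' @return character vector of normalized names.
#' @export
normalize_drugname <- function(x, synonyms = NULL) {
  y <- gsub("[[:space:]]+", " ", trimws(toupper(as.character(x))))
  if (!is.null(synonyms)) {
    hit <- match(y, names(synonyms))
    y[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  y
}

#' Convert a FAERS age value/unit pair to years
#'
#' Unit codes: `YR` years, `MON` months, `WK` weeks, `DY` days, `HR` hours,
#' `DEC` decades. Unknown codes and negative values yield `NA` (never an
#' error): assuming years for a corrupted unit would silently distort the age
#' distribution.
#'
#' @param value numeric vector of age values as recorded.
#' @param unit_code character vector of unit codes.
#' @return numeric vector of ages in years (`NA` where not interpretable).
#' @export
normalize_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(value))
  factors <- c(YR = 1, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25,
               HR = 1 / 8766, DEC = 10)
  f <- factors[toupper(trimws(as.character(unit_code)))]
  out <- value * unname(f)
  out[!is.finite(out) | value < 0] <- NA_real_
  out
}

#' Default column aliases for legacy AERS extracts
#'
#' Pre-2012 legacy files key reports by `ISR`/`CASE` and use `gndr_cod` for
#' sex; this map renames them to the modern FAERS column names at read time.
#'
#' @return named character vector: names are legacy column names (lowercase),
#'   values the modern names.
#' @export
faers_aliases <- function() {
  c(isr = "primaryid", "case" = "caseid", case_id = "caseid",
    gndr_cod = "sex", pt_name = "pt")
}

# required columns per table type (after aliasing, lowercase)
.faers_required <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = "primaryid",
  indi = c("primaryid", "indi_pt"),
  rpsr = "primaryid"
)

# Read one "$"-delimited table. Rows carrying extra delimiters are counted as
# malformed and dropped, never silently discarded.
read_faers_table <- function(path, type) {
  dt <- fread(file = path, sep = "$", header = TRUE, quote = "",
              colClasses = "character", fill = TRUE, na.strings = NULL,
              showProgress = FALSE)
  nm <- tolower(names(dt))
  al <- faers_aliases()
  hit <- match(nm, names(al))
  nm[!is.na(hit)] <- unname(al[hit[!is.na(hit)]])
  setnames(dt, nm)
  extra <- grep("^v\\d+$", names(dt), value = TRUE, ignore.case = TRUE)
  n_malformed <- 0L
  if (length(extra)) {
    bad <- Reduce(`|`, lapply(extra, function(cl) dt[[cl]] != ""))
    n_malformed <- sum(bad)
    dt <- dt[!bad]
    dt[, (extra) := NULL]
  }
  req <- .faers_required[[type]]
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing required column(s) %s", basename(path),
                 paste(sQuote(miss), collapse = ", ")), call. = FALSE)
  attr(dt, "n_malformed") <- n_malformed
  dt
}

#' Read one FAERS quarter
#'
#' Locates `DEMO<yy>Q<q>.txt` etc. under `dir` and parses them. The DEMO,
#' DRUG and REAC files are required; OUTC/THER/INDI/RPSR are optional and
#' yield empty tables when absent. Child-table rows whose `primaryid` does
#' not appear in DEMO are counted and dropped.
#'
#' @param dir directory containing the quarterly files.
#' @param quarter quarter label such as `"2024Q4"`.
#' @return list of class `faers_quarter`: the seven tables, the `quarter`
#'   label, and a `counts` data.frame (per table: parsed, malformed, orphan).
#' @export
read_faers_quarter <- function(dir, quarter) {
  stopifnot(grepl("^\\d{4}Q[1-4]$", quarter))
  suffix <- paste0(substr(quarter, 3, 4), substr(quarter, 5, 6))
  types <- names(.faers_required)
  required_file <- c(demo = TRUE, drug = TRUE, reac = TRUE, outc = FALSE,
                     ther = FALSE, indi = FALSE, rpsr = FALSE)
  tabs <- list()
  counts <- data.frame(table = types, parsed = 0L, malformed = 0L, orphan = 0L)
  for (i in seq_along(types)) {
    ty <- types[i]
    path <- file.path(dir, paste0(toupper(ty), suffix, ".txt"))
    if (!file.exists(path)) {
      if (required_file[[ty]])
        stop(sprintf("missing required file %s", basename(path)), call. = FALSE)
      tabs[[ty]] <- data.table(primaryid = character(0))
      next
    }
    dt <- read_faers_table(path, ty)
    counts$malformed[i] <- attr(dt, "n_malformed")
    counts$parsed[i] <- nrow(dt)
    tabs[[ty]] <- dt
  }
  pid <- unique(tabs$demo$primaryid)
  for (i in seq_along(types)) {
    ty <- types[i]
    if (ty == "demo" || !nrow(tabs[[ty]])) next
    orphan <- !(tabs[[ty]]$primaryid %in% pid)
    counts$orphan[i] <- sum(orphan)
    if (any(orphan)) tabs[[ty]] <- tabs[[ty]][!orphan]
  }
  structure(c(tabs, list(quarter = quarter, counts = counts)),
            class = "faers_quarter")
}

#' Read all FAERS quarters found in a directory
#'
#' @param dir directory containing `DEMO<yy>Q<q>.txt` style files.
#' @param quarters optional character vector of quarter labels; by default all
#'   quarters with a DEMO file are read.
#' @return list of `faers_quarter` objects, sorted by quarter label.
#' @export
read_faers_quarters <- function(dir, quarters = NULL) {
  if (is.null(quarters)) {
    demos <- list.files(dir, pattern = "^DEMO\\d{2}Q[1-4]\\.txt$")
    if (!length(demos))
      stop("no DEMO files found in ", dir, call. = FALSE)
    suf <- sub("^DEMO(\\d{2})(Q[1-4])\\.txt$", "\\1\\2", demos)
    yy <- as.integer(substr(suf, 1, 2))
    century <- ifelse(yy >= 90, 1900L, 2000L)  # FAERS starts 2004; AERS 1997
    quarters <- sort(paste0(century + yy, substr(suf, 3, 4)))
  }
  lapply(quarters, function(q) read_faers_quarter(dir, q))
}

#' Two-stage FAERS report deduplication
#'
#' Stage one keeps, for each `caseid`, the version with the most recent
#' `fda_dt`, breaking ties by the larger `primaryid`. Stage two resolves any
#' remaining repeated `primaryid` by keeping, per `primaryid`, the row with
#' the largest `fda_dt` then the largest `caseid` (mirroring the primary
#' rule). The operation is idempotent.
#'
#' @param demo data.frame/data.table with at least `caseid`, `fda_dt`,
#'   `primaryid`.
#' @return data.table of retained rows, one per report.
#' @export
dedup_reports <- function(demo) {
  d <- as.data.table(demo)
  stopifnot(all(c("caseid", "fda_dt", "primaryid") %in% names(d)))
  d <- copy(d)
  d[, `:=`(.cid = suppressWarnings(as.numeric(caseid)),
           .dt = suppressWarnings(as.numeric(fda_dt)),
           .pid = suppressWarnings(as.numeric(primaryid)))]
  setorderv(d, c(".cid", ".dt", ".pid"), na.last = FALSE)
  d <- d[d[, .I[.N], by = .cid]$V1]
  setorderv(d, c(".pid", ".dt", ".cid"), na.last = FALSE)
  d <- d[d[, .I[.N], by = .pid]$V1]
  d[, c(".cid", ".dt", ".pid") := NULL]
  d[]
}

# demo rows -> one normalized ReportRecord per row
build_report_records <- function(demo) {
  d <- as.data.table(demo)
  has <- function(col) col %in% names(d)
  get_chr <- function(col) if (has(col)) d[[col]] else rep("", nrow(d))
  sex <- toupper(trimws(get_chr("sex")))
  sex[!sex %in% c("F", "M")] <- NA_character_
  age_years <- if (has("age")) normalize_age(d[["age"]], get_chr("age_cod"))
               else rep(NA_real_, nrow(d))
  wt <- suppressWarnings(as.numeric(get_chr("wt")))
  wt_cod <- toupper(trimws(get_chr("wt_cod")))
  weight_kg <- ifelse(wt_cod %in% c("KG", "KGS"), wt,
                      ifelse(wt_cod == "LBS", wt * 0.453592, NA_real_))
  weight_kg[!is.finite(weight_kg) | weight_kg < 0] <- NA_real_
  fda <- suppressWarnings(as.integer(d[["fda_dt"]]))
  evt <- suppressWarnings(as.integer(get_chr("event_dt")))
  event_year <- ifelse(is.na(evt), fda %/% 10000L, evt %/% 10000L)
  data.table(
    primaryid = d$primaryid, caseid = d$caseid, fda_dt = fda,
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    reporter_occupation = {
      oc <- trimws(get_chr("occp_cod")); oc[oc == ""] <- NA_character_; oc
    },
    country = {
      co <- trimws(get_chr("reporter_country")); co[co == ""] <- NA_character_; co
    },
    event_year = event_year)
}
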
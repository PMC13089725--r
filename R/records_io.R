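#' Default discharge-outcome code map
#'
#' Maps raw discharge-reason codes to the outcome classes used throughout
#' the pipeline: `DISCHARGE_ALIVE`, `DEATH`, `STAY` (still hospitalized /
#' hospital permanence), `TRANSFER` (inter-hospital transfer or
#' administrative discharge with a new form issued). Raw codes absent from
#' the map become `UNKNOWN`. Real distributions use system-specific (and in
#' the private schema, partly disused) numeric codes; supply a custom map
#' through the column dictionary for those dialects.
#'
#' @return Named character vector (raw code -> outcome class).
#' @export
default_outcome_map <- function() {
  c(discharge = "DISCHARGE_ALIVE",
    death     = "DEATH",
    stay      = "STAY",
    transfer  = "TRANSFER")
}

outcome_levels <- c("DISCHARGE_ALIVE", "DEATH", "STAY", "TRANSFER", "UNKNOWN")

#' Outcomes counted as "known" for the mortality analyses
#' @return Character vector: discharge alive and in-hospital death.
#' @export
known_outcomes <- function() c("DISCHARGE_ALIVE", "DEATH")

public_diag_fields <- c("principal", paste0("secondary_", 1:9),
                        "icd_notification", "icd_death", "icd_associated")
private_diag_fields <- paste0("icd_", 1:4)

#' Column dictionaries for the two claims dialects
#'
#' The readers are schema-agnostic: every physical column name, the date
#' format and the discharge-outcome map live in a dictionary, defaulting to
#' the synthetic dialect written by [simulate_cohort()] (ISO-8601 dates,
#' symbolic discharge codes). Map a real distribution by overriding the
#' entries.
#'
#' @param date_format Date format string for the admission/discharge columns.
#' @param outcome_map Named character vector, see [default_outcome_map()].
#' @return A list of column names and parsing options.
#' @export
public_columns <- function(date_format = "%Y-%m-%d",
                           outcome_map = default_outcome_map()) {
  list(
    form_id = "form_id", person_key = "person_key",
    hospital_key = "hospital_key",
    admission_date = "admission_date", discharge_date = "discharge_date",
    discharge_reason = "discharge_reason", icu_days = "icu_days",
    diagnosis_fields = setNames(paste0("diag_", public_diag_fields),
                                public_diag_fields),
    procedure_form_id = "form_id", procedure_code = "procedure",
    date_format = date_format, outcome_map = outcome_map
  )
}

#' @rdname public_columns
#' @export
private_columns <- function(date_format = "%Y-%m-%d",
                            outcome_map = default_outcome_map()) {
  list(
    form_id = "event_id",
    admission_date = "admission_date", discharge_date = "discharge_date",
    discharge_reason = "discharge_reason",
    type_of_hospitalization = "type_of_hospitalization",
    diagnosis_fields = setNames(private_diag_fields, private_diag_fields),
    procedure_form_id = "event_id", procedure_code = "procedure",
    date_format = date_format, outcome_map = outcome_map
  )
}

map_outcome <- function(raw, outcome_map) {
  out <- unname(outcome_map[as.character(raw)])
  out[is.na(out)] <- "UNKNOWN"
  factor(out, levels = outcome_levels)
}

read_delim_chr <- function(path, delim) {
  readr::read_delim(path, delim = delim,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
}

# Shared core for both dialects: main admission table + linked procedure acts.
read_pair <- function(main_path, proc_path, columns, schema, delim) {
  terminology <- if (schema == "PUBLIC") "SIGTAP" else "TUSS"
  main <- read_delim_chr(main_path, delim)
  proc <- read_delim_chr(proc_path, delim)

  key <- columns$form_id
  require_cols(main, c(key, columns$admission_date, columns$discharge_date),
               main_path)
  require_cols(proc, c(columns$procedure_form_id, columns$procedure_code),
               proc_path)

  adm <- tibble::tibble(
    form_id = main[[key]],
    admission_date = as.Date(main[[columns$admission_date]],
                             format = columns$date_format),
    discharge_date = as.Date(main[[columns$discharge_date]],
                             format = columns$date_format),
    discharge_reason_raw = main[[columns$discharge_reason]],
    outcome = map_outcome(main[[columns$discharge_reason]],
                          columns$outcome_map)
  )
  if (schema == "PUBLIC") {
    adm$person_key <- main[[columns$person_key]]
    adm$hospital_key <- main[[columns$hospital_key]]
    adm$icu_days <- suppressWarnings(as.integer(main[[columns$icu_days]]))
    adm$icu_days[is.na(adm$icu_days)] <- 0L
    adm$type_of_hospitalization <- NA_character_
  } else {
    adm$person_key <- NA_character_
    adm$hospital_key <- NA_character_
    adm$icu_days <- 0L
    adm$type_of_hospitalization <- main[[columns$type_of_hospitalization]]
  }

  # date-flagged rows are kept out of the cohort but accounted for
  flagged <- is.na(adm$admission_date) | is.na(adm$discharge_date) |
    adm$discharge_date < adm$admission_date | is.na(adm$form_id)
  dup <- duplicated(adm$form_id) & !flagged
  if (any(dup)) flagged <- flagged | adm$form_id %in% adm$form_id[dup]

  diag_cols <- columns$diagnosis_fields
  present <- diag_cols[diag_cols %in% names(main)]
  diagnoses <- tibble::tibble(form_id = character(0), field = character(0),
                              icd_raw = character(0), icd = character(0))
  if (length(present) > 0) {
    long <- tidyr::pivot_longer(
      dplyr::select(main, form_id = dplyr::all_of(key),
                    dplyr::all_of(unname(present))),
      cols = -"form_id", names_to = "field", values_to = "icd_raw")
    long$field <- names(present)[match(long$field, unname(present))]
    long <- long[!is.na(long$icd_raw) & nzchar(trimws(long$icd_raw)), ]
    long$icd <- normalize_icd(long$icd_raw)
    diagnoses <- long
  }
  diagnoses <- diagnoses[diagnoses$form_id %in% adm$form_id[!flagged], ]

  procs <- tibble::tibble(
    form_id = proc[[columns$procedure_form_id]],
    code_raw = proc[[columns$procedure_code]],
    code = normalize_procedure(proc[[columns$procedure_code]], terminology),
    terminology = terminology
  )
  orphan <- !procs$form_id %in% adm$form_id[!flagged]
  report <- list(
    schema = schema,
    rows_in = nrow(main),
    records = sum(!flagged),
    flagged_rows = sum(flagged),
    flagged_form_ids = adm$form_id[flagged],
    procedure_rows_in = nrow(procs),
    orphan_procedure_rows = sum(orphan),
    orphan_form_ids = unique(procs$form_id[orphan]),
    invalid_icd = sum(is.na(diagnoses$icd)),
    invalid_procedure = sum(is.na(procs$code) & !orphan)
  )
  structure(
    list(schema = schema,
         admissions = adm[!flagged, ],
         diagnoses = diagnoses,
         procedures = procs[!orphan, c("form_id", "code_raw", "code",
                                       "terminology")],
         report = report),
    class = "smm_cohort"
  )
}

#' Read a public-schema (SIH/SUS-like) file pair
#'
#' Loads the "reduced" admissions table (one row per admission form, with
#' the diagnosis fields, dates, discharge reason and ICU-days counter) and
#' the "professional services" table of procedure acts, linking them by the
#' admission-form number. Rows with unparseable or inverted dates are
#' flagged and excluded from the cohort (they remain visible in the load
#' report); procedure rows whose key matches no admission form are reported
#' as orphans, not silently dropped.
#'
#' @param reduced_path,services_path CSV file paths.
#' @param columns Column dictionary, see [public_columns()].
#' @param delim Field delimiter.
#' @return An `smm_cohort`: a list of tibbles `admissions`, `diagnoses`
#'   (long, with field provenance and normalized codes), `procedures`, plus
#'   a load `report`.
#' @export
read_public_pair <- function(reduced_path, services_path,
                             columns = public_columns(), delim = ",") {
  read_pair(reduced_path, services_path, columns, "PUBLIC", delim)
}

#' Read a private-schema (ANS-like) file pair
#'
#' Loads the "consolidated" admissions table (type-of-hospitalization field,
#' four ICD fields, dates, discharge reason) and the "detailed" procedures
#' table, linked by the health-care event key. Missing-ICD admissions are
#' legal (ICD registration is not mandatory in this schema) and load as
#' records with an empty diagnosis list.
#'
#' @param consolidated_path,detailed_path CSV file paths.
#' @param columns Column dictionary, see [private_columns()].
#' @param delim Field delimiter.
#' @return An `smm_cohort`; see [read_public_pair()].
#' @export
read_private_pair <- function(consolidated_path, detailed_path,
                              columns = private_columns(), delim = ",") {
  read_pair(consolidated_path, detailed_path, columns, "PRIVATE", delim)
}

#' @export
print.smm_cohort <- function(x, ...) {
  cat("<smm_cohort> ", x$schema, ": ", nrow(x$admissions), " records, ",
      nrow(x$diagnoses), " diagnoses, ", nrow(x$procedures),
      " procedure acts\n", sep = "")
  r <- x$report
  cat("  load report: ", r$rows_in, " rows in, ", r$flagged_rows,
      " flagged, ", r$orphan_procedure_rows, " orphan procedure rows\n",
      sep = "")
  invisible(x)
}

#' Load report of a cohort
#'
#' Conservation summary of a read: rows in = records kept + flagged rows,
#' with orphan procedure rows and invalid code counts.
#'
#' @param cohort An `smm_cohort`.
#' @return A list of counts and flagged/orphan keys.
#' @export
load_report <- function(cohort) {
  stopifnot(inherits(cohort, "smm_cohort"))
  cohort$report
}

#' Write a cohort back to its schema's file pair
#'
#' Emits the admissions table and the procedure table in the same dialect
#' the cohort was read from (or generated in), such that re-reading
#' round-trips: `read_*_pair()` on the written files reproduces the
#' cohort's record content.
#'
#' @param cohort An `smm_cohort`.
#' @param main_path,proc_path Output CSV paths for the admissions and
#'   procedures tables.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, main_path, proc_path) {
  stopifnot(inherits(cohort, "smm_cohort"))
  columns <- if (cohort$schema == "PUBLIC") public_columns()
             else private_columns()
  adm <- cohort$admissions
  wide <- tidyr::pivot_wider(
    cohort$diagnoses[, c("form_id", "field", "icd_raw")],
    names_from = "field", values_from = "icd_raw",
    values_fn = function(x) x[1])
  fields <- names(columns$diagnosis_fields)
  for (f in fields) if (!f %in% names(wide)) wide[[f]] <- NA_character_

  out <- tibble::tibble(form_id = adm$form_id)
  out[[columns$admission_date]] <- format(adm$admission_date, "%Y-%m-%d")
  out[[columns$discharge_date]] <- format(adm$discharge_date, "%Y-%m-%d")
  out[[columns$discharge_reason]] <- adm$discharge_reason_raw
  if (cohort$schema == "PUBLIC") {
    out[[columns$person_key]] <- adm$person_key
    out[[columns$hospital_key]] <- adm$hospital_key
    out[[columns$icu_days]] <- adm$icu_days
  } else {
    out[[columns$type_of_hospitalization]] <- adm$type_of_hospitalization
  }
  wide <- wide[match(out$form_id, wide$form_id), fields, drop = FALSE]
  names(wide) <- unname(columns$diagnosis_fields[fields])
  out <- dplyr::bind_cols(out, wide)
  names(out)[names(out) == "form_id"] <- columns$form_id

  procs <- tibble::tibble(cohort$procedures$form_id,
                          cohort$procedures$code_raw)
  names(procs) <- c(columns$procedure_form_id, columns$procedure_code)

  readr::write_csv(out, main_path, na = "", progress = FALSE)
  readr::write_csv(procs, proc_path, na = "", progress = FALSE)
  invisible(c(main_path, proc_path))
}
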
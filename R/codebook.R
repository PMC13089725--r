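#' Normalize recorded ICD-10 codes
#'
#' Administrative discharge files record ICD-10 codes with inconsistent case
#' and punctuation ("O45.0", "o720"). Normalization uppercases, strips dots
#' and whitespace, and validates against the ICD-10 shape (a letter followed
#' by two digits and an optional third digit). Malformed values are flagged
#' as `NA` so that they can never silently match a code set.
#'
#' @param raw Character vector of recorded codes.
#' @return Character vector of normalized codes; `NA` where the input does
#'   not normalize to a valid ICD-10 code.
#' @examples
#' normalize_icd(c("O45.0", "o720", "Z999X"))
#' @export
normalize_icd <- function(raw) {
  x <- toupper(gsub("[.[:space:]]", "", as.character(raw)))
  x[!grepl("^[A-Z][0-9]{2}[0-9]?$", x)] <- NA_character_
  x
}

#' Test whether normalized ICD codes are valid
#'
#' @param code Character vector.
#' @return Logical vector: `TRUE` where `code` is a normalized 3- or
#'   4-character ICD-10 code.
#' @export
icd_is_valid <- function(code) {
  !is.na(code) & grepl("^[A-Z][0-9]{2}[0-9]?$", code)
}

#' Build an ICD-10 code set
#'
#' A code set mixes exact codes, category prefixes and inclusive ranges:
#' \itemize{
#'   \item a 4-character entry (e.g. `"O450"`) matches exactly;
#'   \item a 1- to 3-character entry (e.g. `"O45"`, `"O"`) matches any code
#'     sharing that prefix (category semantics);
#'   \item an equal-width range `"Z34-Z39"` matches any code whose prefix of
#'     that width sorts within the endpoints (inclusive).
#' }
#'
#' @param entries Character vector of codes, prefixes and ranges.
#' @return An object of class `icd_code_set`.
#' @examples
#' s <- icd_set(c("O450", "O45", "Z34-Z39"))
#' icd_matches(c("O451", "Z370", "J81"), s)
#' @export
icd_set <- function(entries) {
  entries <- toupper(gsub("[.[:space:]]", "", as.character(entries)))
  entries <- entries[!is.na(entries) & nzchar(entries)]
  is_range <- grepl("^[A-Z][0-9]{1,3}-[A-Z][0-9]{1,3}$", entries)
  plain <- entries[!is_range]
  bad <- plain[!grepl("^[A-Z]$|^[A-Z][0-9]{1,3}$", plain)]
  if (length(bad) > 0) {
    stop("invalid ICD code set entries: ", paste(unique(bad), collapse = ", "))
  }
  rng <- entries[is_range]
  lo <- sub("-.*$", "", rng)
  hi <- sub("^.*-", "", rng)
  if (any(nchar(lo) != nchar(hi))) {
    stop("range endpoints must have equal width: ",
         paste(rng[nchar(lo) != nchar(hi)], collapse = ", "))
  }
  if (any(lo > hi)) {
    stop("range lower endpoint sorts above upper: ",
         paste(rng[lo > hi], collapse = ", "))
  }
  structure(
    list(
      entries = entries,
      exact   = plain[nchar(plain) == 4],
      prefix  = plain[nchar(plain) < 4],
      ranges  = data.frame(lo = lo, hi = hi, width = nchar(lo),
                           stringsAsFactors = FALSE)
    ),
    class = "icd_code_set"
  )
}

#' @export
print.icd_code_set <- function(x, ...) {
  cat("<icd_code_set> ", length(x$exact), " exact, ", length(x$prefix),
      " prefix, ", nrow(x$ranges), " range entries\n", sep = "")
  invisible(x)
}

#' Match normalized ICD codes against a code set
#'
#' @param code Character vector of normalized codes (see [normalize_icd()]).
#'   `NA` (flagged-invalid) codes never match.
#' @param set An [icd_set()] object.
#' @return Logical vector, one element per code.
#' @export
icd_matches <- function(code, set) {
  stopifnot(inherits(set, "icd_code_set"))
  code <- as.character(code)
  hit <- !is.na(code) & code %in% set$exact
  for (w in unique(nchar(set$prefix))) {
    hit <- hit | (!is.na(code) &
                    substr(code, 1L, w) %in% set$prefix[nchar(set$prefix) == w])
  }
  if (nrow(set$ranges) > 0) {
    for (i in seq_len(nrow(set$ranges))) {
      w <- set$ranges$width[i]
      p <- substr(code, 1L, w)
      hit <- hit | (!is.na(code) & nchar(code) >= w &
                      p >= set$ranges$lo[i] & p <= set$ranges$hi[i])
    }
  }
  hit
}

#' Normalize procedure codes
#'
#' SIGTAP (the SUS unified procedure table) is a fixed-width 10-digit
#' terminology usually printed with dots and a check-digit dash
#' ("02.01.01.001-1"); codes that lost a leading zero in transcription are
#' left-zero-padded. TUSS (the supplementary-health terminology) is an
#' 8-digit terminology. Values with the wrong digit count after removing
#' separators are flagged as `NA`.
#'
#' @param raw Character vector of recorded procedure codes.
#' @param terminology `"SIGTAP"` or `"TUSS"`.
#' @return Character vector of canonical digit strings, `NA` where invalid.
#' @examples
#' normalize_procedure("02.01.01.001-1", "SIGTAP")
#' normalize_procedure("411020048", "SIGTAP")   # left-padded to 10 digits
#' @export
normalize_procedure <- function(raw, terminology = c("SIGTAP", "TUSS")) {
  terminology <- match.arg(terminology)
  x <- gsub("[^0-9]", "", as.character(raw))
  if (terminology == "SIGTAP") {
    ok <- nchar(x) >= 7 & nchar(x) <= 10
    x[ok] <- paste0(strrep("0", 10L - nchar(x[ok])), x[ok])
  } else {
    ok <- nchar(x) == 8
  }
  x[!ok | is.na(x) | !nzchar(x)] <- NA_character_
  x
}

criterion_groups <- c("HAEMORRHAGIC", "HYPERTENSIVE", "OTHER_SYSTEMIC",
                      "MANAGEMENT")
derived_rules <- c("PROLONGED_STAY", "ICU_DAYS_COUNTER",
                   "CONDITIONAL_CURETTAGE")

# expected partition of the 22 operationalized criteria over the four groups
.op_group_counts <- c(HAEMORRHAGIC = 4L, HYPERTENSIVE = 4L,
                      OTHER_SYSTEMIC = 7L, MANAGEMENT = 7L)

as_code_chr <- function(x) {
  if (is.null(x)) character(0) else as.character(unlist(x, use.names = FALSE))
}

norm_proc_entries <- function(x, terminology, where) {
  x <- as_code_chr(x)
  if (terminology == "SIGTAP" && any(nchar(gsub("[^0-9]", "", x)) < 9)) {
    stop("SIGTAP entries in ", where, " must carry 9 or 10 digits")
  }
  out <- normalize_procedure(x, terminology)
  if (anyNA(out)) {
    stop("invalid ", terminology, " code(s) in ", where, ": ",
         paste(x[is.na(out)], collapse = ", "))
  }
  out
}

#' Path of the shipped PLTC codebook document
#'
#' @return Path to the YAML codebook installed with the package.
#' @export
default_codebook_path <- function() {
  system.file("extdata", "pltc_codebook.yaml", package = "smmsurv",
              mustWork = TRUE)
}

#' Load a PLTC criterion codebook
#'
#' Reads the structured codebook document (YAML) that registers the WHO
#' potentially life-threatening condition criteria: for each criterion its
#' severity group, ICD-10 code set, SIGTAP and TUSS procedure sets and any
#' derived rule, plus the per-schema obstetric-identification rule sets and
#' auxiliary configuration (delivery procedure subset, prolonged-stay
#' threshold, curettage condition). The shipped default transcribes the
#' national 2015-2022 operationalization: 26 criteria, of which 22 are
#' operationalized (4 haemorrhagic, 4 hypertensive, 7 other systemic, 7
#' severe-management) and 4 are declared but not identifiable in either
#' schema.
#'
#' @param path Path to a codebook YAML document; defaults to the shipped
#'   registry.
#' @return An object of class `smm_codebook`: a list with elements
#'   `criteria` (tibble with list-columns `icd`, `sigtap`, `tuss`),
#'   `obstetric`, `delivery` and `rules`.
#' @examples
#' cb <- load_codebook()
#' nrow(cb$criteria)
#' @export
load_codebook <- function(path = default_codebook_path()) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$criteria) || length(doc$criteria) == 0) {
    stop("codebook document has no criteria")
  }
  nm <- names(doc$criteria)
  if (anyDuplicated(nm)) {
    stop("duplicate criterion names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  crit <- purrr::imap(doc$criteria, function(entry, name) {
    group <- as.character(entry$group %||% NA_character_)
    if (!group %in% criterion_groups) {
      stop("unknown group '", group, "' for criterion '", name, "'")
    }
    op <- isTRUE(entry$operationalized %||% TRUE)
    rule <- entry$derived_rule
    if (!is.null(rule) && !rule %in% derived_rules) {
      stop("unknown derived rule '", rule, "' for criterion '", name, "'")
    }
    icd_entries <- as_code_chr(entry$icd)
    tibble::tibble(
      name = name,
      label = as.character(entry$label %||% name),
      group = group,
      operationalized = op,
      derived_rule = if (is.null(rule)) NA_character_ else as.character(rule),
      icd = list(icd_set(icd_entries)),
      sigtap = list(norm_proc_entries(entry$sigtap, "SIGTAP", name)),
      tuss = list(norm_proc_entries(entry$tuss, "TUSS", name))
    )
  })
  criteria <- dplyr::bind_rows(crit)

  if (nrow(criteria) != 26L) {
    stop("codebook must define exactly 26 criteria, found ", nrow(criteria))
  }
  if (sum(!criteria$operationalized) != 4L) {
    stop("codebook must declare exactly 4 non-operationalized criteria")
  }
  counts <- table(factor(criteria$group[criteria$operationalized],
                         levels = criterion_groups))
  if (!all(as.integer(counts) == as.integer(.op_group_counts[criterion_groups]))) {
    stop("operationalized criteria must partition 4/4/7/7 over ",
         "HAEMORRHAGIC/HYPERTENSIVE/OTHER_SYSTEMIC/MANAGEMENT; found ",
         paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  }
  no_trigger <- criteria$operationalized & is.na(criteria$derived_rule) &
    vapply(criteria$icd, function(s) length(s$entries) == 0, logical(1)) &
    lengths(criteria$sigtap) == 0 & lengths(criteria$tuss) == 0
  if (any(no_trigger)) {
    stop("operationalized criteria without any trigger: ",
         paste(criteria$name[no_trigger], collapse = ", "))
  }

  pub <- doc$obstetric$public
  priv <- doc$obstetric$private
  obstetric <- list(
    public = list(
      icd = icd_set(as_code_chr(pub$icd_prefixes)),
      sigtap = norm_proc_entries(pub$sigtap, "SIGTAP", "obstetric/public")
    ),
    private = list(
      obstetric_type_code = as.character(priv$obstetric_type_code),
      pediatric_type_code = as.character(priv$pediatric_type_code),
      icd = icd_set(c(as_code_chr(priv$icd_prefixes),
                      as_code_chr(priv$icd_ranges),
                      as_code_chr(priv$p_group_diagnosis))),
      p_allow = icd_set(as_code_chr(priv$p_group_type3_allow)),
      tuss = norm_proc_entries(priv$tuss, "TUSS", "obstetric/private")
    )
  )
  delivery <- list(
    sigtap = norm_proc_entries(doc$delivery$sigtap, "SIGTAP", "delivery"),
    tuss = norm_proc_entries(doc$delivery$tuss, "TUSS", "delivery")
  )
  rules <- list(
    newborn_care_sigtap = normalize_procedure(
      as.character(doc$rules$newborn_care_sigtap), "SIGTAP"),
    prolonged_stay_days = as.integer(doc$rules$prolonged_stay_days),
    curettage_sigtap = normalize_procedure(
      as.character(doc$rules$curettage_sigtap), "SIGTAP"),
    puerperal_complication = icd_set(
      as_code_chr(doc$rules$puerperal_complication_icd))
  )
  structure(
    list(version = as.character(doc$version %||% "unversioned"),
         criteria = criteria, obstetric = obstetric, delivery = delivery,
         rules = rules, doc = doc),
    class = "smm_codebook"
  )
}

#' Serialize a codebook back to its interchange document
#'
#' Writes the YAML document the codebook was loaded from, so that
#' `load_codebook(write_codebook(cb, path))` reproduces an identical
#' registry. Code vectors are emitted as quoted strings (zero-padded
#' SIGTAP codes must not be reinterpreted as numbers).
#'
#' @param codebook An `smm_codebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "smm_codebook"))
  doc <- rapply(codebook$doc, as.character, classes = c("numeric", "integer"),
                how = "replace")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.smm_codebook <- function(x, ...) {
  cat("<smm_codebook> version ", x$version, ": ", nrow(x$criteria),
      " criteria (", sum(x$criteria$operationalized),
      " operationalized)\n", sep = "")
  print(dplyr::count(x$criteria, .data$group, .data$operationalized))
  invisible(x)
}

#' Names of the operationalized criteria, in codebook order
#'
#' @param codebook An `smm_codebook`.
#' @return Character vector of 22 criterion names.
#' @export
operational_criteria <- function(codebook) {
  codebook$criteria$name[codebook$criteria$operationalized]
}

#' Criterion-to-group map
#'
#' @param codebook An `smm_codebook`.
#' @return Named character vector mapping operationalized criterion names to
#'   their severity group.
#' @export
criterion_group_map <- function(codebook) {
  crit <- codebook$criteria[codebook$criteria$operationalized, ]
  stats::setNames(crit$group, crit$name)
}
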
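#' Classify episodes of care as obstetric
#'
#' Applies the per-schema obstetric-identification rules from the codebook.
#'
#' Public schema (no type-of-hospitalization field): an episode is
#' obstetric iff any diagnosis in any field carries a pregnancy-chapter
#' ("O") code, or any procedure act is in the SIGTAP obstetric list.
#'
#' Private schema, any of:
#' \itemize{
#'   \item (a) the type-of-hospitalization field codes an obstetric stay
#'     (code 3) and the record does not carry a perinatal-chapter ("P")
#'     diagnosis outside the tolerated categories — such a P diagnosis
#'     marks a newborn admission billed under the insured woman;
#'   \item (b) any diagnosis is an "O" code, in Z34-Z39, or on the
#'     enumerated P-group allow-list, provided the type of hospitalization
#'     is not the pediatric code;
#'   \item (c) any procedure act is in the TUSS obstetric list.
#' }
#' Rule (a) deliberately works on records with all ICD fields empty:
#' roughly 30\% of private-schema admissions carry no ICD at all.
#'
#' @param episodes An `smm_episodes` object.
#' @param codebook An `smm_codebook`.
#' @return Logical vector, one element per episode.
#' @export
is_obstetric <- function(episodes, codebook) {
  stopifnot(inherits(episodes, "smm_episodes"),
            inherits(codebook, "smm_codebook"))
  if (episodes$schema == "PUBLIC") {
    is_obstetric_public(episodes, codebook)
  } else {
    is_obstetric_private(episodes, codebook)
  }
}

episodes_with <- function(episodes, ids) {
  episodes$episodes$episode_id %in% ids
}

diag_hits <- function(episodes, set) {
  d <- episodes$diagnoses
  unique(d$episode_id[icd_matches(d$icd, set)])
}

proc_hits <- function(episodes, codes) {
  p <- episodes$procedures
  unique(p$episode_id[!is.na(p$code) & p$code %in% codes])
}

#' @rdname is_obstetric
#' @export
is_obstetric_public <- function(episodes, codebook) {
  stopifnot(episodes$schema == "PUBLIC")
  rules <- codebook$obstetric$public
  episodes_with(episodes, diag_hits(episodes, rules$icd)) |
    episodes_with(episodes, proc_hits(episodes, rules$sigtap))
}

#' @rdname is_obstetric
#' @export
is_obstetric_private <- function(episodes, codebook) {
  stopifnot(episodes$schema == "PRIVATE")
  rules <- codebook$obstetric$private
  d <- episodes$diagnoses

  p_group <- !is.na(d$icd) & substr(d$icd, 1, 1) == "P"
  p_blocked <- p_group & !icd_matches(d$icd, rules$p_allow)
  blocked_ids <- unique(d$episode_id[p_blocked])
  type <- episodes$episodes$type_of_hospitalization
  rule_a <- !is.na(type) & type == rules$obstetric_type_code &
    !episodes_with(episodes, blocked_ids)

  rule_b <- episodes_with(episodes, diag_hits(episodes, rules$icd)) &
    (is.na(type) | type != rules$pediatric_type_code)

  rule_c <- episodes_with(episodes, proc_hits(episodes, rules$tuss))

  rule_a | rule_b | rule_c
}
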
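#' Assemble admission forms into episodes of care
#'
#' In the public schema a single hospital stay can generate several
#' admission forms (e.g. when a surgical procedure is indicated during an
#' initially clinical admission), so forms must be chained into episodes of
#' care before any classification. Two public records chain when they share
#' `person_key` and (by default) `hospital_key` and the next admission
#' starts no more than `max_gap_days` after the running discharge date of
#' the episode; chaining is transitive. Private-schema events cannot be
#' linked (the schema carries neither the hospital number nor the woman's
#' date of birth) and always yield singleton episodes, as do public records
#' lacking a person or hospital key (these are flagged).
#'
#' Episode fields aggregate over members: admission date is the minimum,
#' discharge the maximum, ICU days the sum, diagnoses and procedures the
#' union (field provenance kept), and the outcome is the chronologically
#' final member's outcome. A death recorded on a non-final member is a
#' validation error.
#'
#' @param cohort An `smm_cohort` from [read_public_pair()],
#'   [read_private_pair()] or [simulate_cohort()].
#' @param max_gap_days Maximum allowed gap (days) between a member's
#'   discharge and the next admission; default 1 (same-day or next-day
#'   continuation).
#' @param require_same_hospital Chain only within one facility (default).
#' @return An `smm_episodes` object: tibbles `episodes`, `members`
#'   (form-to-episode partition), `diagnoses`, `procedures`.
#' @export
assemble_episodes <- function(cohort, max_gap_days = 1,
                              require_same_hospital = TRUE) {
  stopifnot(inherits(cohort, "smm_cohort"), max_gap_days >= 0)
  adm <- cohort$admissions
  if (nrow(adm) == 0) {
    ep <- tibble::tibble(episode_id = character(0), schema = character(0),
                         n_forms = integer(0), person_key = character(0),
                         hospital_key = character(0),
                         admission_date = as.Date(character(0)),
                         discharge_date = as.Date(character(0)),
                         icu_days = integer(0),
                         type_of_hospitalization = character(0),
                         outcome = factor(character(0),
                                          levels = outcome_levels),
                         flagged_missing_key = logical(0))
    return(structure(list(schema = cohort$schema, episodes = ep,
                          members = tibble::tibble(form_id = character(0),
                                                   episode_id = character(0)),
                          diagnoses = cohort$diagnoses[0, ],
                          procedures = cohort$procedures[0, ]),
                     class = "smm_episodes"))
  }

  missing_key <- is.na(adm$person_key) |
    (require_same_hospital & is.na(adm$hospital_key))
  if (cohort$schema == "PRIVATE") missing_key <- rep(TRUE, nrow(adm))

  grp_person <- ifelse(missing_key, paste0("..solo:", adm$form_id),
                       adm$person_key)
  grp_hosp <- if (require_same_hospital) {
    ifelse(missing_key, "", adm$hospital_key)
  } else ""
  ord <- order(grp_person, grp_hosp, adm$admission_date, adm$discharge_date,
               adm$form_id)
  a <- adm[ord, ]
  gp <- grp_person[ord]
  gh <- grp_hosp[ord]
  key <- paste(gp, gh, sep = "\r")
  new_group <- c(TRUE, key[-1] != key[-length(key)])

  # running max discharge within group, reset at group starts
  disch <- as.integer(a$discharge_date)
  admi <- as.integer(a$admission_date)
  run_max <- disch
  brk <- logical(nrow(a))
  brk[1] <- TRUE
  for (i in seq_len(nrow(a))[-1]) {
    if (new_group[i] || admi[i] - run_max[i - 1] > max_gap_days) {
      brk[i] <- TRUE
    } else {
      run_max[i] <- max(run_max[i - 1], disch[i])
    }
  }
  ep_index <- cumsum(brk)
  first_form <- a$form_id[brk][ep_index]
  episode_id <- paste0("ep_", first_form)

  a$episode_id <- episode_id
  last_in_ep <- !duplicated(ep_index, fromLast = TRUE)
  if (any(a$outcome == "DEATH" & !last_in_ep)) {
    bad <- a$form_id[a$outcome == "DEATH" & !last_in_ep]
    stop("death recorded on a non-final admission form of an episode: ",
         paste(head(bad, 5), collapse = ", "))
  }

  episodes <- tibble::tibble(
    episode_id = a$episode_id[brk],
    schema = cohort$schema,
    n_forms = as.integer(tabulate(ep_index)),
    person_key = a$person_key[brk],
    hospital_key = a$hospital_key[brk],
    admission_date = as.Date(as.vector(tapply(admi, ep_index, min)),
                             origin = "1970-01-01"),
    discharge_date = as.Date(as.vector(tapply(disch, ep_index, max)),
                             origin = "1970-01-01"),
    icu_days = as.integer(as.vector(tapply(a$icu_days, ep_index, sum))),
    type_of_hospitalization = a$type_of_hospitalization[brk],
    outcome = a$outcome[last_in_ep],
    flagged_missing_key = (missing_key[ord])[brk] &
      cohort$schema == "PUBLIC"
  )

  members <- tibble::tibble(form_id = a$form_id, episode_id = a$episode_id)
  diagnoses <- dplyr::distinct(
    dplyr::inner_join(cohort$diagnoses, members, by = "form_id"),
    .data$episode_id, .data$field, .data$icd, .data$icd_raw)
  procedures <- dplyr::distinct(
    dplyr::inner_join(cohort$procedures, members, by = "form_id"),
    .data$episode_id, .data$code, .data$terminology)

  structure(list(schema = cohort$schema, episodes = episodes,
                 members = members, diagnoses = diagnoses,
                 procedures = procedures),
            class = "smm_episodes")
}

#' @export
print.smm_episodes <- function(x, ...) {
  cat("<smm_episodes> ", x$schema, ": ", nrow(x$episodes),
      " episodes from ", nrow(x$members), " admission forms (",
      sum(x$episodes$n_forms > 1), " multi-form)\n", sep = "")
  invisible(x)
}

#' Outcome of an episode from its members' outcomes
#'
#' The episode outcome is the chronologically last member's discharge
#' outcome; `STAY` or `TRANSFER` on the final member leaves the episode
#' with an unknown survival outcome. A `DEATH` on a non-final member is
#' invalid: death must terminate the episode.
#'
#' @param outcomes Character or factor vector of member outcomes, in
#'   chronological order.
#' @return A single outcome (factor level).
#' @export
episode_outcome <- function(outcomes) {
  outcomes <- as.character(outcomes)
  stopifnot(length(outcomes) >= 1, all(outcomes %in% outcome_levels))
  if (any(outcomes[-length(outcomes)] == "DEATH")) {
    stop("DEATH must be the final member outcome of an episode")
  }
  factor(outcomes[length(outcomes)], levels = outcome_levels)
}
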
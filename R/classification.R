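stay_days <- function(episodes) {
  as.numeric(episodes$episodes$discharge_date -
               episodes$episodes$admission_date)
}

has_delivery <- function(episodes, codebook) {
  codes <- if (episodes$schema == "PUBLIC") codebook$delivery$sigtap
           else codebook$delivery$tuss
  episodes_with(episodes, proc_hits(episodes, codes))
}

#' Prolonged postpartum hospital stay rule
#'
#' Fires for episodes admitted for childbirth (a configured delivery
#' procedure is present) whose stay exceeds the configured threshold
#' (strictly more than 7 postpartum days by default). In the public schema,
#' episodes carrying the in-hospital newborn-care procedure are excluded:
#' there the long stay belongs to the newborn, not the woman.
#'
#' @param episodes An `smm_episodes` object.
#' @param codebook An `smm_codebook`.
#' @return Logical vector over episodes.
#' @export
prolonged_stay_rule <- function(episodes, codebook) {
  hit <- has_delivery(episodes, codebook) &
    stay_days(episodes) > codebook$rules$prolonged_stay_days
  if (episodes$schema == "PUBLIC") {
    newborn <- episodes_with(
      episodes, proc_hits(episodes, codebook$rules$newborn_care_sigtap))
    hit <- hit & !newborn
  }
  hit
}

#' Intensive-care admission rule
#'
#' Public schema: the monthly ICU-days counter is positive, or an ICU
#' daily-rate SIGTAP procedure is present. Private schema: an ICU TUSS
#' procedure is present.
#'
#' @inheritParams prolonged_stay_rule
#' @return Logical vector over episodes.
#' @export
icu_rule <- function(episodes, codebook) {
  def <- codebook$criteria[codebook$criteria$name == "icu_admission", ]
  if (episodes$schema == "PUBLIC") {
    episodes$episodes$icu_days > 0 |
      episodes_with(episodes, proc_hits(episodes, def$sigtap[[1]]))
  } else {
    episodes_with(episodes, proc_hits(episodes, def$tuss[[1]]))
  }
}

#' Conditional curettage clause of the surgical-intervention criterion
#'
#' The public-schema uterine-curettage procedure does not distinguish
#' post-abortion from puerperal curettage, so it counts toward the
#' surgical-intervention criterion only when the episode also contains a
#' delivery procedure or a puerperal-complication diagnosis (O85-O92 by
#' default). A curettage in an abortion episode does not fire this
#' criterion.
#'
#' @inheritParams prolonged_stay_rule
#' @return Logical vector over episodes.
#' @export
conditional_curettage_rule <- function(episodes, codebook) {
  if (episodes$schema != "PUBLIC") {
    return(rep(FALSE, nrow(episodes$episodes)))
  }
  curettage <- episodes_with(
    episodes, proc_hits(episodes, codebook$rules$curettage_sigtap))
  puerperal <- episodes_with(
    episodes, diag_hits(episodes, codebook$rules$puerperal_complication))
  curettage & (has_delivery(episodes, codebook) | puerperal)
}

#' Evaluate one morbidity criterion over episodes
#'
#' A criterion fires when any episode diagnosis matches its ICD set, any
#' procedure act matches the schema's procedure set, or its derived rule
#' fires ([prolonged_stay_rule()], [icu_rule()],
#' [conditional_curettage_rule()]). Evaluating a non-operationalized
#' criterion is an explicit error, never a silent `FALSE`.
#'
#' @param episodes An `smm_episodes` object.
#' @param criterion Criterion name (see [operational_criteria()]) or a
#'   one-row slice of `codebook$criteria`.
#' @param codebook An `smm_codebook`.
#' @return Logical vector over episodes.
#' @export
evaluate_criterion <- function(episodes, criterion, codebook) {
  stopifnot(inherits(episodes, "smm_episodes"),
            inherits(codebook, "smm_codebook"))
  if (is.character(criterion)) {
    def <- codebook$criteria[codebook$criteria$name == criterion, ]
    if (nrow(def) != 1) stop("unknown criterion: ", criterion)
  } else {
    def <- criterion
  }
  if (!def$operationalized) {
    stop("criterion '", def$name, "' is declared but not operationalized; ",
         "it cannot be evaluated from these schemas")
  }
  hit <- episodes_with(episodes, diag_hits(episodes, def$icd[[1]]))
  proc_set <- if (episodes$schema == "PUBLIC") def$sigtap[[1]]
              else def$tuss[[1]]
  hit <- hit | episodes_with(episodes, proc_hits(episodes, proc_set))
  if (!is.na(def$derived_rule)) {
    hit <- hit | switch(
      def$derived_rule,
      PROLONGED_STAY = prolonged_stay_rule(episodes, codebook),
      ICU_DAYS_COUNTER = icu_rule(episodes, codebook),
      CONDITIONAL_CURETTAGE = conditional_curettage_rule(episodes, codebook)
    )
  }
  hit
}

#' Classify severe maternal morbidity over obstetric episodes
#'
#' Evaluates the 22 operationalized potentially-life-threatening-condition
#' criteria for every episode and returns the per-episode morbidity
#' profile. The classification is deterministic and order-independent: each
#' criterion is a set-membership test over the episode's pooled diagnoses
#' and procedures.
#'
#' @param episodes An `smm_episodes` object, normally already restricted to
#'   obstetric episodes (see [is_obstetric()]).
#' @param codebook An `smm_codebook`.
#' @return An `smm_profiles` tibble: `episode_id`, `schema`, `outcome`, one
#'   logical column per operationalized criterion, `n_criteria` and
#'   `is_smm`. The criterion-to-group map is attached as attribute
#'   `criterion_groups`.
#' @examples
#' \dontrun{
#' profiles <- smm_classify(episodes, load_codebook())
#' table(profiles$n_criteria)
#' }
#' @export
smm_classify <- function(episodes, codebook) {
  stopifnot(inherits(episodes, "smm_episodes"),
            inherits(codebook, "smm_codebook"))
  ops <- codebook$criteria[codebook$criteria$operationalized, ]
  profiles <- tibble::tibble(
    episode_id = episodes$episodes$episode_id,
    schema = episodes$episodes$schema,
    outcome = episodes$episodes$outcome
  )
  for (i in seq_len(nrow(ops))) {
    profiles[[ops$name[i]]] <- evaluate_criterion(episodes, ops[i, ],
                                                  codebook)
  }
  m <- as.matrix(profiles[, ops$name, drop = FALSE])
  profiles$n_criteria <- as.integer(rowSums(m))
  profiles$is_smm <- profiles$n_criteria >= 1L
  attr(profiles, "criterion_groups") <- criterion_group_map(codebook)
  class(profiles) <- c("smm_profiles", class(profiles))
  profiles
}

profile_criteria <- function(profiles) {
  names(attr(profiles, "criterion_groups"))
}

#' Run the full surveillance pipeline on one cohort
#'
#' Convenience wrapper: assemble episodes of care, identify obstetric
#' episodes, and classify morbidity criteria.
#'
#' @param cohort An `smm_cohort`.
#' @param codebook An `smm_codebook`.
#' @param max_gap_days Episode-chaining gap, see [assemble_episodes()].
#' @return A list: `episodes` (all episodes), `obstetric` (logical vector),
#'   `n_episodes`, `n_obstetric`, and `profiles` (classification of the
#'   obstetric episodes).
#' @export
smm_surveillance <- function(cohort, codebook = load_codebook(),
                             max_gap_days = 1) {
  episodes <- assemble_episodes(cohort, max_gap_days = max_gap_days)
  obst <- is_obstetric(episodes, codebook)
  kept <- subset_episodes(episodes, obst)
  list(episodes = episodes, obstetric = obst,
       n_episodes = nrow(episodes$episodes), n_obstetric = sum(obst),
       profiles = smm_classify(kept, codebook))
}

#' Subset an episodes object
#'
#' @param episodes An `smm_episodes` object.
#' @param keep Logical or integer index over episodes.
#' @return An `smm_episodes` containing the selected episodes.
#' @export
subset_episodes <- function(episodes, keep) {
  ep <- episodes$episodes[keep, ]
  ids <- ep$episode_id
  structure(list(
    schema = episodes$schema, episodes = ep,
    members = episodes$members[episodes$members$episode_id %in% ids, ],
    diagnoses = episodes$diagnoses[episodes$diagnoses$episode_id %in% ids, ],
    procedures =
      episodes$procedures[episodes$procedures$episode_id %in% ids, ]),
    class = "smm_episodes")
}
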
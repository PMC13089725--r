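# Build tiny cohorts through the public CSV interface so the readers are
# exercised on every fixture.

pub_row <- function(form_id, person = "P1", hosp = "H1",
                    adm = "2020-03-01", dis = "2020-03-03",
                    reason = "discharge", icu = 0L, ...) {
  diag <- list(...)
  row <- tibble::tibble(form_id = form_id, person_key = person,
                        hospital_key = hosp, admission_date = adm,
                        discharge_date = dis, discharge_reason = reason,
                        icu_days = icu)
  for (nm in names(diag)) row[[paste0("diag_", nm)]] <- diag[[nm]]
  row
}

pub_cohort <- function(rows, procs = NULL) {
  red <- tempfile(fileext = ".csv")
  srv <- tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(rows), red, na = "")
  if (is.null(procs)) {
    procs <- tibble::tibble(form_id = character(0), procedure = character(0))
  }
  readr::write_csv(procs, srv, na = "")
  read_public_pair(red, srv)
}

priv_row <- function(event_id, adm = "2020-03-01", dis = "2020-03-03",
                     reason = "discharge", type = NA_character_, ...) {
  diag <- list(...)
  row <- tibble::tibble(event_id = event_id, admission_date = adm,
                        discharge_date = dis, discharge_reason = reason,
                        type_of_hospitalization = type)
  for (nm in names(diag)) row[[nm]] <- diag[[nm]]
  row
}

priv_cohort <- function(rows, procs = NULL) {
  con <- tempfile(fileext = ".csv")
  det <- tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_rows(rows), con, na = "")
  if (is.null(procs)) {
    procs <- tibble::tibble(event_id = character(0), procedure = character(0))
  }
  readr::write_csv(procs, det, na = "")
  read_private_pair(con, det)
}

sigtap_procs <- function(form_id, codes) {
  tibble::tibble(form_id = rep(form_id, length(codes)), procedure = codes)
}

tuss_procs <- function(event_id, codes) {
  tibble::tibble(event_id = rep(event_id, length(codes)), procedure = codes)
}

# Random hand-sized profiles for the statistics oracles.
random_profiles <- function(n, seed, codebook = load_codebook(),
                            p_hit = 0.25) {
  set.seed(seed)
  groups <- criterion_group_map(codebook)
  lv <- c("DISCHARGE_ALIVE", "DEATH", "STAY", "TRANSFER", "UNKNOWN")
  p <- tibble::tibble(
    episode_id = sprintf("e%04d", seq_len(n)), schema = "PUBLIC",
    outcome = factor(sample(c("DISCHARGE_ALIVE", "DEATH", "TRANSFER",
                              "STAY"), n, TRUE,
                            prob = c(0.55, 0.25, 0.1, 0.1)), levels = lv))
  for (cr in names(groups)) p[[cr]] <- stats::runif(n) < p_hit
  m <- as.matrix(p[, names(groups)])
  p$n_criteria <- as.integer(rowSums(m))
  p$is_smm <- p$n_criteria >= 1L
  attr(p, "criterion_groups") <- groups
  p
}

# Exhaustive pairwise-closure oracle for episode chaining.
closure_partition <- function(adm, gap) {
  n <- nrow(adm)
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    same <- identical(adm$person_key[i], adm$person_key[j]) &&
      identical(adm$hospital_key[i], adm$hospital_key[j])
    if (!same) next
    dij <- as.numeric(adm$admission_date[j] - adm$discharge_date[i])
    chain <- adm$admission_date[j] >= adm$admission_date[i] && dij <= gap
    dji <- as.numeric(adm$admission_date[i] - adm$discharge_date[j])
    chain <- chain ||
      (adm$admission_date[i] >= adm$admission_date[j] && dji <= gap)
    if (chain) edge[i, j] <- edge[j, i] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (edge[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(adm$form_id, comp)
}

partition_sets <- function(members) {
  unname(lapply(
    split(members$form_id, members$episode_id),
    function(x) sort(x)))
}

canonical_partition <- function(sets) {
  sets <- unname(lapply(sets, sort))
  sets[order(vapply(sets, `[`, character(1), 1))]
}
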
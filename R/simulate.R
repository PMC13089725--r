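# Criterion order must match the shipped codebook's operationalized entries.
.criterion_names <- c(
  "abruptio_placentae", "ectopic_pregnancy", "postpartum_haemorrhage",
  "ruptured_uterus", "severe_preeclampsia", "eclampsia",
  "severe_hypertension", "hypertensive_encephalopathy", "endometritis",
  "pulmonary_oedema", "respiratory_failure", "seizures", "sepsis", "shock",
  "thyroid_crisis", "blood_transfusion", "central_venous_access",
  "hysterectomy", "icu_admission", "prolonged_stay",
  "non_anaesthetic_intubation", "surgical_intervention")

#' Default planted per-criterion prevalences
#'
#' Per-criterion probabilities of planting a morbidity hit on an obstetric
#' episode, set to the order of magnitude each criterion shows among
#' public-sector obstetric hospitalizations nationally (shares ranging from
#' ~3.5\% for severe hypertension down to below 1 per 100,000 for thyroid
#' crisis).
#'
#' @return Named numeric vector over the 22 operationalized criteria.
#' @export
default_prevalence <- function() {
  c(abruptio_placentae = 0.0032, ectopic_pregnancy = 0.0069,
    postpartum_haemorrhage = 0.0012, ruptured_uterus = 0.0002,
    severe_preeclampsia = 0.0105, eclampsia = 0.0030,
    severe_hypertension = 0.0347, hypertensive_encephalopathy = 1e-06,
    endometritis = 0.0028, pulmonary_oedema = 1e-05,
    respiratory_failure = 6e-04, seizures = 3e-05, sepsis = 2e-04,
    shock = 7e-05, thyroid_crisis = 1e-06, blood_transfusion = 0.0099,
    central_venous_access = 2e-04, hysterectomy = 7e-04,
    icu_admission = 0.0053, prolonged_stay = 0.0156,
    non_anaesthetic_intubation = 1e-04, surgical_intervention = 0.0070)
}

#' Configuration of the synthetic-cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' public/private schema mix, planted per-criterion prevalences, a
#' logit-linear in-hospital death model on the number of observable
#' criteria, the private-schema missing-ICD fraction (~30\% of admissions
#' carry no ICD), multi-form episode structure in the public schema, and
#' the unknown-outcome fractions (about 1\% public, 5.2\% private).
#'
#' @param n_episodes Number of episodes of care to generate.
#' @param private_fraction Share of episodes in the private schema.
#' @param prevalence Named per-criterion plant probabilities, see
#'   [default_prevalence()].
#' @param beta0,beta1 Death model `logit(p) = beta0 + beta1 * n_observable`.
#'   The defaults (-8, 1.1) are explicitly synthetic: they reproduce a
#'   mortality gradient of the observed magnitude, they are not estimates.
#' @param missing_icd_fraction Private-schema records with all ICD fields
#'   blank.
#' @param non_obstetric_fraction Episodes that are not obstetric (other
#'   admissions of women 10-49, plus neonatal billing records in the
#'   private schema).
#' @param neonatal_fraction Share of private non-obstetric episodes that
#'   are newborn admissions billed under the mother (type 3 with an
#'   out-of-allow-list P diagnosis).
#' @param delivery_fraction Obstetric episodes admitted for childbirth
#'   (carrying a delivery procedure).
#' @param multi_form_fraction Public-schema episodes split over 2-3
#'   admission forms.
#' @param gap_one_day_prob Probability that a continuation form starts the
#'   day after (rather than the day of) the previous form's discharge.
#' @param unknown_outcome_fraction Named vector (`PUBLIC`, `PRIVATE`) of
#'   stay/transfer (unknown survival) outcome fractions.
#' @param seed Integer seed; fully determines the output.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_episodes = 10000,
                       private_fraction = 0.167,
                       prevalence = default_prevalence(),
                       beta0 = -8, beta1 = 1.1,
                       missing_icd_fraction = 0.30,
                       non_obstetric_fraction = 0.25,
                       neonatal_fraction = 0.10,
                       delivery_fraction = 0.70,
                       multi_form_fraction = 0.08,
                       gap_one_day_prob = 0.3,
                       unknown_outcome_fraction = c(PUBLIC = 0.010,
                                                    PRIVATE = 0.052),
                       seed = 1L) {
  n_episodes <- as.integer(n_episodes)
  if (is.na(n_episodes) || n_episodes < 1) {
    stop("n_episodes must be a positive integer")
  }
  if (length(prevalence) != length(.criterion_names) ||
      !setequal(names(prevalence), .criterion_names)) {
    stop("prevalence must be a named vector over the ",
         length(.criterion_names), " operationalized criteria")
  }
  prevalence <- prevalence[.criterion_names]
  probs <- c(prevalence, private_fraction, missing_icd_fraction,
             non_obstetric_fraction, neonatal_fraction, delivery_fraction,
             multi_form_fraction, gap_one_day_prob,
             unknown_outcome_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all fractions and prevalences must lie in [0, 1]")
  }
  if (!all(c("PUBLIC", "PRIVATE") %in% names(unknown_outcome_fraction))) {
    stop("unknown_outcome_fraction needs PUBLIC and PRIVATE entries")
  }
  structure(list(
    n_episodes = n_episodes, private_fraction = private_fraction,
    prevalence = prevalence, beta0 = beta0, beta1 = beta1,
    missing_icd_fraction = missing_icd_fraction,
    non_obstetric_fraction = non_obstetric_fraction,
    neonatal_fraction = neonatal_fraction,
    delivery_fraction = delivery_fraction,
    multi_form_fraction = multi_form_fraction,
    gap_one_day_prob = gap_one_day_prob,
    unknown_outcome_fraction = unknown_outcome_fraction,
    seed = as.integer(seed)), class = "sim_config")
}

pick <- function(u, codes) codes[1L + floor(u * length(codes))]

# context/background code pools; none of these trigger any criterion
.ctx_public <- c("O800", "O801", "O809", "O820", "O821", "O234", "O200")
.ctx_private <- c("O800", "O801", "O809", "O820", "O821", "Z340", "Z348")
.ctx_nonobst <- c("J189", "K359", "N390", "S525", "M545", "I839")
.ctx_neonatal <- c("P220", "P590", "P071")
.generic_sigtap <- "0301010010"
.generic_tuss <- "40801012"

#' Generate a schema-faithful synthetic cohort
#'
#' Writes a public-schema file pair (reduced + professional services), a
#' private-schema pair (consolidated + detailed) and a truth table into
#' `dir`. Every planted criterion hit is realized by at least one
#' triggering code drawn uniformly from the criterion's code set; on
#' private missing-ICD records an ICD-based hit is substituted by a
#' procedure trigger when the criterion has one, and is otherwise recorded
#' in the truth table as planted-but-unobservable. Death is sampled from
#' `logit(p) = beta0 + beta1 * n_observable`. Output is fully determined by
#' the seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param codebook An `smm_codebook` supplying the code sets.
#' @return A list: `paths` (named file paths) and `truth` (tibble with one
#'   row per episode: planted and observable flags per criterion, death and
#'   outcome, linkage key `episode_key` matching the episode ids produced
#'   by [assemble_episodes()]).
#' @export
simulate_cohort <- function(config, dir, codebook = load_codebook()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ops <- codebook$criteria[codebook$criteria$operationalized, ]
  if (!identical(ops$name, .criterion_names)) {
    stop("codebook criterion order does not match the generator's")
  }
  set.seed(config$seed)
  n <- config$n_episodes
  ncrit <- length(.criterion_names)
  prev <- config$prevalence

  ## -- all randomness drawn here, in fixed order, independent of the
  ##    fraction parameters, so thresholds nest across configurations --
  n_private <- round(n * config$private_fraction)
  priv_pick <- sample.int(n, n_private)
  u_obst <- runif(n); u_neo <- runif(n)
  U_crit <- matrix(runif(n * ncrit), n, ncrit)
  U_route <- matrix(runif(n * ncrit), n, ncrit)
  U_icd_pick <- matrix(runif(n * ncrit), n, ncrit)
  U_proc_pick <- matrix(runif(n * ncrit), n, ncrit)
  u_icu_route <- runif(n); u_icu_days <- runif(n)
  u_deliv <- runif(n); u_dcode <- runif(n); u_ctx <- runif(n)
  u_stay <- runif(n); u_pls <- runif(n); u_date <- runif(n)
  u_hosp <- runif(n)
  u_split <- runif(n); u_k3 <- runif(n)
  U_cut <- matrix(runif(2 * n), n, 2); U_gap <- matrix(runif(2 * n), n, 2)
  u_mask <- runif(n); u_unknown <- runif(n); u_death <- runif(n)
  u_censor <- runif(n)

  schema <- rep("PUBLIC", n); schema[priv_pick] <- "PRIVATE"
  is_priv <- schema == "PRIVATE"
  obst <- u_obst >= config$non_obstetric_fraction
  neonatal <- !obst & is_priv & u_neo < config$neonatal_fraction
  planted <- sweep(U_crit, 2, prev, "<") & obst
  colnames(planted) <- .criterion_names
  masked <- is_priv & !neonatal & u_mask < config$missing_icd_fraction
  delivery <- obst &
    (u_deliv < config$delivery_fraction | planted[, "prolonged_stay"])

  stay <- integer(n)
  stay[!obst] <- 1L + as.integer(floor(u_stay[!obst] * 7))
  nd <- obst & !delivery
  stay[nd] <- 1L + as.integer(floor(u_stay[nd] * 5))
  stay[delivery] <- 2L + as.integer(floor(u_stay[delivery] * 3))
  pls <- planted[, "prolonged_stay"]
  stay[pls] <- 8L + as.integer(floor(u_pls[pls] * 7))

  day0 <- as.Date("2015-01-01")
  span <- as.integer(as.Date("2022-11-30") - day0)
  adm_date <- day0 + as.integer(floor(u_date * (span + 1)))
  dis_date <- adm_date + stay

  icu_hit <- planted[, "icu_admission"]
  icu_counter <- icu_hit & !is_priv & u_icu_route < 0.7
  icu_days <- ifelse(icu_counter, 1L + as.integer(floor(u_icu_days * 5)), 0L)

  ## -- realize planted hits as codes --
  hits <- which(planted, arr.ind = TRUE)
  route <- character(nrow(hits))   # "icd", "proc", "derived", "hidden"
  icd_code <- proc_code <- rep(NA_character_, nrow(hits))
  if (nrow(hits) > 0) {
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]; j <- hits[h, 2]
      name <- .criterion_names[j]
      icd_entries <- ops$icd[[j]]$entries
      proc_set <- if (is_priv[i]) ops$tuss[[j]] else ops$sigtap[[j]]
      if (name == "prolonged_stay") {
        route[h] <- "derived"
      } else if (name == "icu_admission") {
        if (icu_counter[i]) route[h] <- "derived"
        else { route[h] <- "proc"
               proc_code[h] <- pick(U_proc_pick[i, j], proc_set) }
      } else if (name == "surgical_intervention") {
        route[h] <- "proc"
        proc_code[h] <- pick(U_proc_pick[i, j], proc_set)
      } else if (masked[i] || length(icd_entries) == 0 ||
                 (length(proc_set) > 0 && U_route[i, j] >= 0.8)) {
        if (length(proc_set) > 0) {
          route[h] <- "proc"
          proc_code[h] <- pick(U_proc_pick[i, j], proc_set)
        } else if (!masked[i] && length(icd_entries) > 0) {
          route[h] <- "icd"
          icd_code[h] <- pick(U_icd_pick[i, j], icd_entries)
        } else {
          route[h] <- "hidden"
        }
      } else {
        route[h] <- "icd"
        icd_code[h] <- pick(U_icd_pick[i, j], icd_entries)
      }
    }
    # diagnosis-field capacity (14 public, 4 private, one slot for context)
    icd_rows <- which(route == "icd")
    over <- integer(0)
    if (length(icd_rows) > 0) {
      seq_icd <- stats::ave(rep(1L, length(icd_rows)), hits[icd_rows, 1],
                            FUN = cumsum)
      cap <- ifelse(is_priv[hits[icd_rows, 1]], 3L, 13L)
      over <- icd_rows[seq_icd > cap]
    }
    for (h in over) {
      i <- hits[h, 1]; j <- hits[h, 2]
      proc_set <- if (is_priv[i]) ops$tuss[[j]] else ops$sigtap[[j]]
      if (length(proc_set) > 0) {
        route[h] <- "proc"; icd_code[h] <- NA_character_
        proc_code[h] <- pick(U_proc_pick[i, j], proc_set)
      } else {
        route[h] <- "hidden"; icd_code[h] <- NA_character_
      }
    }
  }
  observable <- planted
  if (nrow(hits) > 0) {
    observable[hits[route == "hidden", , drop = FALSE]] <- FALSE
  }
  n_obs <- as.integer(rowSums(observable))

  p_death <- plogis(config$beta0 + config$beta1 * n_obs)
  death <- u_death < p_death
  unknown <- unname(u_unknown <
                      config$unknown_outcome_fraction[schema])
  outcome_raw <- ifelse(unknown,
                        ifelse(u_censor < 0.5, "stay", "transfer"),
                        ifelse(death, "death", "discharge"))

  ## -- context diagnoses --
  ctx <- rep(NA_character_, n)
  sel <- obst & !is_priv
  ctx[sel] <- pick_vec(u_ctx[sel], .ctx_public)
  sel <- obst & is_priv & !masked
  ctx[sel] <- pick_vec(u_ctx[sel], .ctx_private)
  sel <- !obst & !neonatal & !masked
  ctx[sel] <- pick_vec(u_ctx[sel], .ctx_nonobst)
  ctx[neonatal] <- pick_vec(u_ctx[neonatal], .ctx_neonatal)

  ## -- multi-form structure (public only) --
  k <- rep(1L, n)
  can_split <- !is_priv & u_split < config$multi_form_fraction
  k[can_split] <- ifelse(u_k3[can_split] < 0.2, 3L, 2L)

  ## -- assemble per-record code lists --
  rec_diag <- tibble::tibble(
    rec = c(which(!is.na(ctx)), if (nrow(hits) > 0) hits[route == "icd", 1]),
    code = c(ctx[!is.na(ctx)], icd_code[route == "icd"]),
    is_ctx = c(rep(TRUE, sum(!is.na(ctx))), rep(FALSE, sum(route == "icd")))
  )
  rec_diag <- rec_diag[order(rec_diag$rec, !rec_diag$is_ctx), ]

  dcode <- rep(NA_character_, n)
  sel <- delivery & !is_priv
  dcode[sel] <- pick_vec(u_dcode[sel], codebook$delivery$sigtap)
  sel <- delivery & is_priv
  dcode[sel] <- pick_vec(u_dcode[sel], codebook$delivery$tuss)
  gen <- ifelse(is_priv, .generic_tuss, .generic_sigtap)

  rec_proc <- tibble::tibble(
    rec = c(which(delivery), if (nrow(hits) > 0) hits[route == "proc", 1],
            which(!obst)),
    code = c(dcode[delivery], proc_code[route == "proc"], gen[!obst])
  )
  rec_proc <- rec_proc[order(rec_proc$rec), ]

  type_raw <- ifelse(obst | neonatal, "3", "1")
  write_synthetic_files(dir, config, schema, adm_date, dis_date, stay,
                        icu_days, outcome_raw, type_raw, k, u_hosp, U_cut,
                        U_gap, rec_diag, rec_proc)

  form1 <- ifelse(is_priv, sprintf("V%07d", seq_len(n)),
                  sprintf("F%07d_1", seq_len(n)))
  truth <- tibble::tibble(
    episode_key = paste0("ep_", form1),
    schema = schema, obstetric = obst, neonatal = neonatal,
    masked = masked, delivery = delivery, n_forms = k, stay = stay,
    n_planted = as.integer(rowSums(planted)), n_observable = n_obs,
    death = death, unknown_outcome = unknown, outcome = outcome_raw
  )
  for (j in seq_len(ncrit)) {
    truth[[paste0("planted_", .criterion_names[j])]] <- planted[, j]
  }
  for (j in seq_len(ncrit)) {
    truth[[paste0("observable_", .criterion_names[j])]] <- observable[, j]
  }
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(truth, truth_path, progress = FALSE)
  list(
    paths = list(reduced = file.path(dir, "reduced.csv"),
                 services = file.path(dir, "services.csv"),
                 consolidated = file.path(dir, "consolidated.csv"),
                 detailed = file.path(dir, "detailed.csv"),
                 truth = truth_path),
    truth = truth
  )
}

pick_vec <- function(u, codes) codes[1L + floor(u * length(codes))]

# Expand records into admission forms and write the four schema files.
write_synthetic_files <- function(dir, config, schema, adm_date, dis_date,
                                  stay, icu_days, outcome_raw, type_raw, k,
                                  u_hosp, U_cut, U_gap, rec_diag, rec_proc) {
  n <- length(schema)
  is_priv <- schema == "PRIVATE"
  gp <- config$gap_one_day_prob

  # per-record form boundaries (vectorized over the three split shapes)
  idx1 <- which(!is_priv & k == 1L)
  idx2 <- which(k == 2L)
  idx3 <- which(k == 3L)

  f1 <- data.frame(rec = idx1, seq = 1L, adm = adm_date[idx1],
                   dis = dis_date[idx1])

  a <- adm_date[idx2]; d <- dis_date[idx2]
  c1 <- pmin(a + floor(U_cut[idx2, 1] * (stay[idx2] + 1)), d)
  a2 <- pmin(c1 + as.integer(U_gap[idx2, 1] < gp), d)
  f2 <- data.frame(rec = rep(idx2, 2), seq = rep(1:2, each = length(idx2)),
                   adm = c(a, a2), dis = c(c1, d))

  a <- adm_date[idx3]; d <- dis_date[idx3]
  cA <- a + floor(U_cut[idx3, 1] * (stay[idx3] + 1))
  cB <- a + floor(U_cut[idx3, 2] * (stay[idx3] + 1))
  c1 <- pmin(pmin(cA, cB), d)
  a2 <- pmin(c1 + as.integer(U_gap[idx3, 1] < gp), d)
  c2 <- pmax(pmin(pmax(cA, cB), d), a2)
  a3 <- pmin(c2 + as.integer(U_gap[idx3, 2] < gp), d)
  f3 <- data.frame(rec = rep(idx3, 3), seq = rep(1:3, each = length(idx3)),
                   adm = c(a, a2, a3), dis = c(c1, c2, d))

  forms <- rbind(f1, f2, f3)
  forms <- forms[order(forms$rec, forms$seq), ]
  forms$form_id <- sprintf("F%07d_%d", forms$rec, forms$seq)
  last <- forms$seq == k[forms$rec]
  forms$reason <- ifelse(last, outcome_raw[forms$rec], "stay")
  forms$icu_days <- ifelse(forms$seq == 1L, icu_days[forms$rec], 0L)
  forms$person <- sprintf("P%07d", forms$rec)
  forms$hospital <- sprintf("H%03d", 1L + floor(u_hosp[forms$rec] * 150))

  # distribute diagnoses/procedures of split records over their forms;
  # these draws are last so earlier streams stay aligned across configs
  pub_diag <- rec_diag[!is_priv[rec_diag$rec], ]
  pub_proc <- rec_proc[!is_priv[rec_proc$rec], ]
  pub_diag$form_seq <- 1L + floor(runif(nrow(pub_diag)) * k[pub_diag$rec])
  pub_proc$form_seq <- 1L + floor(runif(nrow(pub_proc)) * k[pub_proc$rec])
  pub_diag$form_id <- sprintf("F%07d_%d", pub_diag$rec, pub_diag$form_seq)
  pub_proc$form_id <- sprintf("F%07d_%d", pub_proc$rec, pub_proc$form_seq)

  # wide diagnosis slots per form, filled in item order
  cols_pub <- paste0("diag_", public_diag_fields)
  reduced <- tibble::tibble(
    form_id = forms$form_id, person_key = forms$person,
    hospital_key = forms$hospital,
    admission_date = format(forms$adm, "%Y-%m-%d"),
    discharge_date = format(forms$dis, "%Y-%m-%d"),
    discharge_reason = forms$reason, icu_days = forms$icu_days
  )
  dmat <- matrix(NA_character_, nrow(forms), length(cols_pub),
                 dimnames = list(NULL, cols_pub))
  if (nrow(pub_diag) > 0) {
    ridx <- match(pub_diag$form_id, forms$form_id)
    slot <- stats::ave(rep(1L, nrow(pub_diag)), ridx, FUN = cumsum)
    keep <- slot <= length(cols_pub)
    dmat[cbind(ridx[keep], slot[keep])] <- pub_diag$code[keep]
  }
  reduced <- dplyr::bind_cols(reduced, tibble::as_tibble(dmat))
  services <- tibble::tibble(form_id = pub_proc$form_id,
                             procedure = pub_proc$code)

  priv_idx <- which(is_priv)
  event_id <- sprintf("V%07d", priv_idx)
  cols_priv <- private_diag_fields
  consolidated <- tibble::tibble(
    event_id = event_id,
    admission_date = format(adm_date[priv_idx], "%Y-%m-%d"),
    discharge_date = format(dis_date[priv_idx], "%Y-%m-%d"),
    type_of_hospitalization = type_raw[priv_idx],
    discharge_reason = outcome_raw[priv_idx]
  )
  pmat <- matrix(NA_character_, length(priv_idx), length(cols_priv),
                 dimnames = list(NULL, cols_priv))
  priv_diag <- rec_diag[is_priv[rec_diag$rec], ]
  if (nrow(priv_diag) > 0) {
    ridx <- match(priv_diag$rec, priv_idx)
    slot <- stats::ave(rep(1L, nrow(priv_diag)), ridx, FUN = cumsum)
    keep <- slot <= length(cols_priv)
    pmat[cbind(ridx[keep], slot[keep])] <- priv_diag$code[keep]
  }
  consolidated <- dplyr::bind_cols(consolidated, tibble::as_tibble(pmat))
  priv_proc <- rec_proc[is_priv[rec_proc$rec], ]
  detailed <- tibble::tibble(event_id = sprintf("V%07d", priv_proc$rec),
                             procedure = priv_proc$code)

  readr::write_csv(reduced, file.path(dir, "reduced.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(services, file.path(dir, "services.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(consolidated, file.path(dir, "consolidated.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(detailed, file.path(dir, "detailed.csv"), na = "",
                   progress = FALSE)
  invisible(NULL)
}

#' Recovery report: classification against planted truth
#'
#' Joins classified profiles to the generator's truth table and reports,
#' per criterion, sensitivity against planted and against
#' planted-and-observable hits, specificity, and the prevalence bias
#' (classified minus planted prevalence among truly obstetric episodes),
#' plus the sign of the fitted death gradient (logistic regression of
#' death on the number of classified criteria over known-outcome
#' episodes).
#'
#' @param profiles An `smm_profiles` tibble from [smm_classify()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @return A list: `criteria` (per-criterion tibble) and `death_gradient`
#'   (fitted slope, its sign, and the model n).
#' @export
recover_parameters <- function(profiles, truth) {
  crit <- profile_criteria(profiles)
  if (is.null(crit)) stop("profiles lack the criterion_groups attribute")
  if (nrow(truth) == 0) {
    return(list(criteria = tibble::tibble(
      criterion = character(0), n_planted = integer(0),
      n_observable = integer(0), sensitivity = numeric(0),
      sensitivity_observable = numeric(0), specificity = numeric(0),
      prevalence_planted = numeric(0), prevalence_classified = numeric(0),
      prevalence_bias = numeric(0)),
      death_gradient = list(slope = NA_real_, sign = NA_integer_, n = 0L)))
  }
  tr <- truth[truth$obstetric, ]
  m <- match(tr$episode_key, profiles$episode_id)
  rows <- lapply(crit, function(cr) {
    planted <- tr[[paste0("planted_", cr)]]
    observable <- tr[[paste0("observable_", cr)]]
    v <- profiles[[cr]]
    classified <- !is.na(m) & !is.na(v[pmax(m, 1L)]) & v[pmax(m, 1L)]
    classified[is.na(m)] <- FALSE
    tibble::tibble(
      criterion = cr,
      n_planted = sum(planted),
      n_observable = sum(observable),
      sensitivity = if (any(planted)) mean(classified[planted]) else NA_real_,
      sensitivity_observable =
        if (any(observable)) mean(classified[observable]) else NA_real_,
      specificity =
        if (any(!planted)) mean(!classified[!planted]) else NA_real_,
      prevalence_planted = mean(planted),
      prevalence_classified = mean(classified),
      prevalence_bias = mean(classified) - mean(planted)
    )
  })
  known <- known_outcome_filter(profiles)
  grad <- list(slope = NA_real_, sign = NA_integer_, n = nrow(known))
  if (nrow(known) > 1 && length(unique(known$n_criteria)) > 1) {
    fit <- tryCatch(
      suppressWarnings(
        glm((as.character(outcome) == "DEATH") ~ n_criteria,
            family = binomial(), data = known)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      grad$slope <- unname(coef(fit)["n_criteria"])
      grad$sign <- as.integer(sign(grad$slope))
    }
  }
  list(criteria = dplyr::bind_rows(rows), death_gradient = grad)
}
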
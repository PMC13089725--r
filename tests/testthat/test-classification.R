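cb <- load_codebook()

pub_ep <- function(...) assemble_episodes(pub_cohort(...))
priv_ep <- function(...) assemble_episodes(priv_cohort(...))

test_that("criteria fire on listed diagnoses or schema-matched procedures", {
  ep <- pub_ep(list(pub_row("f1", principal = "O141")))
  expect_true(evaluate_criterion(ep, "severe_preeclampsia", cb))
  expect_false(evaluate_criterion(ep, "eclampsia", cb))

  ep <- pub_ep(list(pub_row("f1")), procs = sigtap_procs("f1", "0303100028"))
  expect_true(evaluate_criterion(ep, "eclampsia", cb))

  ep <- priv_ep(list(priv_row("v1", type = "3")),
                procs = tuss_procs("v1", "40302016"))
  expect_true(evaluate_criterion(ep, "respiratory_failure", cb))

  # no listed code: all 22 criteria false
  ep <- pub_ep(list(pub_row("f1", principal = "O800")))
  p <- smm_classify(ep, cb)
  expect_equal(p$n_criteria, 0L)
  expect_false(p$is_smm)
})

test_that("prolonged stay needs a delivery, a strict 7-day excess, and no newborn-care act", {
  del <- function(dis, extra = character(0)) {
    pub_ep(list(pub_row("f1", adm = "2020-03-01", dis = dis)),
           procs = sigtap_procs("f1", c("0310010012", extra)))
  }
  expect_true(prolonged_stay_rule(del("2020-03-10"), cb))    # 9 days
  expect_false(prolonged_stay_rule(del("2020-03-08"), cb))   # exactly 7
  expect_false(prolonged_stay_rule(del("2020-03-10", "0802010024"), cb))
  # no delivery procedure: a long stay alone is not the criterion
  long_stay <- pub_ep(list(pub_row("f1", adm = "2020-03-01",
                                   dis = "2020-03-15",
                                   principal = "O800")))
  expect_false(prolonged_stay_rule(long_stay, cb))
  # the private dialect has no newborn-care exclusion
  pep <- priv_ep(list(priv_row("v1", type = "3", adm = "2020-03-01",
                               dis = "2020-03-10")),
                 procs = tuss_procs("v1", "31309062"))
  expect_true(prolonged_stay_rule(pep, cb))
})

test_that("ICU admission uses the days counter or the unit procedures", {
  ep <- pub_ep(list(pub_row("f1", icu = 1L, principal = "O800")))
  expect_true(icu_rule(ep, cb))
  ep <- pub_ep(list(pub_row("f1", icu = 0L, principal = "O800")))
  expect_false(icu_rule(ep, cb))
  ep <- pub_ep(list(pub_row("f1")), procs = sigtap_procs("f1", "0802010105"))
  expect_true(icu_rule(ep, cb))
  ep <- priv_ep(list(priv_row("v1", type = "3")),
                procs = tuss_procs("v1", "60001038"))
  expect_true(icu_rule(ep, cb))
})

test_that("curettage counts as surgical intervention only in a childbirth or puerperal context", {
  cur_del <- pub_ep(list(pub_row("f1")),
                    procs = sigtap_procs("f1", c("0411020013",
                                                 "0310010012")))
  expect_true(evaluate_criterion(cur_del, "surgical_intervention", cb))

  cur_only <- pub_ep(list(pub_row("f1", principal = "O039")),
                     procs = sigtap_procs("f1", "0411020013"))
  expect_false(evaluate_criterion(cur_only, "surgical_intervention", cb))

  cur_puerp <- pub_ep(list(pub_row("f1", principal = "O85")),
                      procs = sigtap_procs("f1", "0411020013"))
  expect_true(evaluate_criterion(cur_puerp, "surgical_intervention", cb))

  # an unconditional listed act fires regardless of context
  plain <- pub_ep(list(pub_row("f1")), procs = sigtap_procs("f1",
                                                            "0407040161"))
  expect_true(evaluate_criterion(plain, "surgical_intervention", cb))
})

test_that("classification is the per-criterion union with group mapping", {
  ep <- pub_ep(list(pub_row("f1", principal = "O150",
                            secondary_1 = "Z513")))
  p <- smm_classify(ep, cb)
  hits <- operational_criteria(cb)[unlist(p[1, operational_criteria(cb)])]
  expect_setequal(hits, c("eclampsia", "blood_transfusion"))
  expect_equal(p$n_criteria, 2L)
  groups <- criterion_group_map(cb)
  expect_setequal(unique(groups[hits]), c("HYPERTENSIVE", "MANAGEMENT"))
})

test_that("an episode engineered to fire ten criteria counts exactly ten", {
  codes <- c(abruptio_placentae = "O450", ectopic_pregnancy = "O000",
             postpartum_haemorrhage = "O720", ruptured_uterus = "O710",
             severe_preeclampsia = "O141", eclampsia = "O150",
             hypertensive_encephalopathy = "I674",
             severe_hypertension = "I109", endometritis = "O85",
             pulmonary_oedema = "J81")
  row <- pub_row("f1", principal = codes[[1]])
  for (i in 2:10) row[[paste0("diag_secondary_", i - 1)]] <- codes[[i]]
  ep <- pub_ep(list(row))
  p <- smm_classify(ep, cb)
  # oracle: evaluate each criterion independently
  per_crit <- vapply(operational_criteria(cb), function(cr) {
    evaluate_criterion(ep, cr, cb)
  }, logical(1))
  expect_equal(p$n_criteria, sum(per_crit))
  expect_equal(p$n_criteria, 10L)
  expect_setequal(names(per_crit)[per_crit], names(codes))
})

test_that("removing a code that triggers only one criterion changes only that criterion", {
  with_code <- pub_ep(list(pub_row("f1", principal = "O450",
                                   secondary_1 = "Z513")))
  without <- pub_ep(list(pub_row("f1", secondary_1 = "Z513")))
  pw <- smm_classify(with_code, cb)
  po <- smm_classify(without, cb)
  crit <- operational_criteria(cb)
  delta <- vapply(crit, function(cr) pw[[cr]] != po[[cr]], logical(1))
  expect_equal(names(delta)[delta], "abruptio_placentae")
})

test_that("union bound and group union semantics hold on a simulated cohort", {
  dir <- tempfile()
  res <- simulate_cohort(sim_config(n_episodes = 3000, seed = 99), dir)
  pub <- read_public_pair(file.path(dir, "reduced.csv"),
                          file.path(dir, "services.csv"))
  sp <- smm_surveillance(pub, cb)
  p <- sp$profiles
  crit <- operational_criteria(cb)
  per_counts <- vapply(crit, function(cr) sum(p[[cr]]), integer(1))
  expect_lte(sum(p$is_smm), sum(per_counts))
  freq <- frequency_table(p, sp$n_obstetric)
  groups <- criterion_group_map(cb)
  for (g in unique(unname(groups))) {
    grp_total <- freq$n_cases[freq$name == g]
    col_sum <- sum(per_counts[names(groups)[groups == g]])
    expect_lte(grp_total, col_sum)
    expect_gte(grp_total, max(per_counts[names(groups)[groups == g]]))
  }
  unlink(dir, recursive = TRUE)
})
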
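test_that("same-day or next-day continuations chain; longer gaps split", {
  co <- pub_cohort(list(
    pub_row("a1", adm = "2020-03-01", dis = "2020-03-05"),
    pub_row("a2", adm = "2020-03-05", dis = "2020-03-08",
            reason = "discharge")))
  ep <- assemble_episodes(co)
  expect_equal(nrow(ep$episodes), 1L)
  expect_equal(ep$episodes$n_forms, 2L)
  expect_equal(ep$episodes$admission_date, as.Date("2020-03-01"))
  expect_equal(ep$episodes$discharge_date, as.Date("2020-03-08"))

  co2 <- pub_cohort(list(
    pub_row("a1", adm = "2020-03-01", dis = "2020-03-05"),
    pub_row("a2", adm = "2020-03-09", dis = "2020-03-12")))
  expect_equal(nrow(assemble_episodes(co2)$episodes), 2L)

  # different hospital or person always splits
  co3 <- pub_cohort(list(
    pub_row("a1", adm = "2020-03-01", dis = "2020-03-05"),
    pub_row("a2", hosp = "H2", adm = "2020-03-05", dis = "2020-03-08")))
  expect_equal(nrow(assemble_episodes(co3)$episodes), 2L)
})

test_that("chaining is transitive over consecutive handoffs", {
  co <- pub_cohort(list(
    pub_row("a1", adm = "2020-03-01", dis = "2020-03-03", icu = 1L,
            principal = "O800"),
    pub_row("a2", adm = "2020-03-03", dis = "2020-03-06", icu = 2L,
            secondary_1 = "O450"),
    pub_row("a3", adm = "2020-03-07", dis = "2020-03-10",
            reason = "death")))
  ep <- assemble_episodes(co)
  expect_equal(nrow(ep$episodes), 1L)
  expect_equal(ep$episodes$n_forms, 3L)
  expect_equal(ep$episodes$icu_days, 3L)     # summed over members
  expect_equal(as.character(ep$episodes$outcome), "DEATH")
  # union of member diagnoses, re-keyed to the episode
  expect_setequal(ep$diagnoses$icd, c("O800", "O450"))
  expect_equal(unique(ep$diagnoses$episode_id), "ep_a1")
})

test_that("assembled partition matches the exhaustive pairwise-closure oracle", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    rows <- lapply(seq_len(n), function(i) {
      adm <- as.Date("2020-06-01") + sample(0:9, 1)
      pub_row(sprintf("f%02d", i),
              person = sample(c("PA", "PB"), 1),
              hosp = sample(c("H1", "H2"), 1),
              adm = format(adm), dis = format(adm + sample(0:3, 1)))
    })
    co <- pub_cohort(rows)
    ep <- assemble_episodes(co, max_gap_days = 1)
    got <- canonical_partition(partition_sets(ep$members))
    want <- canonical_partition(closure_partition(co$admissions, 1))
    expect_equal(got, want)
    # partition property: every record in exactly one episode
    expect_equal(sum(ep$episodes$n_forms), nrow(co$admissions))
    expect_equal(sort(ep$members$form_id), sort(co$admissions$form_id))
  }
})

test_that("episode count is non-increasing in the gap threshold", {
  set.seed(303)
  rows <- lapply(1:15, function(i) {
    adm <- as.Date("2020-06-01") + sample(0:20, 1)
    pub_row(sprintf("f%02d", i), person = sample(c("PA", "PB"), 1),
            adm = format(adm), dis = format(adm + sample(0:4, 1)))
  })
  co <- pub_cohort(rows)
  counts <- vapply(c(0, 1, 2, 5, 30), function(g) {
    nrow(assemble_episodes(co, max_gap_days = g)$episodes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("private events and single records pass through unchanged", {
  priv <- priv_cohort(list(
    priv_row("v1", type = "3", adm = "2020-01-01", dis = "2020-01-02"),
    priv_row("v2", type = "3", adm = "2020-01-02", dis = "2020-01-03")),
    procs = tuss_procs("v1", "31309062"))
  ep <- assemble_episodes(priv)
  expect_equal(nrow(ep$episodes), 2L)       # never chained
  expect_true(all(ep$episodes$n_forms == 1L))

  pub <- pub_cohort(list(pub_row("f1", adm = "2020-05-01",
                                 dis = "2020-05-04", icu = 3L,
                                 principal = "O149", reason = "death")),
                    procs = sigtap_procs("f1", "0310010012"))
  ep1 <- assemble_episodes(pub)
  expect_equal(ep1$episodes$admission_date, as.Date("2020-05-01"))
  expect_equal(ep1$episodes$discharge_date, as.Date("2020-05-04"))
  expect_equal(ep1$episodes$icu_days, 3L)
  expect_equal(as.character(ep1$episodes$outcome), "DEATH")
  expect_equal(ep1$diagnoses$icd, "O149")
  expect_equal(ep1$procedures$code, "0310010012")
})

test_that("records lacking keys become flagged singletons", {
  co <- pub_cohort(list(
    pub_row("f1", person = NA, adm = "2020-03-01", dis = "2020-03-02"),
    pub_row("f2", person = NA, adm = "2020-03-02", dis = "2020-03-03")))
  ep <- assemble_episodes(co)
  expect_equal(nrow(ep$episodes), 2L)
  expect_true(all(ep$episodes$flagged_missing_key))
})

test_that("episode outcome is the final member's; early death is invalid", {
  expect_equal(as.character(episode_outcome(c("TRANSFER", "DEATH"))),
               "DEATH")
  expect_equal(as.character(episode_outcome("DISCHARGE_ALIVE")),
               "DISCHARGE_ALIVE")
  expect_equal(as.character(episode_outcome(c("STAY", "TRANSFER"))),
               "TRANSFER")
  expect_error(episode_outcome(c("DEATH", "DISCHARGE_ALIVE")),
               "final")
  # the same validation fires during assembly
  co <- pub_cohort(list(
    pub_row("f1", adm = "2020-03-01", dis = "2020-03-03",
            reason = "death"),
    pub_row("f2", adm = "2020-03-03", dis = "2020-03-06")))
  expect_error(assemble_episodes(co), "non-final")
})
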
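cb <- load_codebook()

test_that("odds ratio follows the cross-product contract with explicit edge markers", {
  expect_equal(round_half_up(
    odds_ratio(two_by_two(160, 59899, 7456 - 160, 18621293 - 59899)), 2),
    6.80)
  expect_equal(round_half_up(
    odds_ratio(two_by_two(269, 1006, 7456 - 269, 18621293 - 1006)), 2),
    692.78)
  expect_equal(odds_ratio(two_by_two(0, 10, 5, 100)), 0)
  expect_equal(odds_ratio(two_by_two(7, 7, 13, 13)), 1)
  expect_true(is.na(odds_ratio(two_by_two(3, 0, 5, 100))))
  expect_true(is.na(odds_ratio(two_by_two(3, 10, 0, 100))))
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
  expect_error(two_by_two(1.5, 2, 3, 4), "integer")
})

test_that("the complement criterion's odds ratio is the reciprocal", {
  set.seed(11)
  for (i in 1:10) {
    cells <- sample(1:500, 4)
    or1 <- odds_ratio(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    or2 <- odds_ratio(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(or2, 1 / or1)
  }
})

test_that("known-outcome filter retains exactly live discharges and deaths", {
  p <- random_profiles(5, seed = 21)
  p$outcome <- factor(c("DISCHARGE_ALIVE", "DEATH", "TRANSFER",
                        "DISCHARGE_ALIVE", "DEATH"),
                      levels = levels(p$outcome))
  k <- known_outcome_filter(p)
  expect_equal(nrow(k), 4L)
  expect_identical(known_outcome_filter(k), k)      # idempotent
  p$outcome <- factor(rep("STAY", 5), levels = levels(p$outcome))
  expect_equal(nrow(known_outcome_filter(p)), 0L)
})

test_that("frequency table uses the full obstetric denominator and union group totals", {
  p <- random_profiles(200, seed = 31)
  freq <- frequency_table(p, n_obstetric = 400)
  one <- freq[freq$level == "criterion", ][1, ]
  expect_equal(one$pct_of_hospitalizations, 100 * one$n_cases / 400)
  expect_equal(one$pct_of_smm_cases, 100 * one$n_cases / sum(p$is_smm))
  overall <- freq[freq$level == "overall", ]
  expect_equal(overall$n_cases, sum(p$is_smm))
  expect_true(is.na(overall$pct_of_smm_cases))
  # a profile with zero cases yields zero percentages
  p0 <- random_profiles(50, seed = 32, p_hit = 0)
  f0 <- frequency_table(p0, 50)
  expect_true(all(f0$pct_of_hospitalizations == 0))
})

test_that("criterion, group and overall 2x2 cells match exhaustive enumeration", {
  p <- random_profiles(20, seed = 5)
  tab <- criterion_or_table(p)
  groups <- attr(p, "criterion_groups")
  # oracle: walk the 20 episodes one by one and count the four cells
  for (r in seq_len(nrow(tab))) {
    a <- b <- cc <- d <- 0L
    for (i in seq_len(nrow(p))) {
      oc <- as.character(p$outcome[i])
      if (!oc %in% c("DISCHARGE_ALIVE", "DEATH")) next
      hit <- switch(tab$level[r],
        criterion = p[[tab$name[r]]][i],
        group = any(unlist(p[i, names(groups)[groups == tab$name[r]]])),
        overall = p$is_smm[i])
      if (hit && oc == "DEATH") a <- a + 1L
      else if (hit) b <- b + 1L
      else if (oc == "DEATH") cc <- cc + 1L
      else d <- d + 1L
    }
    expect_equal(unlist(tab[r, c("a", "b", "c", "d")], use.names = FALSE),
                 c(a, b, cc, d))
    want_or <- if (b == 0 || cc == 0) NA_real_
               else if (a == 0) 0 else (a * d) / (b * cc)
    expect_equal(tab$odds_ratio[r], want_or)
  }
  # a criterion met by every known-outcome episode is undefined (c = 0)
  p2 <- random_profiles(10, seed = 6)
  p2$eclampsia <- TRUE
  t2 <- criterion_or_table(p2)
  expect_true(is.na(t2$odds_ratio[t2$name == "eclampsia"]))
})

test_that("deaths by criterion count partition the known-outcome cohort", {
  p <- random_profiles(300, seed = 41)
  tab <- deaths_by_count(p)
  known <- known_outcome_filter(p)
  expect_equal(sum(tab$total), nrow(known))
  expect_equal(sum(tab$deaths),
               sum(as.character(known$outcome) == "DEATH"))
  expect_equal(tab$alive + tab$deaths, tab$total)
  expect_equal(tab$n_criteria, 0:max(known$n_criteria))
  expect_equal(tab$pct_death,
               ifelse(tab$total > 0, 100 * tab$deaths / tab$total, NA))
  # an all-zero-criteria cohort collapses to a single row
  p0 <- random_profiles(40, seed = 42, p_hit = 0)
  expect_equal(nrow(deaths_by_count(p0)), 1L)
})

test_that("cross-schema ratios divide hospitalization shares with safe zeros", {
  p1 <- random_profiles(150, seed = 51)
  p2 <- random_profiles(150, seed = 52)
  f1 <- frequency_table(p1, 300); f2 <- frequency_table(p2, 300)
  r <- cross_schema_ratio(f1, f2)
  i <- which(r$level == "criterion")[1]
  nm <- r$name[i]
  expect_equal(r$ratio_hospitalizations[i],
               f1$pct_of_hospitalizations[f1$name == nm] /
                 f2$pct_of_hospitalizations[f2$name == nm])
  expect_equal(cross_schema_ratio(f1, f1)$ratio_hospitalizations[1], 1)
  f2z <- f2; f2z$pct_of_hospitalizations[] <- 0
  expect_true(all(is.na(
    cross_schema_ratio(f1, f2z)$ratio_hospitalizations)))
})

test_that("report writer emits the three surveillance tables", {
  p1 <- random_profiles(120, seed = 61)
  p2 <- random_profiles(120, seed = 62)
  dir <- tempfile()
  paths <- write_report_tables(p1, p2, dir, 200, 200)
  expect_true(all(file.exists(paths)))
  freq <- readr::read_csv(paths[["frequency"]], show_col_types = FALSE)
  expect_setequal(unique(freq$schema), c("PUBLIC", "PRIVATE"))
  expect_true("ratio_hospitalizations" %in% names(freq))
  ors <- readr::read_csv(paths[["odds_ratios"]], show_col_types = FALSE)
  expect_equal(nrow(ors), 2 * (22 + 4 + 1))
  dbc <- readr::read_csv(paths[["deaths_by_count"]], show_col_types = FALSE)
  expect_true(all(c("TOTAL_HOSPITALIZATIONS", "TOTAL_SMM_CASES") %in%
                    dbc$row))
  unlink(dir, recursive = TRUE)
})
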
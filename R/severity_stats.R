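#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.005 -> 0.01), matching
#' how the surveillance tables print percentages and odds ratios; R's
#' `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a 2x2 criterion-by-death table
#'
#' Cell contract: `a` deaths with the criterion, `b` alive with the
#' criterion, `c` deaths without, `d` alive without — all counted over
#' known-outcome episodes, with "without the criterion" meaning every other
#' episode (including those meeting other criteria).
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells))) stop("2x2 cells must not be NA")
  if (any(cells < 0)) stop("2x2 cells must be non-negative")
  if (any(cells != trunc(cells))) stop("2x2 cells must be integer counts")
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("criterion", "no criterion"),
                              c("death", "alive")))
  print(m)
  invisible(x)
}

#' Odds ratio of death for a 2x2 table
#'
#' Plain cross-product ratio `(a*d)/(b*c)` with no continuity correction.
#' A zero death cell in the criterion arm (`a = 0`) gives 0; a zero `b` or
#' `c` cell makes the ratio undefined and returns `NA`.
#'
#' @param table A [two_by_two()] object.
#' @return A single number, 0, or `NA` (undefined).
#' @examples
#' odds_ratio(two_by_two(269, 1006, 7456 - 269, 18621293 - 1006))
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  if (table$b == 0 || table$c == 0) return(NA_real_)
  if (table$a == 0) return(0)
  (table$a * table$d) / (table$b * table$c)
}

#' Woolf (log-OR) confidence interval
#'
#' Provided for completeness; the surveillance tables print point odds
#' ratios only, so no interval is attached by default anywhere else.
#'
#' @param table A [two_by_two()] object with all cells positive.
#' @param conf Confidence level.
#' @return Named numeric vector `or`, `lower`, `upper`.
#' @export
woolf_ci <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  if (any(unlist(table) == 0)) stop("Woolf interval needs all cells > 0")
  or <- odds_ratio(table)
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Restrict profiles to episodes with a known survival outcome
#'
#' The mortality analyses use only episodes that ended in live discharge or
#' in-hospital death; stays, transfers and unreported discharges are
#' excluded. Idempotent.
#'
#' @param profiles An `smm_profiles` tibble.
#' @return The retained rows, attributes preserved.
#' @export
known_outcome_filter <- function(profiles) {
  keep <- as.character(profiles$outcome) %in% known_outcomes()
  out <- profiles[keep, ]
  attr(out, "criterion_groups") <- attr(profiles, "criterion_groups")
  out
}

group_hit_matrix <- function(profiles) {
  groups <- attr(profiles, "criterion_groups")
  if (is.null(groups)) stop("profiles lack the criterion_groups attribute")
  vapply(unique(unname(groups)), function(g) {
    cols <- names(groups)[groups == g]
    rowSums(as.matrix(profiles[, cols, drop = FALSE])) > 0
  }, logical(nrow(profiles)))
}

#' Criterion frequency table
#'
#' Counts cases and percentages per criterion, per severity group and
#' overall, from classified profiles. Percentages of obstetric
#' hospitalizations use `n_obstetric` (all obstetric episodes, not
#' outcome-filtered); percentages of SMM cases use the number of episodes
#' meeting at least one criterion. Group totals count episodes meeting any
#' criterion of the group once (union semantics), so a group total can be
#' below its column sum.
#'
#' @param profiles An `smm_profiles` tibble over all obstetric episodes.
#' @param n_obstetric Denominator for the hospital share; defaults to
#'   `nrow(profiles)`.
#' @return Tibble: `name`, `level` (criterion/group/overall), `n_cases`,
#'   `pct_of_hospitalizations`, `pct_of_smm_cases`.
#' @export
frequency_table <- function(profiles, n_obstetric = nrow(profiles)) {
  crit <- profile_criteria(profiles)
  groups <- attr(profiles, "criterion_groups")
  n_smm <- sum(profiles$is_smm)
  gm <- group_hit_matrix(profiles)

  rows <- list()
  for (g in colnames(gm)) {
    for (cr in names(groups)[groups == g]) {
      rows[[length(rows) + 1]] <-
        tibble::tibble(name = cr, level = "criterion",
                       n_cases = sum(profiles[[cr]]))
    }
    rows[[length(rows) + 1]] <-
      tibble::tibble(name = g, level = "group", n_cases = sum(gm[, g]))
  }
  rows[[length(rows) + 1]] <-
    tibble::tibble(name = "SMM", level = "overall", n_cases = n_smm)
  out <- dplyr::bind_rows(rows)
  out$pct_of_hospitalizations <-
    if (n_obstetric > 0) 100 * out$n_cases / n_obstetric else NA_real_
  out$pct_of_smm_cases <-
    if (n_smm > 0) 100 * out$n_cases / n_smm else NA_real_
  out$pct_of_smm_cases[out$level == "overall"] <- NA_real_
  out
}

#' Odds ratios of death per criterion, group and overall
#'
#' For each criterion (and each severity group and the overall case
#' definition, both under union semantics) builds the 2x2 table of death
#' against the criterion's complement within the known-outcome cohort and
#' computes the odds ratio. The reference arm is every episode not meeting
#' the criterion under analysis, including episodes meeting other criteria.
#'
#' @param profiles An `smm_profiles` tibble (filtered internally to known
#'   outcomes; [known_outcome_filter()] is idempotent).
#' @return Tibble: `name`, `level`, cells `a`, `b`, `c`, `d`, and
#'   `odds_ratio` (`NA` where undefined).
#' @export
criterion_or_table <- function(profiles) {
  profiles <- known_outcome_filter(profiles)
  groups <- attr(profiles, "criterion_groups")
  death <- as.character(profiles$outcome) == "DEATH"
  gm <- group_hit_matrix(profiles)

  one_row <- function(hit, name, level) {
    tab <- two_by_two(sum(death & hit), sum(!death & hit),
                      sum(death & !hit), sum(!death & !hit))
    tibble::tibble(name = name, level = level, a = tab$a, b = tab$b,
                   c = tab$c, d = tab$d, odds_ratio = odds_ratio(tab))
  }
  rows <- list()
  for (g in colnames(gm)) {
    for (cr in names(groups)[groups == g]) {
      rows[[length(rows) + 1]] <- one_row(profiles[[cr]], cr, "criterion")
    }
    rows[[length(rows) + 1]] <- one_row(gm[, g], g, "group")
  }
  rows[[length(rows) + 1]] <- one_row(profiles$is_smm, "SMM", "overall")
  dplyr::bind_rows(rows)
}

#' Deaths by number of criteria met
#'
#' Partitions the known-outcome cohort by the number of morbidity criteria
#' met and tabulates deaths, survivors and the death percentage per row.
#'
#' @param profiles An `smm_profiles` tibble (known-outcome filter applied
#'   internally).
#' @return Tibble with one row per observed criterion count (0 upward,
#'   gaps filled): `n_criteria`, `deaths`, `alive`, `total`, `pct_death`.
#' @export
deaths_by_count <- function(profiles) {
  profiles <- known_outcome_filter(profiles)
  death <- as.character(profiles$outcome) == "DEATH"
  kmax <- if (nrow(profiles) > 0) max(profiles$n_criteria) else 0L
  k <- factor(profiles$n_criteria, levels = 0:kmax)
  deaths <- as.integer(table(k[death]))
  totals <- as.integer(table(k))
  tibble::tibble(
    n_criteria = 0:kmax,
    deaths = deaths,
    alive = totals - deaths,
    total = totals,
    pct_death = ifelse(totals > 0, 100 * deaths / totals, NA_real_)
  )
}

#' Cross-schema frequency ratios
#'
#' Ratio of each criterion's share of hospitalizations (and of SMM cases)
#' between the public and private schemas, mirroring the sector-comparison
#' columns of the surveillance frequency table.
#'
#' @param freq_public,freq_private Outputs of [frequency_table()].
#' @return Tibble: `name`, `level`, `ratio_hospitalizations`, `ratio_smm`
#'   (`NA` where the private-schema share is zero).
#' @export
cross_schema_ratio <- function(freq_public, freq_private) {
  j <- dplyr::inner_join(freq_public, freq_private,
                         by = c("name", "level"),
                         suffix = c("_public", "_private"))
  safe_ratio <- function(num, den) {
    ifelse(is.na(den) | den == 0, NA_real_, num / den)
  }
  tibble::tibble(
    name = j$name, level = j$level,
    ratio_hospitalizations =
      safe_ratio(j$pct_of_hospitalizations_public,
                 j$pct_of_hospitalizations_private),
    ratio_smm = safe_ratio(j$pct_of_smm_cases_public,
                           j$pct_of_smm_cases_private)
  )
}
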
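#' National reference surveillance counts (Brazil, 2015-2022)
#'
#' Published national counts from the public (SIH/SUS) and private (ANS)
#' hospitalization databases, shipped as plain-text reference data:
#' cohort totals, criterion frequencies, death/alive cells per criterion
#' for the odds-ratio analysis, and deaths by number of criteria met. Used
#' to check that the package's estimators reproduce the published
#' percentages and odds ratios exactly from the printed counts. Note two
#' documented internal inconsistencies of the published private-sector
#' tables: the odds-ratio table's header N and overall-SMM death count do
#' not match the deaths-by-count table's totals; reconstruction checks are
#' therefore restricted to rows consistent with the latter.
#'
#' @param which One of `"totals"`, `"frequency"`, `"or_cells"`,
#'   `"deaths_by_count"`.
#' @return A tibble.
#' @export
national_reference <- function(which = c("totals", "frequency", "or_cells",
                                         "deaths_by_count")) {
  which <- match.arg(which)
  file <- c(totals = "national_totals.csv",
            frequency = "national_frequency.csv",
            or_cells = "national_or_cells.csv",
            deaths_by_count = "national_deaths_by_count.csv")[[which]]
  path <- system.file("extdata", file, package = "smmsurv", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reconstruct the published odds ratios from printed cells
#'
#' For each criterion/group/overall row of the published odds-ratio table,
#' rebuilds the full 2x2 table from the printed (death, alive) cells of
#' the criterion arm and the schema's known-outcome totals, and recomputes
#' the odds ratio.
#'
#' @param schema `"PUBLIC"` or `"PRIVATE"`.
#' @return Tibble with cells, the recomputed `odds_ratio` and the
#'   published value `or_published`.
#' @export
reconstruct_national_or <- function(schema = c("PUBLIC", "PRIVATE")) {
  schema <- match.arg(schema)
  cells <- national_reference("or_cells")
  cells <- cells[cells$schema == schema, ]
  totals <- national_reference("totals")
  totals <- totals[totals$schema == schema, ]
  out <- cells
  out$c <- totals$deaths_known - cells$deaths_with
  out$d <- totals$alive_known - cells$alive_with
  out$odds_ratio <- vapply(seq_len(nrow(out)), function(i) {
    odds_ratio(two_by_two(out$deaths_with[i], out$alive_with[i],
                          out$c[i], out$d[i]))
  }, numeric(1))
  out
}
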
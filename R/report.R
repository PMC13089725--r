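#' Write the three surveillance report tables
#'
#' Emits the standard analysis surfaces as CSV, in codebook row order with
#' group totals after their members and the overall case-definition row
#' last:
#' \itemize{
#'   \item `frequency.csv` — criterion frequencies per schema with the
#'     cross-schema ratio columns;
#'   \item `odds_ratios.csv` — per-criterion 2x2 cells and odds ratio of
#'     in-hospital death per schema;
#'   \item `deaths_by_count.csv` — deaths by number of criteria met per
#'     schema, with marginal totals.
#' }
#' Either profile argument may be `NULL` when only one sector was
#' processed.
#'
#' @param profiles_public,profiles_private `smm_profiles` tibbles.
#' @param dir Output directory (created if needed).
#' @param n_obstetric_public,n_obstetric_private Obstetric-hospitalization
#'   denominators; default to the profile row counts.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report_tables <- function(profiles_public = NULL,
                                profiles_private = NULL, dir,
                                n_obstetric_public =
                                  NROW(profiles_public),
                                n_obstetric_private =
                                  NROW(profiles_private)) {
  if (is.null(profiles_public) && is.null(profiles_private)) {
    stop("at least one schema's profiles are required")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  freq <- list(); ors <- list(); dbc <- list()
  if (!is.null(profiles_public)) {
    f <- frequency_table(profiles_public, n_obstetric_public)
    freq$public <- dplyr::mutate(f, schema = "PUBLIC", .before = 1)
    ors$public <- dplyr::mutate(criterion_or_table(profiles_public),
                                schema = "PUBLIC", .before = 1)
    dbc$public <- dplyr::mutate(with_count_totals(profiles_public),
                                schema = "PUBLIC", .before = 1)
  }
  if (!is.null(profiles_private)) {
    f <- frequency_table(profiles_private, n_obstetric_private)
    freq$private <- dplyr::mutate(f, schema = "PRIVATE", .before = 1)
    ors$private <- dplyr::mutate(criterion_or_table(profiles_private),
                                 schema = "PRIVATE", .before = 1)
    dbc$private <- dplyr::mutate(with_count_totals(profiles_private),
                                 schema = "PRIVATE", .before = 1)
  }
  freq_tab <- dplyr::bind_rows(freq)
  if (length(freq) == 2) {
    ratios <- cross_schema_ratio(
      freq$public[-1], freq$private[-1])
    freq_tab <- dplyr::left_join(freq_tab, ratios, by = c("name", "level"))
  }

  paths <- c(frequency = file.path(dir, "frequency.csv"),
             odds_ratios = file.path(dir, "odds_ratios.csv"),
             deaths_by_count = file.path(dir, "deaths_by_count.csv"))
  readr::write_csv(freq_tab, paths[["frequency"]], na = "",
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(ors), paths[["odds_ratios"]], na = "",
                   progress = FALSE)
  readr::write_csv(dplyr::bind_rows(dbc), paths[["deaths_by_count"]],
                   na = "", progress = FALSE)
  invisible(paths)
}

with_count_totals <- function(profiles) {
  tab <- deaths_by_count(profiles)
  known <- known_outcome_filter(profiles)
  death <- as.character(known$outcome) == "DEATH"
  smm <- known$is_smm
  deaths_tot <- c(sum(death), sum(death & smm))
  n_tot <- c(nrow(known), sum(smm))
  totals <- tibble::tibble(
    n_criteria = NA_integer_,
    deaths = deaths_tot,
    alive = n_tot - deaths_tot,
    total = n_tot,
    pct_death = 100 * deaths_tot / pmax(n_tot, 1L),
    row = c("TOTAL_HOSPITALIZATIONS", "TOTAL_SMM_CASES")
  )
  tab$row <- as.character(tab$n_criteria)
  dplyr::bind_rows(tab, totals)
}
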
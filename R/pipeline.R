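#' Run the full screening pipeline
#'
#' Orchestrates cohort selection, sex/gender attention coding, study-class
#' labeling and summary-table generation as one reproducible run.  Writes
#' the cohort (JSON lines), the decision/assignment/class CSVs, the
#' summary tables and a JSON run manifest with a config snapshot, input
#' file digests and mutually consistent per-stage record counts.  Rerun on
#' identical inputs and config, the outputs are byte-identical.
#'
#' @param input Dump location: directory of AACT-dialect CSV tables, or a
#'   JSON-lines registrations file.
#' @param out_dir Output directory.
#' @param dialect `"aact"` or `"jsonl"`.
#' @param terms COVID term specs.
#' @param sg_terms Sex/gender term specs.
#' @param bank Sex/gender rule bank.
#' @param from,to Cohort date window.
#' @return The run manifest (a list), invisibly.
#' @export
run_pipeline <- function(input, out_dir, dialect = c("aact", "jsonl"),
                         terms = covid_terms(),
                         sg_terms = sexgender_terms(),
                         bank = default_rule_bank(),
                         from = "2020-01-01", to = "2021-01-26") {
  dialect <- match.arg(dialect)
  if (!file.exists(input)) {
    stop("input dump path does not exist: ", input, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  registry <- load_registry_dump(input, dialect = dialect)
  report <- attr(registry, "load_report")

  sel <- select_cohort(registry, terms = terms, from = from, to = to)
  cohort <- sel$cohort
  if (nrow(cohort) == 0) {
    stop("cohort selection produced zero studies", call. = FALSE)
  }
  assignments <- assign_category(cohort, terms = sg_terms, bank = bank)
  classes <- classify_study(cohort)
  frame <- analysis_frame(cohort, assignments, classes)

  cohort_path <- file.path(out_dir, "cohort.jsonl")
  write_registrations(cohort, cohort_path)
  readr::write_csv(
    sel$decisions, file.path(out_dir, "cohort_decisions.csv"),
    progress = FALSE
  )
  flat_assign <- assignments |>
    dplyr::mutate(
      fired_rules = vapply(.data$fired_rules, paste, character(1),
        collapse = ";"
      )
    ) |>
    dplyr::select("nct_id", "category", "subtag", "fired_rules",
      "n_matches", "needs_review")
  readr::write_csv(flat_assign, file.path(out_dir, "assignments.csv"),
    progress = FALSE
  )
  readr::write_csv(
    flat_assign[flat_assign$needs_review, , drop = FALSE],
    file.path(out_dir, "review_queue.csv"),
    progress = FALSE
  )
  readr::write_csv(classes, file.path(out_dir, "classes.csv"),
    progress = FALSE
  )
  table_paths <- write_summary_tables(frame, file.path(out_dir, "tables"))

  input_files <- if (dir.exists(input)) {
    list.files(input, full.names = TRUE, recursive = TRUE)
  } else {
    input
  }
  excluded <- table(sel$decisions$rule[!sel$decisions$included])
  manifest <- list(
    package_version = as.character(utils::packageVersion("trialcoder")),
    config = list(
      input = input, dialect = dialect, from = from, to = to,
      n_covid_terms = nrow(terms), n_sexgender_terms = nrow(sg_terms),
      n_rules = nrow(bank)
    ),
    input_digests = as.list(tools::md5sum(input_files)),
    counts = list(
      loaded = nrow(registry) + report$n_duplicate_ids,
      duplicate_rows_dropped_at_load = report$n_duplicate_ids,
      unique_registrations = nrow(registry),
      excluded = as.list(unclass(excluded)),
      cohort = nrow(cohort),
      by_category = as.list(table(
        factor(assignments$category, levels = .category_levels)
      )),
      by_label = as.list(table(
        factor(classes$label, levels = .label_levels)
      )),
      needs_review = sum(assignments$needs_review)
    )
  )
  stopifnot(
    manifest$counts$unique_registrations ==
      manifest$counts$cohort + sum(unlist(manifest$counts$excluded)),
    sum(unlist(manifest$counts$by_category)) == manifest$counts$cohort,
    sum(unlist(manifest$counts$by_label)) == manifest$counts$cohort
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
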
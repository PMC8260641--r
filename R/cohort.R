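.title_condition_fields <- c("OfficialTitle", "BriefTitle", "Conditions")
.primary_outcome_fields <- c("PrimaryOutcomeTitle", "PrimaryOutcomeDescription")

#' COVID-19 relevance decision for each registration
#'
#' A registration is included when a COVID-19 term occurs in its titles or
#' conditions (`TitleOrCondition`); otherwise when one occurs in a primary
#' outcome title/description (`PrimaryOutcome`); otherwise when terms occur
#' in at least two distinct other fields of the COVID search scope —
#' brief summary, detailed description, and the secondary/other outcome
#' titles and descriptions (`TwoOtherFields`).  Anything else is excluded
#' as `NotMatched`.
#'
#' @param registry A registry tibble.
#' @param terms COVID term specs (default [covid_terms()]).
#' @return A tibble with `nct_id`, `included`, `rule`, `n_matches` and an
#'   `evidence` list-column of term-match tibbles.
#' @export
covid_relevance <- function(registry, terms = covid_terms()) {
  matches <- registry_matches(registry, covid_scope(), terms)
  other_fields <- setdiff(
    covid_scope(), c(.title_condition_fields, .primary_outcome_fields)
  )
  per_id <- split(
    matches, factor(matches$nct_id, levels = unique(registry$nct_id))
  )
  rule <- vapply(registry$nct_id, function(id) {
    m <- per_id[[id]]
    if (is.null(m) || nrow(m) == 0) {
      return("NotMatched")
    }
    if (any(m$field %in% .title_condition_fields)) {
      return("TitleOrCondition")
    }
    if (any(m$field %in% .primary_outcome_fields)) {
      return("PrimaryOutcome")
    }
    if (length(unique(m$field[m$field %in% other_fields])) >= 2) {
      return("TwoOtherFields")
    }
    "NotMatched"
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    nct_id = registry$nct_id,
    included = rule %in% c("TitleOrCondition", "PrimaryOutcome",
      "TwoOtherFields"),
    rule = rule,
    n_matches = vapply(registry$nct_id, function(id) {
      m <- per_id[[id]]
      if (is.null(m)) 0L else nrow(m)
    }, integer(1), USE.NAMES = FALSE),
    evidence = lapply(registry$nct_id, function(id) {
      per_id[[id]] %||% empty_matches()
    })
  )
}

#' Date-window and status filter
#'
#' The effective date is the start date when present, else the submission
#' date.  A registration is kept iff the effective date lies in
#' `[from, to]` (both ends inclusive) and its status is not `Withdrawn` or
#' `No longer available`.
#'
#' @param registry A registry tibble.
#' @param from,to Window endpoints (default 2020-01-01 to 2021-01-26).
#' @return A list with `kept` (registry subset) and `log` (tibble of
#'   `nct_id`, `rule` in `{OutOfWindow, BadStatus}` for removed studies).
#' @export
window_and_status_filter <- function(registry, from = "2020-01-01",
                                     to = "2021-01-26") {
  from <- as.Date(from)
  to <- as.Date(to)
  effective <- dplyr::coalesce(registry$start_date, registry$submitted_date)
  in_window <- effective >= from & effective <= to
  bad_status <- tolower(trimws(registry$status)) %in%
    c("withdrawn", "no longer available")
  rule <- dplyr::case_when(
    !in_window ~ "OutOfWindow",
    bad_status ~ "BadStatus",
    .default = NA_character_
  )
  keep <- is.na(rule)
  list(
    kept = registry[keep, , drop = FALSE],
    log = tibble::tibble(
      nct_id = registry$nct_id[!keep], rule = rule[!keep]
    )
  )
}

#' Remove duplicate registrations
#'
#' Keeps the first record per `nct_id` (input order).  Records whose
#' normalized title pair (official + brief, lower-cased, punctuation and
#' whitespace collapsed) repeats an earlier record are flagged as
#' *candidate* duplicates in the log but retained, since identity beyond
#' the registry identifier is not decidable mechanically.
#'
#' @param registry A registry tibble.
#' @return A list with `kept` (deduplicated registry) and `log` (tibble of
#'   `nct_id`, `rule` in `{Duplicate, CandidateDuplicate}`).
#' @export
deduplicate <- function(registry) {
  dup <- duplicated(registry$nct_id)
  kept <- registry[!dup, , drop = FALSE]
  norm_title <- vapply(kept$texts, function(tx) {
    t <- tolower(paste(tx$OfficialTitle, tx$BriefTitle))
    gsub("[^a-z0-9]+", " ", t)
  }, character(1))
  candidate <- duplicated(norm_title) & nzchar(trimws(norm_title))
  list(
    kept = kept,
    log = dplyr::bind_rows(
      tibble::tibble(nct_id = registry$nct_id[dup], rule = "Duplicate"),
      tibble::tibble(
        nct_id = kept$nct_id[candidate], rule = "CandidateDuplicate"
      )
    )
  )
}

#' Select the COVID-19 study cohort
#'
#' Composes [deduplicate()], [window_and_status_filter()] and
#' [covid_relevance()] and returns the cohort plus one decision per input
#' registration.  Decision precedence for excluded records: `Duplicate`,
#' then `OutOfWindow`, then `BadStatus`, then `NotMatched`.
#'
#' @param registry A registry tibble.
#' @param terms COVID term specs.
#' @param from,to Date window (see [window_and_status_filter()]).
#' @return A list with `cohort` (registry subset), `decisions` (tibble of
#'   `nct_id`, `included`, `rule`, `n_matches`), and `evidence`
#'   (list-column copy of the term matches for included studies).
#' @export
select_cohort <- function(registry, terms = covid_terms(),
                          from = "2020-01-01", to = "2021-01-26") {
  dd <- deduplicate(registry)
  wf <- window_and_status_filter(dd$kept, from = from, to = to)
  rel <- covid_relevance(wf$kept, terms = terms)
  cohort <- wf$kept[rel$included, , drop = FALSE]
  decisions <- dplyr::bind_rows(
    tibble::tibble(
      nct_id = dd$log$nct_id[dd$log$rule == "Duplicate"],
      included = FALSE, rule = "Duplicate", n_matches = 0L
    ),
    tibble::tibble(
      nct_id = wf$log$nct_id, included = FALSE, rule = wf$log$rule,
      n_matches = 0L
    ),
    rel[, c("nct_id", "included", "rule", "n_matches")]
  )
  list(
    cohort = cohort,
    decisions = decisions,
    evidence = rel[rel$included, c("nct_id", "evidence")],
    candidate_duplicates = dd$log$nct_id[dd$log$rule == "CandidateDuplicate"]
  )
}
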
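#' Registration field catalogue
#'
#' The fixed set of free-text fields a trial registration carries.  Every
#' term search is restricted to a named subset (a *scope*) of this
#' catalogue; field order here defines the reporting order of matches.
#'
#' @return Character vector of field names.
#' @export
field_catalogue <- function() {
  c(
    "OfficialTitle", "BriefTitle", "BriefSummary", "DetailedDescription",
    "Conditions",
    "PrimaryOutcomeTitle", "PrimaryOutcomeDescription",
    "SecondaryOutcomeTitle", "SecondaryOutcomeDescription",
    "OtherOutcomeTitle", "OtherOutcomeDescription",
    "EligibilityPopulation", "EligibilityGenderDescription",
    "EligibilityCriteria",
    "GroupTitle", "GroupDescription", "InterventionDescription"
  )
}

#' Search scopes
#'
#' `covid_scope()` is the field set searched for COVID-19 terms: titles,
#' brief summary, detailed description, conditions, and all outcome
#' titles/descriptions.  `sexgender_scope()` is the field set searched for
#' sex/gender terms: everything in the catalogue except `Conditions`
#' (titles, summaries, eligibilities, group titles/descriptions,
#' intervention descriptions, and all outcomes).
#'
#' @return Character vector of field names.
#' @export
covid_scope <- function() {
  c(
    "OfficialTitle", "BriefTitle", "BriefSummary", "DetailedDescription",
    "Conditions",
    "PrimaryOutcomeTitle", "PrimaryOutcomeDescription",
    "SecondaryOutcomeTitle", "SecondaryOutcomeDescription",
    "OtherOutcomeTitle", "OtherOutcomeDescription"
  )
}

#' @rdname covid_scope
#' @export
sexgender_scope <- function() {
  setdiff(field_catalogue(), "Conditions")
}

#' Construct a term specification table
#'
#' A term spec describes one search term: its surface form, whether a
#' trailing wildcard applies (the surface then ends in `*` and matches any
#' trailing letters), whether regular-plural variants are generated, and
#' whether matching is case sensitive (used only for the all-caps `RCT`
#' token).  `wildcard` and `expand_plural` are mutually exclusive.
#'
#' @param surface Character vector of term surfaces; a trailing `*` marks a
#'   wildcard stem.
#' @param expand_plural Logical vector; generate plural variants.
#' @param case_sensitive Logical vector; default `FALSE`.
#' @return A tibble with columns `surface`, `wildcard`, `expand_plural`,
#'   `case_sensitive`.
#' @export
term_spec <- function(surface, expand_plural = FALSE, case_sensitive = FALSE) {
  stopifnot(is.character(surface), all(nzchar(surface)))
  wildcard <- grepl("\\*$", surface)
  expand_plural <- rep_len(expand_plural, length(surface))
  case_sensitive <- rep_len(case_sensitive, length(surface))
  if (any(wildcard & expand_plural)) {
    stop("expand_plural must be FALSE for wildcard terms", call. = FALSE)
  }
  tibble::tibble(
    surface = surface,
    wildcard = wildcard,
    expand_plural = expand_plural,
    case_sensitive = case_sensitive
  )
}

#' Default term lists
#'
#' `covid_terms()` returns the COVID-19 synonym list (no plural expansion;
#' matching is case-insensitive and blind to internal hyphen/space use, so
#' e.g. "SARSCoV2", "SARS CoV2" and "SARS-CoV-2" are equivalent).
#' `sexgender_terms()` returns the sex/gender term list with plural
#' expansion on the nouns and wildcard stems `pregnan*` and `transg*`.
#'
#' @return A term-spec tibble (see [term_spec()]).
#' @export
covid_terms <- function() {
  term_spec(c(
    "Coronavirus", "Corona Virus", "SARS-CoV-2", "SARS CoV2", "SARSCoV2",
    "COVID", "2019 nCov", "2019nCoV"
  ))
}

#' @rdname covid_terms
#' @export
sexgender_terms <- function() {
  dplyr::bind_rows(
    term_spec(
      c("sex", "gender", "woman", "female", "man", "male", "girl", "boy"),
      expand_plural = TRUE
    ),
    term_spec(c("pregnan*", "transg*"))
  )
}

# terms used by pharmacological-RCT text rules
rct_text_terms <- function() {
  dplyr::bind_rows(
    term_spec(c("random*", "control*", "placebo*")),
    term_spec("RCT", case_sensitive = TRUE)
  )
}
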
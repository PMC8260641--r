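#' Default sex/gender coding rule bank
#'
#' Each rule is a lower-case regular expression evaluated against the
#' context window (the sentence, or +/-120 characters when sentence bounds
#' are unclear) around a sex/gender term match.  Rule kinds:
#' * `spurious` (negative; evaluated first — a window that fires a
#'   spurious rule contributes no positive evidence): contraception and
#'   pregnancy-test requirements, donor/parent sex, literature-summary
#'   phrasing.
#' * `analysis`: stratification, subgroup analysis, covariates,
#'   interactions, adjustment, disaggregation, sex/gender-effect
#'   hypotheses.
#' * `other_matched` / `other_record`: sex-matched or representative
#'   samples; explicit intent to record or report participant sex/gender.
#' * `recruitment`: explicit recruiting/eligibility statements.
#'
#' The bank is an ordinary tibble and can be edited, filtered, or extended
#' before being passed to [assign_category()].
#'
#' @return Tibble with columns `rule_id`, `kind`, `pattern`.
#' @export
default_rule_bank <- function() {
  tibble::tribble(
    ~rule_id, ~kind, ~pattern,
    "sp_contraception", "spurious", "contracept|condom",
    "sp_pregnancy_test", "spurious", "pregnancy test",
    "sp_donor", "spurious", "\\bdonor",
    "sp_parent", "spurious", "\\bparent",
    "sp_literature", "spurious",
    paste0("previous stud|prior stud|earlier stud|has been shown|",
      "have been shown|have shown|it is known|in the literature"),
    "an_stratify", "analysis", "stratif",
    "an_subgroup", "analysis", "subgroup",
    "an_covariate", "analysis", "covariate",
    "an_interaction", "analysis", "interaction",
    "an_adjusted", "analysis", "adjust(ed|ing)? for",
    "an_disaggregate", "analysis", "disaggregat",
    "an_hypothesis", "analysis", "hypothes",
    "om_matched", "other_matched", "match",
    "om_representative", "other_matched", "representativ",
    "om_balanced", "other_matched", "balanced",
    "or_record", "other_record", "record",
    "or_report", "other_record", "report",
    "rc_eligible", "recruitment", "eligib",
    "rc_inclusion", "recruitment", "inclusion",
    "rc_enrol", "recruitment", "enrol",
    "rc_recruit", "recruitment", "recruit",
    "rc_aged", "recruitment", "\\baged\\b",
    "rc_both_sexes", "recruitment",
    paste0("men and women|women and men|male and female|female and male|",
      "both sexes|all sexes|any sex|all genders|either sex")
  )
}

# sentence-based context window with a character fallback
context_window <- function(text, start, end, fallback = 120L) {
  bounds <- gregexpr("[.!?\n]", text)[[1]]
  bounds <- if (bounds[1] == -1L) integer() else as.integer(bounds)
  lo <- c(0L, bounds)
  lo <- max(lo[lo <= start])
  hi <- c(bounds[bounds >= end + 1L], nchar(text))
  hi <- min(hi)
  if (hi - lo > 2L * fallback + (end - start)) {
    lo <- max(lo, start - fallback)
    hi <- min(hi, end + fallback)
  }
  substr(text, lo + 1L, hi)
}

#' Detect single-sex study designs
#'
#' @param sexes_eligible Character vector over
#'   `{"All","Male","Female","Missing"}`.
#' @return `"FemaleOnly"`, `"MaleOnly"`, or `NA` per element.
#' @export
detect_single_sex <- function(sexes_eligible) {
  dplyr::case_match(sexes_eligible,
    "Female" ~ "FemaleOnly", "Male" ~ "MaleOnly",
    .default = NA_character_
  )
}

#' Recruitment-only auto rule
#'
#' `TRUE` iff at least one sex/gender match exists and every match falls in
#' the eligibility inclusion-criteria field — such registrations can only
#' be candidates for sex/gender recruitment and are categorized without
#' context coding.
#'
#' @param matches A term-match tibble (see [find_matches()]).
#' @return Logical flag.
#' @export
auto_recruitment_only <- function(matches) {
  nrow(matches) > 0 && all(matches$field == "EligibilityCriteria")
}

#' Classify the context of each sex/gender match
#'
#' For each match, the surrounding window is tested against the rule bank;
#' spurious rules are evaluated first and suppress all positive evidence
#' from that window.
#'
#' @param texts Named list of field texts.
#' @param matches Term-match tibble over the sex/gender scope.
#' @param bank Rule bank (see [default_rule_bank()]).
#' @return Tibble: one row per match with `field`, `start`, `term`,
#'   `window`, `spurious` flag, and `rules` (list-column of fired rule
#'   ids, spurious or positive).
#' @export
classify_contexts <- function(texts, matches, bank = default_rule_bank()) {
  if (nrow(matches) == 0) {
    return(tibble::tibble(
      field = character(), start = integer(), term = character(),
      window = character(), spurious = logical(),
      lit_analysis = logical(), rules = list()
    ))
  }
  neg <- bank[bank$kind == "spurious", , drop = FALSE]
  pos <- bank[bank$kind != "spurious", , drop = FALSE]
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    field <- matches$field[i]
    win <- tolower(context_window(
      texts[[field]], matches$start[i], matches$end[i]
    ))
    neg_hit <- neg$rule_id[vapply(neg$pattern, function(p) {
      grepl(p, win, perl = TRUE)
    }, logical(1))]
    spurious <- length(neg_hit) > 0
    pos_hit <- if (spurious) character() else {
      pos$rule_id[vapply(pos$pattern, function(p) {
        grepl(p, win, perl = TRUE)
      }, logical(1))]
    }
    # flag analysis cues suppressed by a literature context
    lit_analysis <- spurious && any(neg_hit == "sp_literature") &&
      any(vapply(
        pos$pattern[pos$kind == "analysis"],
        function(p) grepl(p, win, perl = TRUE), logical(1)
      ))
    tibble::tibble(
      field = field, start = matches$start[i], term = matches$term[i],
      window = win, spurious = spurious,
      lit_analysis = lit_analysis,
      rules = list(c(neg_hit, pos_hit))
    )
  })
  dplyr::bind_rows(rows)
}

.female_terms <- c("woman", "female", "girl")
.male_terms <- c("man", "male", "boy")
.neutral_terms <- c("sex", "gender")

# category assignment for one registration (row i of a registry)
assign_one <- function(texts, sexes_eligible, matches,
                       bank = default_rule_bank()) {
  res <- list(
    category = NA_character_, subtag = NA_character_,
    fired_rules = character(), needs_review = FALSE,
    n_matches = nrow(matches)
  )
  single <- detect_single_sex(sexes_eligible)
  if (!is.na(single)) {
    res$category <- single
    res$fired_rules <- if (single == "FemaleOnly") {
      "single_sex_female"
    } else {
      "single_sex_male"
    }
    return(res)
  }
  if (sexes_eligible == "Missing") res$needs_review <- TRUE
  if (nrow(matches) == 0) {
    res$category <- "NoMention"
    return(res)
  }
  if (auto_recruitment_only(matches)) {
    res$category <- "RecruitmentOnly"
    res$subtag <- "AutoEligibilityOnly"
    res$fired_rules <- "auto_recruitment_only"
    return(res)
  }
  ctx <- classify_contexts(texts, matches, bank)
  bank_kind <- stats::setNames(bank$kind, bank$rule_id)
  fired <- unique(unlist(ctx$rules))
  kinds_by_match <- lapply(ctx$rules, function(r) unname(bank_kind[r]))
  has_kind <- function(kind) {
    any(vapply(seq_len(nrow(ctx)), function(i) {
      !ctx$spurious[i] && kind %in% kinds_by_match[[i]]
    }, logical(1)))
  }
  if (any(ctx$lit_analysis)) res$needs_review <- TRUE
  res$fired_rules <- fired

  if (has_kind("analysis")) {
    res$category <- "Analysis"
    return(res)
  }
  if (has_kind("other_matched") || has_kind("other_record")) {
    res$category <- "OtherMention"
    res$subtag <- if (has_kind("other_matched")) {
      "MatchedOrRepresentative"
    } else {
      "RecordOrReport"
    }
    return(res)
  }
  # explicit recruitment statement must cover both sexes: a neutral term
  # (sex/gender) in a recruitment window, or a female term and a male term
  recr <- vapply(seq_len(nrow(ctx)), function(i) {
    !ctx$spurious[i] && "recruitment" %in% kinds_by_match[[i]]
  }, logical(1))
  if (any(recr)) {
    terms_in_recr <- sub("\\*$", "", tolower(ctx$term[recr]))
    covered <- any(terms_in_recr %in% .neutral_terms) ||
      (any(terms_in_recr %in% .female_terms) &&
        any(terms_in_recr %in% .male_terms))
    if (covered) {
      res$category <- "RecruitmentOnly"
      return(res)
    }
  }
  if (all(ctx$spurious)) {
    res$category <- "NoMention"
    res$subtag <- "SpuriousMention"
    return(res)
  }
  # matches present but no rule accounts for them: flag for human review
  res$category <- "NoMention"
  res$needs_review <- TRUE
  res
}

#' Assign each cohort study to one sex/gender attention category
#'
#' Implements the mutually exclusive hierarchy: single-sex designs
#' (`FemaleOnly`/`MaleOnly`, from the structured sexes-eligible field) take
#' precedence, then `Analysis` (sex/gender as an analytical variable),
#' then `OtherMention` (sex-matched/representative samples, or explicit
#' intent to record/report), then `RecruitmentOnly` (via the
#' eligibility-only auto rule or an explicit both-sex recruitment
#' statement), then `NoMention` (no match, or only spurious matches).
#' Studies whose matches no rule accounts for are flagged
#' `needs_review`, as are registrations with a missing sexes-eligible
#' value and analysis cues occurring only in literature-summary contexts.
#'
#' @param registry Cohort registry tibble.
#' @param terms Sex/gender term specs (default [sexgender_terms()]).
#' @param bank Rule bank (default [default_rule_bank()]).
#' @return Tibble with `nct_id`, `category`, `subtag`, `n_matches`,
#'   `fired_rules` (list-column), `needs_review`, `evidence` (list-column
#'   of term matches).
#' @export
assign_category <- function(registry, terms = sexgender_terms(),
                            bank = default_rule_bank()) {
  matches <- registry_matches(registry, sexgender_scope(), terms)
  per_id <- split(
    matches, factor(matches$nct_id, levels = unique(registry$nct_id))
  )
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    id <- registry$nct_id[i]
    m <- per_id[[id]] %||% empty_matches()
    a <- assign_one(
      registry$texts[[i]], registry$sexes_eligible[i], m, bank
    )
    tibble::tibble(
      nct_id = id, category = a$category, subtag = a$subtag,
      n_matches = a$n_matches,
      fired_rules = list(a$fired_rules),
      needs_review = a$needs_review,
      evidence = list(m)
    )
  })
  dplyr::bind_rows(rows)
}
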
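#' Generator specification for synthetic registry dumps
#'
#' The defaults emulate the statistical structure of the COVID-19
#' registration sample the package is designed to audit: attention-category
#' shares of roughly 2.3/0.5/4/5.4/21.2/66.7 percent (female-only,
#' male-only, analysis, other mention, recruitment-only, no mention), a
#' study-type mix of roughly 37.5/29.7/26.3/5.9/0.6 percent (observational,
#' other interventional, pharmacological RCT, patient registry, expanded
#' access), COVID terms placed in titles/conditions for 98 percent of
#' in-cohort records, log-normal enrollment with per-group median targets
#' (700 for analysis-planners, 176 for no-mention studies, otherwise
#' 287/400/160/100 per study class), and monthly submission weights over
#' Nov 2019 - Feb 2021 placing about 56 percent of in-window submissions
#' in the first half of 2020.
#'
#' @param n_studies Number of unique registrations to generate.
#' @param seed Integer seed; fully determines the output.
#' @param category_mix Named probability vector over the six attention
#'   categories.
#' @param type_mix Named probability vector over the five study classes.
#' @param covid_rule_mix Named probability vector over
#'   `{TitleOrCondition, PrimaryOutcome, TwoOtherFields, NonCovid}`.
#' @param enrollment_medians Named medians: `Analysis`, `NoMention`
#'   (category-level targets) and `Observational`, `PatientRegistry`,
#'   `PharmaRCT`, `OtherIntervention` (class-level fallbacks).
#' @param enrollment_sdlog Log-scale dispersion of enrollment (default 1).
#' @param date_weights Named monthly weights (`YYYY-MM`) over
#'   2019-11 .. 2021-02; normalized internally.
#' @param adversarial_rate Fraction of records built from adversarial trap
#'   templates.
#' @param dup_rate Fraction of records duplicated verbatim in the written
#'   dumps.
#' @param withdrawn_rate Fraction with status Withdrawn / No longer
#'   available.
#' @param missing_sex_rate Fraction of no-mention records with a missing
#'   sexes-eligible value.
#' @param start_date_rate Probability a record carries a start date.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(n_studies = 1000,
                           seed = 1,
                           category_mix = c(
                             FemaleOnly = 100, MaleOnly = 24,
                             Analysis = 178, OtherMention = 237,
                             RecruitmentOnly = 935, NoMention = 2946
                           ) / 4420,
                           type_mix = c(
                             Observational = 1659, OtherIntervention = 1314,
                             PharmaRCT = 1161, PatientRegistry = 260,
                             ExpandedAccess = 26
                           ) / 4420,
                           covid_rule_mix = c(
                             TitleOrCondition = 0.95 * 0.98,
                             PrimaryOutcome = 0.95 * 0.01,
                             TwoOtherFields = 0.95 * 0.01,
                             NonCovid = 0.05
                           ),
                           enrollment_medians = c(
                             Analysis = 700, NoMention = 176,
                             Observational = 287, PatientRegistry = 400,
                             PharmaRCT = 160, OtherIntervention = 100
                           ),
                           enrollment_sdlog = 1,
                           date_weights = NULL,
                           adversarial_rate = 0.05,
                           dup_rate = 0.01,
                           withdrawn_rate = 0.02,
                           missing_sex_rate = 0.01,
                           start_date_rate = 0.7) {
  if (is.null(date_weights)) {
    months <- format(seq(as.Date("2019-11-01"), as.Date("2021-02-01"),
      by = "month"
    ), "%Y-%m")
    # H1-2020 weight mass ~0.56 of the in-window total
    date_weights <- stats::setNames(c(
      0.010, 0.015, # 2019-11, 2019-12
      0.040, 0.050, 0.100, 0.120, 0.120, 0.100, # Jan-Jun 2020
      0.080, 0.070, 0.060, 0.055, 0.050, 0.050, # Jul-Dec 2020
      0.046, # Jan 2021
      0.010 # Feb 2021
    ), months)
  }
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1",
        call. = FALSE
      )
    }
  }
  check_prob(category_mix, "category_mix")
  check_prob(type_mix, "type_mix")
  check_prob(covid_rule_mix, "covid_rule_mix")
  stopifnot(n_studies >= 1, length(seed) == 1)
  structure(
    list(
      n_studies = as.integer(n_studies), seed = as.integer(seed),
      category_mix = category_mix, type_mix = type_mix,
      covid_rule_mix = covid_rule_mix,
      enrollment_medians = enrollment_medians,
      enrollment_sdlog = enrollment_sdlog,
      date_weights = date_weights / sum(date_weights),
      adversarial_rate = adversarial_rate, dup_rate = dup_rate,
      withdrawn_rate = withdrawn_rate,
      missing_sex_rate = missing_sex_rate,
      start_date_rate = start_date_rate
    ),
    class = "generator_spec"
  )
}

.covid_surfaces <- c(
  "COVID-19", "COVID-19", "COVID-19", "COVID19", "Covid-19",
  "SARS-CoV-2", "SARS-CoV-2", "SARSCoV2", "SARS CoV2",
  "coronavirus", "Corona Virus", "2019-nCoV", "2019nCoV", "COVID"
)

.drug_names <- c(
  "remdesivir", "tocilizumab", "favipiravir", "baricitinib",
  "dexamethasone", "nitazoxanide", "colchicine", "interferon beta"
)

.filler_sentences <- c(
  "The study is conducted at multiple clinical sites.",
  "Data will be collected at baseline and at scheduled follow-up visits.",
  "The protocol was approved by the local ethics committee.",
  "Vital signs and laboratory values will be assessed during hospitalization.",
  "The expected duration of participation is twelve weeks.",
  "Safety will be monitored by an independent data monitoring committee.",
  "Clinical progression will be graded on an ordinal severity scale.",
  "Follow-up telephone contacts are scheduled at day 30 and day 90."
)

.analysis_sentences <- c(
  "Outcomes will be stratified by sex and age.",
  "Prespecified subgroup analyses by sex will be performed.",
  "Sex will be included as a covariate in the primary regression model.",
  "All results will be disaggregated by gender.",
  "The investigators hypothesize that sex will modify treatment response."
)

.other_matched_sentences <- c(
  "Controls will be sex-matched to cases.",
  "The sample will be representative of women and men in the source population.",
  "Study arms will be balanced with respect to sex."
)

.other_record_sentences <- c(
  "The sex of each participant will be recorded at baseline.",
  "Gender will be reported for all study arms."
)

.recruitment_sentences <- c(
  "Both men and women aged 18 to 80 years will be recruited.",
  "Male and female participants will be enrolled at all sites.",
  "Adults of any sex are eligible to participate."
)

.sexed_criteria <- paste(
  "Inclusion Criteria:",
  "- Male or female, aged 18 years or older",
  "- Admitted to a participating hospital",
  "Exclusion Criteria:",
  "- Unable to provide informed consent",
  sep = "\n"
)

.plain_criteria <- paste(
  "Inclusion Criteria:",
  "- Aged 18 years or older",
  "- Admitted to a participating hospital",
  "Exclusion Criteria:",
  "- Unable to provide informed consent",
  sep = "\n"
)

# adversarial trap templates with their expected hand-decided outcomes
.adversarial_templates <- list(
  adv_contraception = list(
    sentence = paste(
      "Women of childbearing potential must agree to use adequate",
      "contraception throughout the study."
    ),
    where = "DetailedDescription",
    category = "NoMention", subtag = "SpuriousMention", review = FALSE
  ),
  adv_literature = list(
    sentence = paste(
      "Previous studies have shown that male patients experience more",
      "severe disease."
    ),
    where = "DetailedDescription",
    category = "NoMention", subtag = "SpuriousMention", review = FALSE
  ),
  adv_lit_analysis = list(
    sentence = paste(
      "Previous studies have shown that outcomes stratified by sex",
      "differ markedly."
    ),
    where = "DetailedDescription",
    category = "NoMention", subtag = "SpuriousMention", review = TRUE
  ),
  adv_donor = list(
    sentence = paste(
      "Convalescent plasma obtained from male donors will be",
      "administered to participants."
    ),
    where = "DetailedDescription",
    category = "NoMention", subtag = "SpuriousMention", review = FALSE
  ),
  adv_pregnancy_test = list(
    sentence = "A negative pregnancy test will be required at screening.",
    where = "DetailedDescription",
    category = "NoMention", subtag = "SpuriousMention", review = FALSE
  ),
  adv_female_trap = list(
    sentence = paste(
      "The cohort will include approximately 200 female participants",
      "enrolled at three sites."
    ),
    where = "DetailedDescription",
    category = "NoMention", subtag = NA_character_, review = TRUE
  ),
  adv_elig_contraception = list(
    sentence = paste(
      "Inclusion Criteria:",
      "- Women of childbearing potential must use effective contraception",
      "- Aged 18 years or older",
      sep = "\n"
    ),
    where = "EligibilityCriteria",
    category = "RecruitmentOnly", subtag = "AutoEligibilityOnly",
    review = FALSE
  )
)

sample1 <- function(x) x[[sample.int(length(x), 1L)]]

# class-specific design metadata; returns list(allocation, groups,
# interventions, title_stub, rct_rule, phase)
build_design <- function(class, drug) {
  phase_interventional <- function() {
    sample(
      c(NA_character_, "NA", "EarlyPhase1", "Phase1", "Phase1_2",
        "Phase2", "Phase2_3", "Phase3", "Phase4"),
      1L,
      prob = c(0.18, 0.18, 0.02, 0.06, 0.08, 0.20, 0.06, 0.17, 0.05)
    )
  }
  drug_interventions <- function() {
    tibble::tibble(
      intervention_type = "Drug",
      description = paste0(
        "Intravenous ", drug, " administered once daily for five days."
      )
    )
  }
  if (class == "PharmaRCT") {
    rule <- sample(
      c("GroupTypeControl", "GroupTextControl", "TitleOrInterventionText"),
      1L,
      prob = c(0.80, 0.15, 0.05)
    )
    if (rule == "GroupTypeControl") {
      groups <- tibble::tibble(
        group_type = c("Experimental", "PlaceboComparator"),
        title = c(drug, "Placebo"),
        description = c(
          paste0("Participants receive ", drug, "."),
          "Participants receive matching placebo."
        )
      )
      title_stub <- paste0("Randomized Trial of ", drug)
    } else if (rule == "GroupTextControl") {
      groups <- tibble::tibble(
        group_type = c("Experimental", "ActiveComparator"),
        title = c(drug, "Standard care control"),
        description = c(
          paste0("Participants receive ", drug, "."),
          "Participants in the control arm receive standard care alone."
        )
      )
      title_stub <- paste0("Randomized Trial of ", drug)
    } else {
      groups <- tibble::tibble(
        group_type = c("Experimental", "ActiveComparator"),
        title = c(drug, "Comparator"),
        description = c(
          paste0("Participants receive ", drug, "."),
          "Participants receive standard of care."
        )
      )
      title_stub <- if (stats::runif(1) < 0.5) {
        paste0("A Randomized, Placebo-Controlled Trial of ", drug)
      } else {
        paste0("RCT of ", drug)
      }
    }
    return(list(
      study_type = "Interventional", allocation = "Randomized",
      groups = groups, interventions = drug_interventions(),
      title_stub = title_stub, rct_rule = rule,
      phase = phase_interventional()
    ))
  }
  if (class == "OtherIntervention") {
    kind <- sample(c("behavioral", "device", "uncontrolled_drug"), 1L,
      prob = c(0.60, 0.25, 0.15)
    )
    if (kind == "behavioral") {
      list(
        study_type = "Interventional",
        allocation = sample(c("Randomized", "NonRandomized", "NA"), 1L,
          prob = c(0.5, 0.3, 0.2)
        ),
        groups = tibble::tibble(
          group_type = c("Experimental", "NoIntervention"),
          title = c("Telehealth program", "Usual care"),
          description = c(
            "Participants receive a structured telehealth support program.",
            "Participants receive usual care."
          )
        ),
        interventions = tibble::tibble(
          intervention_type = "Behavioral",
          description = "A twelve-week structured telehealth support program."
        ),
        title_stub = "Effect of a Telehealth Support Program on Anxiety",
        rct_rule = NA_character_, phase = phase_interventional()
      )
    } else if (kind == "device") {
      list(
        study_type = "Interventional",
        allocation = sample(c("Randomized", "NonRandomized"), 1L),
        groups = tibble::tibble(
          group_type = "Experimental",
          title = "High-flow oxygen device",
          description = "Participants receive high-flow nasal oxygen therapy."
        ),
        interventions = tibble::tibble(
          intervention_type = "Device",
          description = "High-flow nasal oxygen delivered per protocol."
        ),
        title_stub = "High-Flow Nasal Oxygen Therapy",
        rct_rule = NA_character_, phase = phase_interventional()
      )
    } else {
      list(
        study_type = "Interventional", allocation = "Randomized",
        groups = tibble::tibble(
          group_type = c("Experimental", "Experimental"),
          title = paste(drug, c("high dose", "low dose")),
          description = paste0(
            "Participants receive ", drug, " at the ",
            c("high", "low"), " dose level."
          )
        ),
        interventions = drug_interventions(),
        title_stub = paste0(
          "Randomized Trial of High Versus Low Dose ", drug
        ),
        rct_rule = NA_character_, phase = phase_interventional()
      )
    }
  } else if (class == "Observational") {
    list(
      study_type = "Observational", allocation = "NA",
      groups = empty_groups(), interventions = empty_interventions(),
      title_stub = "Clinical Characteristics and Outcomes of Hospitalized Patients",
      rct_rule = NA_character_, phase = NA_character_
    )
  } else if (class == "PatientRegistry") {
    list(
      study_type = "PatientRegistry", allocation = "NA",
      groups = empty_groups(), interventions = empty_interventions(),
      title_stub = "Prospective Registry of Hospitalized Patients",
      rct_rule = NA_character_, phase = NA_character_
    )
  } else {
    list(
      study_type = "ExpandedAccess", allocation = "Missing",
      groups = empty_groups(),
      interventions = tibble::tibble(
        intervention_type = "Drug",
        description = paste0(
          "Treatment with ", drug, " under an expanded access protocol."
        )
      ),
      title_stub = paste0("Expanded Access Program for ", drug),
      rct_rule = NA_character_, phase = NA_character_
    )
  }
}

#' Generate synthetic registrations with ground truth
#'
#' Assembles `n_studies` registrations from sentence templates so that the
#' planted cohort rule, attention category and study class are recoverable
#' by the pipeline's documented rules, and computes the ground-truth table
#' from the planted values by direct arithmetic on the documented rules
#' (date window, status, field placement) — independently of the pipeline
#' code.
#'
#' @param spec A [generator_spec()].
#' @return A list with `registry` (tibble of unique registrations),
#'   `truth` (tibble: `nct_id`, `in_cohort`, `cohort_rule`, `category`,
#'   `subtag`, `expect_review`, `class`, `rct_rule`, `adversarial`,
#'   `template`), and `dup_ids` (ids duplicated verbatim in written
#'   dumps).
#' @export
generate_registrations <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_studies
  classes <- sample(names(spec$type_mix), n,
    replace = TRUE, prob = spec$type_mix
  )
  categories <- sample(names(spec$category_mix), n,
    replace = TRUE, prob = spec$category_mix
  )
  covid_rules <- sample(names(spec$covid_rule_mix), n,
    replace = TRUE, prob = spec$covid_rule_mix
  )
  adversarial <- stats::runif(n) < spec$adversarial_rate
  months <- sample(names(spec$date_weights), n,
    replace = TRUE, prob = spec$date_weights
  )
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("NCT%08d", 70000000L + i)
    class <- classes[i]
    drug <- sample1(.drug_names)
    design <- build_design(class, drug)
    covid_rule <- covid_rules[i]
    covid <- sample1(.covid_surfaces)

    template <- if (adversarial[i]) {
      sample1(names(.adversarial_templates))
    } else {
      categories[i]
    }
    adv <- if (adversarial[i]) .adversarial_templates[[template]] else NULL
    category <- if (adversarial[i]) adv$category else categories[i]
    subtag <- NA_character_
    expect_review <- FALSE

    sexes <- "All"
    criteria <- .plain_criteria
    desc_sentences <- sample(
      .filler_sentences, sample(2:4, 1L),
      replace = FALSE
    )
    if (adversarial[i]) {
      subtag <- adv$subtag
      expect_review <- adv$review
      if (adv$where == "EligibilityCriteria") {
        criteria <- adv$sentence
      } else {
        desc_sentences <- c(desc_sentences, adv$sentence)
      }
    } else if (category == "FemaleOnly") {
      sexes <- "Female"
      criteria <- paste(
        "Inclusion Criteria:",
        "- Pregnant women in the second or third trimester",
        "- Aged 18 years or older",
        sep = "\n"
      )
      desc_sentences <- c(
        desc_sentences,
        "The study follows pregnant women until delivery."
      )
      subtag <- NA_character_
    } else if (category == "MaleOnly") {
      sexes <- "Male"
      criteria <- paste(
        "Inclusion Criteria:",
        "- Men aged 18 years or older",
        sep = "\n"
      )
    } else if (category == "Analysis") {
      desc_sentences <- c(desc_sentences, sample1(.analysis_sentences))
      if (stats::runif(1) < 0.5) criteria <- .sexed_criteria
      if (stats::runif(1) < 0.3) {
        desc_sentences <- c(desc_sentences, sample1(.recruitment_sentences))
      }
    } else if (category == "OtherMention") {
      if (stats::runif(1) < 0.5) {
        desc_sentences <- c(desc_sentences, sample1(.other_matched_sentences))
        subtag <- "MatchedOrRepresentative"
      } else {
        desc_sentences <- c(desc_sentences, sample1(.other_record_sentences))
        subtag <- "RecordOrReport"
      }
      if (stats::runif(1) < 0.5) criteria <- .sexed_criteria
    } else if (category == "RecruitmentOnly") {
      if (stats::runif(1) < 0.83) {
        criteria <- .sexed_criteria
        subtag <- "AutoEligibilityOnly"
      } else {
        desc_sentences <- c(desc_sentences, sample1(.recruitment_sentences))
      }
    } else if (category == "NoMention") {
      if (stats::runif(1) < spec$missing_sex_rate) {
        sexes <- "Missing"
        expect_review <- TRUE
      }
    }

    # COVID term placement by planted cohort rule
    title <- design$title_stub
    conditions <- "Acute Respiratory Illness"
    brief <- "This study evaluates clinical outcomes in hospitalized adult patients."
    primary_desc <- "Proportion of participants alive at day 28."
    secondary_desc <- "Number of days from hospital admission to discharge."
    if (covid_rule == "TitleOrCondition") {
      title <- paste0(title, " in Patients With ", covid)
      conditions <- covid
    } else if (covid_rule == "PrimaryOutcome") {
      title <- paste0(title, " in Severe Viral Pneumonia")
      conditions <- "Viral Pneumonia"
      primary_desc <- paste0(
        "Mortality among participants with confirmed ", covid,
        " infection at day 28."
      )
    } else if (covid_rule == "TwoOtherFields") {
      title <- paste0(title, " in Severe Viral Pneumonia")
      conditions <- "Viral Pneumonia"
      brief <- paste0(
        brief, " The investigators will follow patients recovering from ",
        covid, "."
      )
      secondary_desc <- paste0(
        "Persistent symptoms following ", covid, " infection."
      )
    } else {
      title <- "Effect of Exercise Training on Blood Pressure in Adults"
      conditions <- "Hypertension"
    }

    submitted <- as.Date(paste0(months[i], "-", sample(1:28, 1L)))
    start <- if (stats::runif(1) < spec$start_date_rate) {
      submitted + sample(-20:40, 1L)
    } else {
      as.Date(NA)
    }
    status <- if (class == "ExpandedAccess") {
      "Available"
    } else if (stats::runif(1) < spec$withdrawn_rate) {
      sample(c("Withdrawn", "No longer available"), 1L)
    } else {
      sample(c(
        "Recruiting", "Completed", "Active, not recruiting",
        "Not yet recruiting"
      ), 1L)
    }

    med <- if (category %in% c("Analysis", "NoMention")) {
      spec$enrollment_medians[[category]]
    } else if (class %in% names(spec$enrollment_medians)) {
      spec$enrollment_medians[[class]]
    } else {
      NA_real_
    }
    enrollment <- if (class == "ExpandedAccess" || is.na(med)) {
      NA_integer_
    } else {
      max(1L, as.integer(round(stats::rlnorm(
        1,
        meanlog = log(med), sdlog = spec$enrollment_sdlog
      ))))
    }
    enrollment_type <- if (is.na(enrollment)) {
      "Missing"
    } else if (stats::runif(1) < 0.8) {
      "Anticipated"
    } else {
      "Actual"
    }

    countries <- if (stats::runif(1) < 0.11) {
      character()
    } else if (stats::runif(1) < 0.23) {
      c("United States", if (stats::runif(1) < 0.3) "Canada")
    } else {
      sample(
        c("France", "Italy", "Spain", "Denmark", "Netherlands", "Brazil",
          "China", "Canada"),
        sample(1:2, 1L)
      )
    }

    rows[[i]] <- trial_registration(
      nct_id = id,
      study_type = design$study_type,
      allocation = design$allocation,
      phase = design$phase,
      sexes_eligible = sexes,
      status = status,
      start_date = start,
      submitted_date = submitted,
      enrollment_count = enrollment,
      enrollment_type = enrollment_type,
      texts = list(
        OfficialTitle = title,
        BriefTitle = title,
        BriefSummary = brief,
        DetailedDescription = paste(desc_sentences, collapse = " "),
        Conditions = conditions,
        PrimaryOutcomeTitle = "All-cause mortality at day 28",
        PrimaryOutcomeDescription = primary_desc,
        SecondaryOutcomeTitle = "Duration of hospitalization",
        SecondaryOutcomeDescription = secondary_desc,
        EligibilityCriteria = criteria
      ),
      groups = design$groups,
      interventions = design$interventions,
      facility_countries = countries,
      has_document = stats::runif(1) < 0.03
    )

    # ground truth from planted values, by the documented rules
    effective <- if (is.na(start)) submitted else start
    in_window <- effective >= as.Date("2020-01-01") &
      effective <= as.Date("2021-01-26")
    bad_status <- status %in% c("Withdrawn", "No longer available")
    cohort_rule <- if (!in_window) {
      "OutOfWindow"
    } else if (bad_status) {
      "BadStatus"
    } else if (covid_rule == "NonCovid") {
      "NotMatched"
    } else {
      covid_rule
    }
    truth[[i]] <- tibble::tibble(
      nct_id = id,
      in_cohort = in_window && !bad_status && covid_rule != "NonCovid",
      cohort_rule = cohort_rule,
      category = category,
      subtag = subtag,
      expect_review = expect_review,
      class = class,
      rct_rule = design$rct_rule,
      adversarial = adversarial[i],
      template = template
    )
  }
  registry <- as_registry(dplyr::bind_rows(rows))
  truth <- dplyr::bind_rows(truth)
  n_dup <- as.integer(floor(spec$dup_rate * n))
  dup_ids <- if (n_dup > 0) {
    sort(sample(registry$nct_id, n_dup))
  } else {
    character()
  }
  list(registry = registry, truth = truth, dup_ids = dup_ids)
}

#' Write a synthetic dump in both dialects plus its truth table
#'
#' Writes the AACT-dialect CSV tables under `<out_dir>/aact/`, the JSON
#' lines file at `<out_dir>/registrations.jsonl` (both including any
#' planted verbatim duplicates), and the truth table at
#' `<out_dir>/truth.csv`.  Running twice with the same spec produces
#' byte-identical files.
#'
#' @param spec A [generator_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `aact_dir`, `jsonl`, `truth_csv`,
#'   `registry`, `truth`, `dup_ids`.
#' @export
generate_dump <- function(spec, out_dir) {
  gen <- generate_registrations(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_dups <- dplyr::bind_rows(
    gen$registry,
    gen$registry[match(gen$dup_ids, gen$registry$nct_id), , drop = FALSE]
  )
  aact_dir <- file.path(out_dir, "aact")
  write_dump(with_dups, aact_dir)
  jsonl <- file.path(out_dir, "registrations.jsonl")
  write_registrations(with_dups, jsonl)
  truth_csv <- file.path(out_dir, "truth.csv")
  readr::write_csv(gen$truth, truth_csv, progress = FALSE)
  invisible(list(
    aact_dir = aact_dir, jsonl = jsonl, truth_csv = truth_csv,
    registry = gen$registry, truth = gen$truth, dup_ids = gen$dup_ids
  ))
}
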
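#' Curated edge-case registrations with expected outcomes
#'
#' A fixed, hand-written set of registrations, one per documented edge
#' case of the matching, cohort, coding and RCT rules, shipped with the
#' expected decision for every pipeline stage.  Used by the test suite as
#' a rule-coverage audit and available to users as worked examples of
#' each rule.
#'
#' @return A list with `registry` (tibble of registrations) and `expected`
#'   (tibble: `nct_id`, `case`, `in_cohort`, `cohort_rule`, `category`,
#'   `subtag`, `needs_review`, `label`, `rct_rule`; coding/label columns
#'   are `NA` for records excluded from the cohort).
#' @export
adversarial_fixtures <- function() {
  covid_title <- function(stub) paste0(stub, " in Patients With COVID-19")
  drug_groups_placebo <- tibble::tibble(
    group_type = c("Experimental", "PlaceboComparator"),
    title = c("Remdesivir", "Placebo"),
    description = c(
      "Participants receive remdesivir.",
      "Participants receive matching placebo."
    )
  )
  drug_iv <- tibble::tibble(
    intervention_type = "Drug",
    description = "Intravenous remdesivir administered once daily."
  )
  obs <- function(nct_id, case, texts = list(), sexes = "All", ...) {
    list(
      reg = trial_registration(
        nct_id = nct_id, study_type = "Observational", allocation = "NA",
        sexes_eligible = sexes,
        texts = utils::modifyList(
          list(
            BriefTitle = covid_title("Outcomes of Hospitalized Patients"),
            OfficialTitle = covid_title("Outcomes of Hospitalized Patients"),
            Conditions = "COVID-19",
            EligibilityCriteria = paste(
              "Inclusion Criteria:", "- Aged 18 years or older",
              sep = "\n"
            )
          ),
          texts
        ),
        ...
      ),
      case = case
    )
  }
  exp_row <- function(nct_id, case, in_cohort = TRUE,
                      cohort_rule = "TitleOrCondition",
                      category = NA, subtag = NA, needs_review = FALSE,
                      label = "Observational", rct_rule = NA) {
    tibble::tibble(
      nct_id = nct_id, case = case, in_cohort = in_cohort,
      cohort_rule = cohort_rule, category = as.character(category),
      subtag = as.character(subtag), needs_review = needs_review,
      label = as.character(label), rct_rule = as.character(rct_rule)
    )
  }
  fx <- list()
  ex <- list()
  add <- function(item, expectation) {
    fx[[length(fx) + 1L]] <<- item$reg
    ex[[length(ex) + 1L]] <<- expectation
  }

  # --- sex/gender coding edge cases -------------------------------------
  add(
    obs("NCT90000001", "contraception_in_description", texts = list(
      DetailedDescription = paste(
        "Participants are followed for ninety days.",
        "Women of childbearing potential must use adequate contraception."
      )
    )),
    exp_row("NCT90000001", "contraception_in_description",
      category = "NoMention", subtag = "SpuriousMention"
    )
  )
  add(
    obs("NCT90000002", "literature_summary_mention", texts = list(
      DetailedDescription = paste(
        "Previous studies have shown that male patients experience",
        "more severe disease."
      )
    )),
    exp_row("NCT90000002", "literature_summary_mention",
      category = "NoMention", subtag = "SpuriousMention"
    )
  )
  add(
    obs("NCT90000003", "literature_analysis_cue_flagged", texts = list(
      DetailedDescription = paste(
        "Previous studies have shown that outcomes stratified by sex",
        "differ markedly."
      )
    )),
    exp_row("NCT90000003", "literature_analysis_cue_flagged",
      category = "NoMention", subtag = "SpuriousMention",
      needs_review = TRUE
    )
  )
  add(
    obs("NCT90000004", "donor_sex_mention", texts = list(
      DetailedDescription =
        "Convalescent plasma from male donors will be administered."
    )),
    exp_row("NCT90000004", "donor_sex_mention",
      category = "NoMention", subtag = "SpuriousMention"
    )
  )
  add(
    obs("NCT90000005", "pregnancy_test_requirement", texts = list(
      DetailedDescription =
        "A negative pregnancy test will be required at screening."
    )),
    exp_row("NCT90000005", "pregnancy_test_requirement",
      category = "NoMention", subtag = "SpuriousMention"
    )
  )
  add(
    obs("NCT90000006", "female_only_recruiting_statement", texts = list(
      DetailedDescription = paste(
        "The cohort will include approximately 200 female participants",
        "enrolled at three sites."
      )
    )),
    exp_row("NCT90000006", "female_only_recruiting_statement",
      category = "NoMention", needs_review = TRUE
    )
  )
  add(
    obs("NCT90000007", "eligibility_only_male_female", texts = list(
      EligibilityCriteria = paste(
        "Inclusion Criteria:", "- Male or female, aged 18 years or older",
        sep = "\n"
      )
    )),
    exp_row("NCT90000007", "eligibility_only_male_female",
      category = "RecruitmentOnly", subtag = "AutoEligibilityOnly"
    )
  )
  add(
    obs("NCT90000008", "eligibility_contraception_auto", texts = list(
      EligibilityCriteria = paste(
        "Inclusion Criteria:",
        "- Women of childbearing potential must use effective contraception",
        sep = "\n"
      )
    )),
    exp_row("NCT90000008", "eligibility_contraception_auto",
      category = "RecruitmentOnly", subtag = "AutoEligibilityOnly"
    )
  )
  add(
    obs("NCT90000009", "explicit_recruitment_both_sexes", texts = list(
      DetailedDescription =
        "Both men and women aged 18 to 80 years will be recruited."
    )),
    exp_row("NCT90000009", "explicit_recruitment_both_sexes",
      category = "RecruitmentOnly"
    )
  )
  add(
    obs("NCT90000010", "analysis_stratified", texts = list(
      DetailedDescription = "Outcomes will be stratified by sex and age."
    )),
    exp_row("NCT90000010", "analysis_stratified", category = "Analysis")
  )
  add(
    obs("NCT90000011", "analysis_covariate", texts = list(
      DetailedDescription =
        "Sex will be included as a covariate in the regression model."
    )),
    exp_row("NCT90000011", "analysis_covariate", category = "Analysis")
  )
  add(
    obs("NCT90000012", "analysis_hypothesis", texts = list(
      DetailedDescription =
        "We hypothesize that gender will affect treatment outcomes."
    )),
    exp_row("NCT90000012", "analysis_hypothesis", category = "Analysis")
  )
  add(
    obs("NCT90000013", "analysis_beats_recruitment", texts = list(
      DetailedDescription = paste(
        "Male and female participants will be enrolled at all sites.",
        "Prespecified subgroup analyses by sex will be performed."
      )
    )),
    exp_row("NCT90000013", "analysis_beats_recruitment",
      category = "Analysis"
    )
  )
  add(
    obs("NCT90000014", "sex_matched_controls", texts = list(
      DetailedDescription = "Controls will be sex-matched to cases."
    )),
    exp_row("NCT90000014", "sex_matched_controls",
      category = "OtherMention", subtag = "MatchedOrRepresentative"
    )
  )
  add(
    obs("NCT90000015", "representative_sample", texts = list(
      DetailedDescription = paste(
        "The sample will be representative of women and men in the",
        "source population."
      )
    )),
    exp_row("NCT90000015", "representative_sample",
      category = "OtherMention", subtag = "MatchedOrRepresentative"
    )
  )
  add(
    obs("NCT90000016", "record_sex_intent", texts = list(
      DetailedDescription =
        "The sex of each participant will be recorded at baseline."
    )),
    exp_row("NCT90000016", "record_sex_intent",
      category = "OtherMention", subtag = "RecordOrReport"
    )
  )
  add(
    obs("NCT90000017", "report_gender_intent", texts = list(
      DetailedDescription = "Gender will be reported for all study arms."
    )),
    exp_row("NCT90000017", "report_gender_intent",
      category = "OtherMention", subtag = "RecordOrReport"
    )
  )
  add(
    obs("NCT90000018", "transgender_reporting", texts = list(
      DetailedDescription =
        "Outcomes will be reported for transgender participants."
    )),
    exp_row("NCT90000018", "transgender_reporting",
      category = "OtherMention", subtag = "RecordOrReport"
    )
  )
  add(
    obs("NCT90000019", "female_only_design",
      sexes = "Female",
      texts = list(
        DetailedDescription =
          "The study follows pregnant women until delivery."
      )
    ),
    exp_row("NCT90000019", "female_only_design", category = "FemaleOnly")
  )
  add(
    obs("NCT90000020", "male_only_design", sexes = "Male"),
    exp_row("NCT90000020", "male_only_design", category = "MaleOnly")
  )
  add(
    obs("NCT90000021", "single_sex_beats_analysis",
      sexes = "Female",
      texts = list(
        DetailedDescription = "Outcomes will be stratified by sex."
      )
    ),
    exp_row("NCT90000021", "single_sex_beats_analysis",
      category = "FemaleOnly"
    )
  )
  add(
    obs("NCT90000022", "no_mention_at_all"),
    exp_row("NCT90000022", "no_mention_at_all", category = "NoMention")
  )
  add(
    obs("NCT90000023", "sexes_eligible_missing", sexes = "Missing"),
    exp_row("NCT90000023", "sexes_eligible_missing",
      category = "NoMention", needs_review = TRUE
    )
  )
  add(
    obs("NCT90000024", "uncued_mention_needs_review", texts = list(
      DetailedDescription = "Sex is an important variable in medicine."
    )),
    exp_row("NCT90000024", "uncued_mention_needs_review",
      category = "NoMention", needs_review = TRUE
    )
  )

  # --- cohort selection edge cases --------------------------------------
  add(
    obs("NCT90000025", "covid_nospace_title", texts = list(
      BriefTitle = "Impact of SARSCoV2 Infection on Sleep Quality",
      OfficialTitle = "Impact of SARSCoV2 Infection on Sleep Quality",
      Conditions = "Sleep Disturbance"
    )),
    exp_row("NCT90000025", "covid_nospace_title",
      category = "NoMention"
    )
  )
  add(
    obs("NCT90000026", "covid_hyphen_case_variant", texts = list(
      BriefTitle = "Registry of Patients With 2019-nCoV Pneumonia",
      OfficialTitle = "Registry of Patients With 2019-nCoV Pneumonia",
      Conditions = "Pneumonia"
    )),
    exp_row("NCT90000026", "covid_hyphen_case_variant",
      category = "NoMention"
    )
  )
  add(
    obs("NCT90000027", "covid_primary_outcome_only", texts = list(
      BriefTitle = "Respiratory Recovery After Severe Pneumonia",
      OfficialTitle = "Respiratory Recovery After Severe Pneumonia",
      Conditions = "Pneumonia",
      PrimaryOutcomeDescription =
        "Mortality among participants with confirmed COVID-19."
    )),
    exp_row("NCT90000027", "covid_primary_outcome_only",
      cohort_rule = "PrimaryOutcome", category = "NoMention"
    )
  )
  add(
    obs("NCT90000028", "covid_two_other_fields", texts = list(
      BriefTitle = "Respiratory Recovery After Severe Pneumonia",
      OfficialTitle = "Respiratory Recovery After Severe Pneumonia",
      Conditions = "Pneumonia",
      BriefSummary = "This study follows patients recovering from COVID-19.",
      SecondaryOutcomeDescription =
        "Persistent symptoms following COVID-19 infection."
    )),
    exp_row("NCT90000028", "covid_two_other_fields",
      cohort_rule = "TwoOtherFields", category = "NoMention"
    )
  )
  add(
    obs("NCT90000029", "covid_single_secondary_field", texts = list(
      BriefTitle = "Respiratory Recovery After Severe Pneumonia",
      OfficialTitle = "Respiratory Recovery After Severe Pneumonia",
      Conditions = "Pneumonia",
      SecondaryOutcomeDescription =
        "Persistent symptoms following COVID-19 infection."
    )),
    exp_row("NCT90000029", "covid_single_secondary_field",
      in_cohort = FALSE, cohort_rule = "NotMatched"
    )
  )
  add(
    obs("NCT90000030", "non_covid_study", texts = list(
      BriefTitle = "Effect of Exercise Training on Blood Pressure",
      OfficialTitle = "Effect of Exercise Training on Blood Pressure",
      Conditions = "Hypertension"
    )),
    exp_row("NCT90000030", "non_covid_study",
      in_cohort = FALSE, cohort_rule = "NotMatched"
    )
  )
  add(
    obs("NCT90000031", "withdrawn_status", status = "Withdrawn"),
    exp_row("NCT90000031", "withdrawn_status",
      in_cohort = FALSE, cohort_rule = "BadStatus"
    )
  )
  add(
    obs("NCT90000032", "start_date_before_window",
      start_date = "2019-12-15", submitted_date = "2020-02-01"
    ),
    exp_row("NCT90000032", "start_date_before_window",
      in_cohort = FALSE, cohort_rule = "OutOfWindow"
    )
  )
  add(
    obs("NCT90000033", "submission_date_fallback_kept",
      submitted_date = "2020-05-01"
    ),
    exp_row("NCT90000033", "submission_date_fallback_kept",
      category = "NoMention"
    )
  )

  # --- RCT identification edge cases ------------------------------------
  rct <- function(nct_id, case, groups, interventions, title,
                  allocation = "Randomized") {
    list(
      reg = trial_registration(
        nct_id = nct_id, study_type = "Interventional",
        allocation = allocation, phase = "Phase3",
        texts = list(
          BriefTitle = title, OfficialTitle = title, Conditions = "COVID-19",
          EligibilityCriteria = paste(
            "Inclusion Criteria:", "- Aged 18 years or older",
            sep = "\n"
          )
        ),
        groups = groups, interventions = interventions
      ),
      case = case
    )
  }
  add(
    rct("NCT90000034", "rct_group_type_control", drug_groups_placebo,
      drug_iv, covid_title("Randomized Trial of Remdesivir")
    ),
    exp_row("NCT90000034", "rct_group_type_control",
      category = "NoMention", label = "PharmaRCT",
      rct_rule = "GroupTypeControl"
    )
  )
  add(
    rct("NCT90000035", "rct_group_text_control",
      tibble::tibble(
        group_type = c("Experimental", "ActiveComparator"),
        title = c("Remdesivir", "Standard care"),
        description = c(
          "Participants receive remdesivir.",
          "Participants in the control arm receive standard care."
        )
      ),
      drug_iv, covid_title("Randomized Trial of Remdesivir")
    ),
    exp_row("NCT90000035", "rct_group_text_control",
      category = "NoMention", label = "PharmaRCT",
      rct_rule = "GroupTextControl"
    )
  )
  add(
    rct("NCT90000036", "rct_title_text_fallback",
      tibble::tibble(
        group_type = c("Experimental", "ActiveComparator"),
        title = c("Remdesivir", "Comparator"),
        description = c(
          "Participants receive remdesivir.",
          "Participants receive standard of care."
        )
      ),
      drug_iv,
      covid_title("A Randomized, Placebo-Controlled Trial of Remdesivir")
    ),
    exp_row("NCT90000036", "rct_title_text_fallback",
      category = "NoMention", label = "PharmaRCT",
      rct_rule = "TitleOrInterventionText"
    )
  )
  add(
    rct("NCT90000037", "rct_acronym_token",
      tibble::tibble(
        group_type = "Experimental", title = "Remdesivir",
        description = "Participants receive remdesivir."
      ),
      drug_iv, covid_title("RCT of Remdesivir"),
      allocation = "Missing"
    ),
    exp_row("NCT90000037", "rct_acronym_token",
      category = "NoMention", label = "PharmaRCT",
      rct_rule = "TitleOrInterventionText"
    )
  )
  add(
    rct("NCT90000038", "randomized_drug_no_control",
      tibble::tibble(
        group_type = c("Experimental", "Experimental"),
        title = c("High dose", "Low dose"),
        description = paste0(
          "Participants receive remdesivir at the ",
          c("high", "low"), " dose level."
        )
      ),
      drug_iv,
      covid_title("Randomized Trial of High Versus Low Dose Remdesivir")
    ),
    exp_row("NCT90000038", "randomized_drug_no_control",
      category = "NoMention", label = "OtherIntervention"
    )
  )
  add(
    rct("NCT90000039", "behavioral_randomized_with_control",
      tibble::tibble(
        group_type = c("Experimental", "NoIntervention"),
        title = c("Telehealth program", "Usual care"),
        description = c(
          "Participants receive a telehealth support program.",
          "Participants receive usual care."
        )
      ),
      tibble::tibble(
        intervention_type = "Behavioral",
        description = "A structured telehealth support program."
      ),
      covid_title("Effect of a Telehealth Program on Anxiety")
    ),
    exp_row("NCT90000039", "behavioral_randomized_with_control",
      category = "NoMention", label = "OtherIntervention"
    )
  )
  add(
    rct("NCT90000040", "nonrandomized_drug_with_placebo_group",
      drug_groups_placebo, drug_iv,
      covid_title("Open-Label Study of Remdesivir"),
      allocation = "NonRandomized"
    ),
    exp_row("NCT90000040", "nonrandomized_drug_with_placebo_group",
      category = "NoMention", label = "OtherIntervention"
    )
  )
  add(
    list(
      reg = trial_registration(
        nct_id = "NCT90000041", study_type = "PatientRegistry",
        allocation = "NA",
        texts = list(
          BriefTitle = "COVID-19 Patient Registry",
          OfficialTitle = "COVID-19 Patient Registry",
          Conditions = "COVID-19"
        )
      ),
      case = "patient_registry_pass_through"
    ),
    exp_row("NCT90000041", "patient_registry_pass_through",
      category = "NoMention", label = "PatientRegistry"
    )
  )
  add(
    list(
      reg = trial_registration(
        nct_id = "NCT90000042", study_type = "ExpandedAccess",
        allocation = "Missing", status = "Available",
        texts = list(
          BriefTitle = "Expanded Access Program for Remdesivir in COVID-19",
          OfficialTitle =
            "Expanded Access Program for Remdesivir in COVID-19",
          Conditions = "COVID-19"
        ),
        interventions = drug_iv
      ),
      case = "expanded_access_pass_through"
    ),
    exp_row("NCT90000042", "expanded_access_pass_through",
      category = "NoMention", label = "ExpandedAccess"
    )
  )

  registry <- as_registry(dplyr::bind_rows(lapply(fx, identity)))
  expected <- dplyr::bind_rows(ex)
  expected$label[!expected$in_cohort] <- NA_character_
  expected$category[!expected$in_cohort] <- NA_character_
  list(registry = registry, expected = expected)
}
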
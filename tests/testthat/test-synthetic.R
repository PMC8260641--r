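test_that("generator specs validate their probability vectors", {
  expect_error(
    generator_spec(category_mix = c(
      FemaleOnly = 0.5, MaleOnly = 0.6, Analysis = 0, OtherMention = 0,
      RecruitmentOnly = 0, NoMention = 0
    )),
    "probability vector"
  )
  expect_error(generator_spec(n_studies = 0))
  spec <- generator_spec(n_studies = 10, seed = 3)
  expect_s3_class(spec, "generator_spec")
  expect_equal(sum(spec$date_weights), 1)
})

test_that("generation is fully deterministic under the seed", {
  spec <- generator_spec(n_studies = 60, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dump(spec, d1)
  generate_dump(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f), warn = FALSE),
      readLines(file.path(d2, f), warn = FALSE),
      info = f
    )
  }
  # different seeds diverge
  d3 <- withr::local_tempdir()
  generate_dump(generator_spec(n_studies = 60, seed = 8), d3)
  expect_false(identical(
    readLines(file.path(d1, "registrations.jsonl"), warn = FALSE),
    readLines(file.path(d3, "registrations.jsonl"), warn = FALSE)
  ))
})

test_that("one truth record exists per unique registration", {
  gen <- cached_gen(300, 17)
  expect_equal(nrow(gen$truth), nrow(gen$registry))
  expect_setequal(gen$truth$nct_id, gen$registry$nct_id)
  expect_equal(anyDuplicated(gen$truth$nct_id), 0L)
})

test_that("a degenerate category mix propagates through the pipeline", {
  spec <- generator_spec(
    n_studies = 40, seed = 5,
    category_mix = c(
      FemaleOnly = 0, MaleOnly = 0, Analysis = 0, OtherMention = 0,
      RecruitmentOnly = 0, NoMention = 1
    ),
    adversarial_rate = 0
  )
  gen <- generate_registrations(spec)
  sel <- select_cohort(gen$registry)
  asg <- assign_category(sel$cohort)
  expect_true(all(asg$category == "NoMention"))
})

test_that("planted duplicate rows are dropped again at load", {
  spec <- generator_spec(n_studies = 100, seed = 13, dup_rate = 0.03)
  out <- withr::local_tempdir()
  dmp <- generate_dump(spec, out)
  expect_length(dmp$dup_ids, 3L)
  reg <- load_registry_dump(dmp$aact_dir, dialect = "aact")
  expect_equal(nrow(reg), 100L)
  expect_equal(attr(reg, "load_report")$n_duplicate_ids, 3L)
  jreg <- load_registry_dump(dmp$jsonl, dialect = "jsonl")
  expect_equal(nrow(jreg), 100L)
})

test_that("assigned category shares track the planted mix", {
  run <- cached_run(1000, 1)
  planted <- table(factor(run$truth$category[
    run$truth$nct_id %in% run$cohort$nct_id
  ], levels = names(generator_spec()$category_mix)))
  assigned <- table(factor(run$assignments$category,
    levels = names(generator_spec()$category_mix)
  ))
  expect_true(all(abs(planted - assigned) / nrow(run$cohort) <= 0.03))
})

test_that("enrollment medians converge on the per-group targets", {
  run <- cached_run(1000, 1)
  no_mention <- enrollment_median(run$frame, category == "NoMention")
  expect_lt(abs(no_mention - 176) / 176, 0.15)
  analysis <- enrollment_median(run$frame, category == "Analysis")
  expect_lt(abs(analysis - 700) / 700, 0.35) # small group, wide tolerance
})

test_that("the submission calendar concentrates in the first half of 2020", {
  run <- cached_run(1000, 1)
  ser <- monthly_series(run$frame)
  h1 <- sum(ser$n[ser$month >= "2020-01" & ser$month <= "2020-06"])
  share <- h1 / sum(ser$n)
  expect_lt(abs(share - 0.56), 0.03)
})

test_that("the fixture set exercises every decision rule", {
  fx <- cached_fixture_run()
  run <- cached_run(1000, 1)
  # cohort rules
  rules <- unique(c(fx$sel$decisions$rule, run$sel$decisions$rule))
  expect_true(all(c(
    "TitleOrCondition", "PrimaryOutcome", "TwoOtherFields", "NotMatched",
    "OutOfWindow", "BadStatus"
  ) %in% rules))
  # categories and subtags
  asg <- dplyr::bind_rows(fx$assignments, run$assignments)
  expect_setequal(
    unique(asg$category),
    c("FemaleOnly", "MaleOnly", "Analysis", "OtherMention",
      "RecruitmentOnly", "NoMention")
  )
  expect_true(all(c(
    "MatchedOrRepresentative", "RecordOrReport", "AutoEligibilityOnly",
    "SpuriousMention"
  ) %in% unique(asg$subtag)))
  # labels and RCT rules
  cls <- dplyr::bind_rows(fx$classes, run$classes)
  expect_setequal(
    unique(cls$label),
    c("PharmaRCT", "OtherIntervention", "Observational", "PatientRegistry",
      "ExpandedAccess")
  )
  expect_true(all(c(
    "GroupTypeControl", "GroupTextControl", "TitleOrInterventionText"
  ) %in% unique(cls$rct_rule)))
  # rule-bank rule ids fired somewhere
  fired <- unique(unlist(asg$fired_rules))
  expect_true(all(c(
    "auto_recruitment_only", "single_sex_female", "single_sex_male",
    "an_stratify", "an_covariate", "an_subgroup", "an_hypothesis",
    "om_matched", "or_record", "or_report", "rc_enrol",
    "sp_contraception", "sp_literature", "sp_donor", "sp_pregnancy_test"
  ) %in% fired))
})
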
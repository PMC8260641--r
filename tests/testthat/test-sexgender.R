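test_that("curated fixtures receive their expected assignments", {
  fx <- cached_fixture_run()
  m <- dplyr::inner_join(
    fx$assignments, fx$expected,
    by = "nct_id", suffix = c("", ".exp")
  )
  expect_equal(nrow(m), sum(fx$expected$in_cohort))
  for (i in seq_len(nrow(m))) {
    expect_identical(m$category[i], m$category.exp[i], info = m$case[i])
    expect_identical(m$subtag[i], m$subtag.exp[i], info = m$case[i])
    expect_identical(
      m$needs_review[i], m$needs_review.exp[i],
      info = m$case[i]
    )
  }
})

test_that("single-sex detection follows the structured field", {
  expect_equal(
    detect_single_sex(c("Female", "Male", "All", "Missing")),
    c("FemaleOnly", "MaleOnly", NA, NA)
  )
})

test_that("the auto recruitment-only rule needs eligibility-only matches", {
  elig_only <- tibble::tibble(
    term = "male", field = "EligibilityCriteria", start = 0L, end = 4L,
    surface_form = "Male"
  )
  expect_true(auto_recruitment_only(elig_only))
  mixed <- dplyr::bind_rows(
    elig_only,
    tibble::tibble(
      term = "sex", field = "BriefSummary", start = 0L, end = 3L,
      surface_form = "sex"
    )
  )
  expect_false(auto_recruitment_only(mixed))
  expect_false(auto_recruitment_only(empty_matches <- mixed[0, ]))
})

test_that("spurious context windows contribute no positive evidence", {
  texts <- list(DetailedDescription = paste(
    "Women of childbearing potential must use adequate contraception.",
    "The study collects respiratory samples."
  ))
  m <- find_matches(texts, "DetailedDescription", sexgender_terms())
  ctx <- classify_contexts(texts, m)
  expect_true(all(ctx$spurious))
  expect_true(all(vapply(ctx$rules, function(r) {
    all(startsWith(r, "sp_"))
  }, logical(1))))
})

test_that("analysis statements are recognized at sentence scope", {
  texts <- list(DetailedDescription = paste(
    "Participants receive standard care.",
    "Outcomes will be stratified by sex and age.",
    "Follow-up lasts one year."
  ))
  m <- find_matches(texts, "DetailedDescription", sexgender_terms())
  ctx <- classify_contexts(texts, m)
  expect_false(any(ctx$spurious))
  expect_true("an_stratify" %in% unlist(ctx$rules))
  # the window is the containing sentence, not the whole field
  expect_false(grepl("standard care", ctx$window[1]))
})

test_that("category precedence follows the attention hierarchy", {
  fx <- cached_fixture_run()
  # analysis cue beats a recruitment statement in the same record
  a <- fx$assignments[fx$assignments$nct_id == "NCT90000013", ]
  expect_equal(a$category, "Analysis")
  # single-sex designs precede everything
  b <- fx$assignments[fx$assignments$nct_id == "NCT90000021", ]
  expect_equal(b$category, "FemaleOnly")
})

test_that("demographic-variable phrasing without a sex term is no mention", {
  reg <- reg_with_text(
    "NCT9", "DetailedDescription",
    "Demographic variables will be adjusted for in the analysis."
  )
  asg <- assign_category(reg)
  expect_equal(asg$category, "NoMention")
  expect_equal(asg$n_matches, 0L)
  expect_false(asg$needs_review)
})

test_that("recruitment statements must cover both sexes", {
  one_sided <- reg_with_text(
    "NCT10", "DetailedDescription",
    "About 150 female participants will be enrolled."
  )
  a1 <- assign_category(one_sided)
  expect_equal(a1$category, "NoMention")
  expect_true(a1$needs_review)
  neutral <- reg_with_text(
    "NCT11", "DetailedDescription",
    "Adults of any sex are eligible to participate."
  )
  a2 <- assign_category(neutral)
  expect_equal(a2$category, "RecruitmentOnly")
  expect_false(a2$needs_review)
})

test_that("assignments partition the cohort", {
  run <- cached_run(300, 17)
  asg <- run$assignments
  expect_equal(nrow(asg), nrow(run$cohort))
  expect_equal(anyDuplicated(asg$nct_id), 0L)
  expect_false(any(is.na(asg$category)))
  counts <- table(asg$category)
  expect_equal(sum(counts), nrow(run$cohort))
  # subtags only ever appear with their host category
  expect_true(all(
    asg$category[asg$subtag %in%
      c("MatchedOrRepresentative", "RecordOrReport")] == "OtherMention"
  ))
  expect_true(all(
    asg$category[asg$subtag %in% "AutoEligibilityOnly"] == "RecruitmentOnly"
  ))
  expect_true(all(
    asg$category[asg$subtag %in% "SpuriousMention"] == "NoMention"
  ))
})

test_that("single-sex assignments agree with the eligibility field", {
  run <- cached_run(300, 17)
  asg <- dplyr::inner_join(
    run$assignments,
    run$cohort[, c("nct_id", "sexes_eligible")],
    by = "nct_id"
  )
  expect_true(all(asg$sexes_eligible[asg$category == "FemaleOnly"] == "Female"))
  expect_true(all(asg$sexes_eligible[asg$category == "MaleOnly"] == "Male"))
})

test_that("auto-rule studies carry eligibility-only evidence", {
  run <- cached_run(300, 17)
  auto <- run$assignments[
    run$assignments$subtag %in% "AutoEligibilityOnly",
  ]
  expect_gt(nrow(auto), 0)
  for (i in seq_len(nrow(auto))) {
    ev <- auto$evidence[[i]]
    expect_true(all(ev$field == "EligibilityCriteria"))
  }
})

test_that("adding an analysis sentence never lowers the category", {
  rank <- c(
    NoMention = 0, RecruitmentOnly = 1, OtherMention = 2, Analysis = 3,
    FemaleOnly = 4, MaleOnly = 4
  )
  fx <- cached_fixture_run()
  before <- fx$assignments
  boosted <- fx$cohort
  for (i in seq_len(nrow(boosted))) {
    boosted$texts[[i]]$DetailedDescription <- paste(
      boosted$texts[[i]]$DetailedDescription,
      "Outcomes will additionally be stratified by sex."
    )
  }
  after <- assign_category(boosted)
  m <- dplyr::inner_join(before, after, by = "nct_id",
    suffix = c(".before", ".after"))
  expect_true(all(
    rank[m$category.after] >= rank[m$category.before]
  ))
  # non-single-sex records all climb to Analysis
  open_sex <- m$category.before %in%
    c("NoMention", "RecruitmentOnly", "OtherMention", "Analysis")
  expect_true(all(m$category.after[open_sex] == "Analysis"))
})
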
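covid_reg <- function(id, field, text, ...) {
  reg_with_text(id, field, text, ...)
}

test_that("field placement drives the inclusion rule", {
  regs <- dplyr::bind_rows(
    covid_reg("NCT1", "BriefTitle", "A COVID-19 trial"),
    covid_reg(
      "NCT2", "SecondaryOutcomeDescription",
      "Symptoms after SARS-CoV-2 infection"
    ),
    dplyr::bind_rows(covid_reg("NCT3", "BriefSummary", "We study COVID."))
  )
  regs$texts[[3]]$SecondaryOutcomeDescription <- "COVID symptom burden"
  dec <- covid_relevance(regs)
  expect_equal(dec$rule, c("TitleOrCondition", "NotMatched", "TwoOtherFields"))
  expect_equal(dec$included, c(TRUE, FALSE, TRUE))
  # primary outcome placement is sufficient on its own
  p <- covid_relevance(covid_reg(
    "NCT4", "PrimaryOutcomeDescription", "COVID-19 viral load at day 5"
  ))
  expect_equal(p$rule, "PrimaryOutcome")
  expect_true(p$included)
})

test_that("evidence is attached whenever a term rule fires", {
  dec <- covid_relevance(covid_reg("NCT1", "BriefTitle", "A COVID-19 trial"))
  expect_gt(nrow(dec$evidence[[1]]), 0)
  expect_equal(dec$evidence[[1]]$surface_form[1], "COVID")
})

test_that("the date window is inclusive and falls back to submission", {
  mk <- function(id, start, submitted) {
    trial_registration(id,
      start_date = start, submitted_date = submitted,
      texts = list(BriefTitle = "COVID-19 study")
    )
  }
  regs <- dplyr::bind_rows(
    mk("NCT1", "2019-12-15", "2020-02-01"), # start before window
    mk("NCT2", NA, "2020-05-01"), # fallback keeps
    mk("NCT3", "2020-01-01", "2019-12-01"), # lower boundary inclusive
    mk("NCT4", "2021-01-26", "2020-12-01"), # upper boundary inclusive
    mk("NCT5", "2021-01-27", "2020-12-01") # one past the snapshot
  )
  wf <- window_and_status_filter(regs)
  expect_setequal(wf$kept$nct_id, c("NCT2", "NCT3", "NCT4"))
  expect_equal(
    wf$log$rule[wf$log$nct_id %in% c("NCT1", "NCT5")],
    c("OutOfWindow", "OutOfWindow")
  )
})

test_that("withdrawn and no-longer-available studies are excluded", {
  regs <- dplyr::bind_rows(
    trial_registration("NCT1", status = "Withdrawn"),
    trial_registration("NCT2", status = "No longer available"),
    trial_registration("NCT3", status = "Recruiting")
  )
  wf <- window_and_status_filter(regs)
  expect_equal(wf$kept$nct_id, "NCT3")
  expect_equal(wf$log$rule, c("BadStatus", "BadStatus"))
})

test_that("deduplication keeps first per id and flags title clones", {
  a <- covid_reg("NCT1", "BriefTitle", "Trial A")
  b <- covid_reg("NCT1", "BriefTitle", "Trial A bis")
  c3 <- covid_reg("NCT2", "BriefTitle", "Trial A") # same normalized title
  dd <- deduplicate(dplyr::bind_rows(a, b, c3))
  expect_equal(nrow(dd$kept), 2L)
  expect_equal(dd$kept$texts[[1]]$BriefTitle, "Trial A")
  expect_true("Duplicate" %in% dd$log$rule)
  distinct <- dplyr::bind_rows(lapply(1:10, function(i) {
    covid_reg(paste0("NCT", i), "BriefTitle", paste("Trial", i))
  }))
  expect_equal(nrow(deduplicate(distinct)$kept), 10L)
})

test_that("planted duplicates are removed at the expected rate", {
  base <- dplyr::bind_rows(lapply(1:100, function(i) {
    covid_reg(sprintf("NCT%03d", i), "BriefTitle", paste("Study", i))
  }))
  dups <- base[c(3, 50, 97), ]
  shuffled <- dplyr::bind_rows(base, dups)
  expect_equal(nrow(deduplicate(shuffled)$kept), 100L)
  # 97 survivors when the duplicates replace distinct records
  expect_equal(nrow(deduplicate(dplyr::bind_rows(base[1:97, ], dups))$kept), 97L)
})

test_that("filtering and relevance commute on the cohort set", {
  fx <- cached_fixture_run()
  reg <- fx$registry
  # relevance first, then window/status
  rel <- covid_relevance(reg)
  keep1 <- window_and_status_filter(
    reg[rel$included, , drop = FALSE]
  )$kept$nct_id
  # window/status first, then relevance
  wf <- window_and_status_filter(reg)
  rel2 <- covid_relevance(wf$kept)
  keep2 <- wf$kept$nct_id[rel2$included]
  expect_setequal(keep1, keep2)
  expect_setequal(keep1, fx$sel$cohort$nct_id)
})

test_that("adding a COVID term never removes a study from the cohort", {
  fx <- cached_fixture_run()
  reg <- fx$registry
  wf <- window_and_status_filter(deduplicate(reg)$kept)
  before <- covid_relevance(wf$kept)
  boosted <- wf$kept
  for (i in seq_len(nrow(boosted))) {
    boosted$texts[[i]]$BriefSummary <- paste(
      boosted$texts[[i]]$BriefSummary, "Context: COVID-19 pandemic."
    )
  }
  after <- covid_relevance(boosted)
  expect_true(all(after$included >= before$included))
})
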
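write_mini_dump <- function(dir, studies, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(studies, file.path(dir, "studies.csv"), progress = FALSE)
  extra <- list(...)
  for (nm in names(extra)) {
    readr::write_csv(extra[[nm]], file.path(dir, paste0(nm, ".csv")),
      progress = FALSE
    )
  }
  dir
}

mini_studies <- function(nct_id = "NCT00000001", ...) {
  df <- tibble::tibble(
    nct_id = nct_id, study_type = "Observational",
    brief_title = "A study", official_title = "A longer study title",
    overall_status = "Recruiting", phase = "",
    enrollment = "100", enrollment_type = "Anticipated",
    start_date = "", study_first_submitted_date = "2020-06-01",
    patient_registry = "false"
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

test_that("child rows aggregate with a newline separator", {
  dir <- write_mini_dump(
    withr::local_tempdir(), mini_studies(),
    conditions = tibble::tibble(
      nct_id = "NCT00000001", name = c("COVID-19", "Pneumonia")
    )
  )
  reg <- load_registry_dump(dir, dialect = "aact")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$texts[[1]]$Conditions, "COVID-19\nPneumonia")
})

test_that("missing child tables yield empty fields, never errors", {
  dir <- write_mini_dump(withr::local_tempdir(), mini_studies())
  reg <- load_registry_dump(dir, dialect = "aact")
  expect_equal(reg$texts[[1]]$EligibilityCriteria, "")
  expect_equal(reg$sexes_eligible, "Missing")
  expect_equal(reg$groups[[1]], tibble::tibble(
    group_type = character(), title = character(), description = character()
  ))
  expect_length(reg$facility_countries[[1]], 0)
  expect_false(reg$has_document)
})

test_that("the studies table is mandatory", {
  expect_error(
    load_registry_dump(withr::local_tempdir(), dialect = "aact"),
    "studies table is mandatory"
  )
})

test_that("duplicate study rows keep the first occurrence and are logged", {
  studies <- dplyr::bind_rows(
    mini_studies(brief_title = "first"),
    mini_studies(brief_title = "second")
  )
  dir <- write_mini_dump(withr::local_tempdir(), studies)
  reg <- load_registry_dump(dir, dialect = "aact")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$texts[[1]]$BriefTitle, "first")
  expect_equal(attr(reg, "load_report")$n_duplicate_ids, 1L)
})

test_that("sexes-eligible parsing is case-insensitive and total", {
  expect_equal(parse_sexes_eligible("All"), "All")
  expect_equal(parse_sexes_eligible("FEMALE"), "Female")
  expect_equal(parse_sexes_eligible("male "), "Male")
  expect_equal(parse_sexes_eligible(""), "Missing")
  expect_equal(parse_sexes_eligible("Both"), "Missing")
  expect_equal(parse_sexes_eligible(NA), "Missing")
})

test_that("dates parse at day and month precision", {
  expect_equal(parse_registry_date("2020-05-14"), as.Date("2020-05-14"))
  expect_equal(parse_registry_date("2020-05"), as.Date("2020-05-01"))
  expect_true(is.na(parse_registry_date("May 2020")))
  expect_true(is.na(parse_registry_date("")))
})

test_that("word counts sum whitespace tokens across description fields", {
  r1 <- trial_registration("NCT1", texts = list(
    BriefSummary = "A COVID-19 trial.", DetailedDescription = ""
  ))
  expect_equal(word_count(r1), 3L)
  r2 <- trial_registration("NCT2")
  expect_equal(word_count(r2), 0L)
  long <- paste(rep("token", 245), collapse = " ")
  r3 <- trial_registration("NCT3", texts = list(DetailedDescription = long))
  expect_equal(word_count(r3), 245L)
})

test_that("enrollment invariant: absent count forces Missing type", {
  r <- trial_registration("NCT4",
    enrollment_count = NA_integer_,
    enrollment_type = "Anticipated"
  )
  expect_equal(r$enrollment_type, "Missing")
})

registry_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$nct_id), ]
  b <- b[order(b$nct_id), ]
  for (col in c(
    "nct_id", "study_type", "allocation", "phase", "sexes_eligible",
    "status", "start_date", "submitted_date", "enrollment_count",
    "enrollment_type", "has_document"
  )) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
  for (i in seq_len(nrow(a))) {
    expect_equal(a$texts[[i]], b$texts[[i]], info = a$nct_id[i])
    expect_equal(
      as.data.frame(a$groups[[i]]), as.data.frame(b$groups[[i]])
    )
    expect_equal(
      as.data.frame(a$interventions[[i]]),
      as.data.frame(b$interventions[[i]])
    )
    expect_equal(a$facility_countries[[i]], b$facility_countries[[i]])
  }
  invisible(TRUE)
}

test_that("synthetic dumps round-trip through both dialects", {
  gen <- cached_gen(50, 11)
  out <- withr::local_tempdir()
  write_dump(gen$registry, file.path(out, "aact"))
  write_registrations(gen$registry, file.path(out, "regs.jsonl"))
  from_csv <- load_registry_dump(file.path(out, "aact"), dialect = "aact")
  from_jsonl <- load_registry_dump(
    file.path(out, "regs.jsonl"),
    dialect = "jsonl"
  )
  registry_equal(from_csv, gen$registry)
  registry_equal(from_jsonl, gen$registry)
  # write(load(D)) then reload is a fixed point
  write_dump(from_csv, file.path(out, "aact2"))
  again <- load_registry_dump(file.path(out, "aact2"), dialect = "aact")
  registry_equal(again, from_csv)
})

test_that("permuting child-table row order leaves decisions unchanged", {
  gen <- cached_gen(50, 11)
  out <- withr::local_tempdir()
  write_dump(gen$registry, file.path(out, "aact"))
  ref <- load_registry_dump(file.path(out, "aact"), dialect = "aact")
  set.seed(5)
  for (tab in c("conditions", "design_outcomes", "design_groups",
    "interventions", "facilities")) {
    p <- file.path(out, "aact", paste0(tab, ".csv"))
    df <- readr::read_csv(p,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    readr::write_csv(df[sample(nrow(df)), ], p, progress = FALSE)
  }
  perm <- load_registry_dump(file.path(out, "aact"), dialect = "aact")
  ref_sel <- select_cohort(ref)
  perm_sel <- select_cohort(perm)
  expect_equal(
    perm_sel$decisions[order(perm_sel$decisions$nct_id),
      c("nct_id", "included", "rule")],
    ref_sel$decisions[order(ref_sel$decisions$nct_id),
      c("nct_id", "included", "rule")]
  )
  ref_asg <- assign_category(ref_sel$cohort)
  perm_asg <- assign_category(perm_sel$cohort)
  cols <- c("nct_id", "category", "subtag", "needs_review")
  expect_equal(
    perm_asg[order(perm_asg$nct_id), cols],
    ref_asg[order(ref_asg$nct_id), cols]
  )
  ref_cls <- classify_study(ref_sel$cohort)
  perm_cls <- classify_study(perm_sel$cohort)
  expect_equal(
    perm_cls[order(perm_cls$nct_id), ],
    ref_cls[order(ref_cls$nct_id), ]
  )
})

test_that("awkward text content survives a CSV round trip", {
  tricky <- paste0(
    "Line one with \"quotes\" and, commas.\n",
    "Second line with a trailing clause; plus unicode: éß."
  )
  reg <- trial_registration("NCT7", texts = list(
    BriefSummary = tricky, OfficialTitle = "T", BriefTitle = "T"
  ))
  out <- withr::local_tempdir()
  write_dump(reg, out)
  back <- load_registry_dump(out, dialect = "aact")
  expect_equal(back$texts[[1]]$BriefSummary, tricky)
})
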
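test_that("plural expansion covers regular and irregular forms", {
  expect_setequal(expand_terms("woman", TRUE), c("woman", "women"))
  expect_setequal(expand_terms("man", TRUE), c("man", "men"))
  expect_setequal(expand_terms("sex", TRUE), c("sex", "sexes"))
  expect_setequal(expand_terms("boy", TRUE), c("boy", "boys"))
  expect_setequal(expand_terms("girl", TRUE), c("girl", "girls"))
  expect_setequal(expand_terms("female", TRUE), c("female", "females"))
  # wildcard stems are returned unchanged
  expect_identical(expand_terms("pregnan*"), "pregnan*")
})

test_that("separator-blind matching collapses hyphens and spaces", {
  terms <- term_spec("SARS CoV2")
  m <- find_matches(
    list(BriefTitle = "Efficacy in SARSCoV2 infection"),
    "BriefTitle", terms
  )
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface_form, "SARSCoV2")
  for (v in c("SARS-CoV2", "SARS CoV2", "SARSCoV2")) {
    mm <- find_matches(
      list(BriefTitle = paste("Efficacy in", v, "infection")),
      "BriefTitle", terms
    )
    expect_equal(nrow(mm), 1L, info = v)
  }
})

test_that("letter neighbours block substring hits", {
  texts <- list(BriefSummary = "female participants")
  expect_equal(
    nrow(find_matches(texts, "BriefSummary", term_spec("male"))), 0L
  )
  f <- find_matches(texts, "BriefSummary", term_spec("female"))
  expect_equal(nrow(f), 1L)
  # digits and punctuation are permitted neighbours
  m <- find_matches(
    list(BriefSummary = "COVID19 pneumonia and covid-19 sequelae"),
    "BriefSummary", term_spec("COVID")
  )
  expect_equal(nrow(m), 2L)
  expect_equal(m$surface_form, c("COVID", "covid"))
})

test_that("match spans index the original text", {
  txt <- "A 2019-nCoV and SARS CoV-2 study"
  m <- find_matches(
    list(BriefTitle = txt), "BriefTitle",
    term_spec(c("2019 nCov", "SARS-CoV-2"))
  )
  expect_equal(nrow(m), 2L)
  expect_equal(
    substr(rep(txt, nrow(m)), m$start + 1, m$end), m$surface_form
  )
})

test_that("plural variants match while stems respect boundaries", {
  m <- find_matches(
    list(BriefSummary = "Both sexes will be studied"),
    "BriefSummary", term_spec("sex", expand_plural = TRUE)
  )
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface_form, "sexes")
  m2 <- find_matches(
    list(BriefSummary = "men and women aged 18"),
    "BriefSummary",
    term_spec(c("man", "woman"), expand_plural = TRUE)
  )
  expect_equal(sort(m2$surface_form), c("men", "women"))
})

test_that("wildcard stems consume trailing letters, left rule only", {
  m <- find_matches(
    list(BriefSummary = "pregnancy test and pregnant women"),
    "BriefSummary", term_spec("pregnan*")
  )
  expect_equal(m$surface_form, c("pregnancy", "pregnant"))
})

test_that("case-sensitive token matching is honoured", {
  rct <- term_spec("RCT", case_sensitive = TRUE)
  expect_equal(
    nrow(find_matches(list(BriefTitle = "an RCT of X"), "BriefTitle", rct)),
    1L
  )
  expect_equal(
    nrow(find_matches(list(BriefTitle = "the rct was"), "BriefTitle", rct)),
    0L
  )
})

test_that("unknown scope fields raise a configuration error", {
  expect_error(
    find_matches(list(BriefTitle = "x"), "NotAField", covid_terms()),
    "unknown field"
  )
})

test_that("matching agrees with the brute-force oracle on planted texts", {
  plan <- list(
    list(term = "COVID", variants = "COVID", wildcard = FALSE),
    list(term = "SARS-CoV-2", variants = "SARS-CoV-2", wildcard = FALSE),
    list(term = "Corona Virus", variants = "Corona Virus", wildcard = FALSE),
    list(
      term = "male", variants = c("male", "males"), wildcard = FALSE,
      expand = TRUE
    ),
    list(
      term = "woman", variants = c("woman", "women"), wildcard = FALSE,
      expand = TRUE
    ),
    list(term = "pregnan*", variants = "pregnan*", wildcard = TRUE)
  )
  fillers <- c(
    "the", "of", "19", "covidious", "femalex", "unmanly", "x-ray",
    "patients", "acovid", "woman2", "pneumonia,", "pregnancies"
  )
  planted <- c(
    "COVID", "covid-19", "CoViD19", "SARS-CoV-2", "SARSCoV2", "sars cov 2",
    "Corona Virus", "corona-virus", "coronavirus", "male", "MALES",
    "female", "woman", "women", "pregnant", "Pregnancy", "(covid)"
  )
  set.seed(99)
  for (rep in 1:40) {
    tokens <- sample(c(fillers, planted), size = sample(8:20, 1),
      replace = TRUE
    )
    joiners <- sample(c(" ", " ", " ", "-", ", "), length(tokens) - 1,
      replace = TRUE
    )
    text <- paste0(
      paste0(tokens[-length(tokens)], joiners, collapse = ""),
      tokens[length(tokens)]
    )
    for (p in plan) {
      got <- find_matches(
        list(BriefSummary = text), "BriefSummary",
        term_spec(p$term, expand_plural = isTRUE(p$expand))
      )
      want <- oracle_matches(text, p$variants, wildcard = p$wildcard)
      expect_equal(
        sorted_spans(got), sorted_spans(want),
        info = paste(p$term, "|", text)
      )
    }
  }
})

test_that("every separator/case realization of a term is found", {
  terms <- covid_terms()
  realizations <- function(surface) {
    unique(c(
      surface,
      gsub("[ -]", "", surface),
      gsub("[ -]", "-", surface),
      gsub("[ -]", " ", surface),
      toupper(surface), tolower(surface),
      tolower(gsub("[ -]", "-", surface))
    ))
  }
  for (i in seq_len(nrow(terms))) {
    surface <- terms$surface[i]
    for (r in realizations(surface)) {
      m <- find_matches(
        list(BriefSummary = paste("Study of", r, "pneumonia")),
        "BriefSummary", terms[i, ]
      )
      expect_equal(nrow(m), 1L, info = paste(surface, "->", r))
    }
  }
})

test_that("cohort inclusion is invariant to the term realization used", {
  realizations <- c(
    "COVID-19", "COVID 19", "COVID19", "covid-19",
    "SARS-CoV-2", "SARSCoV2", "sars cov2", "SARS CoV-2",
    "2019-nCoV", "2019 nCov", "2019nCoV", "Coronavirus", "Corona Virus"
  )
  regs <- dplyr::bind_rows(lapply(seq_along(realizations), function(i) {
    reg_with_text(
      sprintf("NCT80%06d", i), "BriefTitle",
      paste("Outcomes of", realizations[i], "pneumonia")
    )
  }))
  dec <- covid_relevance(regs)
  expect_true(all(dec$included))
  expect_true(all(dec$rule == "TitleOrCondition"))
})

test_that("matches are reported in catalogue field order then offset", {
  m <- find_matches(
    list(
      Conditions = "COVID-19",
      BriefTitle = "COVID-19 trial of COVID vaccination"
    ),
    c("Conditions", "BriefTitle"), term_spec("COVID")
  )
  expect_equal(m$field, c("BriefTitle", "BriefTitle", "Conditions"))
  expect_true(!is.unsorted(m$start[m$field == "BriefTitle"]))
})
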
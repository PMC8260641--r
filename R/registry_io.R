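# --- enum maps between canonical values and AACT-dialect raw strings -----

.study_type_map <- c(
  "Interventional" = "Interventional",
  "Observational" = "Observational",
  "Observational [Patient Registry]" = "PatientRegistry",
  "Expanded Access" = "ExpandedAccess"
)

.allocation_map <- c(
  "Randomized" = "Randomized",
  "Non-Randomized" = "NonRandomized",
  "N/A" = "NA"
)

.phase_map <- c(
  "Early Phase 1" = "EarlyPhase1",
  "Phase 1" = "Phase1",
  "Phase 1/Phase 2" = "Phase1_2",
  "Phase 2" = "Phase2",
  "Phase 2/Phase 3" = "Phase2_3",
  "Phase 3" = "Phase3",
  "Phase 4" = "Phase4",
  "N/A" = "NA"
)

.group_type_map <- c(
  "Experimental" = "Experimental",
  "Active Comparator" = "ActiveComparator",
  "Placebo Comparator" = "PlaceboComparator",
  "Sham Comparator" = "ShamComparator",
  "No Intervention" = "NoIntervention",
  "Other" = "Other"
)

.intervention_type_map <- c(
  "Drug" = "Drug", "Biological" = "Biological", "Behavioral" = "Behavioral",
  "Device" = "Device", "Procedure" = "Procedure",
  "Diagnostic Test" = "DiagnosticTest",
  "Dietary Supplement" = "DietarySupplement",
  "Radiation" = "Radiation", "Combination Product" = "CombinationProduct",
  "Genetic" = "Genetic", "Other" = "Other"
)

map_enum <- function(raw, map, missing = "Missing", accept_canonical = TRUE) {
  out <- rep(missing, length(raw))
  raw <- trimws(ifelse(is.na(raw), "", raw))
  hit <- match(raw, names(map))
  out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  if (accept_canonical) {
    canon <- raw %in% unname(map)
    out[canon & is.na(hit)] <- raw[canon & is.na(hit)]
  }
  out
}

unmap_enum <- function(canonical, map, missing_raw = "") {
  rev_map <- stats::setNames(names(map), unname(map))
  out <- rev_map[canonical]
  ifelse(is.na(out) | canonical == "Missing", missing_raw, unname(out))
}

#' Parse the registry "sexes eligible" field
#'
#' The registry mandates one of `All`, `Male`, `Female`; parsing is
#' case-insensitive and anything else (including empty) maps to
#' `"Missing"`.  Total function: never errors.
#'
#' @param raw Character vector of raw field values.
#' @return Character vector over `{"All","Male","Female","Missing"}`.
#' @export
parse_sexes_eligible <- function(raw) {
  raw <- tolower(trimws(ifelse(is.na(raw), "", raw)))
  dplyr::case_match(raw,
    "all" ~ "All", "male" ~ "Male", "female" ~ "Female",
    .default = "Missing"
  )
}

#' Parse a registry date
#'
#' Accepts ISO `YYYY-MM-DD` and month-precision `YYYY-MM` (resolved to the
#' first of the month).  Anything else yields `NA`.
#'
#' @param raw Character vector.
#' @return A `Date` vector.
#' @export
parse_registry_date <- function(raw) {
  raw <- trimws(ifelse(is.na(raw), "", raw))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
  month <- grepl("^\\d{4}-\\d{2}$", raw)
  out <- rep(as.Date(NA), length(raw))
  if (any(full)) out[full] <- as.Date(raw[full])
  if (any(month)) out[month] <- as.Date(paste0(raw[month], "-01"))
  out
}

# join non-empty child-row texts into one field text
join_texts <- function(x, sep = "\n") {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0) "" else paste(x, collapse = sep)
}

empty_groups <- function() {
  tibble::tibble(group_type = character(), title = character(),
    description = character()
  )
}

empty_interventions <- function() {
  tibble::tibble(intervention_type = character(), description = character())
}

#' Construct a single trial registration
#'
#' Builds one row of the registry tibble with sensible defaults; mainly
#' used by the synthetic generator, the curated fixtures, and tests.
#' Unnamed text fields default to the empty string; the full field
#' catalogue is always present in `texts`.
#'
#' @param nct_id Registry identifier.
#' @param study_type One of Interventional, Observational, PatientRegistry,
#'   ExpandedAccess.
#' @param allocation One of Randomized, NonRandomized, NA, Missing.
#' @param phase Canonical phase string or `NA`.
#' @param sexes_eligible One of All, Male, Female, Missing.
#' @param status Registry overall status string.
#' @param start_date,submitted_date `Date` (or parseable string);
#'   `submitted_date` is mandatory.
#' @param enrollment_count Non-negative integer or `NA`.
#' @param enrollment_type Anticipated, Actual, or Missing.
#' @param texts Named list/character of field texts.
#' @param groups Tibble with `group_type`, `title`, `description`.
#' @param interventions Tibble with `intervention_type`, `description`.
#' @param facility_countries Character vector.
#' @param has_document Logical flag for attached supporting documents.
#' @return A one-row registry tibble (see [load_registry_dump()]).
#' @export
trial_registration <- function(nct_id,
                               study_type = "Interventional",
                               allocation = "Missing",
                               phase = NA_character_,
                               sexes_eligible = "All",
                               status = "Recruiting",
                               start_date = NA,
                               submitted_date = "2020-06-01",
                               enrollment_count = NA_integer_,
                               enrollment_type = "Missing",
                               texts = list(),
                               groups = empty_groups(),
                               interventions = empty_interventions(),
                               facility_countries = character(),
                               has_document = FALSE) {
  full <- stats::setNames(
    as.list(rep("", length(field_catalogue()))), field_catalogue()
  )
  bad <- setdiff(names(texts), field_catalogue())
  if (length(bad) > 0) {
    stop("unknown text field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(texts)) full[[nm]] <- texts[[nm]]
  # group/intervention texts mirror the structured lists unless given
  if (!("GroupTitle" %in% names(texts)) && nrow(groups) > 0) {
    full$GroupTitle <- join_texts(groups$title)
  }
  if (!("GroupDescription" %in% names(texts)) && nrow(groups) > 0) {
    full$GroupDescription <- join_texts(groups$description)
  }
  if (!("InterventionDescription" %in% names(texts)) &&
    nrow(interventions) > 0) {
    full$InterventionDescription <- join_texts(interventions$description)
  }
  if (is.na(enrollment_count)) enrollment_type <- "Missing"
  submitted_date <- as.Date(submitted_date)
  if (is.na(submitted_date)) {
    stop("submitted_date is mandatory for ", nct_id, call. = FALSE)
  }
  tibble::tibble(
    nct_id = nct_id,
    study_type = study_type,
    allocation = allocation,
    phase = phase,
    sexes_eligible = sexes_eligible,
    status = status,
    start_date = as.Date(start_date),
    submitted_date = submitted_date,
    enrollment_count = as.integer(enrollment_count),
    enrollment_type = enrollment_type,
    texts = list(full),
    groups = list(groups),
    interventions = list(interventions),
    facility_countries = list(facility_countries),
    has_document = has_document
  )
}

registry_columns <- c(
  "nct_id", "study_type", "allocation", "phase", "sexes_eligible", "status",
  "start_date", "submitted_date", "enrollment_count", "enrollment_type",
  "texts", "groups", "interventions", "facility_countries", "has_document"
)

as_registry <- function(df) {
  stopifnot(all(registry_columns %in% names(df)))
  out <- tibble::as_tibble(df[registry_columns])
  class(out) <- c("trial_registry", class(out))
  out
}

read_table_or_empty <- function(path, required_cols) {
  if (is.null(path) || !file.exists(path)) {
    return(NULL)
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(required_cols, names(df))
  for (m in missing) df[[m]] <- NA_character_
  df
}

#' Load an AACT-dialect registry dump
#'
#' Assembles one registration per distinct `nct_id` in the studies table.
#' Two dialects are supported: `"aact"` — a directory (or named path list)
#' of RFC-4180 CSV tables using AACT column names (`studies` mandatory;
#' `brief_summaries`, `detailed_descriptions`, `conditions`,
#' `design_outcomes`, `eligibilities`, `design_groups`, `designs`,
#' `interventions`, `facilities`, `documents` optional) — and `"jsonl"` —
#' one JSON registration object per line, the generator's native format.
#' Multi-row child tables are aggregated per study by joining non-empty
#' values with `sep`; missing child rows yield empty texts/lists, never
#' errors.  Duplicate `nct_id` rows in the studies table keep the first
#' occurrence and are recorded in the load report
#' (`attr(x, "load_report")`).
#'
#' @param paths For `"aact"`: a directory containing `<table>.csv` files or
#'   a named list of file paths; for `"jsonl"`: a single file path.
#' @param dialect `"aact"` or `"jsonl"`.
#' @param sep Separator used to join child-row texts (default newline).
#' @return A `trial_registry` tibble with columns `nct_id`, `study_type`,
#'   `allocation`, `phase`, `sexes_eligible`, `status`, `start_date`,
#'   `submitted_date`, `enrollment_count`, `enrollment_type`, and
#'   list-columns `texts`, `groups`, `interventions`, `facility_countries`,
#'   plus `has_document`.
#' @export
load_registry_dump <- function(paths, dialect = c("aact", "jsonl"),
                               sep = "\n") {
  dialect <- match.arg(dialect)
  if (dialect == "jsonl") {
    return(read_registrations(paths))
  }
  table_names <- c(
    "studies", "brief_summaries", "detailed_descriptions", "conditions",
    "design_outcomes", "eligibilities", "design_groups", "designs",
    "interventions", "facilities", "documents"
  )
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- stats::setNames(
      file.path(paths, paste0(table_names, ".csv")), table_names
    )
  }
  paths <- as.list(paths)
  if (is.null(paths$studies) || !file.exists(paths$studies)) {
    stop("studies table is mandatory and was not found", call. = FALSE)
  }
  studies <- read_table_or_empty(paths$studies, c(
    "nct_id", "study_type", "brief_title", "official_title",
    "overall_status", "phase", "enrollment", "enrollment_type",
    "start_date", "study_first_submitted_date", "patient_registry"
  ))
  dup <- duplicated(studies$nct_id)
  n_dup <- sum(dup)
  dup_ids <- unique(studies$nct_id[dup])
  studies <- studies[!dup, , drop = FALSE]

  submitted <- parse_registry_date(studies$study_first_submitted_date)
  bad_row <- is.na(studies$nct_id) | !nzchar(trimws(
    ifelse(is.na(studies$nct_id), "", studies$nct_id)
  )) | is.na(submitted)
  skipped <- studies$nct_id[bad_row]
  studies <- studies[!bad_row, , drop = FALSE]
  submitted <- submitted[!bad_row]

  child <- list(
    brief_summaries = read_table_or_empty(
      paths$brief_summaries, c("nct_id", "description")
    ),
    detailed_descriptions = read_table_or_empty(
      paths$detailed_descriptions, c("nct_id", "description")
    ),
    conditions = read_table_or_empty(paths$conditions, c("nct_id", "name")),
    design_outcomes = read_table_or_empty(
      paths$design_outcomes,
      c("nct_id", "outcome_type", "measure", "description")
    ),
    eligibilities = read_table_or_empty(
      paths$eligibilities,
      c("nct_id", "gender", "population", "gender_description", "criteria")
    ),
    design_groups = read_table_or_empty(
      paths$design_groups, c("nct_id", "group_type", "title", "description")
    ),
    designs = read_table_or_empty(paths$designs, c("nct_id", "allocation")),
    interventions = read_table_or_empty(
      paths$interventions, c("nct_id", "intervention_type", "description")
    ),
    facilities = read_table_or_empty(
      paths$facilities, c("nct_id", "country")
    ),
    documents = read_table_or_empty(
      paths$documents, c("nct_id", "document_type")
    )
  )
  by_id <- function(tab) {
    if (is.null(tab)) list() else split(tab, factor(tab$nct_id))
  }
  idx <- lapply(child, by_id)

  blank <- function(x) ifelse(is.na(x), "", x)
  rows <- vector("list", nrow(studies))
  for (i in seq_len(nrow(studies))) {
    id <- studies$nct_id[i]
    elig <- idx$eligibilities[[id]]
    outs <- idx$design_outcomes[[id]]
    grp <- idx$design_groups[[id]]
    ints <- idx$interventions[[id]]
    des <- idx$designs[[id]]
    outcome_texts <- function(type, col) {
      if (is.null(outs)) {
        return("")
      }
      sel <- tolower(blank(outs$outcome_type)) == type
      join_texts(blank(outs[[col]])[sel], sep)
    }
    texts <- list(
      OfficialTitle = blank(studies$official_title[i]),
      BriefTitle = blank(studies$brief_title[i]),
      BriefSummary = if (is.null(idx$brief_summaries[[id]])) "" else {
        join_texts(blank(idx$brief_summaries[[id]]$description), sep)
      },
      DetailedDescription = if (is.null(idx$detailed_descriptions[[id]])) {
        ""
      } else {
        join_texts(blank(idx$detailed_descriptions[[id]]$description), sep)
      },
      Conditions = if (is.null(idx$conditions[[id]])) "" else {
        join_texts(blank(idx$conditions[[id]]$name), sep)
      },
      PrimaryOutcomeTitle = outcome_texts("primary", "measure"),
      PrimaryOutcomeDescription = outcome_texts("primary", "description"),
      SecondaryOutcomeTitle = outcome_texts("secondary", "measure"),
      SecondaryOutcomeDescription = outcome_texts("secondary", "description"),
      OtherOutcomeTitle = outcome_texts("other", "measure"),
      OtherOutcomeDescription = outcome_texts("other", "description"),
      EligibilityPopulation = if (is.null(elig)) "" else {
        join_texts(blank(elig$population), sep)
      },
      EligibilityGenderDescription = if (is.null(elig)) "" else {
        join_texts(blank(elig$gender_description), sep)
      },
      EligibilityCriteria = if (is.null(elig)) "" else {
        join_texts(blank(elig$criteria), sep)
      },
      GroupTitle = if (is.null(grp)) "" else {
        join_texts(blank(grp$title), sep)
      },
      GroupDescription = if (is.null(grp)) "" else {
        join_texts(blank(grp$description), sep)
      },
      InterventionDescription = if (is.null(ints)) "" else {
        join_texts(blank(ints$description), sep)
      }
    )
    groups <- if (is.null(grp)) empty_groups() else tibble::tibble(
      group_type = map_enum(grp$group_type, .group_type_map),
      title = blank(grp$title),
      description = blank(grp$description)
    )
    interventions <- if (is.null(ints)) empty_interventions() else {
      tibble::tibble(
        intervention_type = map_enum(
          ints$intervention_type, .intervention_type_map, missing = "Other"
        ),
        description = blank(ints$description)
      )
    }
    patient_registry <- tolower(blank(studies$patient_registry[i])) %in%
      c("t", "true", "yes", "1")
    study_type <- map_enum(studies$study_type[i], .study_type_map)
    if (study_type == "Observational" && patient_registry) {
      study_type <- "PatientRegistry"
    }
    enrollment <- suppressWarnings(as.integer(studies$enrollment[i]))
    enrollment_type <- map_enum(
      studies$enrollment_type[i],
      c("Anticipated" = "Anticipated", "Actual" = "Actual")
    )
    if (is.na(enrollment)) enrollment_type <- "Missing"
    rows[[i]] <- trial_registration(
      nct_id = id,
      study_type = study_type,
      allocation = if (is.null(des)) "Missing" else {
        map_enum(des$allocation[1], .allocation_map)
      },
      phase = {
        ph <- map_enum(studies$phase[i], .phase_map, missing = NA_character_)
        ph
      },
      sexes_eligible = if (is.null(elig)) "Missing" else {
        parse_sexes_eligible(elig$gender[1])
      },
      status = blank(studies$overall_status[i]),
      start_date = parse_registry_date(studies$start_date[i]),
      submitted_date = submitted[i],
      enrollment_count = enrollment,
      enrollment_type = enrollment_type,
      texts = texts,
      groups = groups,
      interventions = interventions,
      facility_countries = if (is.null(idx$facilities[[id]])) {
        character()
      } else {
        fc <- blank(idx$facilities[[id]]$country)
        fc[nzchar(fc)]
      },
      has_document = !is.null(idx$documents[[id]])
    )
  }
  out <- as_registry(dplyr::bind_rows(rows))
  attr(out, "load_report") <- list(
    n_loaded = nrow(out), n_duplicate_ids = n_dup,
    duplicate_ids = dup_ids, n_skipped_rows = length(skipped),
    skipped_ids = skipped
  )
  out
}

#' Write / read normalized registrations (JSON lines)
#'
#' One JSON object per registration per line; the pipeline's normalized
#' interchange format.  `read_registrations()` is the `"jsonl"` dialect of
#' [load_registry_dump()].
#'
#' @param registry A registry tibble.
#' @param path File path.
#' @return `write_registrations()` returns `path` invisibly;
#'   `read_registrations()` returns a registry tibble.
#' @export
write_registrations <- function(registry, path) {
  lines <- vapply(seq_len(nrow(registry)), function(i) {
    rec <- list(
      nct_id = registry$nct_id[i],
      study_type = registry$study_type[i],
      allocation = registry$allocation[i],
      phase = registry$phase[i],
      sexes_eligible = registry$sexes_eligible[i],
      status = registry$status[i],
      start_date = if (is.na(registry$start_date[i])) NULL else {
        format(registry$start_date[i], "%Y-%m-%d")
      },
      submitted_date = format(registry$submitted_date[i], "%Y-%m-%d"),
      enrollment_count = if (is.na(registry$enrollment_count[i])) NULL else {
        registry$enrollment_count[i]
      },
      enrollment_type = registry$enrollment_type[i],
      texts = registry$texts[[i]],
      groups = registry$groups[[i]],
      interventions = registry$interventions[[i]],
      facility_countries = as.list(registry$facility_countries[[i]]),
      has_document = registry$has_document[i]
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_registrations
#' @export
read_registrations <- function(path) {
  if (!file.exists(path)) {
    stop("registrations file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    groups <- if (length(rec$groups) == 0) empty_groups() else {
      tibble::as_tibble(rec$groups)
    }
    interventions <- if (length(rec$interventions) == 0) {
      empty_interventions()
    } else {
      tibble::as_tibble(rec$interventions)
    }
    trial_registration(
      nct_id = rec$nct_id,
      study_type = rec$study_type,
      allocation = rec$allocation,
      phase = if (is.null(rec$phase)) NA_character_ else rec$phase,
      sexes_eligible = rec$sexes_eligible,
      status = rec$status,
      start_date = if (is.null(rec$start_date)) NA else rec$start_date,
      submitted_date = rec$submitted_date,
      enrollment_count = if (is.null(rec$enrollment_count)) {
        NA_integer_
      } else {
        rec$enrollment_count
      },
      enrollment_type = rec$enrollment_type,
      texts = rec$texts,
      groups = groups,
      interventions = interventions,
      facility_countries = unlist(rec$facility_countries) %||% character(),
      has_document = isTRUE(rec$has_document)
    )
  })
  # keep-first on duplicate ids, mirroring the delimited dialect
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out$nct_id)
  res <- as_registry(out[!dup, , drop = FALSE])
  attr(res, "load_report") <- list(
    n_loaded = nrow(res), n_duplicate_ids = sum(dup),
    duplicate_ids = unique(out$nct_id[dup]),
    n_skipped_rows = 0L, skipped_ids = character()
  )
  res
}

#' Write a registry back out as AACT-dialect CSV tables
#'
#' Inverse of the `"aact"` dialect of [load_registry_dump()]: reconstructs
#' the child tables by splitting newline-joined field texts back into rows.
#' A load/write/reload round trip is field-identical.
#'
#' @param registry A registry tibble.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dump <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(registry)
  lines_of <- function(field, i) {
    v <- registry$texts[[i]][[field]]
    if (is.null(v) || is.na(v) || !nzchar(v)) character() else {
      strsplit(v, "\n", fixed = TRUE)[[1]]
    }
  }
  studies <- tibble::tibble(
    nct_id = registry$nct_id,
    study_type = unmap_enum(
      ifelse(registry$study_type == "PatientRegistry",
        "PatientRegistry", registry$study_type
      ),
      .study_type_map
    ),
    patient_registry = ifelse(registry$study_type == "PatientRegistry",
      "true", "false"
    ),
    brief_title = vapply(seq_len(n), function(i) {
      registry$texts[[i]]$BriefTitle
    }, character(1)),
    official_title = vapply(seq_len(n), function(i) {
      registry$texts[[i]]$OfficialTitle
    }, character(1)),
    overall_status = registry$status,
    phase = ifelse(is.na(registry$phase), "",
      unmap_enum(registry$phase, .phase_map)
    ),
    enrollment = ifelse(is.na(registry$enrollment_count), "",
      as.character(registry$enrollment_count)
    ),
    enrollment_type = ifelse(registry$enrollment_type == "Missing", "",
      registry$enrollment_type
    ),
    start_date = ifelse(is.na(registry$start_date), "",
      format(registry$start_date, "%Y-%m-%d")
    ),
    study_first_submitted_date = format(registry$submitted_date, "%Y-%m-%d")
  )
  readr::write_csv(studies, file.path(dir, "studies.csv"), progress = FALSE)

  single_child <- function(field, col) {
    rows <- lapply(seq_len(n), function(i) {
      ln <- lines_of(field, i)
      if (length(ln) == 0) NULL else {
        df <- tibble::tibble(nct_id = registry$nct_id[i], value = ln)
        names(df)[2] <- col
        df
      }
    })
    dplyr::bind_rows(rows)
  }
  readr::write_csv(
    single_child("BriefSummary", "description"),
    file.path(dir, "brief_summaries.csv"), progress = FALSE
  )
  readr::write_csv(
    single_child("DetailedDescription", "description"),
    file.path(dir, "detailed_descriptions.csv"), progress = FALSE
  )
  readr::write_csv(
    single_child("Conditions", "name"),
    file.path(dir, "conditions.csv"), progress = FALSE
  )

  outcome_rows <- lapply(seq_len(n), function(i) {
    per_type <- function(type, tfield, dfield) {
      titles <- lines_of(tfield, i)
      descs <- lines_of(dfield, i)
      k <- max(length(titles), length(descs))
      if (k == 0) {
        return(NULL)
      }
      length(titles) <- k
      length(descs) <- k
      tibble::tibble(
        nct_id = registry$nct_id[i], outcome_type = type,
        measure = ifelse(is.na(titles), "", titles),
        description = ifelse(is.na(descs), "", descs)
      )
    }
    dplyr::bind_rows(
      per_type("primary", "PrimaryOutcomeTitle", "PrimaryOutcomeDescription"),
      per_type(
        "secondary", "SecondaryOutcomeTitle", "SecondaryOutcomeDescription"
      ),
      per_type("other", "OtherOutcomeTitle", "OtherOutcomeDescription")
    )
  })
  readr::write_csv(dplyr::bind_rows(outcome_rows),
    file.path(dir, "design_outcomes.csv"),
    progress = FALSE
  )

  elig <- tibble::tibble(
    nct_id = registry$nct_id,
    gender = ifelse(registry$sexes_eligible == "Missing", "",
      registry$sexes_eligible
    ),
    population = vapply(seq_len(n), function(i) {
      registry$texts[[i]]$EligibilityPopulation
    }, character(1)),
    gender_description = vapply(seq_len(n), function(i) {
      registry$texts[[i]]$EligibilityGenderDescription
    }, character(1)),
    criteria = vapply(seq_len(n), function(i) {
      registry$texts[[i]]$EligibilityCriteria
    }, character(1))
  )
  readr::write_csv(elig, file.path(dir, "eligibilities.csv"),
    progress = FALSE
  )

  grp_rows <- lapply(seq_len(n), function(i) {
    g <- registry$groups[[i]]
    if (nrow(g) == 0) {
      return(NULL)
    }
    tibble::tibble(
      nct_id = registry$nct_id[i],
      group_type = unmap_enum(g$group_type, .group_type_map),
      title = g$title, description = g$description
    )
  })
  readr::write_csv(dplyr::bind_rows(grp_rows),
    file.path(dir, "design_groups.csv"),
    progress = FALSE
  )

  designs <- tibble::tibble(
    nct_id = registry$nct_id,
    allocation = unmap_enum(registry$allocation, .allocation_map)
  )
  designs <- designs[registry$allocation != "Missing", , drop = FALSE]
  readr::write_csv(designs, file.path(dir, "designs.csv"), progress = FALSE)

  int_rows <- lapply(seq_len(n), function(i) {
    v <- registry$interventions[[i]]
    if (nrow(v) == 0) {
      return(NULL)
    }
    tibble::tibble(
      nct_id = registry$nct_id[i],
      intervention_type = unmap_enum(
        v$intervention_type, .intervention_type_map
      ),
      description = v$description
    )
  })
  readr::write_csv(dplyr::bind_rows(int_rows),
    file.path(dir, "interventions.csv"),
    progress = FALSE
  )

  fac_rows <- lapply(seq_len(n), function(i) {
    fc <- registry$facility_countries[[i]]
    if (length(fc) == 0) {
      return(NULL)
    }
    tibble::tibble(nct_id = registry$nct_id[i], country = fc)
  })
  readr::write_csv(dplyr::bind_rows(fac_rows),
    file.path(dir, "facilities.csv"),
    progress = FALSE
  )

  doc_rows <- tibble::tibble(
    nct_id = registry$nct_id[registry$has_document],
    document_type = "Study Protocol and Statistical Analysis Plan"
  )
  readr::write_csv(doc_rows, file.path(dir, "documents.csv"),
    progress = FALSE
  )
  invisible(dir)
}

#' Total word count of the study description fields
#'
#' Counts whitespace-delimited tokens in `BriefSummary` plus
#' `DetailedDescription`; empty fields contribute zero.
#'
#' @param registry A registry tibble (any number of rows).
#' @return Integer vector, one count per registration.
#' @export
word_count <- function(registry) {
  vapply(registry$texts, function(tx) {
    n_tokens <- function(x) {
      if (is.null(x) || is.na(x) || !nzchar(x)) {
        return(0L)
      }
      length(strsplit(trimws(x), "[[:space:]]+")[[1]])
    }
    n_tokens(tx$BriefSummary) + n_tokens(tx$DetailedDescription)
  }, integer(1))
}
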
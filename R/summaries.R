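.category_levels <- c(
  "FemaleOnly", "MaleOnly", "Analysis", "OtherMention",
  "RecruitmentOnly", "NoMention"
)
.label_levels <- c(
  "PharmaRCT", "OtherIntervention", "Observational", "PatientRegistry",
  "ExpandedAccess"
)

#' Assemble the per-study analysis frame
#'
#' Joins the cohort registry, category assignments and study-class labels
#' into one flat tibble with the derived variables the summary tables use:
#' `phase_bucket` (registry phase, `Phase1_2`/`Phase2_3` retained,
#' `NoPhase` when absent or N/A), `geography` (`US` when any facility
#' country is the United States, `NonUS` otherwise, `NoFacilityData` when
#' none recorded), `month` (`YYYY-MM` of first submission) and
#' `word_count`.
#'
#' @param cohort Cohort registry tibble.
#' @param assignments Output of [assign_category()].
#' @param classes Output of [classify_study()].
#' @return A tibble, one row per study.
#' @export
analysis_frame <- function(cohort, assignments, classes) {
  stopifnot(setequal(cohort$nct_id, assignments$nct_id))
  stopifnot(setequal(cohort$nct_id, classes$nct_id))
  base <- tibble::tibble(
    nct_id = cohort$nct_id,
    sexes_eligible = cohort$sexes_eligible,
    enrollment_count = cohort$enrollment_count,
    enrollment_type = cohort$enrollment_type,
    phase_bucket = ifelse(
      is.na(cohort$phase) | cohort$phase == "NA", "NoPhase", cohort$phase
    ),
    geography = vapply(cohort$facility_countries, function(fc) {
      if (length(fc) == 0) {
        "NoFacilityData"
      } else if (any(fc == "United States")) {
        "US"
      } else {
        "NonUS"
      }
    }, character(1)),
    month = format(cohort$submitted_date, "%Y-%m"),
    has_document = cohort$has_document,
    word_count = word_count(cohort)
  )
  base |>
    dplyr::left_join(
      assignments[, c("nct_id", "category", "subtag", "needs_review")],
      by = "nct_id"
    ) |>
    dplyr::left_join(
      classes[, c("nct_id", "label", "rct_rule")],
      by = "nct_id"
    )
}

summary_variable_levels <- function(df, var) {
  switch(var,
    category = .category_levels,
    label = .label_levels,
    phase_bucket = c(
      "EarlyPhase1", "Phase1", "Phase1_2", "Phase2", "Phase2_3", "Phase3",
      "Phase4", "NoPhase"
    ),
    geography = c("US", "NonUS", "NoFacilityData"),
    enrollment_type = c("Anticipated", "Actual", "Missing"),
    month = sort(unique(df$month)),
    stop("unknown summary variable: ", var, call. = FALSE)
  )
}

#' Cross-tabulate two study variables
#'
#' Counts studies per (row, col) cell over the supported variables
#' (`category`, `label`, `phase_bucket`, `geography`, `enrollment_type`,
#' `month`); percentages are computed per column (column sums as
#' denominators) with half-up rounding via [percentage()].  Column `col =
#' "all"` gives a one-column tally with the cohort size as denominator.
#'
#' @param df Analysis frame from [analysis_frame()].
#' @param row,col Variable ids; `col` may be `"all"`.
#' @param decimals Decimals for percentages (default 1).
#' @return A `summary_table` object: list with `name`, `row_labels`,
#'   `col_labels`, `counts`, `percentages`, `denominator`.
#' @export
crosstab <- function(df, row, col = "all", decimals = 1) {
  row_levels <- summary_variable_levels(df, row)
  rv <- factor(df[[row]], levels = row_levels)
  cv <- if (identical(col, "all")) {
    factor(rep("all", nrow(df)), levels = "all")
  } else {
    factor(df[[col]], levels = summary_variable_levels(df, col))
  }
  counts <- unclass(table(rv, cv))
  dimnames(counts) <- list(row_levels, levels(cv))
  denom <- colSums(counts)
  pct <- counts
  for (j in seq_len(ncol(counts))) {
    pct[, j] <- if (denom[j] > 0) {
      percentage(counts[, j], denom[j], decimals)
    } else {
      0
    }
  }
  structure(
    list(
      name = paste(row, "by", col),
      row_labels = row_levels, col_labels = colnames(counts),
      counts = counts, percentages = pct, denominator = denom
    ),
    class = "summary_table"
  )
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Summary table:", x$name, "\n")
  disp <- matrix(
    paste0(x$counts, " (", format(x$percentages, trim = TRUE), "%)"),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts)
  )
  print(disp, quote = FALSE)
  cat("Column denominators:", paste(x$denominator, collapse = ", "), "\n")
  invisible(x)
}

#' Audit a summary table's percentages
#'
#' Recomputes every percentage from its own printed count and denominator
#' and checks exact agreement (self-consistency of emitted tables).
#'
#' @param x A `summary_table`.
#' @param decimals Decimals used when the table was built.
#' @return `TRUE` invisibly; errors on any mismatch.
#' @export
audit_summary_table <- function(x, decimals = 1) {
  for (j in seq_len(ncol(x$counts))) {
    if (x$denominator[j] == 0) next
    expect <- percentage(x$counts[, j], x$denominator[j], decimals)
    if (!isTRUE(all.equal(unname(expect), unname(x$percentages[, j])))) {
      stop("percentage audit failed for table ", x$name, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Median enrollment over a study selection
#'
#' Missing enrollment counts are excluded; an even-sized selection takes
#' the mean of the two central values.  Errors when the selection is empty
#' after missing-removal.
#'
#' @param df Analysis frame.
#' @param ... Filter expressions over `df` columns (e.g.
#'   `category == "Analysis"`).
#' @return The median enrollment count.
#' @export
enrollment_median <- function(df, ...) {
  sel <- dplyr::filter(df, ...)
  x <- sel$enrollment_count[!is.na(sel$enrollment_count)]
  if (length(x) == 0) {
    stop("empty selection: no enrollment counts available", call. = FALSE)
  }
  stats::median(x)
}

#' Monthly registration series
#'
#' Counts studies per calendar month of first submission (the submission
#' date itself, not the effective windowing date), zero-filled across the
#' full span, with per-category counts alongside.
#'
#' @param df Analysis frame.
#' @return Tibble with `month`, `n`, and one column per attention
#'   category.
#' @export
monthly_series <- function(df) {
  months <- sort(unique(df$month))
  span <- seq(
    as.Date(paste0(min(months), "-01")),
    as.Date(paste0(max(months), "-01")),
    by = "month"
  )
  span <- format(span, "%Y-%m")
  out <- tibble::tibble(month = span)
  out$n <- vapply(span, function(m) sum(df$month == m), integer(1),
    USE.NAMES = FALSE
  )
  for (cat in .category_levels) {
    out[[cat]] <- vapply(span, function(m) {
      sum(df$month == m & df$category == cat)
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Median description word counts by study class
#'
#' @param df Analysis frame.
#' @return Tibble with `label`, `n`, `median_word_count`.
#' @export
wordcount_summary <- function(df) {
  df |>
    dplyr::group_by(label = factor(.data$label, levels = .label_levels)) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_word_count = stats::median(.data$word_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = as.character(.data$label))
}

#' Write the standard summary tables
#'
#' Emits `categories.csv`, `category_by_type.csv`, `monthly.csv`,
#' `enrollment_medians.csv`, `phases.csv`, `geography.csv` and
#' `wordcounts.csv` under `out_dir`, each audited for percentage
#' self-consistency before writing.
#'
#' @param df Analysis frame.
#' @param out_dir Output directory.
#' @return Named list of written file paths, invisibly.
#' @export
write_summary_tables <- function(df, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab_to_df <- function(tab) {
    audit_summary_table(tab)
    long <- expand.grid(
      row = tab$row_labels, col = tab$col_labels,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    long$count <- as.vector(tab$counts)
    long$percent <- as.vector(tab$percentages)
    long$denominator <- tab$denominator[long$col]
    tibble::as_tibble(long)
  }
  paths <- list()
  emit <- function(name, data) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(data, p, progress = FALSE)
    paths[[name]] <<- p
  }
  emit("categories", tab_to_df(crosstab(df, "category")))
  emit("category_by_type", tab_to_df(crosstab(df, "category", "label")))
  emit("monthly", monthly_series(df))
  med <- dplyr::bind_rows(
    lapply(.category_levels, function(cat) {
      sel <- df[df$category == cat & !is.na(df$enrollment_count), ]
      tibble::tibble(
        group = cat, n = nrow(sel),
        median_enrollment = if (nrow(sel) == 0) NA_real_ else {
          stats::median(sel$enrollment_count)
        }
      )
    }),
    lapply(.label_levels, function(lb) {
      sel <- df[df$label == lb & !is.na(df$enrollment_count), ]
      tibble::tibble(
        group = lb, n = nrow(sel),
        median_enrollment = if (nrow(sel) == 0) NA_real_ else {
          stats::median(sel$enrollment_count)
        }
      )
    })
  )
  emit("enrollment_medians", med)
  emit("phases", tab_to_df(crosstab(df, "phase_bucket", "label")))
  emit("geography", tab_to_df(crosstab(df, "category", "geography")))
  emit("wordcounts", wordcount_summary(df))
  invisible(paths)
}
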
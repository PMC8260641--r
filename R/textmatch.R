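#' Expand a term into its matchable variants
#'
#' Non-wildcard terms with `expand_plural` gain their regular English
#' plural: `+es` after s/x/z/ch/sh, `y -> ies` after a consonant, else
#' `+s`; the irregular pairs man/men and woman/women are included
#' explicitly.  Wildcard terms (trailing `*`) return their stem unchanged;
#' the wildcard is applied at pattern-compilation time.
#'
#' @param surface A single term surface (may end in `*`).
#' @param expand_plural Generate plural variants?
#' @return Character vector of surface variants (wildcard stems keep the
#'   trailing `*`).
#' @export
#' @examples
#' expand_terms("woman", expand_plural = TRUE) # "woman" "women"
#' expand_terms("sex", expand_plural = TRUE)   # "sex" "sexes"
expand_terms <- function(surface, expand_plural = FALSE) {
  stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
  if (grepl("\\*$", surface) || !expand_plural) {
    return(surface)
  }
  irregular <- c(man = "men", woman = "women")
  lower <- tolower(surface)
  plural <- if (lower %in% names(irregular)) {
    unname(irregular[[lower]])
  } else if (grepl("(s|x|z|ch|sh)$", lower)) {
    paste0(surface, "es")
  } else if (grepl("[^aeiou]y$", lower)) {
    sub("y$", "ies", surface)
  } else {
    paste0(surface, "s")
  }
  unique(c(surface, plural))
}

# Normalize typographic hyphens/dashes to ASCII "-" (1:1, offsets preserved).
normalize_hyphens <- function(x) {
  # hyphen, non-breaking hyphen, figure dash, en dash, em dash, minus sign
  pat <- paste0(
    "[", intToUtf8(c(0x2010, 0x2011, 0x2012, 0x2013, 0x2014, 0x2212)), "]"
  )
  gsub(pat, "-", x, perl = TRUE)
}

# Compile one variant surface into a PCRE fragment: escape regex
# metacharacters, then let every internal hyphen/space run match zero or
# one of {hyphen, space} in the text.
variant_pattern <- function(variant) {
  stem <- sub("\\*$", "", variant)
  parts <- strsplit(stem, "[ -]+")[[1]]
  parts <- vapply(parts, function(p) {
    gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", p, perl = TRUE)
  }, character(1))
  paste(parts, collapse = "[ -]?")
}

# Full anchored pattern for one term-spec row.  Non-wildcard matches are
# rejected when a letter is directly adjacent on either side; wildcard
# matches apply the left-neighbour rule only and consume trailing letters.
term_pattern <- function(surface, wildcard) {
  variants <- if (wildcard) surface else {
    # caller passes already-expanded variants as a character vector
    surface
  }
  body <- paste(vapply(variants, variant_pattern, character(1)),
    collapse = "|"
  )
  if (wildcard) {
    paste0("(?<![[:alpha:]])(?:", body, ")[[:alpha:]]*")
  } else {
    paste0("(?<![[:alpha:]])(?:", body, ")(?![[:alpha:]])")
  }
}

# Compile a term-spec tibble into a list of ready-to-run patterns.
compile_terms <- function(terms) {
  lapply(seq_len(nrow(terms)), function(i) {
    surface <- terms$surface[i]
    variants <- expand_terms(surface, terms$expand_plural[i])
    # longest-first keeps alternation behaviour predictable
    variants <- variants[order(-nchar(variants))]
    list(
      term = surface,
      pattern = term_pattern(variants, terms$wildcard[i]),
      ignore_case = !terms$case_sensitive[i]
    )
  })
}

empty_matches <- function() {
  tibble::tibble(
    term = character(), field = character(),
    start = integer(), end = integer(), surface_form = character()
  )
}

# Run one compiled pattern over a character vector of texts; returns a
# data.frame of (idx, start, end) with 0-based half-open spans.
scan_texts <- function(texts, compiled) {
  hits <- gregexpr(compiled$pattern, texts,
    perl = TRUE, ignore.case = compiled$ignore_case
  )
  out <- vector("list", length(texts))
  for (i in seq_along(hits)) {
    m <- hits[[i]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    out[[i]] <- data.frame(
      idx = i, start = starts,
      end = starts + attr(m, "match.length")
    )
  }
  do.call(rbind, out)
}

#' Find all term matches in a registration's text fields
#'
#' Matching is case-insensitive (unless a term is flagged case-sensitive),
#' blind to internal hyphen/space use within multi-token terms, and
#' token-bounded: a non-wildcard match is rejected when a letter directly
#' precedes or follows it (digits and punctuation are permitted
#' neighbours), so "COVID" hits "COVID-19" and "COVID19" but "male" never
#' hits "female".  Wildcard terms apply the left-neighbour rule only and
#' consume any trailing letters.  Typographic hyphens are normalized to
#' ASCII before matching.  Matches are reported in catalogue field order,
#' then by offset.
#'
#' @param texts Named list or character vector of field texts (names from
#'   [field_catalogue()]).
#' @param scope Character vector of field names to search; must be a subset
#'   of the catalogue.
#' @param terms A term-spec tibble (see [term_spec()]).
#' @return A tibble with columns `term`, `field`, `start`, `end` (0-based,
#'   half-open character offsets) and `surface_form` (the matched
#'   substring, so `substr(text, start + 1, end)` equals `surface_form`).
#' @export
find_matches <- function(texts, scope = names(texts), terms) {
  bad <- setdiff(scope, field_catalogue())
  if (length(bad) > 0) {
    stop("unknown field(s) in scope: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  scope <- intersect(field_catalogue(), scope)
  compiled <- compile_terms(terms)
  rows <- list()
  for (field in scope) {
    txt <- texts[[field]]
    if (is.null(txt) || length(txt) == 0 || is.na(txt) || !nzchar(txt)) next
    ntxt <- normalize_hyphens(txt)
    for (cp in compiled) {
      hit <- scan_texts(ntxt, cp)
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = cp$term, field = field,
        start = hit$start, end = hit$end,
        surface_form = substring(txt, hit$start + 1L, hit$end)
      )
    }
  }
  if (length(rows) == 0) {
    return(empty_matches())
  }
  out <- dplyr::bind_rows(rows)
  out[order(match(out$field, field_catalogue()), out$start), , drop = FALSE]
}

# Vectorized scan over a whole registry: one gregexpr call per
# (field, term) pair across all records.  Returns nct_id-keyed matches.
registry_matches <- function(registry, scope, terms) {
  compiled <- compile_terms(terms)
  n <- nrow(registry)
  if (n == 0) {
    return(tibble::tibble(nct_id = character(), term = character(),
      field = character(), start = integer(), end = integer(),
      surface_form = character()
    ))
  }
  scope <- intersect(field_catalogue(), scope)
  rows <- list()
  for (field in scope) {
    txts <- vapply(registry$texts, function(tx) {
      v <- tx[[field]]
      if (is.null(v) || length(v) == 0 || is.na(v)) "" else v
    }, character(1))
    ntxts <- normalize_hyphens(txts)
    for (cp in compiled) {
      hit <- scan_texts(ntxts, cp)
      if (is.null(hit)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        nct_id = registry$nct_id[hit$idx],
        term = cp$term, field = field,
        start = hit$start, end = hit$end,
        surface_form = substring(txts[hit$idx], hit$start + 1L, hit$end)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(nct_id = character(), term = character(),
      field = character(), start = integer(), end = integer(),
      surface_form = character()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out[order(match(out$nct_id, registry$nct_id),
    match(out$field, field_catalogue()), out$start
  ), , drop = FALSE]
}
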
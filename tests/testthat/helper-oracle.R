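# Brute-force term-matching oracle: implements the matching rules
# directly over all substrings, independently of the package's regex
# engine.  Variants are explicit surface strings (plural forms spelled
# out); separator positions in a variant may realize as "", " " or "-".

oracle_expansions <- function(variant) {
  parts <- strsplit(variant, "[ -]+")[[1]]
  if (length(parts) == 1) {
    return(variant)
  }
  seps <- c("", " ", "-")
  combos <- expand.grid(
    rep(list(seps), length(parts) - 1),
    stringsAsFactors = FALSE
  )
  apply(combos, 1, function(s) {
    out <- parts[1]
    for (k in seq_along(s)) out <- paste0(out, s[[k]], parts[k + 1])
    out
  })
}

oracle_is_letter <- function(ch) nzchar(ch) && grepl("^[[:alpha:]]$", ch)

# returns data.frame(start, end) of 0-based half-open spans
oracle_matches <- function(text, variants, wildcard = FALSE) {
  lower <- tolower(text)
  n <- nchar(text)
  spans <- list()
  push <- function(s0, e0) {
    spans[[length(spans) + 1L]] <<- c(s0, e0)
  }
  if (!wildcard) {
    for (v in variants) {
      for (e in unique(tolower(oracle_expansions(v)))) {
        le <- nchar(e)
        if (le == 0 || le > n) next
        for (s in seq_len(n - le + 1)) {
          if (substr(lower, s, s + le - 1) != e) next
          before <- if (s > 1) substr(text, s - 1, s - 1) else ""
          after <- if (s + le <= n) substr(text, s + le, s + le) else ""
          if (!oracle_is_letter(before) && !oracle_is_letter(after)) {
            push(s - 1L, s - 1L + le)
          }
        }
      }
    }
  } else {
    for (v in variants) {
      stem <- tolower(sub("\\*$", "", v))
      ls <- nchar(stem)
      if (ls > n) next
      for (s in seq_len(n - ls + 1)) {
        if (substr(lower, s, s + ls - 1) != stem) next
        before <- if (s > 1) substr(text, s - 1, s - 1) else ""
        if (oracle_is_letter(before)) next
        e <- s + ls - 1
        while (e + 1 <= n &&
          oracle_is_letter(substr(text, e + 1, e + 1))) {
          e <- e + 1
        }
        push(s - 1L, e)
      }
    }
  }
  if (length(spans) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- unique(do.call(rbind, spans))
  out <- data.frame(start = out[, 1], end = out[, 2])
  out[order(out$start, out$end), , drop = FALSE]
}

sorted_spans <- function(df) {
  df <- df[order(df$start, df$end), c("start", "end"), drop = FALSE]
  rownames(df) <- NULL
  as.data.frame(df)
}
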
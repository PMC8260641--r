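---
title: "Screening registry dumps for sex and gender attention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening registry dumps for sex and gender attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcoder)
```

`trialcoder` screens clinical-trial registry dumps for disease relevance
and for the attention each registration pays to participant sex and
gender. This vignette explains the procedure, the choices behind it, and
what its tests do and do not demonstrate.

## The registration model

A registration is one row of a tibble with structured design metadata
(study type, allocation, phase, sexes eligible, status, dates, enrollment)
and a fixed catalogue of seventeen free-text fields
(`field_catalogue()`): titles, brief summary, detailed description,
conditions, primary/secondary/other outcome titles and descriptions,
three eligibility fields, group titles/descriptions and intervention
descriptions. Two dump dialects are read: AACT-style CSV tables (the
public relational export of ClinicalTrials.gov) and a JSON-lines format
that is also the pipeline's normalized output. Multi-row child tables
(conditions, outcomes, groups, interventions, facilities) are joined into
one text per field with a newline separator. The separator choice is this
package's own: it preserves term adjacency within a row while keeping
rows apart, and because no search pattern can span a newline, joining can
never manufacture a match across rows. For the same reason outcome rows
need no separate per-row representation — the field-level text is
sufficient for every downstream rule. Month-precision dates (AACT
contains them) resolve to the first of the month.

## Term matching

The matching engine (`find_matches()`) is deliberately simple and fully
inspectable: every decision downstream is backed by `(term, field, span)`
evidence records.

* **Case** is folded; typographic hyphens (en dash, non-breaking hyphen,
  minus) are normalized to ASCII `-` before matching, since registry free
  text contains them.
* **Separators.** Each internal hyphen/space in a multi-token term matches
  zero or one of hyphen or space in the text, so `SARS-CoV-2`,
  `SARS CoV 2` and `SARSCoV2` are one family. We collapse separators at
  the term's own separator positions only. A stronger notion — full
  separator-blindness at every character position — would be needed to
  make matching invariant under hyphen edits of *arbitrary* text, but it
  is incompatible with the boundary rule below (deleting the hyphen in a
  pathological string like `fe-male` must not create a `male` hit).
  The implemented rule keeps both behaviours real data requires:
  separator variants of every term in the shipped lists are all found,
  and `female` never yields `male` matches.
* **Boundaries.** A non-wildcard match is rejected when a letter directly
  precedes or follows it; digits and punctuation are permitted
  neighbours. This single rule simultaneously lets `COVID` hit
  `COVID-19`/`COVID19` and blocks `male` inside `female`. Wildcard terms
  (trailing `*`) apply the left-neighbour rule only and consume trailing
  letters.
* **Plurals.** Noun terms expand to regular English plurals (`+es` after
  s/x/z/ch/sh, consonant-`y` to `ies`, else `+s`) plus the irregular
  pairs man/men and woman/women. This is a morphological approximation,
  not lemmatization; it is exactly what a registry keyword search needs
  and nothing more.

The test suite checks the engine against an independent brute-force
oracle that scans all substrings and applies these rules directly, on
randomized texts seeded with term variants.

## Cohort selection

The disease scope is eleven fields (titles, brief summary, detailed
description, conditions, and all outcome titles/descriptions). The
decision rule is hierarchical: titles-or-conditions, else primary
outcome, else at least two *distinct* other scoped fields. "Two other
fields" counts distinct field names, not occurrences — the intent is
corroboration across sections of the registration, which repeated
mentions inside one field do not provide. The date window
(2020-01-01 to 2021-01-26, both ends inclusive, start date falling back
to submission date) and the status exclusions (Withdrawn, No longer
available) are applied alongside; identifier duplicates keep the first
record, and same-title candidates are logged but retained because
identity beyond the registry identifier is not mechanically decidable.
Filtering and relevance commute, so their order is a non-issue (and is
tested).

## The attention hierarchy

Coding assigns exactly one category per study, in precedence order:

1. **FemaleOnly / MaleOnly** from the structured sexes-eligible field.
   Single-sex designs are set aside before any text is read.
2. **Analysis** — the registration states sex/gender will enter the
   analysis: stratification, subgroup analyses, covariates, interactions,
   adjustment, disaggregation, or an explicit sex-effect hypothesis.
3. **OtherMention** — sex-matched or representative sampling
   (`MatchedOrRepresentative`), or explicit intent to record or report
   participant sex/gender (`RecordOrReport`).
4. **RecruitmentOnly** — reached two ways: the *auto rule* (every
   sex/gender match sits in the eligibility inclusion-criteria field, so
   the registration can only be a recruitment candidate; subtag
   `AutoEligibilityOnly`), or an explicit recruiting statement covering
   both sexes.
5. **NoMention** — no match at all, or only spurious matches
   (`SpuriousMention`).

Two points deserve emphasis. First, the original coding task this
pipeline mechanizes was performed by human readers; the rule bank
(`default_rule_bank()`) encodes the *stated* criteria as transparent
regular-expression cues over a context window, plus a `needs_review`
channel for everything the rules cannot account for. It is an editable
tibble, not a claim to replicate judgment. Second, negative (spurious)
cues run before positive ones within a window: a sentence about
contraception requirements, pregnancy tests, donor or parental sex, or a
literature summary contributes no evidence, whatever else it contains. A
literature-context sentence that *also* carries analysis cues sets
`needs_review` — that is precisely the case a human should adjudicate.

The **context window** is the sentence containing the match (split on
`.!?` and newlines), clipped to ±120 characters when sentence bounds are
unclear — the coding criteria reason about statements, which are
sentence-level objects. Newlines delimit windows so that bullet-list
eligibility criteria are windowed per bullet.

Design decisions taken where the procedure was genuinely open:

* A recruiting statement must cover both sexes to count for
  `RecruitmentOnly`: either a neutral term (*sex*, *gender*, as in "adults
  of any sex") or both a female and a male term in recruitment-cued
  windows. A statement recruiting only one sex in an all-sexes study is
  ambiguous and goes to review instead.
* The auto rule is applied before context classification, which means an
  eligibility-only contraception clause is auto-coded `RecruitmentOnly`.
  This is a documented over-count of the recruitment category, accepted
  deliberately: it biases toward *over*-stating attention, never
  under-stating it.
* "Demographic variables will be analysed" without an explicit sex/gender
  term never yields `Analysis`; windows only exist around term matches,
  so such sentences are invisible by construction.
* Transgender mentions (`transg*`) feed the same categories rather than a
  separate one.
* A missing sexes-eligible value flags the record for review whatever its
  category.

## Pharmacological RCT identification

Registry pass-throughs (observational, patient registry, expanded
access) keep their type. An interventional study is a pharmacological RCT
when it is randomized, has a drug or biological intervention, and shows a
control arm by one of three rules in fixed precedence: comparator group
*type* (placebo/sham/no-intervention); `control*`/`placebo*` in group
titles or descriptions (catching controls mislabeled
experimental/active-comparator); or title/intervention-description text —
the all-caps token `RCT`, or `random*` together with `control*`/`placebo*`
anywhere in those fields (the phrase gives no proximity constraint, so
registration-level co-occurrence is used). `RCT` is matched
case-sensitively: lowercase `rct` substrings are essentially never the
acronym. Missing allocation counts as randomized only when the text
supplies `random*`/`RCT` evidence — positive evidence is required, never
assumed.

## Summaries and rounding

Percentages use exact half-up rounding implemented in integer arithmetic
(`percentage()`): base `round()` is round-half-to-even and fails to
reproduce printed count/percentage pairs at the boundary. Every emitted
table is audited for self-consistency — each percentage must equal
`percentage()` of its own printed count and denominator. Enrollment
medians exclude missing counts and use the mean-of-central-values
convention for even sizes. The monthly series bins by submission month
(not the effective windowing date) and zero-fills the span. The US
geography bucket means "at least one facility in the United States";
counts are always emitted with explicit denominators.

## The synthetic generator

`generator_spec()` defines the study conditions the package is exercised
under; `generate_dump()` realizes them deterministically from a seed, in
both dialects plus a ground-truth table. Defaults were fixed once, from
the statistical structure of pandemic-era registry screening: category
shares of 2.3/0.5/4.0/5.4/21.2/66.7 percent, class shares of
37.5/29.7/26.3/5.9/0.6 percent, 98% of in-cohort records carrying a
disease term in titles/conditions, log-normal enrollment (dispersion 1.0
on the log scale) with medians of 700 for analysis-planners and 176 for
no-mention studies (otherwise 287/400/160/100 by class), monthly
submission weights placing ~56% of in-window submissions in the first
half of 2020, a 5% adversarial-template rate, 1% duplicate rate, 2%
withdrawn rate, and 83% of recruitment-only records realized through the
eligibility-only auto rule.

Registrations are assembled compositionally — class-specific design
metadata, a disease-placement template, a category-realizing sentence,
filler sentences — so that hierarchy precedence is testable by
construction (an analysis sentence can be appended to any record and the
category must not drop). Ground truth is computed by the generator from
its own planted values using the documented rules (date arithmetic,
status sets, field placement), not by running the pipeline. Adversarial
templates plant the documented traps with hand-decided expected outcomes;
`adversarial_fixtures()` additionally ships a fixed, curated set of 42
registrations, one per edge case, used as a rule-coverage audit.

What the generator does *not* emulate: natural-language variety (its
sentences trigger rules by construction, real registrations paraphrase
endlessly), misspellings, non-English text, and free-form PDF
attachments. Passing recovery tests therefore demonstrates that the
pipeline implements its stated rules exactly — not that the rules capture
every phrasing a human coder would accept on real data. That residual is
what the `needs_review` channel and the editable rule bank are for.

## Problem sizes and numerical notes

The shipped tests run the curated fixture set plus synthetic dumps of 50
to 1000 registrations (the 1000-study run at seed 1 is the reference
condition for recovery measurement; `scripts/acceptance.R` repeats it at
a caller-chosen seed). With 1000 studies the whole pipeline completes in
well under a minute on one core. Determinism holds byte-for-byte across
reruns: the single seed drives all sampling, dates are formatted
ISO-only (no locale-dependent month names), and outputs are written in a
fixed order. Degenerate inputs are handled explicitly: empty child
tables yield empty strings, an all-one-category mix propagates cleanly,
empty cohorts produce all-zero tables, and an empty enrollment selection
is an error rather than an `NA`.

## Known limitations

* The rule bank approximates stated coding criteria; phrasings outside it
  land in `NoMention` with `needs_review` rather than being guessed.
* Duplicate detection beyond identifier equality only logs candidates.
* The text fallback for randomization can only *add* RCT labels; a
  comparator-typed group is never demoted by text.
* Absolute counts from any real snapshot depend on that snapshot's
  contents; the package reproduces rules and arithmetic, not a frozen
  database.
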
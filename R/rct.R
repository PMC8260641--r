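#' Classify cohort studies into study-type labels
#'
#' Observational, patient-registry and expanded-access records pass
#' through from the study type.  Interventional studies are labeled
#' `PharmaRCT` when they have randomized allocation (or `random*`/`RCT`
#' text evidence in the titles or intervention descriptions when
#' allocation is missing), at least one drug or biological/vaccine
#' intervention, and an identifiable control arm, found by rule
#' precedence:
#' 1. `GroupTypeControl` — a participant group typed placebo/sham
#'    comparator or no-intervention;
#' 2. `GroupTextControl` — `control*`/`placebo*` in a group title or
#'    description (catches controls mislabeled experimental/active
#'    comparator);
#' 3. `TitleOrInterventionText` — the all-caps token `RCT`, or `random*`
#'    together with `control*`/`placebo*`, anywhere in the study titles or
#'    intervention descriptions.
#' All remaining interventional studies are `OtherIntervention`.
#'
#' @param registry Cohort registry tibble.
#' @return Tibble with `nct_id`, `label`, `rct_rule` (`NA` unless
#'   `PharmaRCT`).
#' @export
classify_study <- function(registry) {
  terms <- rct_text_terms()
  group_scope <- c("GroupTitle", "GroupDescription")
  title_scope <- c("OfficialTitle", "BriefTitle", "InterventionDescription")
  matches <- registry_matches(
    registry, c(group_scope, title_scope), terms
  )
  per_id <- split(
    matches, factor(matches$nct_id, levels = unique(registry$nct_id))
  )
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    id <- registry$nct_id[i]
    st <- registry$study_type[i]
    if (st %in% c("Observational", "PatientRegistry", "ExpandedAccess")) {
      return(tibble::tibble(
        nct_id = id, label = st, rct_rule = NA_character_
      ))
    }
    label <- "OtherIntervention"
    rct_rule <- NA_character_
    ints <- registry$interventions[[i]]
    pharma <- any(ints$intervention_type %in% c("Drug", "Biological"))
    if (pharma) {
      m <- per_id[[id]] %||% empty_matches()
      in_title <- m[m$field %in% title_scope, , drop = FALSE]
      in_group <- m[m$field %in% group_scope, , drop = FALSE]
      random_text <- any(in_title$term == "random*") ||
        any(in_title$term == "RCT")
      randomized <- registry$allocation[i] == "Randomized" || random_text
      grp <- registry$groups[[i]]
      if (randomized) {
        if (any(grp$group_type %in%
          c("PlaceboComparator", "ShamComparator", "NoIntervention"))) {
          rct_rule <- "GroupTypeControl"
        } else if (any(in_group$term %in% c("control*", "placebo*"))) {
          rct_rule <- "GroupTextControl"
        } else if (any(in_title$term == "RCT") ||
          (any(in_title$term == "random*") &&
            any(in_title$term %in% c("control*", "placebo*")))) {
          rct_rule <- "TitleOrInterventionText"
        }
      }
      if (!is.na(rct_rule)) label <- "PharmaRCT"
    }
    tibble::tibble(nct_id = id, label = label, rct_rule = rct_rule)
  })
  dplyr::bind_rows(rows)
}
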
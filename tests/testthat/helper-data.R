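# Session-level cache so the larger synthetic runs are generated once and
# shared across test files.

.trialcoder_test_cache <- new.env(parent = emptyenv())

cached_gen <- function(n, seed) {
  key <- paste0("gen_", n, "_", seed)
  if (is.null(.trialcoder_test_cache[[key]])) {
    .trialcoder_test_cache[[key]] <- generate_registrations(
      generator_spec(n_studies = n, seed = seed)
    )
  }
  .trialcoder_test_cache[[key]]
}

# full in-memory pipeline run over a cached generation
cached_run <- function(n, seed) {
  key <- paste0("run_", n, "_", seed)
  if (is.null(.trialcoder_test_cache[[key]])) {
    gen <- cached_gen(n, seed)
    sel <- select_cohort(gen$registry)
    asg <- assign_category(sel$cohort)
    cls <- classify_study(sel$cohort)
    .trialcoder_test_cache[[key]] <- list(
      registry = gen$registry, truth = gen$truth, sel = sel,
      cohort = sel$cohort, assignments = asg, classes = cls,
      frame = analysis_frame(sel$cohort, asg, cls)
    )
  }
  .trialcoder_test_cache[[key]]
}

cached_fixture_run <- function() {
  key <- "fixture_run"
  if (is.null(.trialcoder_test_cache[[key]])) {
    fx <- adversarial_fixtures()
    sel <- select_cohort(fx$registry)
    asg <- assign_category(sel$cohort)
    cls <- classify_study(sel$cohort)
    .trialcoder_test_cache[[key]] <- list(
      registry = fx$registry, expected = fx$expected, sel = sel,
      cohort = sel$cohort, assignments = asg, classes = cls
    )
  }
  .trialcoder_test_cache[[key]]
}

# one-field registration shorthand
reg_with_text <- function(nct_id, field, text, ...) {
  texts <- stats::setNames(list(text), field)
  trial_registration(nct_id = nct_id, texts = texts, ...)
}
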
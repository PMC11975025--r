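# Shared fixtures: small cohorts and trained models, built once per run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fast_sngp_config <- function(seed = 7L, ...) {
  sngp_config(D = 128L, epochs = 15L, seed = seed, ...)
}

# default cohort: 100 patients, ambiguous fraction 2/3
test_cohort <- function() cached("cohort", generate_cohort(cohort_config(seed = 101L)))

# fully separable cohort (no ambiguous tiles)
sep_cohort <- function() cached("sep",
  generate_cohort(cohort_config(ambiguous_fraction = 0, seed = 202L)))

test_model <- function() cached("model", sngp(test_cohort(), config = fast_sngp_config()))

sep_model <- function() cached("sep_model", sngp(sep_cohort(), config = fast_sngp_config()))

# patient-level probabilities for a cohort under a model
patient_probs <- function(model, cohort) {
  pred <- predict(model, cohort)
  agg <- aggregate_hierarchy(pred$probs, cohort$manifest)
  agg$patient
}
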
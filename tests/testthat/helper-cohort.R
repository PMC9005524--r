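# A moderately sized training cohort and fitted model shared across test
# files (built once per test run).
.shared <- new.env()

shared_cohort <- function() {
  if (is.null(.shared$cohort)) {
    .shared$cohort <- simulate_cohort(fixture_params(n_loci = 360L, seed = 4242L))
  }
  .shared$cohort
}

shared_model <- function() {
  if (is.null(.shared$model)) {
    .shared$model <- loh_model(loh ~ ., data = shared_cohort()$features,
                               seed = 11L)
  }
  .shared$model
}
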
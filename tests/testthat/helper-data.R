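# Shared small fixtures, generated in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# small noiseless-ish dataset reused by model/routing tests
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- gen_config(n_proteins = 24L, length_range = c(40L, 70L),
                      feature_noise = 0, ss_error_rate = 0.05, seed = 42L)
    .fixture_env$small <- generate_dataset(cfg)
  }
  .fixture_env$small
}

# quick bundle trained on the small dataset (few epochs; used for routing,
# persistence and prediction-contract tests, not for accuracy)
small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    ds <- small_dataset()
    .fixture_env$bundle <- train_bundle(
      ds$train, ds$validation,
      schedule = training_schedule(max_epochs = 8L, seed = 5L))
  }
  .fixture_env$bundle
}

random_chain <- function(n = 6L) {
  phi <- c(NA, runif(n - 1, -180, 180))
  psi <- c(runif(n - 1, -180, 180), NA)
  seqv <- paste(sample(c("A", "C", "D", "G", "K", "L", "S", "V"), n,
                       replace = TRUE), collapse = "")
  build_backbone(seqv, phi, psi)
}
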
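# One shared scaled-down simulation for every model-dependent test:
# 30 training / 10 held-out phantoms at 12 x 128 x 128, default model
# configs, fixed seed. Trained once per session and memoized.
.fixture <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (is.null(.fixture$report))
    .fixture$report <- run_pipeline(pipeline_config(seed = 1L))
  .fixture$report
}

# the held-out phantom cases of the fixture run (regenerated, deterministic)
fixture_test_cases <- function() {
  if (is.null(.fixture$test_cases)) {
    rep <- pipeline_fixture()
    cfg <- rep$config
    cases <- generate_dataset(cfg$phantom, cfg$n_train + cfg$n_test)
    .fixture$test_cases <- cases[cfg$n_train + seq_len(cfg$n_test)]
  }
  .fixture$test_cases
}

# cached corrected / 2D-only predictions on the held-out cases
fixture_predictions <- function() {
  if (is.null(.fixture$preds)) {
    rep <- pipeline_fixture()
    mods <- rep$models
    .fixture$preds <- lapply(fixture_test_cases(), function(ca) {
      list(case = ca,
           corrected = predict_pipeline(ca$image, mods$localizer, mods$seg2d,
                                        mods$corrector),
           seg2d_only = predict_pipeline(ca$image, mods$localizer, mods$seg2d,
                                         NULL))
    })
  }
  .fixture$preds
}
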
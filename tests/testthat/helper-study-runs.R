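# The replicate study used by the acceptance checks: primary outcome,
# n = 422, 500 replicates per generative family, profile CIs for the
# correctly specified analysis model.  Run once and cached for the
# whole test session.
acceptance_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      models <- list(nb = calibrated_model("nb"),
                     zinb = calibrated_model("zinb"))
      cache <<- list(
        models = models,
        nb = run_simulation(models$nb, reps = 500, n = 422, seed = 2024,
                            ci_families = "nb"),
        zinb = run_simulation(models$zinb, reps = 500, n = 422,
                              seed = 2025, ci_families = "zinb")
      )
    }
    cache
  }
})
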
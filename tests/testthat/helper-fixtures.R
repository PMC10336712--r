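# Shared fixtures built in code.

toy_records <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    y = c(-0.2, 0.1, -0.4, 0.3, -0.1, 0.05),
    se = c(0.15, 0.2, 0.25, 0.3, 0.1, 0.2),
    disease_area = c("onc", "onc", "onc", "cardio", "cardio", "cardio"),
    comparison_type = c("active_vs_active", "active_vs_inactive",
                        "active_vs_active", "active_vs_inactive",
                        "active_vs_inactive", "active_vs_active"),
    outcome_type = c("binary", "survival", "binary", "binary",
                     "survival", "binary"),
    year = c(1999L, 2001L, 2003L, 1995L, 2005L, 2008L),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() trial_dataset(toy_records())

# A quick small fit reused across predictive tests (cached per session).
cached_small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sim <- simulate_trial_dataset(generator_config(
        area_sizes = rep(20L, 4L), seed = 101L))
      fit <<- rte_hier(sim$data, settings = mcmc_settings(
        "test", n_burnin = 1000L, n_samples = 3000L, seed = 11L))
    }
    fit
  }
})

cached_small_fit2 <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sim <- simulate_trial_dataset(generator_config(
        area_sizes = rep(20L, 4L), B_true = 0.05, seed = 102L))
      fit <<- rte_hier(sim$data, model = "model2", settings = mcmc_settings(
        "test", n_burnin = 1000L, n_samples = 3000L, seed = 12L))
    }
    fit
  }
})
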
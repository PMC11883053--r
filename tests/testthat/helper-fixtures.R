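# shared fixtures: one small synthetic dataset and memoised quick fits so
# multiple test files can reuse them without re-running the sampler

fixture_env <- new.env(parent = emptyenv())

default_dataset <- function(seed = 7) {
  key <- paste0("ds", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_d6sr_dataset(true_params(seed = seed))
  }
  fixture_env[[key]]
}

quick_mcmc <- function(seed = 42) {
  mcmc_settings(chains = 4, iter = 2000, warmup = 1000, seed = seed)
}

quick_fit <- function(form = "gmm", use_sample_means = FALSE, seed = 42) {
  key <- paste("fit", form, use_sample_means, seed, sep = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- fit_d6sr(
      default_dataset(),
      spec = d6sr_model_spec(form = form, use_sample_means = use_sample_means),
      mcmc = quick_mcmc(seed))
  }
  fixture_env[[key]]
}

# scaling records for point-parameter scenario tests, on realistic field scales
point_scaling <- function(dbh_sd = 25) {
  list(ca = structure(list(center = 350, scale = 30), class = "std_scale"),
       tday = structure(list(center = 25, scale = 1), class = "std_scale"),
       precip = structure(list(center = 1500, scale = 200), class = "std_scale"),
       dbh = structure(list(center = 0, scale = dbh_sd), class = "std_scale"))
}
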
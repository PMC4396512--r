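# Shared fixtures: noisy profiles, small trial designs, reference thresholds.

noisy_profile <- function(genotype, params, cv, sample_id = "s") {
  mu <- unclass(predict_profile(genotype, params, sample_id = sample_id))
  sdlog <- sqrt(log(1 + cv^2))
  x <- mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  x[mu == 0] <- 0
  suppressWarnings(gsl_profile(x, sample_id = sample_id))
}

chamber_params <- function() pathway_params(field_mode = FALSE)

col0_thresholds <- function(params = chamber_params()) {
  caller_thresholds(reference_total =
    total_aliphatic(predict_profile(gsl_genotype("Col-0"), params)))
}

small_trial <- function(seed, genotypes = 6, blocks_per_plot = 4, ...) {
  generate_trial(trial_config(genotypes = genotypes,
                              blocks_per_plot = blocks_per_plot,
                              seed = seed, ...))
}

# independent brute-force chi-square oracle: explicit loop over all states
brute_force_chi2 <- function(observed, expected_df) {
  total <- 0
  n <- sum(observed)
  for (i in seq_len(nrow(expected_df))) {
    key <- expected_df$key[i]
    e <- n * expected_df$prob[i]
    o <- if (key %in% names(observed)) observed[[key]] else 0
    if (e > 0) total <- total + (o - e)^2 / e
  }
  total
}
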
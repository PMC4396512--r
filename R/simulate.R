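#' Configuration for a synthetic field trial
#'
#' Effect sizes and design sizes for [generate_trial()]. The defaults
#' emulate the reference split-plot layout (17 genotypes, 3 environments,
#' 2 treatments, 12 plots, 120 blocks) and produce the qualitative variance
#' pattern seen in real trials: strong genotype and genotype-by-environment
#' signal, weak treatment main effects, and a modest plot component.
#' Fitness components act on the log scale (fitness is non-negative and
#' right-skewed); leaf damage arises from a thresholded latent normal
#' binned to the 0-10 visual score.
#'
#' @param genotypes Genotype labels (default the 17-genotype laboratory
#'   population) or a count.
#' @param environments,treatments,plots_per_cell,blocks_per_plot Design
#'   sizes, as in [split_plot_design()].
#' @param tfc,silique,leaf_damage,flowering Per-trait effect lists with
#'   elements `mu` (or `mu_log` for TFC), `sd_g`, `sd_e`, `sd_t`, `sd_ge`,
#'   `sd_plot`, `sd_res` -- genotype, environment, treatment,
#'   genotype-by-environment, plot and residual SDs (log scale for TFC,
#'   trait units otherwise; days for flowering, mm for silique length).
#' @param survival `base` survival probability and `sd_ge_logit`, the SD of
#'   genotype-by-environment offsets on the logit scale.
#' @param gsl `noise_cv` (lognormal CV per structure) and `env_scale`
#'   (per-environment multiplier on the aliphatic pools).
#' @param seed Mandatory RNG seed.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(genotypes = names(gsl_population()),
                         environments = 3,
                         treatments = c("control", "pesticide"),
                         plots_per_cell = 2, blocks_per_plot = 10,
                         tfc = list(mu_log = log(50), sd_g = 0.3, sd_e = 0.3,
                                    sd_t = 0.05, sd_ge = 0.25, sd_plot = 0.1,
                                    sd_res = 0.5),
                         silique = list(mu = 12, sd_g = 0.5, sd_e = 1,
                                        sd_t = 0.1, sd_ge = 0.3,
                                        sd_plot = 0.2, sd_res = 1.5),
                         leaf_damage = list(mu = 3, sd_g = 0.5, sd_e = 1,
                                            sd_t = 0.7, sd_ge = 0.5,
                                            sd_plot = 0.3, sd_res = 1.5),
                         flowering = list(mu = 45, sd_g = 2, sd_e = 3,
                                          sd_t = 0.3, sd_ge = 1,
                                          sd_plot = 0.5, sd_res = 3),
                         survival = list(base = 0.85, sd_ge_logit = 0.5),
                         gsl = list(noise_cv = 0.2,
                                    env_scale = c(1, 0.8, 1.2)),
                         seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  cfg <- list(genotypes = genotypes, environments = environments,
              treatments = treatments, plots_per_cell = plots_per_cell,
              blocks_per_plot = blocks_per_plot,
              tfc = tfc, silique = silique, leaf_damage = leaf_damage,
              flowering = flowering, survival = survival, gsl = gsl,
              seed = as.integer(seed))
  for (tr in c("tfc", "silique", "leaf_damage", "flowering")) {
    sds <- unlist(cfg[[tr]][grep("^sd", names(cfg[[tr]]))])
    if (any(sds < 0)) stop("negative SD in ", tr)
  }
  if (cfg$survival$base < 0 || cfg$survival$base > 1)
    stop("survival base rate must be in [0, 1]")
  class(cfg) <- "trial_config"
  cfg
}

draw_effects <- function(cfg_tr, G, E, Tt, P) {
  list(g = stats::setNames(stats::rnorm(length(G), 0, cfg_tr$sd_g), G),
       e = stats::setNames(stats::rnorm(length(E), 0, cfg_tr$sd_e), E),
       t = stats::setNames(stats::rnorm(length(Tt), 0, cfg_tr$sd_t), Tt),
       ge = matrix(stats::rnorm(length(G) * length(E), 0, cfg_tr$sd_ge),
                   length(G), length(E), dimnames = list(G, E)),
       plot = stats::setNames(stats::rnorm(length(P), 0, cfg_tr$sd_plot), P))
}

eff_sum <- function(eff, d) {
  eff$g[d$genotype] + eff$e[d$environment] + eff$t[d$treatment] +
    eff$ge[cbind(d$genotype, d$environment)] + eff$plot[d$plot]
}

#' Generate a synthetic split-plot field trial
#'
#' Draws one plant per genotype per block on the configured split-plot
#' layout. Total fruit count is lognormal on the latent scale (rounded to a
#' count), silique length and flowering time are normal, survival is
#' Bernoulli with genotype-by-environment logit offsets, leaf damage is a
#' latent normal binned to the 0-10 ordinal score, and each plant receives
#' a GSL profile equal to its genotype's forward-model mean (field mode)
#' scaled per environment and perturbed by multiplicative lognormal noise.
#' Dead plants have missing fruit and silique measurements. Output is fully
#' reproducible from the config seed.
#'
#' @param config A [trial_config()].
#' @return Data frame of plant records (design columns, `tfc`,
#'   `silique_length`, `survival`, `leaf_damage`, `flowering_time`,
#'   `total_aliphatic`, `total_indole`) with attributes `gsl` (plants x
#'   structures concentration matrix) and `effects` (the true simulated
#'   effects, for recovery checks).
#' @examples
#' trial <- generate_trial(trial_config(seed = 1))
#' nrow(trial)  # 2040
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  d <- split_plot_design(config$genotypes, config$environments,
                         config$treatments, config$plots_per_cell,
                         config$blocks_per_plot)
  G <- unique(d$genotype); E <- unique(d$environment)
  Tt <- unique(d$treatment); P <- unique(d$plot)
  n <- nrow(d)
  pop <- gsl_population()
  params <- pathway_params(field_mode = TRUE)
  env_scale <- rep_len(config$gsl$env_scale, length(E))
  names(env_scale) <- E

  withr_seed(config$seed, {
    eff <- list(tfc = draw_effects(config$tfc, G, E, Tt, P),
                silique = draw_effects(config$silique, G, E, Tt, P),
                leaf_damage = draw_effects(config$leaf_damage, G, E, Tt, P),
                flowering = draw_effects(config$flowering, G, E, Tt, P))
    surv_ge <- matrix(stats::rnorm(length(G) * length(E), 0,
                                   config$survival$sd_ge_logit),
                      length(G), length(E), dimnames = list(G, E))

    p_surv <- stats::plogis(stats::qlogis(config$survival$base) +
                              surv_ge[cbind(d$genotype, d$environment)])
    survival <- stats::rbinom(n, 1, p_surv)

    log_tfc <- config$tfc$mu_log + eff_sum(eff$tfc, d) +
      stats::rnorm(n, 0, config$tfc$sd_res)
    tfc <- round(exp(log_tfc))
    silique <- config$silique$mu + eff_sum(eff$silique, d) +
      stats::rnorm(n, 0, config$silique$sd_res)
    silique <- pmax(silique, 0.5)
    latent <- config$leaf_damage$mu + eff_sum(eff$leaf_damage, d) +
      stats::rnorm(n, 0, config$leaf_damage$sd_res)
    leaf_damage <- pmin(10, pmax(0, round(latent)))
    flowering <- config$flowering$mu + eff_sum(eff$flowering, d) +
      stats::rnorm(n, 0, config$flowering$sd_res)

    tfc[survival == 0] <- NA
    silique[survival == 0] <- NA

    means <- vapply(G, function(g) {
      geno <- if (g %in% names(pop)) pop[[g]] else gsl_genotype(g)
      unclass(predict_profile(geno, params))
    }, numeric(nrow(gsl_structures())))
    sdlog <- sqrt(log(1 + config$gsl$noise_cv^2))
    gsl <- t(means[, d$genotype]) * env_scale[d$environment]
    noise <- matrix(stats::rlnorm(length(gsl), -sdlog^2 / 2, sdlog),
                    nrow(gsl), ncol(gsl))
    gsl <- gsl * noise
    colnames(gsl) <- gsl_structures()$id

    reg <- gsl_structures()
    ali <- rowSums(gsl[, reg$id[reg$chain_class != "indole"], drop = FALSE])
    ind <- rowSums(gsl[, reg$id[reg$chain_class == "indole"], drop = FALSE])

    out <- data.frame(d, tfc = tfc, silique_length = silique,
                      survival = survival, leaf_damage = leaf_damage,
                      flowering_time = flowering,
                      total_aliphatic = ali, total_indole = ind,
                      stringsAsFactors = FALSE)
    rownames(gsl) <- NULL
    attr(out, "gsl") <- gsl
    attr(out, "effects") <- c(eff, list(survival_ge = surv_ge))
    out
  })
}

#' Configuration for a synthetic accession panel
#'
#' Settings for [generate_accession_panel()]: panel size, per-locus allele
#' frequencies (or a haplotype frequency table), optional per-haplotype
#' enrichment multipliers (renormalized), profile noise, and the growth
#' mode. Default allele frequencies sketch a natural panel in which most
#' accessions carry functional MYB regulators, the AOP alternatives are
#' common and the Col-0-like AOP-null state is the minority.
#'
#' @param n Number of accessions.
#' @param freqs Named list of per-locus frequencies (scalar = probability
#'   of the functional allele; AOP is a named 3-state vector), or `NULL`
#'   when `haplotypes` is given.
#' @param haplotypes Optional data frame with the six locus columns and a
#'   `prob` column, e.g. from [expected_haplotype_frequencies()].
#' @param enrichment Named numeric vector of multipliers applied to
#'   haplotype probabilities (names are state keys); mass is renormalized.
#' @param noise_cv Lognormal CV of per-structure profile noise.
#' @param esp_freq Frequency of the (chemically silent) functional ESP
#'   allele carried through to the true genotypes.
#' @param chamber Grow accessions in chamber mode (default), where the MT
#'   structures diagnostic for GSOX accumulate.
#' @param seed Mandatory RNG seed.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(n = 144,
                         freqs = list(MYB28 = 0.95, MYB29 = 0.95,
                                      MAM1 = 0.6, GSOX = 0.9,
                                      AOP = c(AOP2 = 0.5, AOP3 = 0.3,
                                              null = 0.2),
                                      GSOH = 0.6),
                         haplotypes = NULL, enrichment = NULL,
                         noise_cv = 0.15, esp_freq = 0.5,
                         chamber = TRUE, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  if (n < 1) stop("n must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n = as.integer(n), freqs = freqs, haplotypes = haplotypes,
                 enrichment = enrichment, noise_cv = noise_cv,
                 esp_freq = esp_freq, chamber = isTRUE(chamber),
                 seed = as.integer(seed)),
            class = "panel_config")
}

haplotype_row_to_genotype <- function(states, fl, esp_functional, label) {
  draw <- function(l) {
    p <- fl[[l]]
    sample(names(p), 1, prob = p)
  }
  s <- lapply(names(states), function(l)
    if (is.na(states[[l]])) draw(l) else states[[l]])
  names(s) <- names(states)
  gsl_genotype(label,
               myb28 = s$MYB28 == "+", myb29 = s$MYB29 == "+",
               mam1 = s$MAM1 == "+",
               gsox1 = s$GSOX == "+", gsox3 = TRUE,
               aop2 = s$AOP == "AOP2", aop3 = s$AOP == "AOP3",
               gsoh = s$GSOH == "+", esp = esp_functional)
}

#' Generate a synthetic accession panel
#'
#' Samples multi-locus haplotypes from the configured distribution (the
#' linkage-equilibrium product of per-locus frequencies, optionally
#' enriched for chosen haplotypes), expands each to a full genotype
#' (epistatically hidden locus states are drawn from their marginal
#' frequencies), and produces a noisy leaf profile for each accession via
#' the forward model. The true genotypes are returned alongside, so caller
#' and frequency-test behaviour can be validated against truth.
#'
#' @param config A [panel_config()].
#' @return List with `profiles` (list of [gsl_profile()]), `truth` (data
#'   frame of locus-level states and the observable-state key per
#'   accession) and `haplotype_probs` (the sampling distribution used).
#' @examples
#' panel <- generate_accession_panel(panel_config(n = 20, seed = 7))
#' length(panel$profiles)
#' @export
generate_accession_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  if (is.null(config$haplotypes)) {
    fl <- as_freq_list(config$freqs)
    space <- expected_haplotype_frequencies(config$freqs, loci = FREQ_LOCI,
                                            epistasis = TRUE)
  } else {
    space <- config$haplotypes
    fl <- as_freq_list(config$freqs)
  }
  pr <- space$prob
  if (!is.null(config$enrichment)) {
    i <- match(names(config$enrichment), space$key)
    if (anyNA(i)) stop("enrichment names must be state keys of the space")
    pr[i] <- pr[i] * config$enrichment
    pr <- pr / sum(pr)
  }
  params <- pathway_params(field_mode = !config$chamber)
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  withr_seed(config$seed, {
    rows <- sample(nrow(space), config$n, replace = TRUE, prob = pr)
    esp <- stats::runif(config$n) < config$esp_freq
    profiles <- vector("list", config$n)
    truth <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      st <- as.list(space[rows[i], FREQ_LOCI])
      id <- sprintf("acc%03d", i)
      geno <- haplotype_row_to_genotype(st, fl, esp[i], id)
      mu <- unclass(predict_profile(geno, params, sample_id = id))
      noisy <- mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      noisy[mu == 0] <- 0
      profiles[[i]] <- gsl_profile(noisy, sample_id = id)
      truth[[i]] <- data.frame(accession = id,
                               as.data.frame(genotype_locus_states(geno),
                                             stringsAsFactors = FALSE),
                               key = space$key[rows[i]],
                               stringsAsFactors = FALSE)
    }
    list(profiles = profiles, truth = do.call(rbind, truth),
         haplotype_probs = data.frame(key = space$key, prob = pr,
                                      stringsAsFactors = FALSE))
  })
}
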
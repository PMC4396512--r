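#' Absolute fitness of field plants
#'
#' Absolute fitness is total fruit count (TFC = fruits + flowers + buds)
#' times mean silique length times survival. With survivorship included,
#' plants that died before harvest score exactly 0; with survivorship
#' excluded, fitness is defined only for survivors (non-survivors are
#' `NA`). Plants with missing survival are excluded (`NA`) in both modes.
#'
#' @param tfc Total fruit count (non-negative, may be `NA`).
#' @param silique_length Mean silique length in mm (positive, may be `NA`).
#' @param survival 0/1 survival score (may be `NA`).
#' @param include_survivorship Include the survival factor (default).
#' @return Numeric vector of fitness values.
#' @examples
#' absolute_fitness(10, 12, 1)                        # 120
#' absolute_fitness(10, 12, 0)                        # 0
#' absolute_fitness(10, 12, 0, include_survivorship = FALSE)  # NA
#' @export
absolute_fitness <- function(tfc, silique_length, survival,
                             include_survivorship = TRUE) {
  n <- max(length(tfc), length(silique_length), length(survival))
  tfc <- rep_len(tfc, n); silique_length <- rep_len(silique_length, n)
  survival <- rep_len(survival, n)
  if (any(tfc < 0, na.rm = TRUE) || any(silique_length <= 0, na.rm = TRUE))
    stop("tfc must be >= 0 and silique_length > 0")
  if (any(!survival %in% c(0, 1, NA)))
    stop("survival must be 0, 1 or NA")
  dead <- !is.na(survival) & survival == 0
  alive <- !is.na(survival) & survival == 1
  out <- rep(NA_real_, n)
  if (include_survivorship) {
    out[dead] <- 0
    out[alive] <- tfc[alive] * silique_length[alive]
  } else {
    out[alive] <- tfc[alive] * silique_length[alive]
  }
  if (any(alive & (is.na(tfc) | is.na(silique_length))))
    warning("survivors with missing tfc or silique length set to NA",
            call. = FALSE)
  out
}

#' Genotype-by-environment trait means
#'
#' Unweighted mean of a trait per genotype within each environment, dropping
#' missing plants (no imputation).
#'
#' @param trial Data frame of plant records with at least `genotype`,
#'   `environment` and the trait column.
#' @param trait Name of the trait column.
#' @return Data frame with `genotype`, `environment`, `mean`, `n`.
#' @export
genotype_env_means <- function(trial, trait) {
  stopifnot(is.data.frame(trial),
            all(c("genotype", "environment", trait) %in% names(trial)))
  y <- trial[[trait]]
  keep <- !is.na(y)
  ag <- stats::aggregate(y[keep],
                         by = list(genotype = trial$genotype[keep],
                                   environment = trial$environment[keep]),
                         FUN = mean)
  n <- stats::aggregate(y[keep],
                        by = list(genotype = trial$genotype[keep],
                                  environment = trial$environment[keep]),
                        FUN = length)
  out <- data.frame(genotype = ag$genotype, environment = ag$environment,
                    mean = ag$x, n = n$x, stringsAsFactors = FALSE)
  out[order(out$environment, out$genotype), , drop = FALSE]
}

#' Relative fitness of genotypes within environments
#'
#' Two conventions are supported: dividing each genotype's mean absolute
#' fitness by the unweighted mean of all genotype means in that environment
#' (`"population_mean"`, the default -- relative fitness then averages
#' exactly 1 per environment), or by the Col-0 reference genotype's mean
#' (`"col0_reference"` -- Col-0's relative fitness is then 1 everywhere).
#'
#' @param means Data frame from [genotype_env_means()] (columns `genotype`,
#'   `environment`, `mean`).
#' @param convention `"population_mean"` or `"col0_reference"`.
#' @param reference Reference genotype label for `"col0_reference"`.
#' @return `means` with a `relative` column added.
#' @export
relative_fitness <- function(means,
                             convention = c("population_mean", "col0_reference"),
                             reference = "Col-0") {
  convention <- match.arg(convention)
  stopifnot(all(c("genotype", "environment", "mean") %in% names(means)))
  out <- means
  out$relative <- NA_real_
  for (env in unique(means$environment)) {
    i <- means$environment == env
    denom <- if (convention == "population_mean") mean(means$mean[i])
             else means$mean[i][means$genotype[i] == reference]
    if (!length(denom) || is.na(denom) || denom <= 0)
      stop("undefined or non-positive denominator in environment ", env)
    out$relative[i] <- means$mean[i] / denom
  }
  out
}

#' Mean-normalize genotype means across environments
#'
#' Rescales genotype-by-environment means so environments become
#' comparable: each value is divided by its environment's mean (over
#' genotype means) and multiplied by the grand mean, so each environment's
#' average equals the grand mean while genotype contrasts within an
#' environment are preserved. The operation is idempotent.
#'
#' @param means Data frame from [genotype_env_means()].
#' @return `means` with a `normalized` column added.
#' @export
mean_normalize <- function(means) {
  stopifnot(all(c("genotype", "environment", "mean") %in% names(means)))
  env_means <- tapply(means$mean, means$environment, mean)
  if (any(env_means <= 0)) stop("environment means must be > 0")
  grand <- mean(env_means)
  out <- means
  out$normalized <-
    as.vector(means$mean * grand / env_means[as.character(means$environment)])
  out
}

#' Genetic correlations between traits
#'
#' Correlations across genotype means within one environment, for pairs of
#' traits -- the genotype-mean analogue of a genetic correlation in a
#' common-garden design. Pearson and Spearman coefficients are computed via
#' [stats::cor.test()]; constant traits give `NA` with a warning.
#'
#' @param means_wide Data frame with one row per genotype and one column
#'   per trait.
#' @param traits Trait column names (default: all numeric columns).
#' @param method `"pearson"`, `"spearman"` or `"both"` (Pearson in the
#'   upper triangle, Spearman in the lower, as conventionally displayed).
#' @return List with matrices `estimate` and `p`, and the genotype count
#'   `n`.
#' @export
genetic_correlations <- function(means_wide, traits = NULL,
                                 method = c("pearson", "spearman", "both")) {
  method <- match.arg(method)
  if (is.null(traits))
    traits <- names(means_wide)[vapply(means_wide, is.numeric, logical(1))]
  stopifnot(length(traits) >= 2, nrow(means_wide) >= 3)
  k <- length(traits)
  est <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(est) <- 1
  one <- function(x, y, m) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant trait; correlation undefined", call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = m))
    c(unname(ct$estimate), ct$p.value)
  }
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    x <- means_wide[[traits[i]]]; y <- means_wide[[traits[j]]]
    keep <- !is.na(x) & !is.na(y)
    mu <- if (method == "both") "pearson" else method
    ml <- if (method == "both") "spearman" else method
    up <- one(x[keep], y[keep], mu)
    lo <- if (identical(mu, ml)) up else one(x[keep], y[keep], ml)
    est[i, j] <- up[1]; p[i, j] <- up[2]
    est[j, i] <- lo[1]; p[j, i] <- lo[2]
  }
  list(estimate = est, p = p, n = nrow(means_wide), method = method)
}
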
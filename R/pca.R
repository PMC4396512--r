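#' Assemble a genotype-by-structure profile matrix
#'
#' Stacks profiles into the matrix consumed by [fit_pca()], optionally
#' restricted to the aliphatic structures (the indole pool does not vary
#' with the aliphatic pathway loci).
#'
#' @param profiles Named list of [gsl_profile()] objects (names become row
#'   names).
#' @param aliphatic_only Drop the indole columns (default).
#' @return Numeric matrix, genotypes x structures.
#' @export
profile_matrix <- function(profiles, aliphatic_only = TRUE) {
  reg <- gsl_structures()
  ids <- if (aliphatic_only) reg$id[reg$chain_class != "indole"] else reg$id
  M <- t(vapply(profiles, function(p) unclass(p)[ids], numeric(length(ids))))
  colnames(M) <- ids
  if (is.null(rownames(M)))
    rownames(M) <- vapply(profiles, function(p) attr(p, "sample_id"),
                          character(1))
  M
}

#' Principal components of reference genotype mean profiles
#'
#' Centered (unscaled) PCA of a genotype-by-structure matrix of mean GSL
#' concentrations, as used to summarize chemotype variation in a reference
#' environment. Concentrations share units, so the covariance (not
#' correlation) decomposition is the default. Component signs are fixed by
#' making each loading's largest-magnitude element positive, so results are
#' bit-stable across runs and platforms.
#'
#' @param X Genotypes x structures matrix (e.g. [profile_matrix()]).
#' @param n_components Components to retain (default 4).
#' @param scale. Scale columns to unit variance before decomposition.
#' @return Object of class `gsl_pca`: `center`, orthonormal `loadings`,
#'   `var_fractions` (all components), `scores` of the reference data, and
#'   `n_components`.
#' @export
fit_pca <- function(X, n_components = 4, scale. = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 genotypes and >= 2 structures")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(rot))
  structure(list(center = pc$center,
                 scale = if (scale.) pc$scale else NULL,
                 loadings = rot, var_fractions = vf,
                 scores = scores[, seq_len(k), drop = FALSE],
                 n_components = k),
            class = "gsl_pca")
}

#' @export
print.gsl_pca <- function(x, ...) {
  k <- x$n_components
  cat("<gsl_pca>", length(x$center), "structures,", k, "components retained\n",
      "variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$var_fractions[seq_len(k)]),
            collapse = " "),
      sprintf("(top-%d %.2f%%)\n", k,
              100 * sum(x$var_fractions[seq_len(k)])))
  invisible(x)
}

#' Project genotype means onto a fitted PCA
#'
#' Returns scores of a new genotype-mean matrix on the retained components.
#' By default the new matrix is centered by its own column means
#' (`center = "data"`): environments differ in overall GSL levels, and
#' per-environment centering makes the scores reflect genotype contrasts
#' only, so a profile set that is a constant shift of the reference yields
#' identical scores. Projecting the reference data reproduces the reference
#' scores under either convention. `center = "model"` centers by the fitted
#' model's means instead.
#'
#' @param model A [fit_pca()] result.
#' @param X Genotypes x structures matrix over the same structures.
#' @param center `"data"` (default) or `"model"`.
#' @return Scores matrix, genotypes x retained components.
#' @export
project_scores <- function(model, X, center = c("data", "model")) {
  center <- match.arg(center)
  stopifnot(inherits(model, "gsl_pca"))
  X <- as.matrix(X)
  if (!identical(colnames(X), names(model$center)))
    stop("structure columns do not match the fitted model")
  ctr <- if (center == "data") colMeans(X) else model$center
  Xc <- sweep(X, 2, ctr)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  Xc %*% model$loadings[, seq_len(model$n_components), drop = FALSE]
}

#' Per-component correlation of scores between environments
#'
#' Pearson correlation (and p value) of genotype scores on each retained
#' component between a reference environment and another environment --
#' high correlations mean the genotypes' chemotype contrasts are preserved
#' across environments.
#'
#' @param ref_scores,env_scores Score matrices over the same genotypes
#'   (rows aligned), e.g. from [project_scores()].
#' @return Data frame: component, r, p, n.
#' @export
score_correlations <- function(ref_scores, env_scores) {
  stopifnot(nrow(ref_scores) == nrow(env_scores),
            ncol(ref_scores) == ncol(env_scores))
  if (nrow(ref_scores) < 3) stop("need >= 3 genotypes")
  rows <- lapply(seq_len(ncol(ref_scores)), function(j) {
    x <- ref_scores[, j]; y <- env_scores[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant scores on component ", j)
    ct <- stats::cor.test(x, y)
    data.frame(component = paste0("PC", j), r = unname(ct$estimate),
               p = ct$p.value, n = nrow(ref_scores),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
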
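#' Split-plot field-trial design
#'
#' Lays out the split-plot structure used in the field trials: within each
#' environment, plots (rows of blocks) are whole-plot units receiving one
#' treatment each, blocks nest in plots, and every block contains each
#' genotype exactly once. The default sizes reproduce the reference layout:
#' 17 genotypes, 3 environments, 2 treatments, 2 plots per
#' environment-by-treatment cell and 10 blocks per plot, i.e. 40 blocks per
#' environment, 120 blocks and 12 plots in total.
#'
#' @param genotypes Character vector of genotype labels, or a count.
#' @param environments Environment labels, or a count.
#' @param treatments Treatment labels (default control / pesticide).
#' @param plots_per_cell Plots per environment-by-treatment combination.
#' @param blocks_per_plot Blocks nested in each plot.
#' @return Data frame of class `split_plot_design` with one row per plant:
#'   `environment`, `treatment`, `plot`, `block`, `genotype`.
#' @examples
#' d <- split_plot_design()
#' nrow(d)                      # 2040 plants
#' length(unique(d$plot))       # 12 plots
#' length(unique(d$block))      # 120 blocks
#' @export
split_plot_design <- function(genotypes = 17, environments = 3,
                              treatments = c("control", "pesticide"),
                              plots_per_cell = 2, blocks_per_plot = 10) {
  lab <- function(x, prefix) {
    if (is.numeric(x) && length(x) == 1) paste0(prefix, seq_len(x))
    else as.character(x)
  }
  genotypes <- lab(genotypes, "G")
  environments <- if (is.numeric(environments) && environments == 3)
    c("UCD2012", "UWY2011", "UWY2012") else lab(environments, "E")
  treatments <- lab(treatments, "T")
  cells <- expand.grid(treatment = treatments, environment = environments,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    for (p in seq_len(plots_per_cell)) {
      plot_id <- paste(cells$environment[i], cells$treatment[i], p, sep = ".")
      for (b in seq_len(blocks_per_plot)) {
        block_id <- paste(plot_id, b, sep = ".")
        rows[[length(rows) + 1L]] <-
          data.frame(environment = cells$environment[i],
                     treatment = cells$treatment[i],
                     plot = plot_id, block = block_id,
                     genotype = genotypes, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("split_plot_design", "data.frame")
  out
}

# --- internal GLS machinery -------------------------------------------------

# Whiten y / columns of X for V = I + lambda * Z Z' with Z the plot
# indicator: per plot of size m, (I + lambda J)^{-1/2} = I - c J with
# c = (1 - 1/sqrt(1 + lambda m)) / m.
whiten <- function(M, plot, lambda) {
  if (lambda == 0) return(M)
  M <- as.matrix(M)
  sizes <- tabulate(plot)
  cc <- (1 - 1 / sqrt(1 + lambda * sizes)) / sizes
  sums <- rowsum(M, plot, reorder = TRUE)
  M - cc[as.integer(plot)] * sums[as.integer(plot), , drop = FALSE]
}

# -2 * restricted log-likelihood (up to a constant) for the profiled model.
reml_dev <- function(lambda, y, X, plot) {
  n <- length(y); p <- qr(X)$rank
  Xs <- whiten(X, plot, lambda)
  ys <- drop(whiten(cbind(y), plot, lambda))
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  sizes <- tabulate(plot)
  ldV <- sum(log(1 + lambda * sizes))
  qrX <- qr(Xs)
  ldXX <- 2 * sum(log(abs(diag(qr.R(qrX))[seq_len(qrX$rank)])))
  (n - p) * log(rss / (n - p)) + ldV + ldXX
}

rss_of <- function(X, y, cols = NULL) {
  if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  fit <- stats::lm.fit(X, y)
  c(rss = sum(fit$residuals^2), rank = fit$rank)
}

is_balanced <- function(trial) {
  m <- table(trial$plot)
  g <- table(trial$genotype, trial$plot)
  length(unique(as.vector(m))) == 1 && length(unique(as.vector(g))) == 1
}

#' Fit the split-plot linear mixed model to a field trait
#'
#' Fits `trait ~ Genotype * Environment * Treatment` with a random intercept
#' for plot nested in treatment-by-environment, by restricted maximum
#' likelihood. The single variance ratio (plot / residual) is profiled in
#' one dimension; for balanced complete data the closed-form stratum
#' (ANOVA) estimator is used, which coincides with REML there. Fixed terms
#' are then assessed with Type II sums of squares from full-versus-reduced
#' generalized-least-squares comparisons respecting marginality (each term
#' tested against the model containing every term that does not contain
#' it). Denominators for F follow either the containment rule (whole-plot
#' factors -- environment, treatment and their interaction -- tested against
#' the among-plot stratum, all others against the subplot residual;
#' classical split-plot tables) or the GLS residual. The plot variance
#' component is tested by a REML likelihood-ratio statistic against the
#' plot-free model, referred to the equal-mixture of a point mass at zero
#' and a 1-df chi-square.
#'
#' @param trial Data frame with columns `genotype`, `environment`,
#'   `treatment`, `plot` and the trait.
#' @param trait Name of the trait column. Rows with a missing trait are
#'   dropped.
#' @param denominator `"containment"` (default; classical stratum tests on
#'   ordinary Type II SS) or `"residual"` (whitened-GLS Type II SS tested
#'   against the REML residual variance).
#' @param plot_variance `NULL` to estimate by REML, or a fixed value (e.g.
#'   0, which reduces the model to ordinary least squares).
#' @return Object of class `split_plot_fit`: `fixed` (term table with df,
#'   SS, MS, F, p), `random` (variance components and the mixture
#'   likelihood-ratio test), coefficient estimates with their GLS
#'   covariance, and bookkeeping needed by [lsmeans()].
#' @examples
#' d <- split_plot_design(genotypes = 4, blocks_per_plot = 3)
#' d$y <- rnorm(nrow(d))
#' fit <- fit_split_plot(d, "y")
#' fit$fixed
#' @export
fit_split_plot <- function(trial, trait, denominator = c("containment", "residual"),
                           plot_variance = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("genotype", "environment", "treatment", "plot", trait)
                %in% names(trial)))
  trial <- trial[!is.na(trial[[trait]]), , drop = FALSE]
  if (stats::var(trial[[trait]]) == 0) stop("trait is constant")
  dat <- data.frame(G = factor(trial$genotype), E = factor(trial$environment),
                    Trt = factor(trial$treatment), P = factor(trial$plot))
  y <- as.numeric(trial[[trait]])
  cell <- interaction(dat$E, dat$Trt, drop = TRUE)
  ppc <- rowSums(table(cell, dat$P) > 0)
  if (any(ppc < 2)) stop("need >= 2 plots per environment x treatment cell")

  form <- ~ G * E * Trt
  X <- stats::model.matrix(form, dat)
  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(form), "term.labels")
  n <- length(y)
  p <- qr(X)$rank

  # --- variance components ---------------------------------------------
  balanced <- is_balanced(data.frame(plot = dat$P, genotype = dat$G))
  if (!is.null(plot_variance)) {
    stopifnot(plot_variance >= 0)
    # residual variance at the fixed plot variance via profiling identity
    lam_fun <- function(s2r) if (s2r > 0) plot_variance / s2r else 0
    # one-step: iterate sigma2_res = RSS*/ (n - p)
    s2r <- stats::var(y); lambda <- lam_fun(s2r)
    for (i in 1:25) {
      ys <- drop(whiten(cbind(y), dat$P, lambda))
      Xs <- whiten(X, dat$P, lambda)
      s2r_new <- rss_of(Xs, ys)[["rss"]] / (n - p)
      if (abs(s2r_new - s2r) < 1e-10 * s2r_new) { s2r <- s2r_new; break }
      s2r <- s2r_new; lambda <- lam_fun(s2r)
    }
    lambda <- lam_fun(s2r)
    s2p <- plot_variance
    conv <- list(method = "fixed", trace = NULL)
  } else if (balanced) {
    m <- as.vector(table(dat$P))[1]
    pm <- tapply(y, dat$P, mean)
    cell_of_plot <- tapply(as.character(cell), dat$P, `[`, 1)
    cm <- tapply(pm, cell_of_plot, mean)
    # whole-plot error: plot means about their E x Trt cell means
    ss_whole <- m * sum((pm - cm[cell_of_plot])^2)
    df_whole <- nlevels(dat$P) - length(unique(cell_of_plot))
    # subplot error: residual after fixed effects + fixed plot
    Xp <- cbind(X, stats::model.matrix(~ P - 1, dat))
    sub <- rss_of(Xp, y)
    df_sub <- n - sub[["rank"]]
    ms_whole <- ss_whole / df_whole
    ms_sub <- sub[["rss"]] / df_sub
    if (ms_whole > ms_sub) {          # interior: stratum estimator = REML
      s2r <- ms_sub
      s2p <- (ms_whole - ms_sub) / m
    } else {                          # boundary: REML collapses to OLS
      s2r <- rss_of(X, y)[["rss"]] / (n - p)
      s2p <- 0
    }
    lambda <- s2p / s2r
    conv <- list(method = "anova", trace = NULL)
  } else {
    obj <- function(loglam) reml_dev(exp(loglam), y, X, dat$P)
    opt <- stats::optimize(obj, interval = log(c(1e-8, 1e4)), tol = 1e-7)
    d0 <- reml_dev(0, y, X, dat$P)
    if (d0 <= opt$objective) {
      lambda <- 0
    } else lambda <- exp(opt$minimum)
    ys <- drop(whiten(cbind(y), dat$P, lambda))
    Xs <- whiten(X, dat$P, lambda)
    s2r <- rss_of(Xs, ys)[["rss"]] / (n - p)
    s2p <- lambda * s2r
    conv <- list(method = "profile", trace = opt)
  }

  dev_hat <- reml_dev(lambda, y, X, dat$P)
  dev_0 <- reml_dev(0, y, X, dat$P)
  lr <- max(0, dev_0 - dev_hat)
  p_plot <- if (lr == 0) 1 else 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE)

  # --- Type II SS -------------------------------------------------------
  ss_lambda <- if (denominator == "containment") 0 else lambda
  Xs <- whiten(X, dat$P, ss_lambda)
  ys <- drop(whiten(cbind(y), dat$P, ss_lambda))
  full <- rss_of(Xs, ys)

  split_terms <- strsplit(term_labels, ":", fixed = TRUE)
  contains <- function(a, b) all(split_terms[[b]] %in% split_terms[[a]])
  tab <- lapply(seq_along(term_labels), function(ti) {
    keep <- vapply(seq_along(term_labels),
                   function(tj) tj != ti && !contains(tj, ti), logical(1))
    red_cols <- asgn %in% c(0, which(keep))
    with_cols <- red_cols | asgn == ti
    r_red <- rss_of(Xs, ys, red_cols)
    r_with <- rss_of(Xs, ys, with_cols)
    data.frame(term = term_labels[ti],
               df = r_with[["rank"]] - r_red[["rank"]],
               SS = r_red[["rss"]] - r_with[["rss"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  tab$MS <- tab$SS / tab$df

  whole_terms <- c("E", "Trt", "E:Trt")
  if (denominator == "containment") {
    # among-plot stratum (OLS): plots within E x Trt cells
    Xet <- stats::model.matrix(~ E * Trt, dat)
    Xetp <- cbind(Xet, stats::model.matrix(~ P - 1, dat))
    r_et <- rss_of(Xet, y); r_etp <- rss_of(Xetp, y)
    ss_plot_strat <- r_et[["rss"]] - r_etp[["rss"]]
    df_plot_strat <- r_etp[["rank"]] - r_et[["rank"]]
    Xfp <- cbind(X, stats::model.matrix(~ P - 1, dat))
    r_fp <- rss_of(Xfp, y)
    df_sub_err <- n - r_fp[["rank"]]
    ms_sub_err <- r_fp[["rss"]] / df_sub_err
    ms_whole_err <- ss_plot_strat / df_plot_strat
    denom_ms <- ifelse(tab$term %in% whole_terms, ms_whole_err, ms_sub_err)
    denom_df <- ifelse(tab$term %in% whole_terms, df_plot_strat, df_sub_err)
    resid_row <- data.frame(term = "Residual", df = df_sub_err,
                            SS = r_fp[["rss"]], MS = ms_sub_err,
                            stringsAsFactors = FALSE)
  } else {
    denom_ms <- rep(s2r, nrow(tab))
    denom_df <- rep(n - p, nrow(tab))
    resid_row <- data.frame(term = "Residual", df = n - p,
                            SS = full[["rss"]], MS = s2r,
                            stringsAsFactors = FALSE)
  }
  tab$F <- tab$MS / denom_ms
  tab$p <- stats::pf(tab$F, tab$df, denom_df, lower.tail = FALSE)
  tab$denom_df <- denom_df
  resid_row$F <- resid_row$p <- resid_row$denom_df <- NA

  # --- GLS coefficients for LSMeans ------------------------------------
  Xg <- whiten(X, dat$P, lambda)
  yg <- drop(whiten(cbind(y), dat$P, lambda))
  gfit <- stats::lm.fit(Xg, yg)
  aliased <- is.na(gfit$coefficients)
  XtXi <- tryCatch(chol2inv(chol(crossprod(Xg[, !aliased, drop = FALSE]))),
                   error = function(e) stop("fixed-effect design is ",
                                            "numerically singular"))
  cov_beta <- s2r * XtXi

  structure(list(
    trait = trait,
    fixed = rbind(tab, resid_row),
    random = list(plot_variance = s2p, residual_variance = s2r,
                  lambda = lambda, lr_chi2 = lr, p = p_plot),
    beta = gfit$coefficients, cov_beta = cov_beta, aliased = aliased,
    formula = form, xlevels = lapply(dat[c("G", "E", "Trt")], levels),
    contrasts = attr(X, "contrasts"),
    df_residual = if (denominator == "containment") resid_row$df else n - p,
    denominator = denominator, n = n, convergence = conv
  ), class = "split_plot_fit")
}

#' @export
print.split_plot_fit <- function(x, ...) {
  cat("<split_plot_fit> trait:", x$trait, " n =", x$n,
      " (", x$denominator, "denominators )\n")
  tab <- x$fixed
  tab$SS <- signif(tab$SS, 4); tab$MS <- signif(tab$MS, 4)
  tab$F <- signif(tab$F, 3); tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "df", "SS", "MS", "F", "p")], row.names = FALSE)
  r <- x$random
  cat(sprintf("plot variance %.4g, residual %.4g; LR chi^2 = %.3f, p = %.4g\n",
              r$plot_variance, r$residual_variance, r$lr_chi2, r$p))
  invisible(x)
}

#' Model-based marginal means (LSMeans)
#'
#' Marginal predictions for one factor (or factor combination) averaged
#' over the levels of the other fixed factors with equal weights, with
#' standard errors from the GLS coefficient covariance.
#'
#' @param fit A [fit_split_plot()] result.
#' @param spec Factor(s) to summarize: any of `"genotype"`,
#'   `"environment"`, `"treatment"`.
#' @return Object of class `lsmeans_tab`: data frame of levels, `lsmean`,
#'   `se`; the full covariance matrix of the means is in attribute `cov`,
#'   the residual df in `df`.
#' @export
lsmeans <- function(fit, spec = "genotype") {
  stopifnot(inherits(fit, "split_plot_fit"))
  if (any(fit$aliased))
    stop("rank-deficient fixed-effect fit; LSMeans undefined")
  map <- c(genotype = "G", environment = "E", treatment = "Trt")
  if (!all(spec %in% names(map))) stop("unknown factor in spec")
  fac <- unname(map[spec])
  grid <- expand.grid(fit$xlevels, stringsAsFactors = TRUE,
                      KEEP.OUT.ATTRS = FALSE)
  for (f in names(fit$xlevels))
    grid[[f]] <- factor(grid[[f]], levels = fit$xlevels[[f]])
  Xg <- stats::model.matrix(fit$formula, grid, contrasts.arg = fit$contrasts)
  key <- interaction(grid[fac], drop = TRUE, sep = ":")
  L <- t(vapply(levels(key), function(k) colMeans(Xg[key == k, , drop = FALSE]),
                numeric(ncol(Xg))))
  est <- drop(L %*% fit$beta)
  V <- L %*% fit$cov_beta %*% t(L)
  out <- data.frame(level = levels(key), lsmean = est,
                    se = sqrt(diag(V)), stringsAsFactors = FALSE)
  names(out)[1] <- paste(spec, collapse = ":")
  attr(out, "cov") <- V
  attr(out, "df") <- fit$df_residual
  class(out) <- c("lsmeans_tab", "data.frame")
  out
}

#' Dunnett comparisons of genotype LSMeans against a control
#'
#' Tests every level against the control level with family-wise adjustment:
#' either by simulating the joint distribution of the maximum absolute
#' standardized contrast from the fitted covariance (default), or by
#' Bonferroni correction.
#'
#' @param lsm An [lsmeans()] table.
#' @param control Control level label (default `"Col-0"`).
#' @param method `"simulation"` or `"bonferroni"`.
#' @param reps Simulation draws (>= 1e5 recommended).
#' @param seed Seed for the simulation draws.
#' @return Data frame: level, estimate (level - control), se, t, raw and
#'   adjusted p.
#' @export
dunnett_vs_control <- function(lsm, control = "Col-0",
                               method = c("simulation", "bonferroni"),
                               reps = 1e5, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(lsm, "lsmeans_tab"))
  lev <- lsm[[1]]
  ci <- match(control, lev)
  if (is.na(ci)) stop("control level '", control, "' not found")
  V <- attr(lsm, "cov"); df <- attr(lsm, "df")
  idx <- setdiff(seq_along(lev), ci)
  est <- lsm$lsmean[idx] - lsm$lsmean[ci]
  vr <- V[idx, idx, drop = FALSE] + V[ci, ci] -
    outer(V[idx, ci], rep(1, length(idx))) -
    outer(rep(1, length(idx)), V[ci, idx])
  se <- sqrt(diag(vr))
  tval <- est / se
  raw <- 2 * stats::pt(-abs(tval), df)
  k <- length(idx)
  if (method == "bonferroni" || k == 1) {
    adj <- pmin(1, raw * k)
  } else {
    R <- vr / outer(se, se)
    U <- chol(R)
    maxabs <- withr_seed(seed, {
      Z <- matrix(stats::rnorm(reps * k), k, reps)
      apply(abs(t(U) %*% Z), 2, max)
    })
    adj <- vapply(tval, function(t0) (1 + sum(maxabs >= abs(t0))) / (reps + 1),
                  numeric(1))
  }
  data.frame(level = lev[idx], estimate = est, se = se, t = tval,
             raw_p = raw, adj_p = adj, stringsAsFactors = FALSE)
}

#' Tukey all-pairwise comparisons with a compact letter display
#'
#' All pairwise contrasts between LSMeans, adjusted with the studentized
#' range distribution, plus the usual letter display (levels sharing a
#' letter are not significantly different).
#'
#' @param lsm An [lsmeans()] table.
#' @param alpha Family-wise level for the letter display.
#' @return List with `pairs` (data frame of contrasts) and `letters`
#'   (named character vector).
#' @export
tukey_all_pairs <- function(lsm, alpha = 0.05) {
  stopifnot(inherits(lsm, "lsmeans_tab"))
  lev <- lsm[[1]]; k <- length(lev)
  if (k < 2) stop("need at least two levels")
  V <- attr(lsm, "cov"); df <- attr(lsm, "df")
  pr <- utils::combn(k, 2)
  est <- lsm$lsmean[pr[2, ]] - lsm$lsmean[pr[1, ]]
  se <- sqrt(V[cbind(pr[1, ], pr[1, ])] + V[cbind(pr[2, ], pr[2, ])] -
               2 * V[cbind(pr[1, ], pr[2, ])])
  tval <- est / se
  adj <- stats::ptukey(sqrt(2) * abs(tval), k, df, lower.tail = FALSE)
  pairs <- data.frame(level1 = lev[pr[1, ]], level2 = lev[pr[2, ]],
                      estimate = est, se = se, t = tval, adj_p = adj,
                      stringsAsFactors = FALSE)

  # letter display: maximal intervals of mean-ordered levels whose pairs
  # are all non-significant
  ord <- order(lsm$lsmean)
  sig <- matrix(FALSE, k, k)
  sig[t(pr)] <- adj < alpha; sig <- sig | t(sig)
  sig <- sig[ord, ord]
  ivs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    ivs[[i]] <- c(i, j)
  }
  ivs <- unique(ivs)
  keep <- vapply(seq_along(ivs), function(a)
    !any(vapply(seq_along(ivs), function(b)
      a != b && ivs[[b]][1] <= ivs[[a]][1] && ivs[[a]][2] <= ivs[[b]][2],
      logical(1))), logical(1))
  ivs <- ivs[keep]
  letts <- rep("", k)
  for (a in seq_along(ivs)) {
    rng <- ivs[[a]][1]:ivs[[a]][2]
    letts[rng] <- paste0(letts[rng], letters[a])
  }
  letters_out <- stats::setNames(letts, lev[ord])[lev]
  list(pairs = pairs, letters = letters_out)
}

#' Between-environment correlations of genotype means
#'
#' Pearson correlation (and p value) of genotype means for one trait
#' between every pair of environments, computed over the genotypes shared
#' by the pair.
#'
#' @param means Data frame from [genotype_env_means()].
#' @return Data frame: env1, env2, r, p, n.
#' @export
env_correlations <- function(means) {
  stopifnot(all(c("genotype", "environment", "mean") %in% names(means)))
  envs <- unique(as.character(means$environment))
  if (length(envs) < 2) stop("need >= 2 environments")
  rows <- list()
  for (i in seq_len(length(envs) - 1)) for (j in (i + 1):length(envs)) {
    a <- means[means$environment == envs[i], c("genotype", "mean")]
    b <- means[means$environment == envs[j], c("genotype", "mean")]
    mg <- merge(a, b, by = "genotype")
    if (nrow(mg) < 3) stop("fewer than 3 shared genotypes for ",
                           envs[i], " vs ", envs[j])
    if (stats::sd(mg$mean.x) == 0 || stats::sd(mg$mean.y) == 0)
      stop("constant genotype means in an environment")
    ct <- stats::cor.test(mg$mean.x, mg$mean.y)
    rows[[length(rows) + 1]] <- data.frame(env1 = envs[i], env2 = envs[j],
                                           r = unname(ct$estimate),
                                           p = ct$p.value, n = nrow(mg),
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
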
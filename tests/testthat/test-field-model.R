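test_that("fixed-term df follow the closed-form factorial counts", {
  trial <- small_trial(21, genotypes = 5, blocks_per_plot = 3)
  fit <- fit_split_plot(trial, "leaf_damage")
  df <- setNames(fit$fixed$df, fit$fixed$term)
  G <- 5; E <- 3; Tt <- 2
  expect_equal(unname(df["G"]), G - 1)
  expect_equal(unname(df["E"]), E - 1)
  expect_equal(unname(df["Trt"]), Tt - 1)
  expect_equal(unname(df["G:E"]), (G - 1) * (E - 1))
  expect_equal(unname(df["G:Trt"]), (G - 1) * (Tt - 1))
  expect_equal(unname(df["E:Trt"]), (E - 1) * (Tt - 1))
  expect_equal(unname(df["G:E:Trt"]), (G - 1) * (E - 1) * (Tt - 1))
})

test_that("containment fit reproduces the classical split-plot ANOVA", {
  trial <- small_trial(22)
  fit <- fit_split_plot(trial, "leaf_damage")
  d <- data.frame(y = trial$leaf_damage, G = factor(trial$genotype),
                  E = factor(trial$environment),
                  Trt = factor(trial$treatment), P = factor(trial$plot))
  a <- summary(aov(y ~ G * E * Trt + Error(P), data = d))
  whole <- as.data.frame(a[["Error: P"]][[1]])
  within <- as.data.frame(a[["Error: Within"]][[1]])
  tab <- fit$fixed
  for (tm in c("E", "Trt", "E:Trt")) {
    i <- trimws(rownames(whole)) == tm
    expect_equal(tab$F[tab$term == tm], whole$`F value`[i], tolerance = 1e-10)
    expect_equal(tab$SS[tab$term == tm], whole$`Sum Sq`[i], tolerance = 1e-8)
  }
  for (tm in c("G", "G:E", "G:Trt", "G:E:Trt")) {
    i <- trimws(rownames(within)) == tm
    expect_equal(tab$F[tab$term == tm], within$`F value`[i], tolerance = 1e-10)
  }
  # REML components agree with lme4
  m <- lme4::lmer(y ~ G * E * Trt + (1 | P), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$random$plot_variance, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$random$residual_variance, vc$vcov[2], tolerance = 1e-6)
})

test_that("profiled REML on unbalanced data matches lme4", {
  trial <- small_trial(23)
  set.seed(23)
  trial <- trial[-sample(nrow(trial), 40), ]
  fit <- fit_split_plot(trial, "leaf_damage")
  d <- data.frame(y = trial$leaf_damage, G = factor(trial$genotype),
                  E = factor(trial$environment),
                  Trt = factor(trial$treatment), P = factor(trial$plot))
  m <- lme4::lmer(y ~ G * E * Trt + (1 | P), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$random$plot_variance, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$random$residual_variance, vc$vcov[2], tolerance = 1e-5)
})

test_that("zero plot variance reduces the model to ordinary Type II ANOVA", {
  trial <- small_trial(24)
  set.seed(24)
  trial <- trial[-sample(nrow(trial), 25), ]   # unbalanced on purpose
  fit <- fit_split_plot(trial, "leaf_damage", denominator = "residual",
                        plot_variance = 0)
  d <- data.frame(y = trial$leaf_damage, G = factor(trial$genotype),
                  E = factor(trial$environment),
                  Trt = factor(trial$treatment))
  ca <- car::Anova(lm(y ~ G * E * Trt, data = d), type = 2)
  i <- match(fit$fixed$term[1:7], rownames(ca))
  expect_equal(fit$fixed$SS[1:7], ca$`Sum Sq`[i], tolerance = 1e-10)
  expect_equal(fit$fixed$F[1:7], ca$`F value`[i], tolerance = 1e-10)
  expect_equal(fit$fixed$p[1:7], ca$`Pr(>F)`[i], tolerance = 1e-10)
})

test_that("the plot variance test uses the boundary-corrected mixture", {
  trial <- small_trial(25, flowering = list(mu = 45, sd_g = 1, sd_e = 1,
                                            sd_t = 0.2, sd_ge = 0.5,
                                            sd_plot = 3, sd_res = 2))
  fit <- fit_split_plot(trial, "flowering_time")
  expect_gt(fit$random$lr_chi2, 0)
  expect_equal(fit$random$p,
               0.5 * pchisq(fit$random$lr_chi2, 1, lower.tail = FALSE))
  expect_gt(fit$random$plot_variance, 0)
})

test_that("LSMeans equal cell means on balanced data and marginalize equally otherwise", {
  trial <- small_trial(26, genotypes = 4, blocks_per_plot = 3)
  fit <- fit_split_plot(trial, "flowering_time")
  lsm <- lsmeans(fit, "genotype")
  raw <- tapply(trial$flowering_time, trial$genotype, mean)
  expect_equal(lsm$lsmean, as.numeric(raw[lsm$genotype]), tolerance = 1e-10)
  # drop one plant: LSMean departs from the raw mean but equals the
  # equal-weight average of cell means
  tr2 <- trial[-1, ]
  g1 <- trial$genotype[1]
  fit2 <- fit_split_plot(tr2, "flowering_time", denominator = "residual",
                         plot_variance = 0)
  lsm2 <- lsmeans(fit2, "genotype")
  raw2 <- mean(tr2$flowering_time[tr2$genotype == g1])
  cellmeans <- tapply(tr2$flowering_time[tr2$genotype == g1],
                      interaction(tr2$environment[tr2$genotype == g1],
                                  tr2$treatment[tr2$genotype == g1]),
                      mean)
  expect_false(isTRUE(all.equal(lsm2$lsmean[lsm2$genotype == g1], raw2)))
  expect_equal(lsm2$lsmean[lsm2$genotype == g1], mean(cellmeans),
               tolerance = 1e-10)
})

test_that("LSMeans and Tukey adjustment agree with emmeans on an unbalanced fit", {
  trial <- small_trial(27)
  set.seed(27)
  trial <- trial[-sample(nrow(trial), 30), ]
  fit <- fit_split_plot(trial, "leaf_damage")
  lsm <- lsmeans(fit, "genotype")
  d <- data.frame(y = trial$leaf_damage, G = factor(trial$genotype),
                  E = factor(trial$environment),
                  Trt = factor(trial$treatment), P = factor(trial$plot))
  m <- lme4::lmer(y ~ G * E * Trt + (1 | P), data = d, REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(m, "G"))
  i <- match(em$G, lsm$genotype)
  expect_equal(lsm$lsmean[i], em$emmean, tolerance = 1e-6)
  expect_equal(lsm$se[i], em$SE, tolerance = 2e-3)
  tk <- tukey_all_pairs(lsm)
  pe <- as.data.frame(emmeans::contrast(emmeans::emmeans(m, "G"),
                                        "pairwise", adjust = "tukey"))
  expect_equal(sort(tk$pairs$adj_p), sort(pe$p.value), tolerance = 1e-3)
})

test_that("Dunnett adjustment is between raw and Bonferroni and finds a planted shift", {
  trial <- small_trial(28)
  fit <- fit_split_plot(trial, "flowering_time")
  lsm <- lsmeans(fit, "genotype")
  sim <- dunnett_vs_control(lsm, "G1", method = "simulation", reps = 5e4,
                            seed = 3)
  bon <- dunnett_vs_control(lsm, "G1", method = "bonferroni")
  expect_true(all(sim$adj_p >= sim$raw_p - 1 / 5e4))
  expect_true(all(sim$adj_p <= bon$adj_p + 0.02))
  expect_error(dunnett_vs_control(lsm, "nope"), "not found")
  # a genotype shifted by 4.5 contrast-SEs is flagged in >= 90% of replicates
  set.seed(303)
  hits <- replicate(60, {
    tr <- small_trial(sample.int(1e6, 1),
                      flowering = list(mu = 45, sd_g = 0, sd_e = 1, sd_t = 0.2,
                                       sd_ge = 0, sd_plot = 0.2, sd_res = 3))
    l <- lsmeans(fit_split_plot(tr, "flowering_time"), "genotype")
    dn0 <- dunnett_vs_control(l, "G1", method = "bonferroni")
    se_c <- dn0$se[dn0$level == "G2"]
    tr$flowering_time[tr$genotype == "G2"] <-
      tr$flowering_time[tr$genotype == "G2"] + 4.5 * se_c
    l2 <- lsmeans(fit_split_plot(tr, "flowering_time"), "genotype")
    dn <- dunnett_vs_control(l2, "G1", method = "simulation", reps = 2e4,
                             seed = 11)
    dn$adj_p[dn$level == "G2"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Tukey pairs reduce to the two-sample test and letter extremes separate", {
  # two groups: Tukey p equals the unadjusted two-sample p
  trial <- small_trial(29, genotypes = 2, blocks_per_plot = 3)
  fit <- fit_split_plot(trial, "flowering_time")
  lsm <- lsmeans(fit, "genotype")
  tk <- tukey_all_pairs(lsm)
  raw <- 2 * pt(-abs(tk$pairs$t), attr(lsm, "df"))
  expect_equal(tk$pairs$adj_p, raw, tolerance = 1e-9)
  # identical means share one letter
  lsm_eq <- lsm; lsm_eq$lsmean <- c(10, 10)
  expect_equal(unname(unique(tukey_all_pairs(lsm_eq)$letters)), "a")
  # an extreme group receives its own letter
  set.seed(31)
  hits <- replicate(50, {
    tr <- small_trial(sample.int(1e6, 1), genotypes = 3,
                      flowering = list(mu = 45, sd_g = 0, sd_e = 1, sd_t = 0.2,
                                       sd_ge = 0, sd_plot = 0.2, sd_res = 3))
    l <- lsmeans(fit_split_plot(tr, "flowering_time"), "genotype")
    tr$flowering_time[tr$genotype == "G3"] <-
      tr$flowering_time[tr$genotype == "G3"] + 5 * l$se[l$genotype == "G3"]
    l2 <- lsmeans(fit_split_plot(tr, "flowering_time"), "genotype")
    lt <- tukey_all_pairs(l2)$letters
    !lt[["G3"]] %in% lt[c("G1", "G2")]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("environment correlations recover trivial and null structure", {
  means <- expand.grid(genotype = paste0("g", 1:17),
                       environment = c("E1", "E2"),
                       stringsAsFactors = FALSE)
  set.seed(55)
  v <- rnorm(17)
  means$mean <- c(v, v)
  ec <- env_correlations(means)
  expect_equal(ec$r, 1)
  means$mean <- c(v, -v)
  expect_equal(env_correlations(means)$r, -1)
  # independent environments: mean correlation near zero
  rs <- replicate(400, {
    means$mean <- rnorm(34)
    env_correlations(means)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(env_correlations(means[means$environment == "E1", ]), ">= 2")
})
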
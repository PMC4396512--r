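test_that("allele frequencies exclude NA calls from both sides", {
  th <- col0_thresholds()
  pop <- gsl_population()
  calls <- lapply(pop, function(g)
    call_haplotype(predict_profile(g, chamber_params()), th))
  af <- allele_frequencies(calls)
  expect_equal(af$n_panel, 17)
  # both-myb-off genotypes are NA downstream, so MAM1 has 15 informative calls
  expect_equal(unname(af$n[["MAM1"]]), 15)
  # GSOH informative only where AOP2 provides substrate: 4 lines, 2 functional
  expect_equal(unname(af$n[["GSOH"]]), 4)
  expect_equal(af$freq$GSOH, 0.5)
  expect_equal(af$freq$MYB28, 11 / 17)
  expect_equal(sum(af$freq$AOP), 1)
  expect_error(allele_frequencies(list()), "empty")
})

test_that("expected frequencies are products of marginals", {
  ex <- expected_haplotype_frequencies(c(A = 0.5, B = 0.5), epistasis = FALSE)
  expect_equal(nrow(ex), 4)
  expect_equal(ex$prob, rep(0.25, 4))
  ex1 <- expected_haplotype_frequencies(c(A = 0.3), epistasis = FALSE)
  expect_equal(sort(ex1$prob), c(0.3, 0.7))
  ex3 <- expected_haplotype_frequencies(c(A = 0.9, B = 0.5, C = 0.2),
                                        epistasis = FALSE)
  expect_equal(ex3$prob[ex3$key == "+|-|-"], 0.9 * 0.5 * 0.8)
  expect_equal(sum(ex3$prob), 1)
})

test_that("epistatic state space marginalizes hidden loci correctly", {
  fl <- panel_config(n = 10, seed = 1)$freqs
  sp <- expected_haplotype_frequencies(fl, epistasis = TRUE)
  expect_equal(sum(sp$prob), 1)
  # the double-myb state aggregates everything downstream
  dm <- sp[sp$MYB28 == "-" & sp$MYB29 == "-", ]
  expect_equal(nrow(dm), 1)
  expect_equal(dm$prob, (1 - fl$MYB28) * (1 - fl$MYB29))
  # a GSOH-NA state equals the sum of its two expanded states
  na_row <- sp[sp$MYB28 == "+" & sp$MYB29 == "+" & sp$MAM1 == "-" &
                 sp$GSOX == "+" & sp$AOP == "AOP2", ]
  expect_equal(nrow(na_row), 1)
  manual <- fl$MYB28 * fl$MYB29 * (1 - fl$MAM1) * fl$GSOX * fl$AOP[["AOP2"]]
  expect_equal(na_row$prob, unname(manual))
})

test_that("global statistic matches hand and brute-force oracles", {
  ex <- expected_haplotype_frequencies(c(A = 0.5), epistasis = FALSE)
  r <- observed_vs_expected_test(c(`+` = 8, `-` = 2), ex, mode = "asymptotic")
  expect_equal(r$global_chi2, 3.6)
  # exact match gives chi2 0, p 1
  r0 <- observed_vs_expected_test(c(`+` = 5, `-` = 5), ex, mode = "asymptotic")
  expect_equal(r0$global_chi2, 0)
  # exhaustive enumeration oracle on panels of up to 4 binary loci
  set.seed(31)
  for (L in 2:4) {
    freqs <- setNames(runif(L, 0.2, 0.8), LETTERS[1:L])
    ex <- expected_haplotype_frequencies(freqs, epistasis = FALSE)
    cnt <- drop(rmultinom(1, 60, ex$prob))
    names(cnt) <- ex$key
    r <- observed_vs_expected_test(cnt[cnt > 0], ex, mode = "asymptotic")
    expect_equal(r$global_chi2, brute_force_chi2(cnt, ex))
    expect_equal(r$global_df, 2^L - 1 - L)
  }
})

test_that("per-haplotype classification flags direction with exact binomial p", {
  ex <- expected_haplotype_frequencies(c(A = 0.5, B = 0.5), epistasis = FALSE)
  r <- observed_vs_expected_test(c(`+|+` = 30, `-|-` = 10), ex,
                                 mode = "asymptotic")
  row <- r$table[r$table$key == "+|+", ]
  expect_equal(row$direction, "over")
  expect_equal(row$raw_p, binom.test(30, 40, 0.25)$p.value)
  expect_equal(row$adj_p, min(1, row$raw_p * 4))
  # unseen state with positive expectation is included at zero count
  expect_true("+|-" %in% r$table$key)
  expect_equal(r$table$observed[r$table$key == "+|-"], 0)
})

test_that("observed states outside the expectation are flagged as infinite", {
  ex <- expected_haplotype_frequencies(list(A = c(`+` = 1, `-` = 0)),
                                       epistasis = FALSE)
  r <- observed_vs_expected_test(c(`+` = 5, `-` = 1), ex, mode = "asymptotic")
  expect_true(is.infinite(r$global_chi2))
  expect_true("-" %in% r$infinite_cells)
})

test_that("Monte-Carlo p values are reproducible and seed-gated", {
  ex <- expected_haplotype_frequencies(c(A = 0.6, B = 0.4), epistasis = FALSE)
  obs <- c(`+|+` = 20, `+|-` = 10, `-|+` = 5, `-|-` = 5)
  expect_error(observed_vs_expected_test(obs, ex, mode = "montecarlo"),
               "seed")
  r1 <- observed_vs_expected_test(obs, ex, mode = "montecarlo", reps = 500,
                                  seed = 7)
  r2 <- observed_vs_expected_test(obs, ex, mode = "montecarlo", reps = 500,
                                  seed = 7)
  expect_identical(r1$global_p, r2$global_p)
  expect_identical(r1$mc, list(reps = 500, seed = 7, refit = TRUE))
})

test_that("an enriched haplotype is flagged over-represented in most panels", {
  fl <- panel_config(n = 144, seed = 1)$freqs
  space <- expected_haplotype_frequencies(fl, epistasis = TRUE)
  i <- which.max(space$prob)
  pr2 <- space$prob; pr2[i] <- pr2[i] * 2; pr2 <- pr2 / sum(pr2)
  set.seed(99)
  hits <- replicate(100, {
    cnt <- drop(rmultinom(1, 144, pr2))
    names(cnt) <- space$key
    r <- observed_vs_expected_test(cnt[cnt > 0], space, mode = "asymptotic")
    r$table$direction[r$table$key == space$key[i]] == "over"
  })
  expect_gte(mean(hits), 0.8)
})
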
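test_that("threshold constructor validates its fields", {
  expect_error(caller_thresholds(dominance_ratio = 1), "dominance_ratio > 1")
  expect_error(caller_thresholds(amount_breaks = c(0.9, 0.5, 0.1)))
  expect_error(caller_thresholds(reference_total = 0), "> 0")
  expect_error(call_haplotype(gsl_profile(c(`4MSO` = 1)), caller_thresholds()),
               "reference_total")
})

test_that("alkenyl structures imply a functional AOP2", {
  th <- col0_thresholds()
  p <- gsl_profile(c(Allyl = 5, `But-3-enyl` = 10, `8MSO` = 3, I3M = 2))
  cl <- call_haplotype(p, th)
  expect_equal(cl$calls$AOP$state, "AOP2")
  expect_equal(cl$calls$GSOH$state, "-")  # butenyl without OH-butenyl
})

test_that("aliphatic-free profiles call both MYBs off and downstream loci NA", {
  th <- col0_thresholds()
  cl <- call_haplotype(gsl_profile(c(I3M = 5)), th)
  expect_equal(cl$calls$MYB28$state, "-")
  expect_equal(cl$calls$MYB29$state, "-")
  for (l in c("MAM1", "GSOX", "AOP", "GSOH"))
    expect_true(is.na(cl$calls[[l]]$state))
  expect_equal(cl$name, "myb28/myb29")
})

test_that("GSOH is only scoreable when its substrate can exist", {
  th <- col0_thresholds()
  only_mso <- call_haplotype(gsl_profile(c(`4MSO` = 20, `8MSO` = 4)), th)
  expect_true(is.na(only_mso$calls$GSOH$state))
  with_oh <- call_haplotype(
    gsl_profile(c(`But-3-enyl` = 8, `OH-But-3-enyl` = 8, `8MSO` = 4)), th)
  expect_equal(with_oh$calls$GSOH$state, "+")
  # NA-consistency: a non-NA GSOH always comes with AOP2
  pop <- gsl_population()
  for (g in pop) {
    cl <- call_haplotype(predict_profile(g, chamber_params()), th)
    if (!is.na(cl$calls$GSOH$state))
      expect_equal(cl$calls$AOP$state, "AOP2")
  }
})

test_that("calls are deterministic and names depend on states only", {
  th <- col0_thresholds()
  p <- predict_profile(gsl_population()[["AOP2"]], chamber_params())
  c1 <- call_haplotype(p, th); c2 <- call_haplotype(p, th)
  expect_identical(c1, c2)
  c2$calls$AOP$evidence <- "another trace"
  expect_identical(haplotype_name(c1), haplotype_name(c2))
})

test_that("haplotype names are Col-0-referenced", {
  th <- col0_thresholds()
  pop <- gsl_population()
  expect_equal(call_haplotype(predict_profile(pop[["Col-0"]], chamber_params()),
                              th)$name, "Col-0")
  nm28 <- call_haplotype(predict_profile(pop[["myb28"]], chamber_params()),
                         th)$name
  expect_match(nm28, "myb28")
  expect_equal(call_haplotype(predict_profile(pop[["AOP2/gsoh"]],
                                              chamber_params()), th)$name,
               "AOP2/gsoh")
})

test_that("noise-free round trips recover every population genotype", {
  pop <- gsl_population()
  for (g in pop) {
    rt <- round_trip(g)
    expect_equal(attr(rt, "agreement"), 1, info = attr(g, "label"))
  }
  # spot-check expected unobservability
  rt0 <- round_trip(pop[["Col-0"]])
  expect_true(is.na(rt0$call[rt0$locus == "GSOH"]))  # no butenyl substrate
  rt2 <- round_trip(pop[["myb28/myb29"]])
  expect_equal(sum(is.na(rt2$call)), 5)              # 4 epistatic + ESP
})

test_that("round trips stay above 95% locus agreement under lognormal noise", {
  pop <- gsl_population()
  params <- chamber_params()
  th <- col0_thresholds(params)
  set.seed(424)
  ag <- replicate(500, {
    g <- pop[[sample.int(17, 1)]]
    pr <- noisy_profile(g, params, cv = 0.2)
    attr(suppressWarnings(round_trip(g, params, th, profile = pr)),
         "agreement")
  })
  expect_gte(mean(ag), 0.95)
})

test_that("panel reference defaults to the upper-quartile total", {
  pop <- gsl_population()
  profs <- lapply(pop, predict_profile)
  ref <- estimate_reference_total(profs)
  tot <- vapply(profs, total_aliphatic, numeric(1))
  expect_equal(ref, unname(quantile(tot, 0.75)))
  calls <- call_haplotypes(profs)
  expect_length(calls, 17)
})
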
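test_that("profiles validate inputs and totals split by class", {
  expect_error(gsl_profile(c(bogus = 1)), "unknown structure")
  expect_error(gsl_profile(c(`4MSO` = -1)), ">= 0")
  p <- gsl_profile(c(`4MSO` = 10, I3M = 5))
  expect_equal(total_aliphatic(p), 10)
  expect_equal(total_indole(p), 5)
  expect_equal(total_aliphatic(gsl_profile(numeric(0))), 0)
  mixed <- gsl_profile(c(`3MSO` = 1, `8MSO` = 2, `Allyl` = 3,
                         I3M = 4, `4MI3M` = 1, NMI3M = 0.5))
  expect_equal(total_indole(mixed), 5.5)
  expect_equal(total_aliphatic(mixed), 6)
})

test_that("genotype constructor enforces the single AOP locus", {
  expect_error(gsl_genotype("bad", aop2 = TRUE, aop3 = TRUE), "alternate")
  expect_error(gsl_genotype(""), "non-empty")
  g <- parse_allele_string("+++++--+-", "Col-0")
  expect_identical(unclass(g), unclass(gsl_genotype("Col-0")))
  expect_error(parse_allele_string("+++"), "nine characters")
})

test_that("the laboratory population has 17 genotypes with the expected allele matrix", {
  pop <- gsl_population()
  expect_length(pop, 17)
  # GSOH functional in all lines except the five gsoh-carrying ones
  gsoh <- vapply(pop, function(g) unclass(g)[["gsoh"]], logical(1))
  expect_equal(sum(gsoh), 12)
  expect_false(any(gsoh[c("AOP2/gsoh", "gsoh", "myb28/gsoh",
                          "myb29/AOP2/gsoh", "myb28/myb29/gsoh")]))
  # locus-level view: GSOX locus off if either gene is off
  expect_equal(genotype_locus_states(pop[["gsox1"]])$GSOX, "-")
  expect_equal(genotype_locus_states(pop[["gsox3"]])$GSOX, "-")
  expect_equal(genotype_locus_states(pop[["AOP2"]])$AOP, "AOP2")
  expect_equal(genotype_locus_states(pop[["Col-0"]])$AOP, "null")
})

test_that("forward model hits the MYB calibration ratios exactly", {
  pop <- gsl_population()
  col0 <- total_aliphatic(predict_profile(pop[["Col-0"]]))
  expect_equal(total_aliphatic(predict_profile(pop[["myb28"]])) / col0, 0.50)
  expect_equal(total_aliphatic(predict_profile(pop[["myb29"]])) / col0, 0.75)
  expect_equal(total_aliphatic(predict_profile(pop[["myb28/myb29"]])), 0)
  # Col-0 total is the sum of the class pools
  par <- pathway_params()
  expect_equal(col0, par$base_short3C + par$base_short4C + par$base_long)
  # long chain vanishes for any myb28-nonfunctional genotype
  long_ids <- c("5MSO", "6MSO", "7MSO", "8MSO")
  for (nm in grep("myb28", names(pop), value = TRUE))
    expect_equal(sum(unclass(predict_profile(pop[[nm]]))[long_ids]), 0)
})

test_that("MYB multipliers act monotonically on total aliphatic content", {
  g <- gsl_genotype("myb28", myb28 = FALSE)
  tots <- vapply(c(0, 0.3, 0.6, 0.9), function(m)
    total_aliphatic(predict_profile(g, pathway_params(myb28_short_mult = m))),
    numeric(1))
  expect_true(all(diff(tots) >= 0))
})

test_that("side-chain conversions conserve class totals", {
  pop <- gsl_population()
  col0 <- total_aliphatic(predict_profile(pop[["Col-0"]]))
  for (nm in c("AOP2", "AOP2/gsoh", "gsm1", "gsox1", "ESP")) {
    par <- pathway_params(field_mode = FALSE)
    expect_equal(total_aliphatic(predict_profile(pop[[nm]], par)), col0,
                 info = nm)
  }
  # AOP3 conversion conserves the 3C class
  g3 <- gsl_genotype("aop3line", mam1 = FALSE, aop3 = TRUE)
  expect_equal(total_aliphatic(predict_profile(g3)), col0)
  expect_gt(unclass(predict_profile(g3))[["OH-Propyl"]], 0)
})

test_that("qualitative chemotypes follow the pathway rules", {
  pop <- gsl_population()
  expect_setequal(predict_structures(pop[["myb28/myb29"]]),
                  c("I3M", "4MI3M", "NMI3M"))
  col0 <- predict_structures(pop[["Col-0"]])
  expect_true(all(c("3MSO", "4MSO", "5MSO", "6MSO", "7MSO", "8MSO") %in% col0))
  expect_false(any(c("Allyl", "But-3-enyl") %in% col0))
  aop2 <- predict_structures(pop[["AOP2"]])
  expect_true(all(c("But-3-enyl", "OH-But-3-enyl") %in% aop2))
  expect_false("4MSO" %in% aop2)          # dominant-class MSO fully converted
  expect_false("Allyl" %in% aop2)         # minor 3C class untouched by AOP2
  # MT only in chamber mode with an impaired GSOX locus
  expect_false("3MT" %in% predict_structures(pop[["gsox1"]], field_mode = TRUE))
  expect_true("3MT" %in% predict_structures(pop[["gsox1"]], field_mode = FALSE))
  expect_false("3MT" %in% predict_structures(pop[["Col-0"]], field_mode = FALSE))
})

test_that("predicted chemotypes agree with observed field traces up to documented trace effects", {
  tc <- trace_concordance()
  exact <- tc$genotype[tc$exact]
  expect_setequal(exact, c("Col-0", "myb29", "gsox1", "gsox3", "myb28/gsm1",
                           "myb28/AOP2", "myb28/myb29", "myb28/myb29/gsoh",
                           "ESP"))
  # differences are confined to detection-level minor long-chain homologs,
  # residual precursor in essentially complete conversions, and trace
  # alkenyl in single field traces
  diffs <- unique(unlist(strsplit(
    c(tc$predicted_only, tc$observed_only), ",")))
  diffs <- diffs[nzchar(diffs)]
  expect_true(all(diffs %in% c("5MSO", "6MSO", "8MSO", "4MSO", "Allyl",
                               "But-3-enyl")))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(pathway_params(aop_conversion = 1.2), "\\[0, 1\\]")
  expect_error(pathway_params(base_long = -1), ">= 0")
  expect_error(pathway_params(long_fractions = c(`5MSO` = 1)), "distribution")
})
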
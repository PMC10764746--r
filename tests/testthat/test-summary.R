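test_that("printed dual-epistasis counts match the published summary", {
  et <- hdPrintedEffects("dualEpistasis")
  s <- summarizeSigns(et, "dualEpistasis")
  expect_identical(s$n_total, 24L)
  expect_identical(s$n_significant, 18L)
  expect_identical(s$n_negative_significant, 10L)
  expect_equal(s$frac_negative, 10 / 18)
})

test_that("printed mixed-epistasis significance fraction rounds to 90.6%", {
  s <- summarizeSigns(hdPrintedEffects("mixedEpistasis"), "mixedEpistasis")
  expect_identical(s$n_total, 32L)
  expect_identical(s$n_significant, 29L)
  expect_equal(round(100 * s$frac_significant, 1), 90.6)
  expect_identical(s$n_negative_significant, 18L)
})

test_that("printed triple-epistasis counts are reported literally", {
  # the source text says 26 significant of 32; the literal starred count is 27
  s <- summarizeSigns(hdPrintedEffects("tripleEpistasis"), "tripleEpistasis")
  expect_identical(s$n_total, 32L)
  expect_identical(s$n_significant, 27L)
  expect_identical(s$n_positive_significant, 15L)
})

test_that("a table without stars has zero significant entries", {
  rows <- list(list(kind = "dualEpistasis", id = "A-1/B-1", class = "d-d",
                    value = 3, stars = ""),
               list(kind = "dualEpistasis", id = "A-2/B-2", class = "a-a",
                    value = -2, stars = ""))
  s <- summarizeSigns(makeEffectTable(rows), "dualEpistasis")
  expect_identical(s$n_significant, 0L)
  expect_identical(s$n_total, 2L)
})

test_that("counting is idempotent and order-independent", {
  et <- hdPrintedEffects("dualEpistasis")
  s1 <- summarizeSigns(et, "dualEpistasis")
  perm <- rev(seq_len(nrow(et@effects)))
  etPerm <- new("EffectTable", effects = et@effects[perm, ],
                envValue = et@envValue[perm, ], envSE = et@envSE[perm, ],
                envP = et@envP[perm, ], envStars = et@envStars[perm, ],
                environments = et@environments, loci = et@loci,
                reference = et@reference, fit = NULL)
  expect_identical(summarizeSigns(etPerm, "dualEpistasis"), s1)
  expect_identical(summarizeSigns(et, "dualEpistasis"), s1)
})

test_that("class statistics match a direct computation", {
  rows <- list(
    list(kind = "dualEpistasis", id = "A-2/B-2", class = "a-a", value = 3, stars = "*"),
    list(kind = "dualEpistasis", id = "A-2/C-2", class = "a-a", value = 3, stars = "**"),
    list(kind = "dualEpistasis", id = "A-1/B-1", class = "d-d", value = -8, stars = "**"),
    list(kind = "dualEpistasis", id = "A-1/C-1", class = "d-d", value = -2, stars = ""))
  cs <- classStats(makeEffectTable(rows), "dualEpistasis")
  aa <- cs[cs$class == "a-a", ]
  expect_equal(aa$mean, 3); expect_equal(aa$sd, 0); expect_identical(aa$n, 2L)
  dd <- cs[cs$class == "d-d", ]
  expect_identical(dd$n, 1L)          # the nonsignificant -2 is excluded
  expect_true(is.na(dd$sd))           # single member: SD undefined
  all4 <- classStats(makeEffectTable(rows), "dualEpistasis", significantOnly = FALSE)
  expect_equal(all4[all4$class == "d-d", "mean"], -5)
})

test_that("dual-epistasis class means are computed per interaction component", {
  cs <- classStats(hdPrintedEffects("dualEpistasis"), "dualEpistasis")
  dd <- cs[cs$class == "d-d", ]
  expect_gte(dd$n, 1L)
  expect_true(is.finite(dd$mean))
  # the heterozygous-by-heterozygous components average strongly negative
  expect_lt(dd$mean, 0)
})

test_that("homeostasis report detects the sign pattern and neutralization", {
  rows <- list(
    list(kind = "additive", id = "A", class = "a", value = 4, stars = "**"),
    list(kind = "additive", id = "B", class = "a", value = 6, stars = "**"),
    list(kind = "dominance", id = "A", class = "d", value = 0, stars = ""),
    list(kind = "dominance", id = "B", class = "d", value = 0, stars = ""),
    list(kind = "pyramiding", id = "A-2/B-2", class = "a-a", value = 4, stars = "**"),
    list(kind = "dualEpistasis", id = "A-2/B-2", class = "a-a", value = -6, stars = "**"),
    list(kind = "tripleEpistasis", id = "A-1/B-1/C-1", class = "d-d-d",
         value = 2, stars = "*"))
  rep1 <- homeostasisReport(makeEffectTable(rows))
  expect_identical(rep1$pattern, "positive/negative/positive")
  pm <- rep1$perMaterial
  expect_equal(pm$singleSum, 10)
  expect_equal(pm$neutralization, 0.6)
  expect_true(pm$opposes)
})

test_that("optional multiplicity adjustment rewrites p-values and stars", {
  tm <- randomTruth(91, noise = TRUE)
  cat13 <- enumerateMaterials(c("Ehd1", "Hd3a"), 2)
  et <- fitAndDecompose(tm, cat13, seed = 13)
  adj <- adjustSignificance(et, method = "bonferroni")
  expect_true(all(adj@effects$p >= et@effects$p, na.rm = TRUE))
  expect_identical(adj@effects$stars, starsForP(adj@effects$p))
  expect_lte(sum(adj@effects$stars != "", na.rm = TRUE),
             sum(et@effects$stars != "", na.rm = TRUE))
})

test_that("zero epistasis gives zero neutralization fractions", {
  rows <- list(
    list(kind = "additive", id = "A", class = "a", value = 4, stars = "**"),
    list(kind = "additive", id = "B", class = "a", value = 6, stars = "**"),
    list(kind = "pyramiding", id = "A-2/B-2", class = "a-a", value = 10, stars = "**"),
    list(kind = "dualEpistasis", id = "A-2/B-2", class = "a-a", value = 0, stars = ""))
  rep0 <- homeostasisReport(makeEffectTable(rows))
  expect_equal(rep0$perMaterial$neutralization, 0)
  expect_false(rep0$perMaterial$opposes)
})
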
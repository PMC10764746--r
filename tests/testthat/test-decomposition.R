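printedSingles <- hdPrintedEffects(c("additive", "dominance", "pyramiding"))

test_that("dual epistasis from the printed tables reproduces the published values", {
  et <- estimateDualEpistasis(printedSingles)
  dual <- effectValues(et, "dualEpistasis")
  want <- c("Ehd1-1/Hd3a-1" = -15.2, "OsMADS50-1/Hd3a-1" = -13.5,
            "Hd3a-1/Hd1-1" = -15.3, "Ehd1-1/Hd3a-2" = 13.0,
            "Hd3a-2/Hd1-1" = 9.1)
  expect_true(all(abs(dual[names(want)] - want) <= 0.05))
  # g exactly equal to the sum of singles -> e = 0
  rows <- list(list(kind = "dominance", id = "A", class = "d", value = 2),
               list(kind = "dominance", id = "B", class = "d", value = 3),
               list(kind = "pyramiding", id = "A-1/B-1", class = "d-d", value = 5))
  et0 <- estimateDualEpistasis(makeEffectTable(rows))
  expect_equal(unname(effectValues(et0, "dualEpistasis")), 0)
})

test_that("mixed and triple epistasis close over the printed constituents", {
  et <- hdPrintedEffects(c("additive", "dominance", "pyramiding", "dualEpistasis"))
  et <- estimateMixedEpistasis(et)
  mixed <- effectValues(et, "mixedEpistasis")
  expect_lt(abs(mixed[["Ehd1-1/Hd3a-2/Hd1-1"]] - 9.9), 0.05)
  expect_lt(abs(mixed[["OsMADS50-1/Hd3a-1/Hd1-1"]] - (-16.0)), 0.05)
  et <- estimateTripleEpistasis(et)
  triple <- effectValues(et, "tripleEpistasis")
  expect_lt(abs(triple[["Ehd1-1/Hd3a-2/Hd1-1"]] - (-8.8)), 0.05)
  # a combination with an unprinted dual constituent stays undefined, not zero
  expect_true(is.na(triple[["Ehd1-2/Hd3a-2/Hd1-1"]]))
})

test_that("noise-free simulation round-trips every truth effect", {
  tm <- randomTruth(101)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  est <- fitAndDecompose(tm, cat65, seed = 1)
  tr <- truthEffects(tm, cat65)
  keys <- rownames(tr@effects)
  expect_true(all(keys %in% rownames(est@effects)))
  expect_equal(est@effects[keys, "value"], tr@effects[keys, "value"],
               tolerance = 1e-9)
  expect_equal(unname(est@envValue[keys, ]), unname(tr@envValue[keys, ]),
               tolerance = 1e-9)
})

test_that("the linear-model estimator matches the sequential differences", {
  tm <- randomTruth(55)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  plots <- simulateExperiment(tm, cat65, seed = 2)
  fit <- predictBlup(plots, quietMinque(plots))
  seq <- decomposeEffects(fit, cat65)
  lmfit <- estimateEffectsLm(fit, cat65)
  keys <- rownames(lmfit@effects)
  expect_equal(lmfit@effects[keys, "value"], seq@effects[keys, "value"],
               tolerance = 1e-9)
  expect_equal(unname(lmfit@envValue[keys, ]), unname(seq@envValue[keys, ]),
               tolerance = 1e-9)
  # permuting the material rows leaves the coefficients unchanged
  perm <- sample(nrow(materialStates(cat65)))
  catPerm <- MaterialCatalog(materialStates(cat65)[perm, ], hdLoci())
  lmPerm <- estimateEffectsLm(fit, catPerm)
  expect_equal(lmPerm@effects[keys, "value"], lmfit@effects[keys, "value"],
               tolerance = 1e-12)
})

test_that("a singles-only design fits without epistasis columns", {
  tm <- randomTruth(7)
  cat1 <- enumerateMaterials(hdLoci(), 1)
  plots <- simulateExperiment(tm, cat1, seed = 3)
  fit <- predictBlup(plots, quietMinque(plots))
  lmfit <- estimateEffectsLm(fit, cat1)
  expect_setequal(unique(lmfit@effects$kind), c("additive", "dominance"))
  seq <- estimateSingleEffects(fit, cat1)
  keys <- rownames(lmfit@effects)
  expect_equal(lmfit@effects[keys, "value"], seq@effects[keys, "value"],
               tolerance = 1e-9)
})

test_that("hierarchical identities hold exactly on computed tables", {
  tm <- randomTruth(77, noise = TRUE)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  et <- fitAndDecompose(tm, cat65, seed = 4)
  st <- materialStates(cat65)
  for (m in materialNames(cat65)[materialOrder(cat65) == 3L]) {
    g <- effectValues(et, "pyramiding")[[m]]
    s <- qtlPyramid:::.singleSums(et, st[m, ])$value
    duals <- sum(vapply(qtlPyramid:::.subCombos(st[m, ], 2L),
                        function(p) effectValues(et, "dualEpistasis")[[p]],
                        numeric(1)))
    e3 <- effectValues(et, "tripleEpistasis")[[m]]
    mixed <- effectValues(et, "mixedEpistasis")[[m]]
    expect_equal(g, s + duals + e3, tolerance = 1e-9)
    expect_equal(mixed, duals + e3, tolerance = 1e-9)
  }
  # interaction components of every effect sum to zero over environments
  expect_lt(max(abs(rowSums(et@envValue))), 1e-6)
})

test_that("significance is calibrated against the plot residual variance", {
  # truth effect ~5 d with contrast SE ~1 d: detection is near-certain
  cat3 <- enumerateMaterials("Q", 1)
  tm <- TruthModel("Q", a = c(Q = 5), d = c(Q = 5), residSd = 2, blockSd = 0.5)
  hits <- vapply(1:40, function(i) {
    et <- fitAndDecompose(tm, cat3, seed = 200 + i)
    all(et@effects[c("additive:Q", "dominance:Q"), "p"] <= 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # stars follow the star thresholds exactly
  expect_identical(starsForP(c(0.0099, 0.01, 0.049, 0.05, 0.0501, NA)),
                   c("**", "**", "*", "*", "", NA))
})

test_that("dominance degree follows the d/a convention", {
  expect_equal(dominanceDegree(4, 8)$ratio, 2)
  expect_identical(dominanceDegree(4, 8)$category, "super-dominant")
  expect_identical(dominanceDegree(2, 1)$category, "partial dominance")
  expect_equal(dominanceDegree(2.1, 2.7)$ratio, 2.7 / 2.1)
  expect_identical(dominanceDegree(0, 3)$category, "dominance only")
  expect_true(is.na(dominanceDegree(0, 3)$ratio))
})
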
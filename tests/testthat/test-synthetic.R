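test_that("genotypic value accumulates the applicable truth terms", {
  tm <- TruthModel(hdLoci(), a = c(Hd3a = 5.6), d = c(Hd1 = 1.7),
                   dualE = c("Hd3a-2/Hd1-1" = 6.6))
  expect_equal(unname(genotypicValue("HJX74", tm)), 0)
  expect_equal(unname(genotypicValue("Hd3a-2/Hd1-1", tm)), 13.9)
})

test_that("genotypic value equals an independent term-list accumulation", {
  tm <- randomTruth(11)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  got <- genotypicValue(cat65, tm)
  # brute-force oracle: walk an explicit (term, member-set) list
  terms <- list()
  for (L in lociNames(cat65)) {
    terms[[paste0(L, "-2")]] <- tm@a[[L]]
    terms[[paste0(L, "-1")]] <- tm@d[[L]]
  }
  for (k in names(tm@dualE)) terms[[k]] <- tm@dualE[[k]]
  for (k in names(tm@tripleE)) terms[[k]] <- tm@tripleE[[k]]
  st <- materialStates(cat65)
  for (m in materialNames(cat65)) {
    tokens <- unlist(lapply(names(terms), function(key) {
      kst <- parseMaterialId(key)[1, ]
      if (all(kst == 0 | kst == st[m, ])) terms[[key]] else NULL
    }))
    expect_equal(unname(got[[m]]), sum(tokens), tolerance = 1e-12)
  }
})

test_that("noise-free generation is exactly mu + E + G per plot", {
  tm <- TruthModel(hdLoci(), mu = 80, envEffects = c(e1 = -4, e2 = 7, e3 = -3),
                   a = c(Hd3a = 5.6, OsMADS50 = -6.1),
                   d = c(Ehd1 = 2.7, Hd1 = 1.7))
  cat65 <- enumerateMaterials(hdLoci(), 3)
  plots <- simulateExperiment(tm, cat65, blocksPerEnv = 2)
  G <- genotypicValue(cat65, tm)
  expect_equal(plots$hd,
               unname(80 + tm@envEffects[plots$env] + G[plots$material]))
})

test_that("the reference design yields 585 plot records, deterministically", {
  tm <- hdTruthPreset()
  cat65 <- enumerateMaterials(hdLoci(), 3)
  p1 <- simulateExperiment(tm, cat65, blocksPerEnv = 3, seed = 99)
  p2 <- simulateExperiment(tm, cat65, blocksPerEnv = 3, seed = 99)
  expect_identical(nrow(p1), 585L)
  expect_identical(p1, p2)
  f1 <- tempfile(); f2 <- tempfile()
  writePlotTable(p1, f1); writePlotTable(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(p1, simulateExperiment(tm, cat65, seed = 100)))
})

test_that("an empty materials list is rejected", {
  tm <- hdTruthPreset()
  empty <- new("MaterialCatalog",
               states = matrix(integer(), 0, 4,
                               dimnames = list(character(), hdLoci()$name)),
               loci = hdLoci())
  expect_error(simulateExperiment(tm, empty), "empty")
})

test_that("simulated genotype spread matches the truth-implied variance", {
  tm <- randomTruth(21)
  cat65 <- enumerateMaterials(hdLoci(), 3)
  plots <- simulateExperiment(tm, cat65, seed = 1)  # noise-free truth
  gMean <- tapply(plots$hd, plots$material, mean)
  expect_equal(unname(var(gMean)),
               unname(var(genotypicValue(cat65, tm) +
                          rowMeans(interactionValue(cat65, tm)))),
               tolerance = 1e-10)
})

test_that("geTerms rows that do not sum to zero are rejected", {
  bad <- matrix(c(1, 1, 1), 1, 3,
                dimnames = list("Hd3a-2", c("e1", "e2", "e3")))
  expect_error(TruthModel(hdLoci(), geTerms = bad), "sum to zero")
})
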
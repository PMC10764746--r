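test_that("ANOVA degrees of freedom and sums of squares are consistent", {
  plots <- simulateVarianceModel(nMaterials = 10, blocksPerEnv = 3, seed = 5)
  an <- fitAnova(plots)
  lay <- attr(an, "layout")
  expect_equal(an$df[an$source == "genotype:environment"],
               (lay$H - 1L) * (lay$J - 1L))
  expect_equal(sum(an$df), lay$N - 1L)
  tot <- sum((plots$hd - mean(plots$hd))^2)
  expect_equal(sum(an$ss), tot, tolerance = 1e-8)
})

test_that("ANOVA mean squares match an independent linear-model computation", {
  plots <- simulateVarianceModel(nMaterials = 8, blocksPerEnv = 2, seed = 17)
  an <- fitAnova(plots)
  blkf <- interaction(plots$env, plots$block, drop = TRUE)
  ref <- anova(lm(hd ~ env + blkf + material + env:material, data = plots))
  want <- c(environments = "env", blocks = "blkf", genotypes = "material",
            `genotype:environment` = "env:material", error = "Residuals")
  for (src in names(want)) {
    expect_equal(an$ss[an$source == src],
                 ref[want[[src]], "Sum Sq"], tolerance = 1e-8,
                 label = src)
    expect_equal(an$df[an$source == src], ref[want[[src]], "Df"], label = src)
  }
})

test_that("noise-free data give zero error mean square and huge genotype F", {
  cat27 <- enumerateMaterials(c("A", "B", "C"), 3)
  tm2 <- randomTruth(3, loci = c("A", "B", "C"))
  plots <- simulateExperiment(tm2, cat27, seed = 1)
  an <- fitAnova(plots)
  expect_lt(an$ms[an$source == "error"], 1e-10)
  expect_gt(an$ms[an$source == "genotypes"], 1)
})

test_that("MINQUE(1) equals the ANOVA/EMS solution on balanced designs", {
  for (seed in c(2, 31)) {
    plots <- simulateVarianceModel(nMaterials = 12, seed = seed)
    m <- quietMinque(plots)
    a <- suppressWarnings(estimateVarianceAnova(plots))
    expect_equal(m@raw, a@raw, tolerance = 1e-8)
  }
})

test_that("a null genotypic component is estimated near zero", {
  plots <- simulateVarianceModel(sigma2 = c(G = 0, GE = 0, B = 1, e = 4),
                                 nMaterials = 20, seed = 8)
  vc <- quietMinque(plots)
  expect_lt(abs(vc@raw[["G"]]), 1)
  expect_equal(vc@sigma2[["G"]], max(0, vc@raw[["G"]]))
})

test_that("invalid priors are rejected and truncation is flagged", {
  plots <- simulateVarianceModel(nMaterials = 6, seed = 1)
  expect_error(estimateVarianceMinque(plots, priors = c(G = 0, GE = 1, B = 1, e = 1)),
               "strictly positive")
  plots0 <- simulateVarianceModel(sigma2 = c(G = 9, GE = 0, B = 0, e = 1),
                                  nMaterials = 6, seed = 7)
  expect_warning(estimateVarianceMinque(plots0), "truncated")
})

test_that("BLUP predictions are centred and shrink toward zero", {
  plots <- simulateVarianceModel(nMaterials = 15, seed = 12)
  fit <- predictBlup(plots, quietMinque(plots))
  expect_lt(abs(sum(fit@G)), 1e-6)
  expect_lt(max(abs(rowSums(fit@GE))), 1e-6)
  expect_lt(max(abs(colSums(fit@GE))), 1e-6)
  dev <- fit@gMean - mean(fit@gMean)
  expect_true(all(abs(fit@G) <= abs(dev) + 1e-8))
})

test_that("zero genotypic variance gives all-zero genotype predictions", {
  plots <- simulateVarianceModel(nMaterials = 8, seed = 3)
  vc <- new("VarianceComponents", sigma2 = c(G = 0, GE = 1, B = 1, e = 2),
            raw = c(G = 0, GE = 1, B = 1, e = 2), method = "ANOVA-EMS",
            truncated = c(G = FALSE, GE = FALSE, B = FALSE, e = FALSE))
  fit <- predictBlup(plots, vc)
  expect_true(all(fit@G == 0))
  vc0 <- new("VarianceComponents", sigma2 = c(G = 0, GE = 0, B = 0, e = 2),
             raw = c(G = 0, GE = 0, B = 0, e = 2), method = "ANOVA-EMS",
             truncated = c(G = FALSE, GE = FALSE, B = FALSE, e = FALSE))
  expect_warning(fit0 <- predictBlup(plots, vc0), "zero")
  expect_true(all(fit0@G == 0) && all(fit0@GE == 0))
})

test_that("BLUP approaches the centred genotype means as residual noise vanishes", {
  plots <- simulateVarianceModel(nMaterials = 10, seed = 9)
  vc <- new("VarianceComponents",
            sigma2 = c(G = 10, GE = 1, B = 1, e = 1e-9),
            raw = c(G = 10, GE = 1, B = 1, e = 1e-9), method = "ANOVA-EMS",
            truncated = c(G = FALSE, GE = FALSE, B = FALSE, e = FALSE))
  fit <- predictBlup(plots, vc)
  expect_equal(unname(fit@G), unname(fit@gMean - mean(fit@gMean)),
               tolerance = 1e-5)
})

test_that("BLUP is invariant to a constant phenotype shift", {
  plots <- simulateVarianceModel(nMaterials = 10, seed = 14)
  vc <- quietMinque(plots)
  fit1 <- predictBlup(plots, vc)
  plots2 <- plots; plots2$hd <- plots2$hd + 100
  fit2 <- predictBlup(plots2, vc)
  expect_equal(fit1@G, fit2@G, tolerance = 1e-8)
  expect_equal(fit1@GE, fit2@GE, tolerance = 1e-8)
  expect_equal(fit2@mu - fit1@mu, 100, tolerance = 1e-8)
})

test_that("heritability is the component share of plot phenotypic variance", {
  vc <- new("VarianceComponents",
            sigma2 = c(G = 31.78, GE = 1.27, B = 0, e = 66.95),
            raw = c(G = 31.78, GE = 1.27, B = 0, e = 66.95),
            method = "ANOVA-EMS",
            truncated = c(G = FALSE, GE = FALSE, B = FALSE, e = FALSE))
  h <- heritability(vc)
  expect_equal(unname(h), c(0.3178, 0.0127), tolerance = 1e-12)
  vc@sigma2[["GE"]] <- 0
  expect_equal(heritability(vc)[["peculiar"]], 0)
  vc0 <- vc; vc0@sigma2[] <- 0
  expect_error(heritability(vc0), "undefined")
  # entry-mean basis divides interaction and plot terms by their replication
  hm <- heritability(vc, basis = "mean", layout = list(H = 3, K = 3))
  expect_gt(hm[["general"]], h[["general"]])
})
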
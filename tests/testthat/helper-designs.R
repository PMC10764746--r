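# Shared builders for simulated designs and truth models.

quietMinque <- function(plots, ...) suppressWarnings(estimateVarianceMinque(plots, ...))

# a seeded truth model with every effect and interaction term nonzero
randomTruth <- function(seed, loci = hdLoci()$name, noise = FALSE) {
  set.seed(seed)
  cat3 <- enumerateMaterials(loci, min(3L, length(loci)))
  ord <- materialOrder(cat3)
  pairIds <- materialNames(cat3)[ord == 2L]
  tripleIds <- materialNames(cat3)[ord == 3L]
  envs <- c("e1", "e2", "e3")
  keys <- c(paste0(rep(loci, each = 2), "-", 1:2), pairIds, tripleIds)
  ge <- matrix(rnorm(length(keys) * 3, 0, 1.5), length(keys), 3,
               dimnames = list(keys, envs))
  ge <- ge - rowMeans(ge)
  TruthModel(
    loci = loci, mu = 80 + rnorm(1),
    envEffects = setNames(rnorm(3, 0, 4), envs),
    a = setNames(rnorm(length(loci), 0, 4), loci),
    d = setNames(rnorm(length(loci), 0, 4), loci),
    dualE = setNames(rnorm(length(pairIds), 0, 5), pairIds),
    tripleE = setNames(rnorm(length(tripleIds), 0, 5), tripleIds),
    geTerms = ge,
    blockSd = if (noise) 1 else 0,
    residSd = if (noise) 1.5 else 0)
}

# full fit + decomposition for one simulated experiment
fitAndDecompose <- function(truth, materials, seed, blocksPerEnv = 3L) {
  plots <- simulateExperiment(truth, materials, blocksPerEnv = blocksPerEnv,
                              seed = seed)
  fit <- predictBlup(plots, quietMinque(plots))
  decomposeEffects(fit, materials)
}

# a small effect table built directly from rows (for summary/format tests)
makeEffectTable <- function(rows, environments = c("e1", "e2", "e3"),
                            loci = c("A", "B", "C"), reference = "HJX74") {
  qtlPyramid:::.rowsToEffectTable(rows, environments, loci, reference, fit = NULL)
}
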
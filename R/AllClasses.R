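## Central S4 classes for the pyramiding analysis.

.EFFECT_KINDS <- c("additive", "dominance", "pyramiding",
                   "dualEpistasis", "mixedEpistasis", "tripleEpistasis")

#' MaterialCatalog: the genotype catalog of a substitution-line study
#'
#' Each material (line) is identified by its per-locus substitution state:
#' 0 = recipient allele absent of any donor segment, 1 = heterozygous donor
#' segment, 2 = homozygous donor segment.  The recipient itself is the
#' all-zero material.  Two materials with identical state vectors are the
#' same material, so state rows are unique by construction.
#'
#' @slot states integer matrix, materials x loci, values in 0/1/2, rownames
#'   are canonical material identifiers (see [materialId()]).
#' @slot loci data.frame of locus metadata with at least a `name` column
#'   (optionally `code` and `donor`).
#'
#' @seealso [enumerateMaterials()], [hdLoci()]
#' @export
setClass("MaterialCatalog",
  representation(states = "matrix", loci = "data.frame"))

setValidity("MaterialCatalog", function(object) {
  st <- object@states
  msg <- character()
  if (!is.numeric(st)) msg <- c(msg, "'states' must be a numeric matrix")
  if (nrow(st) > 0L && (is.null(rownames(st)) || anyDuplicated(rownames(st))))
    msg <- c(msg, "material identifiers must be unique row names")
  if (!all(st %in% 0:2)) msg <- c(msg, "states must be 0 (absent), 1 (het) or 2 (hom)")
  if (!identical(colnames(st), object@loci$name))
    msg <- c(msg, "column names of 'states' must equal loci$name")
  if (anyDuplicated(object@loci$name)) msg <- c(msg, "locus names must be unique")
  if (anyDuplicated(apply(st, 1L, paste, collapse = ",")))
    msg <- c(msg, "duplicated state vectors: identical materials listed twice")
  if (length(msg)) msg else TRUE
})

#' TruthModel: generating parameters for a synthetic pyramiding trial
#'
#' Holds every term of the simulated model
#' \eqn{y_{hjk} = \mu + E_h + G_j + GE_{hj} + B_{k/h} + e_{hjk}} together with
#' the genetic decomposition of \eqn{G_j}: per-locus additive (`a`, the
#' homozygote deviation from the recipient) and dominance (`d`, the
#' heterozygote deviation), dual- and triple-locus epistasis keyed by the
#' canonical material identifier of the interacting state combination, and
#' per-effect environment-interaction deviations (`geTerms`, each row summing
#' to zero over environments).  All units are days.
#'
#' @slot mu grand mean heading date of the recipient, days.
#' @slot envEffects named numeric, fixed environment shifts, days.
#' @slot blockSd standard deviation of block-within-environment effects, days.
#' @slot residSd standard deviation of the plot residual, days.
#' @slot a,d named numeric over loci, days.
#' @slot dualE named numeric over order-2 material identifiers, days.
#' @slot tripleE named numeric over order-3 material identifiers, days.
#' @slot geTerms numeric matrix (effect keys x environments); row keys are
#'   material identifiers: `"L-2"` rows are additive-by-environment terms,
#'   `"L-1"` dominance-by-environment, pair/triple identifiers are
#'   epistasis-by-environment.  Each row sums to zero.
#' @slot loci character, locus names in catalog order.
#' @export
setClass("TruthModel",
  representation(mu = "numeric", envEffects = "numeric", blockSd = "numeric",
                 residSd = "numeric", a = "numeric", d = "numeric",
                 dualE = "numeric", tripleE = "numeric", geTerms = "matrix",
                 loci = "character"))

setValidity("TruthModel", function(object) {
  msg <- character()
  if (object@blockSd < 0 || object@residSd < 0)
    msg <- c(msg, "blockSd and residSd must be nonnegative")
  if (is.null(names(object@envEffects)) || length(object@envEffects) < 1L)
    msg <- c(msg, "envEffects must be a named vector of environments")
  if (!setequal(names(object@a), object@loci) || !setequal(names(object@d), object@loci))
    msg <- c(msg, "'a' and 'd' must be named over the loci")
  if (nrow(object@geTerms)) {
    if (!identical(colnames(object@geTerms), names(object@envEffects)))
      msg <- c(msg, "geTerms columns must match the environments")
    bad <- abs(rowSums(object@geTerms)) > 1e-8
    if (any(bad))
      msg <- c(msg, paste0("geTerms rows must sum to zero over environments: ",
                           paste(rownames(object@geTerms)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' VarianceComponents: plot-basis variance components of the mixed model
#'
#' @slot sigma2 named numeric `c(G=, GE=, B=, e=)`, days^2, after the
#'   nonnegativity truncation policy.
#' @slot raw the untruncated solutions of the estimating equations.
#' @slot method `"MINQUE1"` or `"ANOVA-EMS"`.
#' @slot truncated named logical, which components were truncated to zero.
#' @export
setClass("VarianceComponents",
  representation(sigma2 = "numeric", raw = "numeric", method = "character",
                 truncated = "logical"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  want <- c("G", "GE", "B", "e")
  if (!identical(names(object@sigma2), want))
    msg <- c(msg, "sigma2 must be named c(G, GE, B, e)")
  if (any(object@sigma2 < 0)) msg <- c(msg, "truncated components must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' MixedModelFit: fixed estimates, BLUPs and testing context for one trial
#'
#' Produced by [predictBlup()].  `G` and `GE` are the BLUP predictions of the
#' realized genotypic and genotype-by-environment effects, identified by the
#' usual sum-to-zero conventions (`sum(G) = 0`; `GE` rows and columns centred,
#' the absorbed means being folded into `G`, `envEffects` and `mu`).
#' `gMean`/`cellMean` are the unshrunken genotype and genotype-by-environment
#' means on which significance tests of effect contrasts are based, together
#' with the residual variance `sigma2e` and its degrees of freedom `dfe`.
#'
#' @export
setClass("MixedModelFit",
  representation(mu = "numeric", envEffects = "numeric", G = "numeric",
                 GE = "matrix", B = "numeric", vc = "VarianceComponents",
                 gMean = "numeric", cellMean = "matrix", sigma2e = "numeric",
                 dfe = "numeric", nEnv = "integer", nBlocks = "integer",
                 anova = "data.frame"))

setValidity("MixedModelFit", function(object) {
  msg <- character()
  if (!identical(names(object@G), rownames(object@GE)))
    msg <- c(msg, "G names and GE rownames must agree")
  if (!identical(names(object@envEffects), colnames(object@GE)))
    msg <- c(msg, "environment labels of envEffects and GE must agree")
  if (length(msg)) msg else TRUE
})

#' EffectTable: the hierarchical decomposition of genotypic effects
#'
#' The machine form of the study's effect tables: one row per estimated
#' effect, identified by `kind` (additive, dominance, pyramiding,
#' dualEpistasis, mixedEpistasis, tripleEpistasis) and `id` (a locus name for
#' singles, a canonical material identifier otherwise), with the
#' additive/dominance composition string `class` (e.g. `"d-a"` for a
#' heterozygous-by-homozygous pair), the effect `value` in days, its standard
#' error, p-value and significance stars, and per-environment interaction
#' values (deviation coded, summing to zero over environments for computed
#' tables) in the `envValue`/`envSE`/`envP`/`envStars` matrices.
#'
#' Tables read from printed reports carry `NA` standard errors; tables
#' produced from a [MixedModelFit()] keep the fit in `@fit` so that derived
#' operations can attach significance tests.
#'
#' @export
setClass("EffectTable",
  representation(effects = "data.frame", envValue = "matrix", envSE = "matrix",
                 envP = "matrix", envStars = "matrix",
                 environments = "character", loci = "character",
                 reference = "character", fit = "ANY"))

setValidity("EffectTable", function(object) {
  eff <- object@effects
  msg <- character()
  need <- c("kind", "id", "class", "value", "se", "p", "stars")
  if (!all(need %in% names(eff)))
    msg <- c(msg, paste("effects must have columns", paste(need, collapse = ", ")))
  else {
    if (!all(eff$kind %in% .EFFECT_KINDS))
      msg <- c(msg, "unknown effect kind")
    if (anyDuplicated(paste(eff$kind, eff$id)))
      msg <- c(msg, "duplicated (kind, id) effect rows")
    ok <- !is.na(eff$p)
    expect <- ifelse(eff$p[ok] <= 0.01, "**", ifelse(eff$p[ok] <= 0.05, "*", ""))
    if (!all(eff$stars[ok] == expect, na.rm = TRUE))
      msg <- c(msg, "stars inconsistent with p (** iff p<=0.01, * iff 0.01<p<=0.05)")
  }
  for (nm in c("envValue", "envSE", "envP")) {
    m <- slot(object, nm)
    if (nrow(m) != nrow(eff) || ncol(m) != length(object@environments))
      msg <- c(msg, paste(nm, "must be effects x environments"))
  }
  if (length(msg)) msg else TRUE
})
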
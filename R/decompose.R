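## Hierarchical decomposition of genotypic effects into the study's tables.

## contrast over genotype means for each decomposition level, by
## inclusion-exclusion over sub-combinations of the material's states
.contrastFor <- function(kind, id, loci, reference) {
  if (kind == "additive")
    return(stats::setNames(c(1, -1), c(paste0(id, "-2"), reference)))
  if (kind == "dominance")
    return(stats::setNames(c(1, -1), c(paste0(id, "-1"), reference)))
  st <- drop(parseMaterialId(id, loci))
  singles <- paste0(names(st)[st != 0], "-", st[st != 0])
  k <- length(singles)
  switch(kind,
    pyramiding = stats::setNames(c(1, -1), c(id, reference)),
    dualEpistasis = ,
    mixedEpistasis = stats::setNames(c(1, rep(-1, k), k - 1),
                                     c(id, singles, reference)),
    tripleEpistasis = stats::setNames(
      c(1, rep(-1, 3), rep(1, 3), -1),
      c(id, .subCombos(st, 2L), singles, reference)),
    stop("unknown effect kind: ", kind))
}

.classOf <- function(states) paste(c("d", "a")[states[states != 0]], collapse = "-")

.effectRow <- function(et, kind, id, class, value, env) {
  row <- list(kind = kind, id = id, class = class, value = unname(value),
              env = env)
  if (!is.null(et@fit)) {
    cs <- tryCatch(
      .contrastStats(et@fit, .contrastFor(kind, id, et@loci, et@reference)),
      error = function(e) NULL)  # constituent material absent: no test
    if (!is.null(cs)) {
      row$se <- cs$se; row$p <- cs$p; row$stars <- cs$stars
      row$envSE <- cs$envSE; row$envP <- cs$envP; row$envStars <- cs$envStars
    }
  }
  row
}

#' Additive and dominance effects of single loci
#'
#' In the substitution-line convention the additive effect `a` of a locus is
#' the deviation of its homozygous single-segment line from the recipient
#' and the dominance effect `d` the deviation of the heterozygote:
#' \eqn{a = G(\mathrm{hom}) - G(\mathrm{recipient})},
#' \eqn{d = G(\mathrm{het}) - G(\mathrm{recipient})}.  The same contrasts
#' applied to the per-environment interaction predictions give the
#' additive-by-environment and dominance-by-environment components, which
#' are deviation coded and sum to zero over environments.  A locus whose
#' single-locus material is absent from the design gets an `NA` (not zero)
#' effect.
#'
#' @param fit a [MixedModelFit].
#' @param materials the [MaterialCatalog] of the design (must contain the
#'   recipient).
#' @param reference identifier of the recipient material.
#' @return an [EffectTable] with `additive` and `dominance` rows.
#' @export
estimateSingleEffects <- function(fit, materials, reference = "HJX74") {
  mats <- names(fit@G)
  if (!reference %in% mats) stop("recipient '", reference, "' absent from the fit")
  loci <- lociNames(materials)
  envs <- colnames(fit@GE)
  et0 <- .rowsToEffectTable(list(), envs, loci, reference, fit = fit)
  rows <- list()
  for (L in loci) {
    for (state in c(2L, 1L)) {
      kind <- if (state == 2L) "additive" else "dominance"
      cls <- if (state == 2L) "a" else "d"
      id1 <- paste0(L, "-", state)
      if (id1 %in% mats) {
        value <- fit@G[[id1]] - fit@G[[reference]]
        env <- fit@GE[id1, ] - fit@GE[reference, ]
        rows[[length(rows) + 1L]] <- .effectRow(et0, kind, L, cls, value, env)
      } else {
        rows[[length(rows) + 1L]] <- list(kind = kind, id = L, class = cls,
                                          value = NA_real_,
                                          env = rep(NA_real_, length(envs)))
      }
    }
  }
  .rowsToEffectTable(rows, envs, loci, reference, fit = fit)
}

#' Pyramiding effects of multi-locus materials
#'
#' The pyramiding effect `g` of a dual- or triple-QTL material is its
#' deviation from the recipient, \eqn{g = G(m) - G(\mathrm{recipient})};
#' the same contrast on the interaction predictions gives the `ge`
#' components per environment.
#'
#' @inheritParams estimateSingleEffects
#' @return an [EffectTable] with one `pyramiding` row per order >= 2 material.
#' @export
estimatePyramidingEffects <- function(fit, materials, reference = "HJX74") {
  mats <- names(fit@G)
  if (!reference %in% mats) stop("recipient '", reference, "' absent from the fit")
  loci <- lociNames(materials)
  envs <- colnames(fit@GE)
  st <- materialStates(materials)
  ord <- materialOrder(materials)
  et0 <- .rowsToEffectTable(list(), envs, loci, reference, fit = fit)
  ids <- rownames(st)[ord >= 2L & rownames(st) %in% mats]
  rows <- lapply(ids, function(m)
    .effectRow(et0, "pyramiding", m, .classOf(st[m, ]),
               fit@G[[m]] - fit@G[[reference]],
               fit@GE[m, ] - fit@GE[reference, ]))
  .rowsToEffectTable(rows, envs, loci, reference, fit = fit)
}

## sum of the single-QTL effect rows entering one material; NA if any is NA
.singleSums <- function(et, states) {
  idx <- which(states != 0)
  vals <- numeric(0); envs <- 0
  for (i in idx) {
    s <- .singleEffectOf(et, names(states)[i], states[i])
    vals <- c(vals, s$value)
    envs <- envs + s$env
  }
  list(value = sum(vals), env = envs)
}

#' Dual-QTL epistatic effects
#'
#' The epistasis between the two substituted loci of an order-2 material is
#' the residual of its pyramiding effect after removing the single-QTL
#' effects: \eqn{e = g(m) - \sum_{\mathrm{loci}} s(\mathrm{locus, state})},
#' where a heterozygous locus contributes its dominance and a homozygous
#' locus its additive effect.  The per-environment `ee` components are the
#' analogous residuals of `ge` on `ae`/`de`.  Constituent single effects are
#' carried at their estimated values even when not significant — they are
#' never zeroed.  A missing constituent leaves that epistasis undefined
#' (`NA`).
#'
#' @param et an [EffectTable] containing single and pyramiding rows (from
#'   [estimateSingleEffects()]/[estimatePyramidingEffects()], or a printed
#'   report such as [hdPrintedEffects()]).
#' @return `et` with `dualEpistasis` rows appended.
#' @export
estimateDualEpistasis <- function(et) {
  pyr <- et@effects[et@effects$kind == "pyramiding", , drop = FALSE]
  ids <- pyr$id[materialOrder(pyr$id) == 2L]
  if (!length(ids)) return(et)
  rows <- lapply(ids, function(m) {
    st <- drop(parseMaterialId(m, et@loci))
    s <- .singleSums(et, st)
    .effectRow(et, "dualEpistasis", m, .classOf(st),
               .etValue(et, "pyramiding", m) - s$value,
               .etEnv(et, "pyramiding", m) - s$env)
  })
  .rbindET(et, .rowsToEffectTable(rows, et@environments, et@loci,
                                  et@reference, fit = et@fit))
}

#' Mixed epistatic effects of triple-QTL materials
#'
#' The mixed epistasis of an order-3 material bundles all its dual-QTL
#' interactions with the pure triple interaction: the residual of the
#' pyramiding effect after removing the three single-QTL effects only,
#' \eqn{e_{mixed} = g(m) - \sum s(\mathrm{locus, state})}.
#'
#' @inheritParams estimateDualEpistasis
#' @return `et` with `mixedEpistasis` rows appended.
#' @export
estimateMixedEpistasis <- function(et) {
  pyr <- et@effects[et@effects$kind == "pyramiding", , drop = FALSE]
  ids <- pyr$id[materialOrder(pyr$id) == 3L]
  if (!length(ids)) return(et)
  rows <- lapply(ids, function(m) {
    st <- drop(parseMaterialId(m, et@loci))
    s <- .singleSums(et, st)
    .effectRow(et, "mixedEpistasis", m, .classOf(st),
               .etValue(et, "pyramiding", m) - s$value,
               .etEnv(et, "pyramiding", m) - s$env)
  })
  .rbindET(et, .rowsToEffectTable(rows, et@environments, et@loci,
                                  et@reference, fit = et@fit))
}

#' Triple-QTL epistatic effects
#'
#' The pure three-locus interaction of an order-3 material: the residual of
#' its pyramiding effect after removing the single-QTL effects and the
#' three dual-QTL epistases of its sub-pairs, equivalently
#' \eqn{e_3 = e_{mixed} - \sum_{\mathrm{pairs}} e_{dual}}.  Requires mixed
#' and dual rows (run [estimateMixedEpistasis()] and
#' [estimateDualEpistasis()] first); a missing dual constituent leaves the
#' triple epistasis undefined (`NA`).
#'
#' @inheritParams estimateDualEpistasis
#' @return `et` with `tripleEpistasis` rows appended.
#' @export
estimateTripleEpistasis <- function(et) {
  kinds <- unique(et@effects$kind)
  mix <- et@effects[et@effects$kind == "mixedEpistasis", , drop = FALSE]
  ids <- mix$id
  if (!length(ids)) {
    if (any(materialOrder(et@effects$id[et@effects$kind == "pyramiding"]) == 3L))
      stop("mixed-epistasis rows are required first; run estimateMixedEpistasis()")
    return(et)
  }
  if (!"dualEpistasis" %in% kinds)
    stop("dual-epistasis rows are required first; run estimateDualEpistasis()")
  rows <- lapply(ids, function(m) {
    st <- drop(parseMaterialId(m, et@loci))
    pairs <- .subCombos(st, 2L)
    dualV <- vapply(pairs, function(pid) .etValue(et, "dualEpistasis", pid), numeric(1))
    dualE <- rowSums(vapply(pairs, function(pid) .etEnv(et, "dualEpistasis", pid),
                            numeric(length(et@environments))))
    .effectRow(et, "tripleEpistasis", m, .classOf(st),
               .etValue(et, "mixedEpistasis", m) - sum(dualV),
               .etEnv(et, "mixedEpistasis", m) - dualE)
  })
  .rbindET(et, .rowsToEffectTable(rows, et@environments, et@loci,
                                  et@reference, fit = et@fit))
}

#' Full hierarchical decomposition of a fitted trial
#'
#' Chains [estimateSingleEffects()], [estimatePyramidingEffects()],
#' [estimateDualEpistasis()], [estimateMixedEpistasis()] and
#' [estimateTripleEpistasis()] into the complete effect table.
#'
#' @inheritParams estimateSingleEffects
#' @return an [EffectTable] covering all six effect kinds.
#' @examples
#' tm <- hdTruthPreset(residSd = 0, blockSd = 0)
#' cat65 <- enumerateMaterials()
#' fit <- predictBlup(simulateExperiment(tm, cat65, seed = 1))
#' et <- decomposeEffects(fit, cat65)
#' head(effectValues(et, "dualEpistasis"))
#' @export
decomposeEffects <- function(fit, materials, reference = "HJX74") {
  et <- .rbindET(estimateSingleEffects(fit, materials, reference),
                 estimatePyramidingEffects(fit, materials, reference))
  et <- estimateDualEpistasis(et)
  et <- estimateMixedEpistasis(et)
  estimateTripleEpistasis(et)
}

#' Least-squares estimation of the hierarchical decomposition
#'
#' Regresses the predicted genotypic values on the hierarchical indicator
#' design: an intercept (the recipient), one additive and one dominance
#' indicator per locus, one indicator per dual locus-state combination and
#' one per triple combination occurring in the design.  On the saturated
#' design this linear model reproduces the sequential difference estimates
#' exactly; the same fit applied to each environment's interaction
#' predictions yields the by-environment components.
#'
#' @inheritParams estimateSingleEffects
#' @return an [EffectTable] with `additive`, `dominance`, `dualEpistasis`
#'   and `tripleEpistasis` rows (the linear model's coefficients).
#' @export
estimateEffectsLm <- function(fit, materials, reference = "HJX74") {
  st <- materialStates(materials)
  mats <- intersect(rownames(st), names(fit@G))
  st <- st[mats, , drop = FALSE]
  loci <- lociNames(materials)
  envs <- colnames(fit@GE)
  ord <- rowSums(st != 0)
  pairCols <- unique(unlist(lapply(mats[ord >= 2L], function(m) .subCombos(st[m, ], 2L))))
  tripleCols <- unique(unlist(lapply(mats[ord >= 3L], function(m) .subCombos(st[m, ], 3L))))
  cols <- c("(recipient)",
            unlist(lapply(loci, function(L) paste0(L, c("-2", "-1")))),
            pairCols, tripleCols)
  X <- matrix(0, length(mats), length(cols), dimnames = list(mats, cols))
  X[, "(recipient)"] <- 1
  for (m in mats) {
    s <- st[m, ]
    for (key in .truthKeys(s)) X[m, key] <- 1
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient hierarchical design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qrX, fit@G[mats])
  betaEnv <- qr.coef(qrX, fit@GE[mats, , drop = FALSE])
  et0 <- .rowsToEffectTable(list(), envs, loci, reference, fit = fit)
  rowFor <- function(col) {
    if (col == "(recipient)") return(NULL)
    s <- drop(parseMaterialId(col, loci))
    k <- sum(s != 0)
    kind <- if (k == 1L) { if (any(s == 2L)) "additive" else "dominance" }
            else if (k == 2L) "dualEpistasis" else "tripleEpistasis"
    id <- if (k == 1L) names(s)[s != 0] else col
    .effectRow(et0, kind, id, .classOf(s), beta[[col]], betaEnv[col, ])
  }
  rows <- Filter(Negate(is.null), lapply(cols, rowFor))
  .rowsToEffectTable(rows, envs, loci, reference, fit = fit)
}
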
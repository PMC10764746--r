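## Ground-truth generating model for synthetic pyramiding trials.

#' Construct a TruthModel
#'
#' Defines the generating parameters of a simulated multi-environment
#' randomized-block trial of substitution-line pyramids.  Effects follow the
#' substitution-line convention throughout: `a` is the deviation of the
#' homozygous single-segment line from the recipient, `d` the deviation of
#' the heterozygote (not the classical midparent parameterization), dual and
#' triple epistasis are residual deviations of pyramids from the sum of
#' their lower-order terms.  Environment-interaction terms (`geTerms`) are
#' deviations that sum to zero over environments.
#'
#' @param loci locus names (character) or locus metadata data.frame.
#' @param mu recipient grand mean, days.
#' @param envEffects named numeric of fixed environment shifts, days.
#' @param a,d named numeric per-locus effects, days; unnamed loci get 0.
#' @param dualE named numeric over order-2 material identifiers
#'   (e.g. `"Ehd1-1/Hd3a-2"`), days; missing combinations are 0.
#' @param tripleE named numeric over order-3 material identifiers, days.
#' @param geTerms numeric matrix (effect keys x environments); see
#'   [TruthModel-class].  `NULL` means no genotype-by-environment interaction.
#' @param blockSd,residSd standard deviations of block and plot-residual
#'   effects, days.
#' @return a [TruthModel].
#' @examples
#' tm <- TruthModel(c("Hd3a", "Hd1"), a = c(Hd3a = 5.6), d = c(Hd1 = 1.7),
#'                  dualE = c("Hd3a-2/Hd1-1" = 6.6))
#' genotypicValue("Hd3a-2/Hd1-1", tm)
#' @export
TruthModel <- function(loci = hdLoci(), mu = 80,
                       envEffects = c(e1 = 0, e2 = 0, e3 = 0),
                       a = numeric(), d = numeric(),
                       dualE = numeric(), tripleE = numeric(),
                       geTerms = NULL, blockSd = 0, residSd = 0) {
  loci <- .lociFrame(loci)$name
  envEffects <- unlist(envEffects)
  a <- unlist(a); d <- unlist(d)
  dualE <- unlist(dualE); tripleE <- unlist(tripleE)
  if (is.null(dualE)) dualE <- numeric()
  if (is.null(tripleE)) tripleE <- numeric()
  fill <- function(x) {
    out <- stats::setNames(numeric(length(loci)), loci)
    if (length(x)) {
      bad <- setdiff(names(x), loci)
      if (length(bad)) stop("unknown loci: ", paste(bad, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  if (is.null(geTerms))
    geTerms <- matrix(0, 0, length(envEffects),
                      dimnames = list(character(), names(envEffects)))
  colnames(geTerms) <- names(envEffects)
  new("TruthModel", mu = mu, envEffects = envEffects, blockSd = blockSd,
      residSd = residSd, a = fill(a), d = fill(d),
      dualE = dualE, tripleE = tripleE, geTerms = geTerms, loci = loci)
}

#' @rdname lociNames
#' @export
setMethod("lociNames", "TruthModel", function(x) x@loci)

setMethod("show", "TruthModel", function(object) {
  cat("TruthModel over loci", paste(object@loci, collapse = ", "), "\n")
  cat("  mu =", object@mu, "d;  environments:",
      paste(sprintf("%s=%+.1f", names(object@envEffects), object@envEffects),
            collapse = ", "), "\n")
  cat("  nonzero terms: a", sum(object@a != 0), "| d", sum(object@d != 0),
      "| dual", sum(object@dualE != 0), "| triple", sum(object@tripleE != 0),
      "| ge rows", nrow(object@geTerms), "\n")
  cat("  blockSd =", object@blockSd, "d;  residSd =", object@residSd, "d\n")
})

## identifiers of all k-locus sub-combinations of one state vector
.subCombos <- function(states, k) {
  sub <- which(states != 0)
  if (length(sub) < k) return(character())
  cols <- utils::combn(sub, k)
  apply(cols, 2L, function(idx) {
    st <- states
    st[-idx] <- 0L
    materialId(st)
  })
}

## every truth key applicable to one material: single-locus states, pairs, triple
.truthKeys <- function(states) {
  sub <- which(states != 0)
  if (!length(sub)) return(character())
  keys <- paste0(names(states)[sub], "-", states[sub])
  if (length(sub) >= 2L) keys <- c(keys, .subCombos(states, 2L))
  if (length(sub) >= 3L) keys <- c(keys, .subCombos(states, 3L))
  keys
}

.statesOf <- function(materials, loci) {
  if (is(materials, "MaterialCatalog")) return(materialStates(materials))
  parseMaterialId(materials, loci)
}

#' @rdname genotypicValue
#' @export
setMethod("genotypicValue", c("ANY", "TruthModel"), function(materials, truth) {
  st <- .statesOf(materials, truth@loci)
  lookup <- c(truth@dualE, truth@tripleE)
  vapply(seq_len(nrow(st)), function(i) {
    s <- st[i, ]
    g <- sum(truth@a[s == 2L]) + sum(truth@d[s == 1L])
    if (sum(s != 0) >= 2L) {
      keys <- c(.subCombos(s, 2L), .subCombos(s, 3L))
      g <- g + sum(lookup[intersect(keys, names(lookup))])
    }
    g
  }, numeric(1), USE.NAMES = FALSE) -> g
  stats::setNames(g, rownames(st))
})

#' True genotype-by-environment interaction values
#'
#' Sums the applicable `geTerms` rows of a truth model for each material:
#' additive-by-environment terms of its homozygous loci, dominance-by-
#' environment terms of its heterozygous loci, and epistasis-by-environment
#' terms of its substituted pairs/triples.
#'
#' @inheritParams genotypicValue
#' @return numeric matrix, materials x environments, days.
#' @export
interactionValue <- function(materials, truth) {
  st <- .statesOf(materials, truth@loci)
  ge <- truth@geTerms
  out <- matrix(0, nrow(st), length(truth@envEffects),
                dimnames = list(rownames(st), names(truth@envEffects)))
  if (!nrow(ge)) return(out)
  for (i in seq_len(nrow(st))) {
    keys <- intersect(.truthKeys(st[i, ]), rownames(ge))
    if (length(keys)) out[i, ] <- colSums(ge[keys, , drop = FALSE])
  }
  out
}

#' Export a truth model as an effect table
#'
#' The ground-truth twin of the estimated decomposition: one row per
#' additive, dominance, pyramiding, dual-, mixed- and triple-epistatic
#' effect of the given design, with the true per-environment interaction
#' deviations.  Parameter-recovery tests reduce to a table comparison
#' against [decomposeEffects()] output.
#'
#' @param truth a [TruthModel].
#' @param materials a [MaterialCatalog].
#' @return an [EffectTable] (no standard errors; truth is exact).
#' @export
truthEffects <- function(truth, materials) {
  st <- materialStates(materials)
  ord <- materialOrder(materials)
  envs <- names(truth@envEffects)
  ref <- rownames(st)[ord == 0L]
  if (length(ref) != 1L) stop("design must contain exactly one recipient material")
  ge <- truth@geTerms
  geRow <- function(key) {
    if (key %in% rownames(ge)) ge[key, ] else stats::setNames(numeric(length(envs)), envs)
  }
  rows <- list()
  add <- function(kind, id, class, value, env) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, id = id, class = class,
                                       value = value, env = env)
  }
  for (L in truth@loci) {
    add("additive", L, "a", truth@a[[L]], geRow(paste0(L, "-2")))
    add("dominance", L, "d", truth@d[[L]], geRow(paste0(L, "-1")))
  }
  G <- genotypicValue(materials, truth)
  GE <- interactionValue(materials, truth)
  lookupE <- c(truth@dualE, truth@tripleE)
  for (m in rownames(st)[ord >= 2L]) {
    s <- st[m, ]
    cls <- paste(c("d", "a")[s[s != 0]], collapse = "-")
    add("pyramiding", m, cls, G[[m]], GE[m, ])
    singles <- sum(truth@a[s == 2L]) + sum(truth@d[s == 1L])
    singlesGE <- Reduce(`+`, lapply(paste0(names(s)[s != 0], "-", s[s != 0]), geRow))
    if (ord[[m]] == 2L) {
      val <- if (m %in% names(truth@dualE)) truth@dualE[[m]] else 0
      add("dualEpistasis", m, cls, val, geRow(m))
    } else if (ord[[m]] == 3L) {
      add("mixedEpistasis", m, cls, G[[m]] - singles, GE[m, ] - singlesGE)
      val <- if (m %in% names(truth@tripleE)) truth@tripleE[[m]] else 0
      add("tripleEpistasis", m, cls, val, geRow(m))
    }
  }
  .rowsToEffectTable(rows, envs, truth@loci, ref, fit = NULL)
}
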
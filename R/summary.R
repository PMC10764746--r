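## Aggregate sign/count summaries and the homeostasis pattern report.

## significance indicator: use the p-value when present, otherwise the
## printed stars (bounds 0.01 / 0.05)
.sigAt <- function(eff, alpha) {
  starP <- c("**" = 0.01, "*" = 0.05)
  pEff <- ifelse(!is.na(eff$p), eff$p,
                 ifelse(is.na(eff$stars) | eff$stars == "", 1, starP[eff$stars]))
  !is.na(pEff) & pEff <= alpha
}

#' Sign summary of an effect level
#'
#' Counts the effects of one decomposition level, how many are significant,
#' and how the significant ones split by sign.  A significant effect of
#' exactly zero would be counted as positive (impossible at the reported
#' precision; a message is emitted if it occurs).
#'
#' @param et an [EffectTable].
#' @param kind decomposition level, e.g. `"dualEpistasis"`.
#' @param alpha significance level (applied to p-values when available,
#'   otherwise to the printed stars).
#' @param class optional component-class filter (e.g. `"d-d"`).
#' @return data.frame with one row: counts `n_total`, `n_significant`,
#'   `n_negative_significant`, `n_positive_significant` and the
#'   corresponding fractions.
#' @examples
#' summarizeSigns(hdPrintedEffects("dualEpistasis"), "dualEpistasis")
#' @export
summarizeSigns <- function(et, kind, alpha = 0.05, class = NULL) {
  eff <- et@effects[et@effects$kind == kind, , drop = FALSE]
  if (!is.null(class)) eff <- eff[eff$class %in% class, , drop = FALSE]
  sig <- .sigAt(eff, alpha)
  vals <- eff$value[sig]
  if (any(!is.na(vals) & vals == 0))
    message("significant effect of exactly zero counted as positive")
  nNeg <- sum(vals < 0, na.rm = TRUE)
  nPos <- sum(sig) - nNeg
  data.frame(
    kind = kind, alpha = alpha,
    n_total = nrow(eff), n_significant = sum(sig),
    n_negative_significant = nNeg, n_positive_significant = nPos,
    frac_significant = if (nrow(eff)) sum(sig) / nrow(eff) else NA_real_,
    frac_negative = if (sum(sig)) nNeg / sum(sig) else NA_real_,
    frac_positive = if (sum(sig)) nPos / sum(sig) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Mean and SD of effects per component class
#'
#' Component classes are the additive/dominance composition strings of the
#' constituent loci (`"a-a"`, `"d-d"`, `"d-a-d"`, ...).  By default only
#' significant effects enter, matching the study's class-mean convention;
#' `significantOnly = FALSE` uses every estimated effect.  Classes with a
#' single member report `NA` for the SD.
#'
#' @inheritParams summarizeSigns
#' @param significantOnly restrict to significant effects.
#' @return data.frame with columns `class`, `n`, `mean`, `sd`.
#' @export
classStats <- function(et, kind, significantOnly = TRUE, alpha = 0.05) {
  eff <- et@effects[et@effects$kind == kind, , drop = FALSE]
  if (significantOnly) eff <- eff[.sigAt(eff, alpha), , drop = FALSE]
  eff <- eff[!is.na(eff$value), , drop = FALSE]
  if (!nrow(eff))
    return(data.frame(class = character(), n = integer(), mean = numeric(),
                      sd = numeric(), stringsAsFactors = FALSE))
  sp <- split(eff$value, eff$class)
  out <- data.frame(
    class = names(sp), n = lengths(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Multiplicity-adjusted significance
#'
#' Reporting defaults to raw per-contrast p-values with star thresholds,
#' the convention of substitution-line effect tables.  This optional step
#' adjusts the p-values within each decomposition level
#' (via [stats::p.adjust()]) and rewrites the stars accordingly, for users
#' who prefer family-wise or FDR control across the many contrasts of a
#' full design.
#'
#' @param et an [EffectTable] with p-values.
#' @param method adjustment method, see [stats::p.adjust.methods].
#' @return the adjusted [EffectTable].
#' @export
adjustSignificance <- function(et, method = "BH") {
  eff <- et@effects
  for (k in unique(eff$kind)) {
    i <- eff$kind == k
    eff$p[i] <- stats::p.adjust(eff$p[i], method = method)
    et@envP[i, ] <- apply(et@envP[i, , drop = FALSE], 2L, stats::p.adjust,
                          method = method)
  }
  eff$stars <- .starsForP(eff$p)
  et@effects <- eff
  et@envStars <- matrix(.starsForP(et@envP), nrow(et@envP), ncol(et@envP),
                        dimnames = dimnames(et@envP))
  et
}

.signWord <- function(x) if (is.na(x) || x == 0) "zero" else if (x > 0) "positive" else "negative"

#' Homeostasis report: do epistatic sums oppose the single-QTL sums?
#'
#' Summarizes the buffering pattern across decomposition levels: the signs
#' of the summed significant single-QTL effects, dual epistases and triple
#' epistases (the study's
#' "positive QTLs / negative first-order interactions / positive
#' second-order interactions" pattern), and per pyramid the neutralization
#' fraction |epistasis| / |sum of constituent singles| (dual epistasis for
#' order-2 materials, mixed epistasis for order-3), flagging pyramids whose
#' epistasis opposes the single-effect sum.  Constituent singles enter at
#' their estimated values regardless of significance.
#'
#' @inheritParams summarizeSigns
#' @return list with `pattern` (e.g. `"positive/negative/positive"`),
#'   `levelSums` (signed sums of significant effects per level) and
#'   `perMaterial` (data.frame of per-pyramid fractions and opposition
#'   flags).
#' @export
homeostasisReport <- function(et, alpha = 0.05) {
  sigSum <- function(kind) {
    eff <- et@effects[et@effects$kind %in% kind, , drop = FALSE]
    sum(eff$value[.sigAt(eff, alpha)], na.rm = TRUE)
  }
  sums <- c(singles = sigSum(c("additive", "dominance")),
            dual = sigSum("dualEpistasis"),
            triple = sigSum("tripleEpistasis"))
  pattern <- paste(vapply(sums, .signWord, character(1)), collapse = "/")
  pyr <- et@effects[et@effects$kind == "pyramiding", , drop = FALSE]
  per <- lapply(pyr$id, function(m) {
    st <- drop(parseMaterialId(m, et@loci))
    k <- sum(st != 0)
    singleSum <- .singleSums(et, st)$value
    epi <- if (k == 2L) .etValue(et, "dualEpistasis", m)
           else .etValue(et, "mixedEpistasis", m)
    neut <- if (is.na(epi)) NA_real_
            else if (epi == 0) 0
            else abs(epi) / abs(singleSum)
    data.frame(material = m, order = k, singleSum = singleSum,
               epistasis = epi, neutralization = neut,
               opposes = !is.na(epi) & epi != 0 & sign(epi) != sign(singleSum),
               stringsAsFactors = FALSE)
  })
  perMaterial <- if (length(per))
    do.call(rbind, c(per, list(make.row.names = FALSE)))
  else
    data.frame(material = character(), order = integer(), singleSum = numeric(),
               epistasis = numeric(), neutralization = numeric(),
               opposes = logical(), stringsAsFactors = FALSE)
  list(pattern = pattern,
       levelSums = data.frame(level = names(sums), sum = unname(sums),
                              sign = vapply(sums, .signWord, character(1)),
                              stringsAsFactors = FALSE),
       perMaterial = perMaterial)
}
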
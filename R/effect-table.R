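## Construction and accessors for EffectTable objects.

.starsForP <- function(p) ifelse(is.na(p), NA_character_,
                                 ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))

#' Significance stars for p-values
#'
#' `"**"` for p <= 0.01, `"*"` for 0.01 < p <= 0.05, `""` otherwise
#' (the reporting convention of the study's tables).
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
starsForP <- function(p) .starsForP(p)

## rows: list of list(kind, id, class, value, env, [se], [p], [envSE], [envP])
.rowsToEffectTable <- function(rows, environments, loci, reference, fit = NULL) {
  n <- length(rows)
  g <- function(field, default) {
    vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  eff <- data.frame(
    kind = g("kind", character(1)), id = g("id", character(1)),
    class = g("class", character(1)), value = g("value", numeric(1)),
    se = g("se", NA_real_), p = g("p", NA_real_),
    stars = g("stars", NA_character_), stringsAsFactors = FALSE)
  mat <- function(field, default) {
    m <- t(vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) rep(default, length(environments)) else unname(v)
    }, rep(default, length(environments))))
    dimnames(m) <- list(paste(eff$kind, eff$id, sep = ":"), environments)
    m
  }
  rownames(eff) <- paste(eff$kind, eff$id, sep = ":")
  new("EffectTable", effects = eff,
      envValue = mat("env", NA_real_), envSE = mat("envSE", NA_real_),
      envP = mat("envP", NA_real_), envStars = mat("envStars", NA_character_),
      environments = environments, loci = loci, reference = reference,
      fit = fit)
}

.rbindET <- function(x, y) {
  stopifnot(identical(x@environments, y@environments))
  new("EffectTable",
      effects = rbind(x@effects, y@effects),
      envValue = rbind(x@envValue, y@envValue),
      envSE = rbind(x@envSE, y@envSE),
      envP = rbind(x@envP, y@envP),
      envStars = rbind(x@envStars, y@envStars),
      environments = x@environments, loci = x@loci,
      reference = x@reference,
      fit = if (is.null(x@fit)) y@fit else x@fit)
}

.etKey <- function(kind, id) paste(kind, id, sep = ":")

## value / env-interaction lookups returning NA when the row is absent
.etValue <- function(et, kind, id) {
  key <- .etKey(kind, id)
  if (key %in% rownames(et@effects)) et@effects[key, "value"] else NA_real_
}

.etEnv <- function(et, kind, id) {
  key <- .etKey(kind, id)
  if (key %in% rownames(et@envValue)) et@envValue[key, ]
  else stats::setNames(rep(NA_real_, length(et@environments)), et@environments)
}

## the single-QTL effect of one locus-state token "L-s": d for het, a for hom
.singleEffectOf <- function(et, locus, state) {
  kind <- if (state == 2L) "additive" else "dominance"
  list(value = .etValue(et, kind, locus), env = .etEnv(et, kind, locus), kind = kind)
}

#' Effect values of a table
#'
#' @param et an [EffectTable].
#' @param kind optional kind filter (e.g. `"dualEpistasis"`).
#' @return named numeric vector of effect values (names are effect ids).
#' @export
effectValues <- function(et, kind = NULL) {
  eff <- et@effects
  if (!is.null(kind)) eff <- eff[eff$kind %in% kind, , drop = FALSE]
  stats::setNames(eff$value, eff$id)
}

#' Subset an effect table by kind
#' @inheritParams effectValues
#' @return an [EffectTable] with only the requested kinds.
#' @export
effectSubset <- function(et, kind) {
  keep <- et@effects$kind %in% kind
  new("EffectTable", effects = et@effects[keep, , drop = FALSE],
      envValue = et@envValue[keep, , drop = FALSE],
      envSE = et@envSE[keep, , drop = FALSE],
      envP = et@envP[keep, , drop = FALSE],
      envStars = et@envStars[keep, , drop = FALSE],
      environments = et@environments, loci = et@loci,
      reference = et@reference, fit = et@fit)
}

#' Environments of an effect table
#' @param et an [EffectTable].
#' @export
environmentNames <- function(et) et@environments

#' Coerce an EffectTable to a wide data.frame
#'
#' One row per effect with columns `kind`, `id`, `class`, `value`, `se`,
#' `p`, `stars`, then for every environment `<env>`, `<env>_se`, `<env>_p`,
#' `<env>_stars`.
#'
#' @param x an [EffectTable].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.EffectTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- x@effects
  for (h in seq_along(x@environments)) {
    e <- x@environments[h]
    out[[e]] <- x@envValue[, h]
    out[[paste0(e, "_se")]] <- x@envSE[, h]
    out[[paste0(e, "_p")]] <- x@envP[, h]
    out[[paste0(e, "_stars")]] <- x@envStars[, h]
  }
  rownames(out) <- NULL
  out
}

setMethod("show", "EffectTable", function(object) {
  eff <- object@effects
  cat("EffectTable:", nrow(eff), "effects over",
      length(object@environments), "environments (reference",
      object@reference, ")\n")
  tab <- table(factor(eff$kind, levels = .EFFECT_KINDS))
  tab <- tab[tab > 0]
  cat(" ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = "  "), "\n")
  sig <- sum(!is.na(eff$stars) & eff$stars != "")
  cat("  significant effects:", sig, "\n")
  if (nrow(eff)) {
    head6 <- utils::head(renderEffectReport(object), 6L)
    print(head6, row.names = FALSE)
    if (nrow(eff) > 6L) cat("  ...\n")
  }
})
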
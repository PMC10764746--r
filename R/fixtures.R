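## Packaged printed effect tables of the reference study and the
## study-like truth preset built from them.

.printedFiles <- c(
  additive = "table1_additive.csv",
  dominance = "table2_dominance.csv",
  pyramiding = "table3_pyramiding.csv",
  dualEpistasis = "table4_dual_epistasis.csv",
  tripleEpistasis = "table5_triple_epistasis.csv",
  mixedEpistasis = "table6_mixed_epistasis.csv")

.readPrintedTable <- function(kind) {
  path <- system.file("extdata", .printedFiles[[kind]], package = "qtlPyramid",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  for (col in grep("stars", names(df), value = TRUE)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""  # blank printed cell = not significant
  }
  df
}

#' Printed effect tables of the reference heading-date study
#'
#' The published effect estimates for the four-locus heading-date design in
#' the HJX74 background, packaged as delimited text: additive and dominance
#' effects of the single-segment lines, pyramiding effects of the 56 dual-
#' and triple-QTL materials, and the dual, triple and mixed epistatic
#' components, each with significance stars and the printed per-environment
#' interaction terms.  Values are exactly as printed (one decimal, days);
#' blank cells of the source tables are `NA` values with empty stars (the
#' effect was tested but not significant, and its magnitude is unknown —
#' not zero).  Where a row prints fewer interaction terms than
#' environments, the terms are stored left-to-right from `e1`; the source
#' does not preserve the column assignment.
#'
#' @param kinds which tables to load (default all six), using the kind
#'   names of [EffectTable]: `"additive"`, `"dominance"`, `"pyramiding"`,
#'   `"dualEpistasis"`, `"tripleEpistasis"`, `"mixedEpistasis"`.
#' @return an [EffectTable] (no fit attached; standard errors unavailable).
#' @examples
#' singles <- hdPrintedEffects(c("additive", "dominance", "pyramiding"))
#' derived <- estimateDualEpistasis(singles)
#' effectValues(derived, "dualEpistasis")["Ehd1-1/Hd3a-2"]  # 13.0
#' @export
hdPrintedEffects <- function(kinds = names(.printedFiles)) {
  kinds <- match.arg(kinds, names(.printedFiles), several.ok = TRUE)
  loci <- hdLoci()$name
  envs <- c("e1", "e2", "e3")
  rows <- list()
  for (kind in names(.printedFiles)[names(.printedFiles) %in% kinds]) {
    df <- .readPrintedTable(kind)
    for (i in seq_len(nrow(df))) {
      id <- df$id[i]
      cls <- if (kind == "additive") "a" else if (kind == "dominance") "d"
             else .classOf(drop(parseMaterialId(id, loci)))
      rows[[length(rows) + 1L]] <- list(
        kind = kind, id = id, class = cls, value = df$value[i],
        stars = df$stars[i],
        env = as.numeric(unlist(df[i, envs])),
        envStars = as.character(unlist(df[i, paste0(envs, "_stars")])))
    }
  }
  .rowsToEffectTable(rows, envs, loci, "HJX74", fit = NULL)
}

## completes a partially printed interaction row to a zero-sum deviation row
.zeroSumRow <- function(vals) {
  miss <- is.na(vals)
  if (all(miss)) return(NULL)
  if (any(miss)) vals[miss] <- -sum(vals[!miss]) / sum(miss)
  else vals <- vals - mean(vals)
  vals
}

#' Study-like truth preset
#'
#' A [TruthModel] whose effect magnitudes are taken from the printed tables
#' of the reference study: additive and dominance effects from the
#' single-locus tables, dual and triple epistasis from the printed
#' epistatic components (unprinted, nonsignificant entries set to 0), and
#' genotype-by-environment terms from the printed interaction columns,
#' completed to zero-sum deviation rows.  Design constants not stated in
#' the source (grand mean, environment shifts, block and plot-residual
#' SDs) default to realistic values for plot-mean heading date in a
#' two-season rice trial; see the package vignette.
#'
#' @param mu recipient grand mean, days.
#' @param envEffects fixed environment shifts, days (e1/e3 short-day,
#'   e2 long-day).
#' @param blockSd,residSd block and plot-residual SDs, days.
#' @return a [TruthModel] over the [hdLoci()] catalog.
#' @export
hdTruthPreset <- function(mu = 85, envEffects = c(e1 = -4, e2 = 7, e3 = -3),
                          blockSd = 1, residSd = 1.5) {
  loci <- hdLoci()$name
  envs <- names(envEffects)
  t1 <- .readPrintedTable("additive")
  t2 <- .readPrintedTable("dominance")
  t4 <- .readPrintedTable("dualEpistasis")
  t5 <- .readPrintedTable("tripleEpistasis")
  num <- function(x) ifelse(is.na(x), 0, x)
  a <- stats::setNames(num(t1$value[match(loci, t1$id)]), loci)
  d <- stats::setNames(num(t2$value[match(loci, t2$id)]), loci)
  dualE <- stats::setNames(num(t4$value), t4$id)
  tripleE <- stats::setNames(num(t5$value), t5$id)
  ge <- list()
  addGe <- function(df, key) {
    for (i in seq_len(nrow(df))) {
      row <- .zeroSumRow(as.numeric(unlist(df[i, c("e1", "e2", "e3")])))
      if (!is.null(row)) ge[[key(df$id[i])]] <<- row
    }
  }
  addGe(t1, function(id) paste0(id, "-2"))
  addGe(t2, function(id) paste0(id, "-1"))
  addGe(t4, identity)
  addGe(t5, identity)
  geTerms <- do.call(rbind, ge)
  colnames(geTerms) <- envs
  TruthModel(loci = loci, mu = mu, envEffects = envEffects, a = a, d = d,
             dualE = dualE, tripleE = tripleE, geTerms = geTerms,
             blockSd = blockSd, residSd = residSd)
}
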
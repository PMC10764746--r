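## Delimited-text input/output for plot records and effect reports.

#' Read a plot-record table
#'
#' Comma-separated text with header `env`, `block`, `material`, `hd`
#' (plot-mean heading date, days).  Malformed rows are rejected with their
#' row numbers.
#'
#' @param path file path.
#' @param materials optional [MaterialCatalog]; unknown material
#'   identifiers are then rejected.
#' @return data.frame of validated plot records.
#' @export
readPlotTable <- function(path, materials = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(df)) stop("empty plot table: ", path)
  need <- c("env", "block", "material", "hd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plot table lacks column(s): ", paste(miss, collapse = ", "))
  hd <- suppressWarnings(as.numeric(df$hd))
  bad <- which(is.na(hd) | !is.finite(hd) | hd <= 0)
  if (length(bad))
    stop("invalid heading-date value in row(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path,
         " (hd must be finite and positive)")
  df$hd <- hd
  if (!is.null(materials)) {
    unknown <- which(!df$material %in% materialNames(materials))
    if (length(unknown))
      stop("unknown material identifier in row(s) ",
           paste(unknown + 1L, collapse = ", "), " of ", path)
  }
  df[need]
}

#' @rdname readPlotTable
#' @param plots data.frame of plot records (for writing).
#' @export
writePlotTable <- function(plots, path) {
  utils::write.csv(plots[c("env", "block", "material", "hd")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an effect report
#'
#' The full-precision machine format of an [EffectTable]: one row per
#' effect with `kind`, `id`, `class`, `value`, `se`, `p`, `stars` and the
#' per-environment `<env>`, `<env>_se`, `<env>_p`, `<env>_stars` columns.
#' Writing then reading restores the table (values to full precision).
#'
#' @param et an [EffectTable].
#' @param path file path.
#' @export
writeEffectReport <- function(et, path) {
  utils::write.csv(as.data.frame(et), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeEffectReport
#' @return `readEffectReport` returns an [EffectTable] (no fit attached).
#' @export
readEffectReport <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  base <- c("kind", "id", "class", "value", "se", "p", "stars")
  if (!all(base %in% names(df)))
    stop("not an effect report (missing base columns): ", path)
  envs <- setdiff(names(df), c(base, grep("_(se|p|stars)$", names(df), value = TRUE)))
  fixStars <- function(x) { x <- as.character(x); x[is.na(x)] <- ""; x }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$p[i]
    stars <- if (!is.na(p)) .starsForP(p) else {
      s <- df$stars[i]
      if (is.na(s)) "" else s
    }
    envP <- as.numeric(unlist(df[i, paste0(envs, "_p")]))
    envStars <- ifelse(is.na(envP), fixStars(unlist(df[i, paste0(envs, "_stars")])),
                       .starsForP(envP))
    list(kind = df$kind[i], id = df$id[i], class = df$class[i],
         value = df$value[i], se = df$se[i], p = p, stars = stars,
         env = as.numeric(unlist(df[i, envs])),
         envSE = as.numeric(unlist(df[i, paste0(envs, "_se")])),
         envP = envP, envStars = envStars)
  })
  loci <- unique(c(
    df$id[df$kind %in% c("additive", "dominance")],
    unlist(lapply(df$id[!df$kind %in% c("additive", "dominance")],
                  function(id) sub("-[12]$", "", strsplit(id, "/")[[1L]])))))
  if (all(loci %in% hdLoci()$name)) loci <- intersect(hdLoci()$name, loci)
  .rowsToEffectTable(rows, envs, loci, "HJX74", fit = NULL)
}

#' Render an effect report in the study's table style
#'
#' Values rounded to 0.1 day with significance stars appended (e.g.
#' `"-15.2**"`); unavailable effects render as empty strings.
#'
#' @param et an [EffectTable].
#' @return data.frame of formatted strings.
#' @export
renderEffectReport <- function(et) {
  fmt <- function(v, s) ifelse(is.na(v), "",
                               paste0(sprintf("%.1f", v),
                                      ifelse(is.na(s), "", s)))
  eff <- et@effects
  out <- data.frame(kind = eff$kind, id = eff$id, class = eff$class,
                    effect = fmt(eff$value, eff$stars), stringsAsFactors = FALSE)
  for (h in seq_along(et@environments))
    out[[et@environments[h]]] <- fmt(et@envValue[, h], et@envStars[, h])
  out
}
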
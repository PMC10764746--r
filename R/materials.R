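## Domain types and enumeration for the substitution-line design.

#' The four heading-date loci of the reference study
#'
#' Locus catalog used throughout the package by default: the heading-date
#' QTLs Ehd1, OsMADS50, Hd3a and Hd1 carried by four single-segment
#' substitution lines in the HJX74 (indica) background, in the row order of
#' the study's effect tables.  `code` is the substitution-line code and
#' `donor` the donor variety of the segment.
#'
#' @return data.frame with columns `name`, `code`, `donor`.
#' @examples
#' hdLoci()
#' @export
hdLoci <- function() {
  data.frame(
    name  = c("Ehd1", "OsMADS50", "Hd3a", "Hd1"),
    code  = c("W27-18-03-21", "W23-03-08-09-27-82",
              "W04-47-68-05-04-04-02-02", "W08-18-09-09-06-02"),
    donor = c("IAPAR9", "Lemont", "BG367", "IR64"),
    stringsAsFactors = FALSE)
}

.lociFrame <- function(loci) {
  if (is.character(loci)) loci <- data.frame(name = loci, stringsAsFactors = FALSE)
  if (!is.data.frame(loci) || !"name" %in% names(loci))
    stop("'loci' must be a character vector or a data.frame with a 'name' column")
  if (anyDuplicated(loci$name))
    stop("duplicate locus names: ",
         paste(unique(loci$name[duplicated(loci$name)]), collapse = ", "))
  loci
}

#' Canonical material identifier
#'
#' A material is named by joining `"<locus>-1"` (heterozygous) and
#' `"<locus>-2"` (homozygous) tokens with `"/"` in catalog locus order; the
#' recipient (no substitution) is named by `reference` (default `"HJX74"`).
#'
#' @param states integer vector of per-locus states (0/1/2) named by locus,
#'   or a matrix with loci as columns.
#' @param reference identifier of the all-zero material.
#' @return character identifier(s).
#' @examples
#' materialId(c(Ehd1 = 1, OsMADS50 = 0, Hd3a = 2, Hd1 = 0))
#' @export
materialId <- function(states, reference = "HJX74") {
  if (is.matrix(states))
    return(apply(states, 1L, materialId, reference = reference))
  sub <- states != 0
  if (!any(sub)) return(reference)
  paste(paste0(names(states)[sub], "-", states[sub]), collapse = "/")
}

#' Parse a canonical material identifier
#'
#' @param id character vector of identifiers such as `"Ehd1-1/Hd3a-2"`.
#' @param loci locus names giving the column order of the result.
#' @param reference identifier of the recipient.
#' @return integer matrix of states (rows = ids, columns = loci).
#' @export
parseMaterialId <- function(id, loci = hdLoci()$name, reference = "HJX74") {
  loci <- .lociFrame(loci)$name
  out <- matrix(0L, length(id), length(loci), dimnames = list(id, loci))
  for (i in seq_along(id)) {
    if (id[i] == reference) next
    toks <- strsplit(id[i], "/", fixed = TRUE)[[1L]]
    m <- regmatches(toks, regexec("^(.*)-([12])$", toks))
    for (tk in m) {
      if (length(tk) != 3L || !tk[2L] %in% loci)
        stop("cannot parse material identifier: ", id[i])
      out[i, tk[2L]] <- as.integer(tk[3L])
    }
  }
  out
}

#' Enumerate all materials of a pyramiding design
#'
#' Generates the recipient, every single-locus heterozygote and homozygote,
#' and every k-locus combination of heterozygous/homozygous states for
#' k up to `maxOrder`.  With L loci the design holds
#' \eqn{1 + \sum_{k\le maxOrder} C(L,k) 2^k} materials; the reference study's
#' design (4 loci, order 3) has 65 = 1 + 8 + 24 + 32.  Ordering is canonical
#' and stable: by order, then locus subsets in catalog order, then state
#' combinations with heterozygous before homozygous.
#'
#' @param loci locus names (character) or a locus metadata data.frame.
#' @param maxOrder largest number of simultaneously substituted loci.
#' @param reference identifier of the recipient material.
#' @return a [MaterialCatalog].
#' @examples
#' cat65 <- enumerateMaterials(hdLoci(), 3)
#' table(materialOrder(cat65))
#' @export
enumerateMaterials <- function(loci = hdLoci(), maxOrder = 3L, reference = "HJX74") {
  loci <- .lociFrame(loci)
  L <- nrow(loci)
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1L || maxOrder > L)
    stop("'maxOrder' must be between 1 and the number of loci")
  rows <- list(stats::setNames(integer(L), loci$name))
  for (k in seq_len(maxOrder)) {
    subsets <- utils::combn(L, k)
    # state combinations in lexicographic order, het (1) before hom (2),
    # last locus varying fastest
    grid <- as.matrix(expand.grid(rep(list(1:2), k)))[, k:1, drop = FALSE]
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      for (g in seq_len(nrow(grid))) {
        st <- stats::setNames(integer(L), loci$name)
        st[idx] <- as.integer(grid[g, ])
        rows[[length(rows) + 1L]] <- st
      }
    }
  }
  states <- do.call(rbind, rows)
  rownames(states) <- materialId(states, reference = reference)
  new("MaterialCatalog", states = states, loci = loci)
}

#' Construct a MaterialCatalog from a state matrix
#'
#' @param states numeric matrix (materials x loci) with values 0/1/2; row
#'   names, if absent, are derived canonically.
#' @param loci locus metadata; defaults to the column names of `states`.
#' @return a [MaterialCatalog].
#' @export
MaterialCatalog <- function(states, loci = colnames(states)) {
  loci <- .lociFrame(loci)
  storage.mode(states) <- "integer"
  colnames(states) <- loci$name
  if (is.null(rownames(states))) rownames(states) <- materialId(states)
  new("MaterialCatalog", states = states, loci = loci)
}

#' @describeIn materialOrder per-material order of a catalog
#' @export
setMethod("materialOrder", "MaterialCatalog", function(x)
  stats::setNames(as.integer(rowSums(x@states != 0)), rownames(x@states)))

#' @describeIn materialOrder order parsed from canonical identifiers
#' @export
setMethod("materialOrder", "character", function(x) {
  n <- lengths(strsplit(x, "/", fixed = TRUE))
  n[!grepl("-[12]", x)] <- 0L
  stats::setNames(as.integer(n), x)
})

#' @rdname materialNames
#' @export
setMethod("materialNames", "MaterialCatalog", function(x) rownames(x@states))

#' @rdname lociNames
#' @export
setMethod("lociNames", "MaterialCatalog", function(x) x@loci$name)

#' Per-locus states of a catalog
#' @param x a [MaterialCatalog].
#' @return the integer state matrix (materials x loci).
#' @export
materialStates <- function(x) x@states

setMethod("show", "MaterialCatalog", function(object) {
  ord <- materialOrder(object)
  cat("MaterialCatalog with", nrow(object@states), "materials over",
      nrow(object@loci), "loci\n")
  cat("  loci:", paste(object@loci$name, collapse = ", "), "\n")
  cat("  orders:", paste(sprintf("%d:%d", as.integer(names(table(ord))),
                                 as.integer(table(ord))), collapse = "  "), "\n")
})

#' Read / write a material catalog file
#'
#' Delimited text with a `material_id` column followed by one 0/1/2 column
#' per locus.
#'
#' @param path file path.
#' @param catalog a [MaterialCatalog] (for writing).
#' @return `readMaterialCatalog` returns a [MaterialCatalog].
#' @export
readMaterialCatalog <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"material_id" %in% names(df)) stop("catalog file needs a 'material_id' column")
  st <- as.matrix(df[setdiff(names(df), "material_id")])
  rownames(st) <- df$material_id
  MaterialCatalog(st)
}

#' @rdname readMaterialCatalog
#' @export
writeMaterialCatalog <- function(catalog, path) {
  df <- data.frame(material_id = materialNames(catalog),
                   catalog@states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
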
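#' @importFrom methods setGeneric setMethod new validObject slot show is
NULL

#' Number of substituted loci of a material
#'
#' The order of a material is the number of loci carrying a donor segment
#' (heterozygous or homozygous).  The recipient has order 0.
#'
#' @param x a [MaterialCatalog] (returns a named integer vector over its
#'   materials) or a character vector of canonical material identifiers.
#' @return integer vector of orders.
#' @examples
#' materialOrder("HJX74")
#' materialOrder("Ehd1-1/Hd3a-2/Hd1-1")
#' @export
setGeneric("materialOrder", function(x) standardGeneric("materialOrder"))

#' Material identifiers of a catalog
#' @param x a [MaterialCatalog].
#' @export
setGeneric("materialNames", function(x) standardGeneric("materialNames"))

#' Locus names of an object
#' @param x a [MaterialCatalog] or [TruthModel].
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Genotypic value of materials under a truth model
#'
#' The genotypic effect of a material relative to the recipient is the sum of
#' its applicable truth terms: `a` for each homozygous locus, `d` for each
#' heterozygous locus, every dual-locus epistasis term among its substituted
#' loci, and its triple-locus term.  The recipient has genotypic value 0.
#'
#' @param materials a [MaterialCatalog] or character vector of material
#'   identifiers.
#' @param truth a [TruthModel].
#' @return named numeric vector, days.
#' @export
setGeneric("genotypicValue", function(materials, truth) standardGeneric("genotypicValue"))

#' Variance components as a named vector
#' @param object a [VarianceComponents] or [MixedModelFit].
#' @export
setGeneric("varComp", function(object) standardGeneric("varComp"))
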
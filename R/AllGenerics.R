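#' Number of SNPs
#'
#' @param x a [GeneticMap-class], [AncestralPanel-class],
#'   [LocalAncestryCallset-class] or [SimCohort-class].
#' @return Integer count of SNPs.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Number of individuals
#'
#' @param x a [LocalAncestryCallset-class] or [SimCohort-class].
#' @return Integer count of individuals.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Ancestral-population labels
#'
#' @param x an [AncestralPanel-class], [LocalAncestryCallset-class] or
#'   [SimCohort-class].
#' @return Character vector of population names.
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' Genetic map of an object
#'
#' @param x an object carrying a [GeneticMap-class].
#' @return The [GeneticMap-class].
#' @export
setGeneric("geneticMap", function(x) standardGeneric("geneticMap"))

#' @rdname mapLengthMorgans
#' @export
setGeneric("mapLengthMorgans", function(x) standardGeneric("mapLengthMorgans"))

#' Ancestral allele-frequency matrix
#'
#' @param x an [AncestralPanel-class].
#' @return SNP x population matrix of nonreference allele frequencies.
#' @export
setGeneric("ancestralFreqs", function(x) standardGeneric("ancestralFreqs"))

#' Local-ancestry dosage array
#'
#' @param x a [LocalAncestryCallset-class] or [SimCohort-class].
#' @return SNP x individual x population dosage array.
#' @export
setGeneric("ancestryDosage", function(x) standardGeneric("ancestryDosage"))

#' Genotype dosage matrix
#'
#' @param x a [SimCohort-class].
#' @return SNP x individual matrix in \{0, 0.5, 1\} (half the nonreference
#'   allele count).
#' @export
setGeneric("genoDosage", function(x) standardGeneric("genoDosage"))

#' Global ancestry proportions
#'
#' @param x a [SimCohort-class].
#' @return Individual x population matrix, rows summing to 1.
#' @export
setGeneric("globalProps", function(x) standardGeneric("globalProps"))

#' Phenotype table
#'
#' @param x a [SimCohort-class].
#' @return data.frame with id, age, sex, sbp, dbp, hyp.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname countSegments
#' @export
setGeneric("countSegments",
  function(x, targetPop = NULL, ...) standardGeneric("countSegments"))

#' @rdname hardCall
#' @export
setGeneric("hardCall", function(x, ...) standardGeneric("hardCall"))

#' Per-SNP results table of a scan
#'
#' @param x a [ScanResult-class].
#' @return data.frame with snp_id, beta, se, t, p, q, flag.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' Genomic-control lambda of a scan
#'
#' @param x a [ScanResult-class].
#' @return The inflation factor (NA for scans of fewer than 10 SNPs).
#' @export
setGeneric("gcLambda", function(x) standardGeneric("gcLambda"))
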
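#' Construct a genetic map
#'
#' @param snpId character vector of unique SNP identifiers.
#' @param bp 1-based physical positions, strictly increasing.
#' @param cm genetic positions in centimorgans, non-decreasing.
#' @param chrom chromosome name.
#'
#' @return A [GeneticMap-class] object.
#' @examples
#' GeneticMap(paste0("rs", 1:3), bp = c(100, 200, 300), cm = c(0, 0.1, 0.25))
#' @export
GeneticMap <- function(snpId, bp, cm, chrom = "chr3") {
  new("GeneticMap", snpId = as.character(snpId), chrom = chrom,
      bp = as.numeric(bp), cm = as.numeric(cm))
}

#' Synthetic genetic map
#'
#' Draws `nSnps` SNP positions uniformly along a chromosome and assigns
#' genetic positions proportionally, spanning `lengthCm` centimorgans
#' (default 221.7 cM, the length used throughout: 2.217 morgans).
#'
#' @param nSnps number of SNPs.
#' @param lengthCm total genetic length in centimorgans.
#' @param chromBp physical chromosome length in bp.
#' @param chrom chromosome name.
#' @param seed optional integer seed.
#' @return A [GeneticMap-class].
#' @export
syntheticMap <- function(nSnps, lengthCm = 221.7, chromBp = 198e6,
                         chrom = "chr3", seed = NULL) {
  if (nSnps < 1) stop("nSnps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bp <- sort(sample.int(chromBp, nSnps))
  cm <- (bp - bp[1L]) / (bp[length(bp)] - bp[1L] + (nSnps == 1L)) * lengthCm
  GeneticMap(sprintf("snp%06d", seq_len(nSnps)), bp = bp, cm = cm, chrom = chrom)
}

#' @rdname nSnps
#' @export
setMethod("nSnps", "GeneticMap", function(x) length(x@snpId))

#' Total genetic length in morgans
#'
#' @param x an object with a genetic map.
#' @return `(max(cm) - min(cm)) / 100`.
#' @rdname mapLengthMorgans
#' @export
setMethod("mapLengthMorgans", "GeneticMap",
  function(x) (x@cm[length(x@cm)] - x@cm[1L]) / 100)

#' @rdname mapLengthMorgans
#' @export
setMethod("mapLengthMorgans", "AncestralPanel",
  function(x) mapLengthMorgans(x@map))

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@snpId), "SNPs on", object@chrom,
      sprintf("(%.4g morgans)\n", mapLengthMorgans(object)))
})

#' Coerce a genetic map to a data.frame
#'
#' @param x a `GeneticMap`.
#' @param ... unused.
#' @export
#' @method as.data.frame GeneticMap
as.data.frame.GeneticMap <- function(x, ...) {
  data.frame(snp_id = x@snpId, chrom = x@chrom, bp = x@bp, cm = x@cm,
             stringsAsFactors = FALSE)
}
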
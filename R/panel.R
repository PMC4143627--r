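#' Construct an ancestral allele-frequency panel
#'
#' @param freqs numeric SNP x population matrix of nonreference allele
#'   frequencies in \[0, 1\].
#' @param map the [GeneticMap-class] the rows are aligned to.
#' @param popLabels population names; defaults to `colnames(freqs)`.
#' @return An [AncestralPanel-class].
#' @export
AncestralPanel <- function(freqs, map, popLabels = colnames(freqs)) {
  freqs <- as.matrix(freqs)
  if (is.null(popLabels)) popLabels <- paste0("pop", seq_len(ncol(freqs)))
  dimnames(freqs) <- list(map@snpId, popLabels)
  new("AncestralPanel", freqs = freqs, popLabels = popLabels, map = map)
}

#' Draw ancestral allele frequencies under the Balding-Nichols model
#'
#' For each SNP a shared ancestral frequency is drawn uniformly on
#' `meanRange` (default \[0.1, 0.9\], avoiding near-fixed sites), then each
#' population's frequency is drawn from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with mean `p` and that population's drift
#' parameter `F`. Larger drift gives stronger differentiation; as `F -> 0`
#' all populations collapse onto the shared frequency.
#'
#' @param nSnps number of SNPs (>= 1).
#' @param K number of ancestral populations.
#' @param divergence per-population drift parameter(s) in (0, 1); recycled
#'   to length `K`.
#' @param seed optional integer seed (deterministic output given a seed).
#' @param popLabels population names (default EUR, AFR, NAM for K = 3).
#' @param map optional [GeneticMap-class]; a synthetic map spanning 2.217
#'   morgans is drawn when omitted.
#' @param meanRange range of the shared ancestral frequency.
#' @return An [AncestralPanel-class].
#' @examples
#' pan <- drawAncestralFreqs(100, K = 3, divergence = 0.15, seed = 1)
#' range(ancestralFreqs(pan))
#' @export
drawAncestralFreqs <- function(nSnps, K = 3, divergence = 0.15, seed = NULL,
                               popLabels = NULL, map = NULL,
                               meanRange = c(0.1, 0.9)) {
  if (nSnps < 1) stop("nSnps must be >= 1")
  divergence <- rep_len(divergence, K)
  if (any(divergence <= 0) || any(divergence >= 1))
    stop("each divergence must lie in (0, 1)")
  if (is.null(popLabels))
    popLabels <- if (K == 3) c("EUR", "AFR", "NAM") else paste0("pop", seq_len(K))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- syntheticMap(nSnps)
  if (nSnps(map) != nSnps) stop("map must have nSnps SNPs")
  anc <- runif(nSnps, meanRange[1L], meanRange[2L])
  freqs <- vapply(seq_len(K), function(k) {
    F <- divergence[k]
    rbeta(nSnps, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  }, numeric(nSnps))
  colnames(freqs) <- popLabels
  AncestralPanel(freqs, map)
}

#' Split one ancestral population into drifted subpopulations
#'
#' Emulates closely related reference panels (e.g. two Native-American
#' subgroups) by drawing, for each subpopulation, Balding-Nichols
#' frequencies around the parent population's frequency with a small drift.
#' Used by the pipeline to obtain the within-continent pair required by the
#' AIM filter.
#'
#' @param panel an [AncestralPanel-class].
#' @param pop name of the population to split.
#' @param into names of the subpopulations.
#' @param divergence drift of each subpopulation from the parent (recycled).
#' @param seed optional integer seed.
#' @return A frequency data.frame (`snp_id` plus one column per population),
#'   containing the original populations and the new subpopulations.
#' @export
splitPopulation <- function(panel, pop, into = c("MAY", "PMA"),
                            divergence = 0.02, seed = NULL) {
  if (!pop %in% panel@popLabels) stop("unknown population: ", pop)
  if (!is.null(seed)) set.seed(seed)
  divergence <- rep_len(divergence, length(into))
  p <- panel@freqs[, pop]
  # Beta parameters blow up at p = 0/1; clamp to keep the draw proper
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  sub <- vapply(seq_along(into), function(k) {
    F <- divergence[k]
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }, numeric(length(p)))
  colnames(sub) <- into
  out <- data.frame(snp_id = panel@map@snpId, panel@freqs, sub,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname ancestralFreqs
#' @export
setMethod("ancestralFreqs", "AncestralPanel", function(x) x@freqs)

#' @rdname nSnps
#' @export
setMethod("nSnps", "AncestralPanel", function(x) nSnps(x@map))

#' @rdname popLabels
#' @export
setMethod("popLabels", "AncestralPanel", function(x) x@popLabels)

#' @rdname geneticMap
#' @export
setMethod("geneticMap", "AncestralPanel", function(x) x@map)

setMethod("show", "AncestralPanel", function(object) {
  cat("AncestralPanel:", nSnps(object), "SNPs x",
      length(object@popLabels), "populations (",
      paste(object@popLabels, collapse = ", "), ")\n")
})
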
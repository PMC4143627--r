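#' @import methods
NULL

#' Genetic map of a single chromosome
#'
#' Ordered SNP identifiers with 1-based physical positions (bp) and genetic
#' positions (centimorgans). Physical positions must be strictly increasing
#' and genetic positions non-decreasing; the map length in morgans is
#' `(max(cm) - min(cm)) / 100`.
#'
#' @slot snpId character vector of unique SNP identifiers.
#' @slot chrom single chromosome name.
#' @slot bp numeric vector of 1-based physical positions, strictly increasing.
#' @slot cm numeric vector of genetic positions in centimorgans, non-decreasing.
#'
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(snpId = "character", chrom = "character",
                 bp = "numeric", cm = "numeric"))

setValidity("GeneticMap", function(object) {
  n <- length(object@snpId)
  if (n < 1L) return("map must contain at least one SNP")
  if (length(object@bp) != n || length(object@cm) != n)
    return("snpId, bp and cm must have equal length")
  if (length(object@chrom) != 1L) return("chrom must be a single name")
  if (anyDuplicated(object@snpId)) return("SNP ids must be unique")
  if (any(object@bp < 1)) return("bp positions are 1-based (>= 1)")
  if (n > 1L && any(diff(object@bp) <= 0))
    return("bp positions must be strictly increasing")
  if (n > 1L && any(diff(object@cm) < 0))
    return("cm positions must be non-decreasing")
  TRUE
})

#' Ancestral-population allele-frequency panel
#'
#' Per-SNP nonreference allele frequencies for K ancestral populations,
#' aligned to a [GeneticMap].
#'
#' @slot freqs numeric matrix, one row per SNP of the map, one column per
#'   ancestral population; entries in \[0, 1\].
#' @slot popLabels character vector of population names (columns of `freqs`).
#' @slot map the [GeneticMap] the rows are aligned to.
#'
#' @exportClass AncestralPanel
setClass("AncestralPanel",
  representation(freqs = "matrix", popLabels = "character", map = "GeneticMap"))

setValidity("AncestralPanel", function(object) {
  if (!is.numeric(object@freqs)) return("freqs must be numeric")
  if (nrow(object@freqs) != length(object@map@snpId))
    return("freqs must have one row per SNP of the map")
  if (ncol(object@freqs) != length(object@popLabels))
    return("freqs must have one column per population label")
  if (anyNA(object@freqs) || any(object@freqs < 0) || any(object@freqs > 1))
    return("all allele frequencies must lie in [0, 1]")
  if (anyDuplicated(object@popLabels)) return("population labels must be unique")
  TRUE
})

#' One haplotype's ancestry tract structure
#'
#' A realization of the ancestry switch process along one haplotype:
#' ordered breakpoint positions (cM) and the ancestral-population label of
#' each segment (1-based indices into the population labels).
#'
#' @slot breakpointsCm numeric, ordered switch positions in centimorgans.
#' @slot labels integer, one label per segment
#'   (`length(labels) == length(breakpointsCm) + 1`).
#' @slot K integer, number of ancestral populations.
#'
#' @exportClass HaplotypePath
setClass("HaplotypePath",
  representation(breakpointsCm = "numeric", labels = "integer", K = "integer"))

setValidity("HaplotypePath", function(object) {
  if (length(object@labels) != length(object@breakpointsCm) + 1L)
    return("need exactly one more label than breakpoints")
  if (is.unsorted(object@breakpointsCm)) return("breakpoints must be ordered")
  if (length(object@K) != 1L || object@K < 1L) return("K must be a positive count")
  if (any(object@labels < 1L) || any(object@labels > object@K))
    return("labels must lie in 1..K")
  TRUE
})

#' Local-ancestry call set
#'
#' Per-SNP, per-individual diploid ancestry dosages for K populations:
#' a SNP x individual x population array whose K-vectors sum to 1.
#' Hard-called data take values in \{0, 0.5, 1\} (half the number of
#' haplotypes assigned to each population); fractional dosages from
#' probabilistic inference are also representable and can be snapped with
#' [hardCall()].
#'
#' @slot dosage 3-d numeric array `[snp, individual, population]`.
#' @slot map the [GeneticMap] the first dimension is aligned to.
#' @slot popLabels population names for the third dimension.
#'
#' @exportClass LocalAncestryCallset
setClass("LocalAncestryCallset",
  representation(dosage = "array", map = "GeneticMap", popLabels = "character"))

setValidity("LocalAncestryCallset", function(object) {
  d <- object@dosage
  if (length(dim(d)) != 3L) return("dosage must be a 3-d array")
  if (dim(d)[1L] != length(object@map@snpId))
    return("dosage must have one row per SNP of the map")
  if (dim(d)[3L] != length(object@popLabels))
    return("third dimension must match the population labels")
  if (anyNA(d) || any(d < 0) || any(d > 1))
    return("dosages must lie in [0, 1]")
  sums <- colSums(aperm(d, c(3L, 1L, 2L)))
  if (any(abs(sums - 1) > 1e-9))
    return("each (SNP, individual) dosage K-vector must sum to 1")
  TRUE
})

#' Simulated admixed cohort
#'
#' Genotypes, ground-truth local ancestry, global ancestry proportions,
#' haplotype tract structure and blood-pressure-like phenotypes for `n`
#' simulated individuals, as produced by [simulateCohort()].
#'
#' @slot panel the [AncestralPanel] genotypes were drawn from.
#' @slot globalProps n x K matrix of per-individual ancestry proportions
#'   (rows sum to 1).
#' @slot hapPaths list of length n; each element a list of two
#'   [HaplotypePath-class] objects.
#' @slot genoDosage SNP x individual matrix in \{0, 0.5, 1\}
#'   (half the nonreference allele count).
#' @slot ancestry ground-truth [LocalAncestryCallset].
#' @slot phenotypes data.frame with columns id, age, sex, sbp, dbp, hyp.
#' @slot gTrue generations since admixture used in the simulation.
#' @slot seed master seed used.
#'
#' @exportClass SimCohort
setClass("SimCohort",
  representation(panel = "AncestralPanel", globalProps = "matrix",
                 hapPaths = "list", genoDosage = "matrix",
                 ancestry = "LocalAncestryCallset", phenotypes = "data.frame",
                 gTrue = "numeric", seed = "numeric"))

setValidity("SimCohort", function(object) {
  n <- nrow(object@globalProps)
  m <- length(object@panel@map@snpId)
  if (ncol(object@globalProps) != length(object@panel@popLabels))
    return("globalProps must have one column per ancestral population")
  if (any(abs(rowSums(object@globalProps) - 1) > 1e-12))
    return("each globalProps row must sum to 1")
  if (length(object@hapPaths) != n) return("need one haplotype pair per individual")
  if (!all(dim(object@genoDosage) == c(m, n)))
    return("genoDosage must be SNP x individual")
  g2 <- 2 * object@genoDosage
  if (any(abs(g2 - round(g2)) > 1e-9))
    return("genoDosage entries must be in {0, 0.5, 1}")
  if (nrow(object@phenotypes) != n)
    return("phenotypes must have one row per individual")
  need <- c("id", "age", "sex", "sbp", "dbp", "hyp")
  if (!all(need %in% names(object@phenotypes)))
    return(paste("phenotypes must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Per-individual ancestry-segment counts
#'
#' @slot counts integer-valued vector, one diploid segment count per individual
#'   (sum of the two haplotypes' maximal-run counts).
#' @slot targetPop population the counts were binarized to, or NA for full
#'   multi-way counting.
#'
#' @exportClass SegmentSummary
setClass("SegmentSummary",
  representation(counts = "numeric", targetPop = "character"))

setValidity("SegmentSummary", function(object) {
  if (length(object@counts) < 1L) return("need at least one individual")
  if (any(object@counts < 2)) return("diploid segment counts are >= 2")
  TRUE
})

#' Result of a per-SNP regression scan
#'
#' @slot table data.frame with one row per SNP: `snp_id`, `beta`, `se`, `t`,
#'   `p`, `q` (Benjamini-Hochberg FDR) and `flag` (TRUE for degenerate
#'   designs assigned p = 1).
#' @slot model `"admixmap"` (ancestry-deviation scan) or `"assoc"`
#'   (ancestry-adjusted genotype scan).
#' @slot lambda genomic-control inflation factor for the scan (NA when fewer
#'   than 10 SNPs).
#' @slot n number of individuals.
#' @slot df residual degrees of freedom of the per-SNP fit.
#'
#' @exportClass ScanResult
setClass("ScanResult",
  representation(table = "data.frame", model = "character",
                 lambda = "numeric", n = "numeric", df = "numeric"))

setValidity("ScanResult", function(object) {
  need <- c("snp_id", "beta", "se", "t", "p", "q", "flag")
  if (!all(need %in% names(object@table)))
    return(paste("scan table must contain:", paste(need, collapse = ", ")))
  p <- object@table$p
  if (any(p <= 0 | p > 1, na.rm = TRUE)) return("p-values must lie in (0, 1]")
  if (!object@model %in% c("admixmap", "assoc"))
    return("model must be 'admixmap' or 'assoc'")
  TRUE
})

#' Permutation excess-signal test result
#'
#' @slot threshold t-statistic threshold t*.
#' @slot observed observed number of SNPs exceeding the threshold.
#' @slot counts the B permutation counts.
#' @slot p add-one empirical p-value `(1 + #\{count_b >= observed\}) / (B + 1)`.
#' @slot signed TRUE if the literal one-sided `t > t*` count was used instead
#'   of `|t| > t*`.
#'
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(threshold = "numeric", observed = "numeric",
                 counts = "numeric", p = "numeric", signed = "logical"))

setValidity("PermutationResult", function(object) {
  B <- length(object@counts)
  if (B < 1L) return("need at least one permutation")
  if (object@p <= 0 || object@p > 1) return("empirical p must lie in (0, 1]")
  TRUE
})

#' Case-control power design (dominant penetrance model)
#'
#' @slot maf minor allele frequency in \[0, 1\].
#' @slot model penetrance model; only `"dominant"` is supported.
#' @slot grr genotype relative risk (> 0) for carriers of >= 1 risk allele.
#' @slot nCase,nControl sample sizes (>= 2).
#' @slot alpha two-sided type-I error in (0, 1).
#'
#' @exportClass PowerDesign
setClass("PowerDesign",
  representation(maf = "numeric", model = "character", grr = "numeric",
                 nCase = "numeric", nControl = "numeric", alpha = "numeric"))

setValidity("PowerDesign", function(object) {
  if (object@maf < 0 || object@maf > 1) return("maf must lie in [0, 1]")
  if (object@model != "dominant") return("only the dominant model is supported")
  if (object@grr <= 0) return("grr must be positive")
  if (object@nCase < 2 || object@nControl < 2)
    return("need at least 2 cases and 2 controls")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0, 1)")
  TRUE
})

#' Trait-generation settings for the cohort simulator
#'
#' Linear predictors on the log scale for systolic/diastolic blood pressure,
#' an optional ancestry effect (on the global European proportion or the
#' local European dosage at a causal SNP), an optional genotype effect at the
#' causal SNP, and the hypertension mechanism (liability threshold calibrated
#' to a target prevalence, or a logistic link).
#'
#' @slot interceptSbp,interceptDbp intercepts of log(SBP), log(DBP).
#' @slot ageEffect,sexEffect covariate effects on the log scale.
#' @slot ancestryEffect effect of European ancestry dosage on the log scale.
#' @slot ancestryScope `"global"` or `"local"`.
#' @slot genotypeEffect effect of the causal-SNP genotype dosage.
#' @slot causalSnp index of the causal SNP (NA: middle of the map).
#' @slot noiseSd residual SD on the log scale (> 0).
#' @slot prevalence target hypertension prevalence for the liability threshold.
#' @slot link `"threshold"` or `"logistic"`.
#' @slot logisticIntercept,logisticSlope parameters of the logistic link on the
#'   SBP liability (used only when `link == "logistic"`).
#'
#' @exportClass TraitSpec
setClass("TraitSpec",
  representation(interceptSbp = "numeric", interceptDbp = "numeric",
                 ageEffect = "numeric", sexEffect = "numeric",
                 ancestryEffect = "numeric", ancestryScope = "character",
                 genotypeEffect = "numeric", causalSnp = "numeric",
                 noiseSd = "numeric", prevalence = "numeric",
                 link = "character", logisticIntercept = "numeric",
                 logisticSlope = "numeric"))

setValidity("TraitSpec", function(object) {
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  if (!object@ancestryScope %in% c("global", "local"))
    return("ancestryScope must be 'global' or 'local'")
  if (!object@link %in% c("threshold", "logistic"))
    return("link must be 'threshold' or 'logistic'")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence must lie in (0, 1)")
  TRUE
})
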
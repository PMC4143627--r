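#' Count ancestry segments
#'
#' Counts maximal runs of constant ancestry, summed over the two haplotypes
#' of each individual. With `targetPop` given, labels are first binarized to
#' target vs non-target (the two-class counting assumed by
#' [estimateGenerations()]); otherwise full multi-way runs are counted.
#'
#' For a [SimCohort-class] the exact haplotype paths are used. For a
#' dosage-only [LocalAncestryCallset-class] the diploid segment count is
#' reconstructed from the per-SNP dosage sequence: with a target population,
#' `A_i = 2 + sum_j |2 d_{j+1} - 2 d_j|` over adjacent SNPs (each haploid
#' switch moves the dosage by 0.5); without one, the minimal number of
#' haploid label changes between adjacent unordered diploid states is
#' accumulated. Counts are invariant to SNP density as long as adjacent SNPs
#' flank every switch point.
#'
#' @param x a [SimCohort-class] or [LocalAncestryCallset-class].
#' @param targetPop optional population label (or index) to binarize to.
#' @param ... unused.
#' @return A [SegmentSummary-class].
#' @examples
#' pan <- drawAncestralFreqs(200, seed = 1)
#' coh <- simulateCohort(pan, n = 10, seed = 1)
#' countSegments(coh, targetPop = "EUR")
#' @rdname countSegments
#' @export
setMethod("countSegments", "SimCohort", function(x, targetPop = NULL, ...) {
  popIdx <- resolvePop(targetPop, popLabels(x))
  counts <- vapply(x@hapPaths, function(hp) {
    sum(vapply(hp, function(p) {
      lab <- p@labels
      if (!is.null(popIdx)) lab <- as.integer(lab == popIdx)
      countRuns(lab)
    }, numeric(1)))
  }, numeric(1))
  newSegmentSummary(counts, targetPop, popLabels(x))
})

#' @rdname countSegments
#' @export
setMethod("countSegments", "LocalAncestryCallset",
  function(x, targetPop = NULL, ...) {
  if (nSnps(x) < 1L) stop("empty call set")
  popIdx <- resolvePop(targetPop, x@popLabels)
  n <- nIndividuals(x)
  if (!is.null(popIdx)) {
    d2 <- 2 * x@dosage[, , popIdx, drop = FALSE]
    dim(d2) <- dim(x@dosage)[1:2]
    counts <- 2 + colSums(abs(diff(d2)))
  } else {
    # minimal haploid edits between adjacent unordered diploid states:
    # 2 - (overlap of the two label multisets)
    cnt <- round(2 * x@dosage)  # m x n x K haplotype counts
    m <- dim(cnt)[1L]
    if (m == 1L) { counts <- rep(2, n) } else {
      overlap <- rowSums(pmin(cnt[-1L, , , drop = FALSE],
                              cnt[-m, , , drop = FALSE]), dims = 2L)
      counts <- 2 + colSums(2 - overlap)
    }
  }
  newSegmentSummary(counts, targetPop, x@popLabels)
})

resolvePop <- function(targetPop, labels) {
  if (is.null(targetPop)) return(NULL)
  if (is.character(targetPop)) {
    idx <- match(targetPop, labels)
    if (is.na(idx)) stop("unknown population: ", targetPop)
    idx
  } else as.integer(targetPop)
}

countRuns <- function(lab) {
  if (length(lab) == 0L) return(0)
  1 + sum(lab[-1L] != lab[-length(lab)])
}

newSegmentSummary <- function(counts, targetPop, labels) {
  tp <- if (is.null(targetPop)) NA_character_
        else if (is.character(targetPop)) targetPop
        else labels[targetPop]
  new("SegmentSummary", counts = as.numeric(counts), targetPop = tp)
}

#' Per-individual ancestry-segment counts of a summary
#'
#' @param x a [SegmentSummary-class].
#' @return numeric vector of diploid segment counts.
#' @export
segmentCounts <- function(x) x@counts

setMethod("show", "SegmentSummary", function(object) {
  cat("SegmentSummary (",
      if (is.na(object@targetPop)) "multi-way" else
        paste0("binarized to ", object@targetPop),
      "): ", length(object@counts), " individuals\n", sep = "")
  cat(sprintf("  mean A = %.2f, SD = %.2f\n",
              mean(object@counts), sd(object@counts)))
})

#' Mean and SD of segment counts
#'
#' @param x a [SegmentSummary-class].
#' @return named numeric `c(mean, sd)`.
#' @export
segmentSummaryStats <- function(x) c(mean = mean(x@counts), sd = sd(x@counts))

#' Estimate generations since admixture from segment counts
#'
#' Implements `N = A / (4 a (1 - a) L)`, where `A` is the (mean) number of
#' ancestry segments per diploid individual, `a` the admixture proportion of
#' European ancestry and `L` the genetic map length in morgans;
#' `4 a (1 - a)` is the expected number of ancestry-switching recombination
#' events per generation per diploid morgan. The formula is applied exactly
#' as stated, with no correction for the two baseline segments every diploid
#' individual carries, so simulated cohorts are recovered with a small
#' upward bias of `2 / (4 a (1 - a) L)` generations.
#'
#' @param A segment count(s): a number, vector, or [SegmentSummary-class]
#'   (its mean count is used).
#' @param a European admixture proportion, strictly inside (0, 1).
#' @param L genetic map length in morgans (> 0).
#' @return Estimated generations since admixture (vectorized over `A`).
#' @examples
#' estimateGenerations(c(25.49, 22.40), a = 0.6, L = 2.217)
#' @export
estimateGenerations <- function(A, a, L) {
  if (is(A, "SegmentSummary")) A <- mean(A@counts)
  if (any(A <= 0)) stop("A must be positive")
  if (a <= 0 || a >= 1) stop("a must lie strictly inside (0, 1)")
  if (L <= 0) stop("L must be positive")
  A / (4 * a * (1 - a) * L)
}

#' Compare local-ancestry calls with global ancestry estimates
#'
#' Per individual, the locus-averaged local dosage `m_ik` for each
#' population is compared with the global proportion. Two correlations are
#' reported: the pooled Pearson correlation of all `(i, k)` pairs, and the
#' per-individual correlation over the K populations (mean and SD across
#' individuals). The deviation percentage is `100 * |m_ik - global_ik|`,
#' averaged per individual (mean and SD across individuals; the overall
#' mean equals the pooled mean over all `(i, k)`).
#'
#' @param local a [LocalAncestryCallset-class].
#' @param global n x K matrix of global proportions (e.g. [globalProps()]).
#' @return A list: `pooledCor`, `meanCor`, `sdCor`, `meanDeviationPct`,
#'   `sdDeviationPct`, and the per-individual matrix `localMeans`.
#' @export
compareToGlobal <- function(local, global) {
  d <- local@dosage
  n <- dim(d)[2L]
  if (nrow(global) != n) stop("global must have one row per individual")
  m_ik <- colMeans(d)  # averaging over SNPs gives an individual x population matrix
  if (sd(as.vector(m_ik)) == 0 || sd(as.vector(global)) == 0)
    stop("correlation undefined: constant ancestry values")
  pooled <- cor(as.vector(m_ik), as.vector(global))
  perInd <- vapply(seq_len(n), function(i) {
    if (sd(m_ik[i, ]) == 0 || sd(global[i, ]) == 0) NA_real_
    else cor(m_ik[i, ], global[i, ])
  }, numeric(1))
  devInd <- 100 * rowMeans(abs(m_ik - global))
  list(pooledCor = pooled,
       meanCor = mean(perInd, na.rm = TRUE),
       sdCor = sd(perInd, na.rm = TRUE),
       meanDeviationPct = mean(devInd),
       sdDeviationPct = sd(devInd),
       localMeans = m_ik)
}

#' Hard-call fractional ancestry dosages
#'
#' Snaps each (SNP, individual) K-vector to the nearest valid diploid
#' configuration (entries in \{0, 0.5, 1\} summing to 1) in Euclidean
#' distance; ties are broken by population order (homozygous states first,
#' then heterozygous pairs in lexicographic order).
#'
#' @param x a [LocalAncestryCallset-class].
#' @param ... unused.
#' @return A hard-called [LocalAncestryCallset-class].
#' @rdname hardCall
#' @export
setMethod("hardCall", "LocalAncestryCallset", function(x, ...) {
  d <- x@dosage
  K <- dim(d)[3L]
  states <- diploidStates(K)           # S x K dosage patterns
  flat <- matrix(aperm(d, c(3L, 1L, 2L)), K) # K x cells
  # squared distance to each state: ||v||^2 - 2 v.s + ||s||^2
  cross <- states %*% flat             # S x cells
  d2 <- -2 * cross + rowSums(states^2)
  pick <- apply(d2, 2L, which.min)     # first minimum = population-order tie-break
  out <- aperm(array(t(states)[, pick], c(K, dim(d)[1L], dim(d)[2L])),
               c(2L, 3L, 1L))
  dimnames(out) <- dimnames(d)
  LocalAncestryCallset(out, x@map, x@popLabels)
})

# all unordered diploid dosage configurations, homozygous first then
# heterozygous pairs, each row a K-vector in {0, 0.5, 1} summing to 1
diploidStates <- function(K) {
  hom <- diag(K)
  het <- NULL
  for (k1 in seq_len(K - 1L)) for (k2 in seq.int(k1 + 1L, K)) {
    v <- numeric(K); v[c(k1, k2)] <- 0.5
    het <- rbind(het, v)
  }
  unname(rbind(hom, het))
}

#' Diploid inconsistency between two call sets
#'
#' Hard-calls each (SNP, individual) of both call sets to an unordered
#' diploid ancestry pair (6 states for 3 populations) and returns the
#' percentage of cells whose states differ. Symmetric in its arguments and
#' invariant to a population relabeling applied to both call sets.
#'
#' @param a,b [LocalAncestryCallset-class] objects on the same SNPs and
#'   individuals.
#' @return Percentage in \[0, 100\].
#' @export
diploidInconsistency <- function(a, b) {
  if (!all(dim(a@dosage) == dim(b@dosage)))
    stop("call sets must cover the same SNPs, individuals and populations")
  sa <- stateIds(hardCall(a)@dosage)
  sb <- stateIds(hardCall(b)@dosage)
  100 * mean(sa != sb)
}

stateIds <- function(d) {
  K <- dim(d)[3L]
  flat <- matrix(aperm(d, c(3L, 1L, 2L)), K)
  as.integer(crossprod(flat * 2, 3^seq_len(K)))
}
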
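#' Construct a local-ancestry call set
#'
#' @param dosage SNP x individual x population array; each K-vector must sum
#'   to 1.
#' @param map aligned [GeneticMap-class].
#' @param popLabels population names.
#' @return A [LocalAncestryCallset-class].
#' @export
LocalAncestryCallset <- function(dosage, map, popLabels = NULL) {
  if (is.null(popLabels)) popLabels <- dimnames(dosage)[[3L]]
  if (is.null(popLabels)) popLabels <- paste0("pop", seq_len(dim(dosage)[3L]))
  dimnames(dosage) <- list(map@snpId, dimnames(dosage)[[2L]], popLabels)
  new("LocalAncestryCallset", dosage = dosage, map = map, popLabels = popLabels)
}

#' @rdname ancestryDosage
#' @export
setMethod("ancestryDosage", "LocalAncestryCallset", function(x) x@dosage)

#' @rdname nSnps
#' @export
setMethod("nSnps", "LocalAncestryCallset", function(x) dim(x@dosage)[1L])

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "LocalAncestryCallset", function(x) dim(x@dosage)[2L])

#' @rdname popLabels
#' @export
setMethod("popLabels", "LocalAncestryCallset", function(x) x@popLabels)

#' @rdname geneticMap
#' @export
setMethod("geneticMap", "LocalAncestryCallset", function(x) x@map)

setMethod("show", "LocalAncestryCallset", function(object) {
  cat("LocalAncestryCallset:", nSnps(object), "SNPs x",
      nIndividuals(object), "individuals x",
      length(object@popLabels), "populations\n")
})

#' Trait-generation settings
#'
#' Defaults give blood-pressure-like traits: log(SBP) centered at log(120)
#' mmHg, log(DBP) at log(75) mmHg, small positive age and sex effects, no
#' ancestry or genotype effect, residual SD 0.1 on the log scale, and a
#' hypertension liability threshold calibrated to 33% prevalence.
#'
#' @param interceptSbp,interceptDbp log-scale intercepts.
#' @param ageEffect,sexEffect log-scale covariate effects (per year; male vs
#'   female).
#' @param ancestryEffect log-scale effect of European ancestry dosage.
#' @param ancestryScope `"global"` (European global proportion) or `"local"`
#'   (European dosage at `causalSnp`).
#' @param genotypeEffect log-scale effect of the causal-SNP genotype dosage.
#' @param causalSnp index of the causal SNP (NA: middle SNP).
#' @param noiseSd residual SD on the log scale (> 0).
#' @param prevalence target hypertension prevalence (liability threshold).
#' @param link `"threshold"` (default) or `"logistic"`.
#' @param logisticIntercept,logisticSlope logistic-link parameters applied to
#'   the centered SBP liability.
#' @return A [TraitSpec-class].
#' @export
traitSpec <- function(interceptSbp = log(120), interceptDbp = log(75),
                      ageEffect = 0.004, sexEffect = 0.03,
                      ancestryEffect = 0, ancestryScope = "global",
                      genotypeEffect = 0, causalSnp = NA_real_,
                      noiseSd = 0.1, prevalence = 0.33,
                      link = "threshold",
                      logisticIntercept = 0, logisticSlope = 5) {
  new("TraitSpec", interceptSbp = interceptSbp, interceptDbp = interceptDbp,
      ageEffect = ageEffect, sexEffect = sexEffect,
      ancestryEffect = ancestryEffect, ancestryScope = ancestryScope,
      genotypeEffect = genotypeEffect, causalSnp = causalSnp,
      noiseSd = noiseSd, prevalence = prevalence, link = link,
      logisticIntercept = logisticIntercept, logisticSlope = logisticSlope)
}

#' Simulate one haplotype's ancestry tract structure
#'
#' Ancestry switch points form a Poisson process of rate `g` per morgan
#' along the map; the ancestry at the start and after each switch is drawn
#' independently from the individual's global proportions. Self-switches
#' (redrawing the current ancestry) are collapsed by default, which yields
#' the two-class switch rate `2a(1-a)g` per morgan for a population with
#' proportion `a` and hence the `4a(1-a)gL` expected diploid switch count
#' assumed by [estimateGenerations()].
#'
#' @param globalProps K-vector of ancestry proportions (sums to 1).
#' @param g generations since admixture (>= 0).
#' @param map a [GeneticMap-class].
#' @param seed optional integer seed.
#' @param collapse drop self-switches (default TRUE).
#' @return A [HaplotypePath-class].
#' @examples
#' map <- syntheticMap(10, seed = 1)
#' simulateHaplotypePath(c(0.6, 0.1, 0.3), g = 10, map = map, seed = 1)
#' @export
simulateHaplotypePath <- function(globalProps, g, map, seed = NULL,
                                  collapse = TRUE) {
  if (g < 0) stop("g must be >= 0")
  if (abs(sum(globalProps) - 1) > 1e-8) stop("globalProps must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  K <- length(globalProps)
  L <- mapLengthMorgans(map)
  nSwitch <- rpois(1L, g * L)
  bk <- sort(runif(nSwitch, 0, L)) * 100 + map@cm[1L]
  labels <- sample.int(K, nSwitch + 1L, replace = TRUE, prob = globalProps)
  if (collapse && nSwitch > 0L) {
    keep <- labels[-1L] != labels[-length(labels)]
    bk <- bk[keep]
    labels <- c(labels[1L], labels[-1L][keep])
  }
  new("HaplotypePath", breakpointsCm = bk, labels = as.integer(labels),
      K = as.integer(K))
}

# ancestry label of each map position for one haplotype path
pathLabelsAt <- function(path, cm) {
  path@labels[findInterval(cm, path@breakpointsCm) + 1L]
}

setMethod("show", "HaplotypePath", function(object) {
  cat("HaplotypePath:", length(object@labels), "segment(s), labels",
      paste(object@labels, collapse = " "), "\n")
})

#' Simulate an admixed cohort with known local ancestry
#'
#' Per individual, global ancestry proportions are drawn from
#' `Dirichlet(concentration * meanProps)`; two haplotype ancestry paths are
#' drawn with [simulateHaplotypePath()]; each haplotype's allele at each SNP
#' is Bernoulli with the ancestral frequency of that haplotype's local
#' ancestry; the genotype dosage is half the summed allele count and the
#' local-ancestry dosage averages the two haplotype ancestry indicators.
#' Blood-pressure-like traits are generated from the [traitSpec()]:
#' SBP/DBP are log-normal around their linear predictors and hypertension
#' is, by default, the indicator that an SBP-scale liability exceeds the
#' empirical quantile giving the target prevalence.
#'
#' Draws are organized in per-stage and per-individual seed substreams
#' derived from the master `seed`, so identical seeds give bit-identical
#' cohorts.
#'
#' @param panel an [AncestralPanel-class].
#' @param n number of individuals.
#' @param meanProps mean ancestry proportions (default 0.6/0.1/0.3
#'   European/African/Native-American, recycled to the panel's K).
#' @param concentration Dirichlet concentration (default 30; larger values
#'   concentrate individuals around `meanProps`).
#' @param g generations since admixture (default 10).
#' @param trait a [TraitSpec-class].
#' @param seed master integer seed.
#' @return A [SimCohort-class].
#' @examples
#' pan <- drawAncestralFreqs(50, seed = 1)
#' coh <- simulateCohort(pan, n = 20, seed = 1)
#' coh
#' @export
simulateCohort <- function(panel, n, meanProps = c(0.6, 0.1, 0.3),
                           concentration = 30, g = 10,
                           trait = traitSpec(), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  K <- length(panel@popLabels)
  if (length(meanProps) != K)
    stop("meanProps must have one entry per ancestral population")
  if (abs(sum(meanProps) - 1) > 1e-8) stop("meanProps must sum to 1")
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  m <- nSnps(panel)
  cm <- panel@map@cm
  q <- panel@freqs

  # global proportions: Dirichlet via normalized gammas
  set.seed(substreamSeed(seed, .STAGE[["props"]]))
  gp <- matrix(rgamma(n * K, shape = concentration * rep(meanProps, each = n)),
               n, K)
  gp <- gp / rowSums(gp)
  colnames(gp) <- panel@popLabels

  # covariates
  set.seed(substreamSeed(seed, .STAGE[["covariates"]]))
  age <- as.integer(round(runif(n, 30, 70)))
  sex <- rbinom(n, 1L, 0.5)

  hapPaths <- vector("list", n)
  geno <- matrix(0, m, n)
  local <- array(0, dim = c(m, n, K))
  for (i in seq_len(n)) {
    set.seed(substreamSeed(seed, .STAGE[["individuals"]] + i))
    p1 <- simulateHaplotypePath(gp[i, ], g, panel@map)
    p2 <- simulateHaplotypePath(gp[i, ], g, panel@map)
    hapPaths[[i]] <- list(p1, p2)
    l1 <- pathLabelsAt(p1, cm)
    l2 <- pathLabelsAt(p2, cm)
    a1 <- rbinom(m, 1L, q[cbind(seq_len(m), l1)])
    a2 <- rbinom(m, 1L, q[cbind(seq_len(m), l2)])
    geno[, i] <- (a1 + a2) / 2
    idx <- seq_len(m)
    local[cbind(idx, i, l1)] <- local[cbind(idx, i, l1)] + 0.5
    local[cbind(idx, i, l2)] <- local[cbind(idx, i, l2)] + 0.5
  }
  ids <- sprintf("ind%04d", seq_len(n))
  dimnames(geno) <- list(panel@map@snpId, ids)
  dimnames(local) <- list(panel@map@snpId, ids, panel@popLabels)
  callset <- LocalAncestryCallset(local, panel@map, panel@popLabels)

  # traits
  set.seed(substreamSeed(seed, .STAGE[["traits"]]))
  causal <- if (is.na(trait@causalSnp)) (m + 1L) %/% 2L else as.integer(trait@causalSnp)
  eurIdx <- if ("EUR" %in% panel@popLabels) match("EUR", panel@popLabels) else 1L
  ancDose <- if (trait@ancestryScope == "global") gp[, eurIdx]
             else local[causal, , eurIdx]
  etaBase <- trait@ageEffect * age + trait@sexEffect * sex +
    trait@ancestryEffect * ancDose + trait@genotypeEffect * geno[causal, ]
  sbp <- exp(trait@interceptSbp + etaBase + rnorm(n, 0, trait@noiseSd))
  dbp <- exp(trait@interceptDbp + etaBase + rnorm(n, 0, trait@noiseSd))
  liability <- trait@interceptSbp + etaBase + rnorm(n, 0, trait@noiseSd)
  hyp <- if (trait@link == "threshold") {
    as.integer(liability > quantile(liability, 1 - trait@prevalence,
                                    names = FALSE, type = 7))
  } else {
    pr <- plogis(trait@logisticIntercept +
                 trait@logisticSlope * (liability - mean(liability)))
    rbinom(n, 1L, pr)
  }
  pheno <- data.frame(id = ids, age = age, sex = sex, sbp = unname(sbp),
                      dbp = unname(dbp), hyp = hyp, row.names = NULL,
                      stringsAsFactors = FALSE)

  new("SimCohort", panel = panel, globalProps = gp, hapPaths = hapPaths,
      genoDosage = geno, ancestry = callset, phenotypes = pheno,
      gTrue = g, seed = as.numeric(seed))
}

#' @rdname genoDosage
#' @export
setMethod("genoDosage", "SimCohort", function(x) x@genoDosage)

#' @rdname globalProps
#' @export
setMethod("globalProps", "SimCohort", function(x) x@globalProps)

#' @rdname phenotypes
#' @export
setMethod("phenotypes", "SimCohort", function(x) x@phenotypes)

#' @rdname ancestryDosage
#' @export
setMethod("ancestryDosage", "SimCohort", function(x) x@ancestry@dosage)

#' Ground-truth local-ancestry call set of a simulated cohort
#'
#' @param x a [SimCohort-class].
#' @return The cohort's [LocalAncestryCallset-class].
#' @export
trueAncestry <- function(x) x@ancestry

#' @rdname nSnps
#' @export
setMethod("nSnps", "SimCohort", function(x) nSnps(x@panel))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "SimCohort", function(x) nrow(x@globalProps))

#' @rdname popLabels
#' @export
setMethod("popLabels", "SimCohort", function(x) x@panel@popLabels)

#' @rdname geneticMap
#' @export
setMethod("geneticMap", "SimCohort", function(x) x@panel@map)

setMethod("show", "SimCohort", function(object) {
  cat("SimCohort:", nIndividuals(object), "individuals,", nSnps(object),
      "SNPs,", length(popLabels(object)), "ancestral populations\n")
  cat("  generations since admixture:", object@gTrue, "\n")
  cat("  mean global proportions:",
      paste(sprintf("%s=%.3f", popLabels(object),
                    colMeans(object@globalProps)), collapse = ", "), "\n")
  cat("  hypertension prevalence:",
      sprintf("%.2f", mean(object@phenotypes$hyp)), "\n")
})

#' Perturb a hard-called local-ancestry call set
#'
#' At each (SNP, individual) cell independently with probability `flipRate`,
#' one of the two haploid ancestry labels (chosen at random) is replaced by
#' a different label drawn uniformly from the remaining populations. This
#' emulates disagreement between local-ancestry inference methods while
#' preserving the dosage invariants.
#'
#' @param truth a hard-called [LocalAncestryCallset-class].
#' @param flipRate per-cell perturbation probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return A [LocalAncestryCallset-class].
#' @export
perturbAncestry <- function(truth, flipRate, seed = NULL) {
  if (flipRate < 0 || flipRate > 1) stop("flipRate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- truth@dosage
  K <- dim(d)[3L]
  if (K < 2L) stop("need at least two populations to perturb")
  pair <- dosageToPairs(d) # 2 x (m*n) haploid labels
  nc <- ncol(pair)
  flip <- which(runif(nc) < flipRate)
  if (length(flip)) {
    slot <- sample(c(1L, 2L), length(flip), replace = TRUE)
    old <- pair[cbind(slot, flip)]
    # uniform over the K-1 other labels
    repl <- sample.int(K - 1L, length(flip), replace = TRUE)
    repl <- repl + (repl >= old)
    pair[cbind(slot, flip)] <- repl
  }
  out <- pairsToDosage(pair, dim(d), dimnames(d))
  LocalAncestryCallset(out, truth@map, truth@popLabels)
}

# decompose hard-called dosage K-vectors into two haploid labels per cell
dosageToPairs <- function(d) {
  m <- dim(d)[1L]; n <- dim(d)[2L]; K <- dim(d)[3L]
  flat <- matrix(aperm(d, c(3L, 1L, 2L)), K, m * n) # K x cells
  cnt <- round(flat * 2)
  if (any(abs(flat * 2 - cnt) > 1e-9) || any(colSums(cnt) != 2L))
    stop("call set is not hard-called; apply hardCall() first")
  first <- max.col(t(cnt > 0), ties.method = "first")
  cnt[cbind(first, seq_len(m * n))] <- cnt[cbind(first, seq_len(m * n))] - 1L
  second <- max.col(t(cnt > 0), ties.method = "first")
  rbind(first, second, deparse.level = 0)
}

pairsToDosage <- function(pair, dims, dn = NULL) {
  K <- dims[3L]; cells <- prod(dims[1:2])
  flat <- matrix(0, K, cells)
  flat[cbind(pair[1L, ], seq_len(cells))] <- flat[cbind(pair[1L, ], seq_len(cells))] + 0.5
  flat[cbind(pair[2L, ], seq_len(cells))] <- flat[cbind(pair[2L, ], seq_len(cells))] + 0.5
  out <- aperm(array(flat, c(K, dims[1L], dims[2L])), c(2L, 3L, 1L))
  dimnames(out) <- dn
  out
}
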
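#' Two-population Fst from allele frequencies
#'
#' Nei-style fixation index computed from the two population frequencies
#' with equal weights: with `pbar = (p1 + p2)/2`,
#' `H_T = 2 pbar (1 - pbar)`, `H_S = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`
#' and `Fst = (H_T - H_S) / H_T` (0 when `H_T = 0`). Vectorized over SNPs.
#'
#' @param p1,p2 allele frequencies in \[0, 1\].
#' @return Fst value(s) in \[0, 1).
#' @examples
#' fstTwoPop(0.1, 0.9) # 0.64
#' @export
fstTwoPop <- function(p1, p2) {
  stopIfNot01(p1, "p1"); stopIfNot01(p2, "p2")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ifelse(ht == 0, 0, (ht - hs) / ht)
}

#' Composite LD r-squared between two genotype dosage vectors
#'
#' Squared Pearson correlation of genotype dosages across individuals; no
#' phase information is required.
#'
#' @param g1,g2 equal-length dosage vectors (length >= 2, non-constant).
#' @return r-squared in \[0, 1\].
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("g1 and g2 must have equal length")
  if (length(g1) < 2L) stop("need at least two individuals")
  if (sd(g1) == 0 || sd(g2) == 0)
    stop("LD is undefined for a constant genotype vector")
  cor(g1, g2)^2
}

#' Select ancestry-informative markers (AIMs)
#'
#' Applies the three-condition filter: (a) the two within-continent
#' populations are similar (`Fst < withinThresh`); (b) each outgroup
#' population is differentiated from each within-continent population
#' (all four pairwise `Fst > betweenThresh`); (c) the retained panel is
#' LD-pruned so that every pair of selected SNPs within `window` retained
#' markers has `r^2 < ldCutoff`. Pruning is greedy left-to-right in map
#' order: a SNP is dropped if its r-squared with any already-retained SNP
#' inside the window reaches the cutoff. All inequalities are strict, and
#' the within/between condition sets are configurable.
#'
#' @param freqs data.frame with `snp_id` and one frequency column per
#'   population (as written by [writeFreqTsv()]), aligned to `map`.
#' @param genotypes SNP x individual dosage matrix aligned to `map`
#'   (used for LD pruning).
#' @param map a [GeneticMap-class].
#' @param within character(2): the within-continent population pair.
#' @param between character(2): the outgroup populations.
#' @param withinThresh,betweenThresh,ldCutoff the three thresholds
#'   (defaults 0.1, 0.2, 0.1).
#' @param window LD-pruning window, in retained SNPs (default 250).
#' @return A list of class `AimPanel`: `snp_id` (selected ids in map order),
#'   `fst` (data.frame of all computed pairwise Fst values for every input
#'   SNP), `pass_freq` (logical frequency-filter mask) and the thresholds
#'   used.
#' @export
selectAims <- function(freqs, genotypes, map,
                       within = c("MAY", "PMA"), between = c("EUR", "AFR"),
                       withinThresh = 0.1, betweenThresh = 0.2,
                       ldCutoff = 0.1, window = 250L) {
  pops <- c(within, between)
  missingCols <- setdiff(pops, names(freqs))
  if (length(missingCols))
    stop("missing population column(s): ", paste(missingCols, collapse = ", "))
  if (!identical(as.character(freqs$snp_id), map@snpId))
    stop("freqs must be aligned to the map (same SNPs, same order)")
  m <- nSnps(map)
  if (nrow(genotypes) != m) stop("genotypes must be aligned to the map")

  fst <- data.frame(snp_id = map@snpId, stringsAsFactors = FALSE)
  fst[[paste0(within[1L], ".", within[2L])]] <-
    fstTwoPop(freqs[[within[1L]]], freqs[[within[2L]]])
  for (b in between) for (w in within)
    fst[[paste0(b, ".", w)]] <- fstTwoPop(freqs[[b]], freqs[[w]])

  passA <- fst[[paste0(within[1L], ".", within[2L])]] < withinThresh
  passB <- rep(TRUE, m)
  for (b in between) for (w in within)
    passB <- passB & fst[[paste0(b, ".", w)]] > betweenThresh
  pass <- passA & passB

  # greedy LD pruning in map order within a retained-SNP window
  kept <- integer(0)
  for (j in which(pass)) {
    gj <- genotypes[j, ]
    ok <- TRUE
    if (length(kept)) {
      recent <- kept[seq.int(max(1L, length(kept) - window + 1L), length(kept))]
      for (k in rev(recent)) {
        r2 <- if (sd(gj) == 0 || sd(genotypes[k, ]) == 0) 1
              else cor(gj, genotypes[k, ])^2
        if (r2 >= ldCutoff) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, j)
  }
  structure(list(snp_id = map@snpId[kept], index = kept, fst = fst,
                 pass_freq = pass,
                 thresholds = c(within = withinThresh, between = betweenThresh,
                                ld = ldCutoff, window = window)),
            class = "AimPanel")
}

#' @export
print.AimPanel <- function(x, ...) {
  cat("AimPanel:", length(x$snp_id), "AIMs selected from", nrow(x$fst),
      "SNPs\n")
  cat("  thresholds: within Fst <", x$thresholds[["within"]],
      ", between Fst >", x$thresholds[["between"]],
      ", LD r^2 <", x$thresholds[["ld"]], "\n")
  invisible(x)
}
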
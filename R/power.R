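#' Construct a case-control power design
#'
#' @param maf minor allele frequency.
#' @param grr genotype relative risk for carriers.
#' @param nCase,nControl sample sizes.
#' @param alpha two-sided type-I error.
#' @param model penetrance model (only `"dominant"`).
#' @return A [PowerDesign-class].
#' @examples
#' powerDesign(maf = 0.05, grr = 14.4, nCase = 36, nControl = 72,
#'             alpha = 0.05 / 37438)
#' @export
powerDesign <- function(maf, grr, nCase, nControl, alpha,
                        model = "dominant") {
  new("PowerDesign", maf = maf, model = model, grr = grr,
      nCase = nCase, nControl = nControl, alpha = alpha)
}

setMethod("show", "PowerDesign", function(object) {
  cat(sprintf(
    "PowerDesign: MAF %.3g, %s model, GRR %.3g, %d cases / %d controls, alpha %.3g\n",
    object@maf, object@model, object@grr, object@nCase, object@nControl,
    object@alpha))
})

#' Carrier (exposure) probability under a dominant model
#'
#' Probability of carrying at least one copy of the risk allele under
#' Hardy-Weinberg: `1 - (1 - maf)^2`. At MAF 5% this is 9.75%.
#'
#' @param maf minor allele frequency in \[0, 1\].
#' @return Exposure probability.
#' @export
dominantExposureProb <- function(maf) {
  stopIfNot01(maf, "maf")
  1 - (1 - maf)^2
}

#' Exposure probability among cases
#'
#' Maps a genotype relative risk to the carrier probability among cases:
#' `p1 = grr * p0 / (grr * p0 + 1 - p0)` (Bayes with carrier risk grr-fold
#' the non-carrier risk).
#'
#' @param p0 exposure probability among controls, strictly inside (0, 1).
#' @param grr genotype relative risk (> 0).
#' @return Exposure probability among cases.
#' @export
caseExposure <- function(p0, grr) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must lie strictly inside (0, 1)")
  if (any(grr <= 0)) stop("grr must be positive")
  grr * p0 / (grr * p0 + 1 - p0)
}

#' Power of the two-sided two-proportion z-test
#'
#' Case and control exposure probabilities are compared with the pooled-SE
#' normal approximation: with `p1 = caseExposure(p0, grr)`, pooled
#' proportion `pbar = (n1 p1 + n0 p0) / (n1 + n0)`,
#' `SE0 = sqrt(pbar (1 - pbar) (1/n1 + 1/n0))` under the null and
#' `SE1 = sqrt(p1 (1 - p1)/n1 + p0 (1 - p0)/n0)` under the alternative,
#' `power = Phi((|p1 - p0| - z_{alpha/2} SE0) / SE1)`.
#'
#' @param design a [PowerDesign-class].
#' @return Power in (0, 1).
#' @examples
#' powerTwoProp(powerDesign(0.05, 14.4, 36, 72, 0.05 / 37438))
#' @export
powerTwoProp <- function(design) {
  stopifnot(is(design, "PowerDesign"))
  validObject(design)
  p0 <- dominantExposureProb(design@maf)
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate design: control exposure is 0 or 1")
  p1 <- caseExposure(p0, design@grr)
  n1 <- design@nCase; n0 <- design@nControl
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  if (se1 == 0) stop("degenerate design: zero alternative-variance")
  z <- qnorm(1 - design@alpha / 2)
  pnorm((abs(p1 - p0) - z * se0) / se1)
}

#' Genotype relative risk achieving a target power
#'
#' Bisection on grr over \[1, 1000\] (power is increasing in grr) until the
#' achieved power is within `tol` of the target.
#'
#' @param targetPower target power, strictly between `alpha` and 1.
#' @param maf,nCase,nControl,alpha design parameters (dominant model).
#' @param tol convergence tolerance on power (default 1e-4).
#' @return The genotype relative risk.
#' @export
grrForPower <- function(targetPower, maf, nCase, nControl, alpha,
                        tol = 1e-4) {
  if (targetPower <= alpha || targetPower >= 1)
    stop("targetPower must lie strictly between alpha and 1")
  pw <- function(grr)
    powerTwoProp(powerDesign(maf, grr, nCase, nControl, alpha))
  lo <- 1; hi <- 1000
  if (pw(hi) < targetPower)
    stop("target power unattainable with grr <= 1000")
  if (pw(lo) > targetPower)
    stop("target power already exceeded at grr = 1")
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    pm <- pw(mid)
    if (abs(pm - targetPower) < tol) return(mid)
    if (pm < targetPower) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
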
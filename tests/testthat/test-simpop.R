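test_that("Balding-Nichols panel: determinism, limits, and differentiation match a direct sampling oracle", {
  p1 <- drawAncestralFreqs(200, K = 3, divergence = 0.15, seed = 11)
  p2 <- drawAncestralFreqs(200, K = 3, divergence = 0.15, seed = 11)
  expect_identical(ancestralFreqs(p1), ancestralFreqs(p2))
  expect_true(all(ancestralFreqs(p1) >= 0 & ancestralFreqs(p1) <= 1))

  # zero-drift limit: populations collapse onto the shared frequency
  tiny <- drawAncestralFreqs(500, K = 3, divergence = 1e-6, seed = 2)
  f <- ancestralFreqs(tiny)
  expect_lt(mean(abs(f[, 1] - f[, 2])), 1e-3)
  expect_lt(mean(abs(f[, 1] - f[, 3])), 1e-3)

  # mean pairwise Fst of the generated panel agrees with an independent
  # beta-sampling oracle of the same model (both populations drift 0.15)
  pan <- drawAncestralFreqs(5000, K = 2, divergence = 0.15, seed = 3)
  f <- ancestralFreqs(pan)
  genFst <- mean(fstTwoPop(f[, 1], f[, 2]))
  set.seed(99)
  anc <- runif(50000, 0.1, 0.9)
  F <- 0.15
  o1 <- rbeta(50000, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  o2 <- rbeta(50000, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  oracleFst <- mean(fstTwoPop(o1, o2))
  expect_lt(abs(genFst - oracleFst), 0.01)

  expect_error(drawAncestralFreqs(0), "nSnps")
  expect_error(drawAncestralFreqs(10, divergence = 1.2), "divergence")
})

test_that("haplotype ancestry paths: degenerate cases and closed-form switch rate", {
  map <- syntheticMap(50, seed = 1)

  # single-population proportions give a single segment after collapsing
  p <- simulateHaplotypePath(c(1, 0, 0), g = 10, map = map, seed = 5)
  expect_identical(p@labels, 1L)
  expect_length(p@breakpointsCm, 0)

  # g = 0: no recombination since admixture
  p0 <- simulateHaplotypePath(c(0.6, 0.1, 0.3), g = 0, map = map, seed = 5)
  expect_length(p0@labels, 1)

  expect_error(simulateHaplotypePath(c(0.6, 0.1, 0.3), g = -1, map = map),
               "g must")

  # mean binarized European/non-European segment count per haplotype is
  # 1 + 2 a (1 - a) g L
  a <- 0.6; g <- 10; L <- mapLengthMorgans(map)
  expect_equal(L, 2.217, tolerance = 1e-9)
  set.seed(42)
  counts <- vapply(seq_len(10000), function(i) {
    pp <- simulateHaplotypePath(c(a, 0.1, 0.3), g = g, map = map)
    r <- rle(as.integer(pp@labels == 1L))
    length(r$lengths)
  }, numeric(1))
  expect_equal(mean(counts), 1 + 2 * a * (1 - a) * g * L, tolerance = 0.2 / 12)
})

test_that("binarized tract lengths are exponential with mean 1/(g(1-a))", {
  # a long map keeps window-censoring of interior segments negligible
  map <- syntheticMap(10, lengthCm = 50000, seed = 2)
  a <- 0.6; g <- 10
  set.seed(7)
  lens <- c()
  while (length(lens) < 10000) {
    pp <- simulateHaplotypePath(c(a, 0.1, 0.3), g = g, map = map)
    lens <- c(lens, binarySegLengths(pp, 1L, map@cm[1], map@cm[length(map@cm)]))
  }
  fitRate <- 1 / mean(lens)
  expect_equal(fitRate, g * (1 - a), tolerance = 0.1)
  D <- suppressWarnings(ks.test(lens, "pexp", rate = fitRate)$statistic)
  expect_lt(unname(D), 0.05)
})

test_that("simulated cohorts honor the Dirichlet limit, allele-frequency structure and trait prevalence", {
  pan <- drawAncestralFreqs(500, seed = 21)

  # concentration -> infinity pins every individual at the mean proportions
  coh0 <- simulateCohort(pan, n = 30, concentration = 1e8, seed = 4)
  expect_lt(max(abs(sweep(globalProps(coh0), 2, c(0.6, 0.1, 0.3)))), 1e-3)

  coh <- simulateCohort(pan, n = 100, seed = 4)
  # determinism: bit-identical cohorts from identical seeds
  coh2 <- simulateCohort(pan, n = 100, seed = 4)
  expect_identical(genoDosage(coh), genoDosage(coh2))
  expect_identical(ancestryDosage(coh), ancestryDosage(coh2))
  expect_identical(phenotypes(coh), phenotypes(coh2))

  # genotype dosages are half-integer allele counts
  expect_true(all(genoDosage(coh) %in% c(0, 0.5, 1)))

  # pooled sample allele frequency tracks sum_k mean-prop_k * q_k
  expected <- as.vector(ancestralFreqs(pan) %*% colMeans(globalProps(coh)))
  observed <- rowMeans(genoDosage(coh))
  expect_gt(cor(expected, observed), 0.97)
  expect_lt(mean(abs(expected - observed)), 0.04)

  # locus-averaged local ancestry recovers global ancestry
  cmp <- compareToGlobal(trueAncestry(coh), globalProps(coh))
  expect_gt(cmp$pooledCor, 0.9)

  # liability threshold hits the target hypertension prevalence
  expect_equal(mean(phenotypes(coh)$hyp), 0.33, tolerance = 0.011)
  expect_true(all(phenotypes(coh)$sbp > 0))

  expect_error(simulateCohort(pan, n = 10, meanProps = c(0.5, 0.5)),
               "one entry per")
})

test_that("ancestry perturbation keeps invariants and hits the requested disagreement rate", {
  cs <- randCallset(100, 100, seed = 31)

  expect_identical(ancestryDosage(perturbAncestry(cs, 0, seed = 1)),
                   ancestryDosage(cs))

  # enumeration oracle over the 6 unordered diploid states (K = 3):
  # replacing one haploid label with a *different* label never reproduces
  # the original unordered pair, so flip_rate = 1 must disagree everywhere
  states <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  changes <- 0; total <- 0
  for (s in seq_len(nrow(states))) for (slot in 1:2)
    for (repl in setdiff(1:3, states[s, slot])) {
      newState <- sort(c(states[s, -slot], repl))
      total <- total + 1
      changes <- changes + !identical(newState, sort(states[s, ]))
    }
  expect_equal(changes / total, 1)
  expect_equal(diploidInconsistency(cs, perturbAncestry(cs, 1, seed = 2)), 100)

  # so the diploid inconsistency equals the flip rate in expectation
  p18 <- perturbAncestry(cs, 0.18, seed = 3)
  expect_equal(diploidInconsistency(cs, p18), 18, tolerance = 2 / 18)
  d <- ancestryDosage(p18)
  expect_true(all(d %in% c(0, 0.5, 1)))
  expect_true(all(abs(apply(d, 1:2, sum) - 1) < 1e-12))

  expect_error(perturbAncestry(cs, 1.5), "flipRate")
})
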
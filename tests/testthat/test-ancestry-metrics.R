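test_that("segment counting matches hand counts on constructed paths and dosages", {
  map <- gridMap(c(10, 40, 70), bp = c(1e6, 4e6, 7e6))
  pan <- AncestralPanel(matrix(0.5, 3, 3), map, c("EUR", "AFR", "NAM"))
  # haplotype 1: EUR | AFR | EUR (switches at 30 and 60 cM); haplotype 2: NAM
  p1 <- hapPath(c(30, 60), c(1, 2, 1))
  p2 <- hapPath(numeric(0), 3)
  l1 <- matrix(c(1L, 2L, 1L), 3, 1)
  l2 <- matrix(3L, 3, 1)
  cs <- callsetFromLabels(l1, l2, map)
  coh <- new("SimCohort", panel = pan, globalProps = matrix(c(0.5, 0.2, 0.3), 1),
             hapPaths = list(list(p1, p2)), genoDosage = matrix(0, 3, 1),
             ancestry = cs,
             phenotypes = data.frame(id = "i1", age = 50, sex = 0, sbp = 120,
                                     dbp = 80, hyp = 0),
             gTrue = 1, seed = 1)

  # multi-way: 3 + 1 segments; binarized to EUR: 3 + 1 as well
  expect_equal(segmentCounts(countSegments(coh)), 4)
  expect_equal(segmentCounts(countSegments(coh, targetPop = "EUR")), 4)
  # dosage-only reconstruction agrees
  expect_equal(segmentCounts(countSegments(cs)), 4)
  expect_equal(segmentCounts(countSegments(cs, targetPop = "EUR")), 4)

  # an individual entirely of one ancestry has one segment per haplotype
  uni <- callsetFromLabels(matrix(1L, 3, 1), matrix(1L, 3, 1), map)
  expect_equal(segmentCounts(countSegments(uni)), 2)

  # SNP density invariance: a denser grid spanning the same paths gives the
  # same counts as long as adjacent SNPs flank every switch
  dense <- gridMap(c(5, 15, 25, 35, 45, 55, 65, 75), bp = (1:8) * 1e6)
  lab1 <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L), 8, 1)
  lab2 <- matrix(3L, 8, 1)
  expect_equal(segmentCounts(countSegments(callsetFromLabels(lab1, lab2, dense),
                                           targetPop = "EUR")), 4)
})

test_that("mean binarized segment count matches the 2 + 4a(1-a)gL closed form", {
  pan <- drawAncestralFreqs(50, seed = 8)
  a <- 0.6; g <- 10; L <- mapLengthMorgans(geneticMap(pan))
  coh <- simulateCohort(pan, n = 500, concentration = 1e8, g = g, seed = 8)
  A <- mean(segmentCounts(countSegments(coh, targetPop = "EUR")))
  expect_equal(A, 2 + 4 * a * (1 - a) * g * L, tolerance = 0.5 / 23.28)
})

test_that("the generations estimator reproduces the printed arithmetic", {
  expect_equal(estimateGenerations(1, a = 0.5, L = 1), 1)
  N <- estimateGenerations(c(25.49, 22.40), a = 0.6, L = 2.217)
  expect_equal(N, c(11.97658, 10.52473), tolerance = 1e-6)
  expect_true(all(N >= 10 & N <= 12))
  expect_error(estimateGenerations(10, a = 0, L = 2), "strictly inside")
  expect_error(estimateGenerations(10, a = 0.5, L = 0), "positive")
  expect_error(estimateGenerations(-1, a = 0.5, L = 1), "positive")
})

test_that("comparison with global ancestry: exact case, hand example, monotone degradation", {
  # locus means exactly equal to global proportions
  map1 <- gridMap(0)
  cs <- callsetFromLabels(matrix(c(1L, 1L), 1), matrix(c(2L, 1L), 1), map1)
  glob <- rbind(c(0.5, 0.5, 0), c(1, 0, 0))
  cmp <- compareToGlobal(cs, glob)
  expect_equal(cmp$pooledCor, 1)
  expect_equal(cmp$meanDeviationPct, 0)

  # two individuals, K = 2: means (0.7, 0.3) vs (0.6, 0.4) and
  # (0.5, 0.5) vs (0.5, 0.5) -> mean deviation 5%
  map10 <- gridMap(seq_len(10))
  l1 <- cbind(c(rep(1L, 7), rep(2L, 3)), rep(1:2, 5))
  cs2 <- callsetFromLabels(l1, l1, map10, K = 2, pops = c("EUR", "AFR"))
  cmp2 <- compareToGlobal(cs2, rbind(c(0.6, 0.4), c(0.5, 0.5)))
  expect_equal(cmp2$meanDeviationPct, 5)

  # deviation grows monotonically with the perturbation rate
  truth <- trueAncestry(simulateCohort(drawAncestralFreqs(200, seed = 9),
                                       n = 50, seed = 9))
  # reference: the truth's own locus means, so the unperturbed deviation is 0
  ref <- colMeans(ancestryDosage(truth))
  devs <- vapply(c(0, 0.05, 0.1, 0.2), function(fr) {
    pert <- if (fr == 0) truth else perturbAncestry(truth, fr, seed = 100)
    compareToGlobal(pert, ref)$meanDeviationPct
  }, numeric(1))
  expect_true(all(diff(devs) > 0))

  expect_error(compareToGlobal(cs, glob[1, , drop = FALSE]), "one row per")
})

test_that("diploid inconsistency: hand counts, symmetry and relabeling invariance", {
  map <- gridMap(1:4)
  l1 <- matrix(1L, 4, 1); l2 <- matrix(2L, 4, 1)
  a <- callsetFromLabels(l1, l2, map)
  b <- callsetFromLabels(l1, rbind(2L, 2L, 2L, 3L), map)  # one cell differs
  expect_equal(diploidInconsistency(a, a), 0)
  expect_equal(diploidInconsistency(a, b), 25)
  expect_equal(diploidInconsistency(a, b), diploidInconsistency(b, a))
  # every cell different
  c2 <- callsetFromLabels(matrix(3L, 4, 1), matrix(3L, 4, 1), map)
  expect_equal(diploidInconsistency(a, c2), 100)

  # relabeling both call sets leaves the metric unchanged
  x <- randCallset(30, 20, seed = 41)
  y <- perturbAncestry(x, 0.3, seed = 42)
  perm <- c(3L, 1L, 2L)
  relabel <- function(cs) LocalAncestryCallset(cs@dosage[, , perm],
                                               cs@map, cs@popLabels)
  expect_equal(diploidInconsistency(relabel(x), relabel(y)),
               diploidInconsistency(x, y))

  # unordered comparison: swapped haplotype order is not an inconsistency
  swapped <- callsetFromLabels(l2, l1, map)
  expect_equal(diploidInconsistency(a, swapped), 0)

  expect_error(diploidInconsistency(a, randCallset(5, 2)), "same SNPs")
})

test_that("hard-calling snaps to the nearest diploid state with population-order ties", {
  map <- gridMap(1:2)
  d <- array(0, c(2, 1, 3))
  d[1, 1, ] <- c(0.6, 0.4, 0)    # nearest state (0.5, 0.5, 0)
  d[2, 1, ] <- c(1/3, 1/3, 1/3)  # equidistant: population order picks (1,0,0)...
  cs <- LocalAncestryCallset(d, map, c("EUR", "AFR", "NAM"))
  hc <- hardCall(cs)
  expect_equal(hc@dosage[1, 1, ], c(EUR = 0.5, AFR = 0.5, NAM = 0))
  # (1/3,1/3,1/3): distance to each het state is equal and smaller than to
  # any hom state; first het in enumeration order is EUR-AFR
  expect_equal(hc@dosage[2, 1, ], c(EUR = 0.5, AFR = 0.5, NAM = 0))
})
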
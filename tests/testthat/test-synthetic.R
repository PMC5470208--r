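test_that("generated genomes hit the valid-fragment target within 10%", {
  g <- makeGenome(100, 500, seed = 61)
  expect_identical(as.character(g), as.character(makeGenome(100, 500, seed = 61)))
  vf <- validFragments(digestGenome(g))
  nValid <- length(fragments(vf))
  expect_gte(nValid, 90)
  expect_lte(nValid, 110)
  expect_error(makeGenome(0), ">= 1")
  expect_error(makeGenome(10, meanFragmentLen = 30), "infeasible")
})

test_that("ground-truth distances follow the insulation/loop formula", {
  # neutral parameters: distance depends only on |i - j|
  sp0 <- landscapeSpec(30, 1000, insulation = 1, seed = 1)
  gt0 <- makeStructure(sp0)
  expect_equal(gt0@distance[1, 10], sqrt(9))
  expect_equal(gt0@distance[5, 14], sqrt(9))
  expect_equal(length(gt0@boundaries), 0)
  # insulation > 1 inflates cross-TAD distances at equal separation
  sp <- landscapeSpec(30, 1000, tads = list(c(0, 15), c(15, 30)),
                      insulation = 2, seed = 1)
  gt <- makeStructure(sp)
  expect_equal(gt@boundaries, 15L)
  expect_equal(gt@distance[13, 18], 2 * sqrt(5))   # one boundary crossed
  expect_gt(gt@distance[13, 18], gt@distance[8, 13])
  # a loop of strength 4 quarters its pair's distance
  spL <- landscapeSpec(30, 1000, insulation = 1,
                       loops = data.frame(i = 3, j = 20, strength = 4),
                       seed = 1)
  gtL <- makeStructure(spL)
  expect_equal(gtL@distance[4, 21], sqrt(17) / 4)
  expect_equal(gtL@distance[21, 4], gtL@distance[4, 21])
})

test_that("the stored 3D embedding reproduces the target distances", {
  sp <- landscapeSpec(25, 1000, tads = list(c(0, 12), c(12, 25)),
                      insulation = 2, seed = 2)
  gt <- makeStructure(sp)
  emb <- as.matrix(dist(gt@structure))
  off <- upper.tri(emb)
  expect_gt(cor(emb[off], gt@distance[off], method = "spearman"), 0.95)
})

test_that("simulated 4C counts decay with distance and conserve coverage", {
  sp <- landscapeSpec(50, 1000, insulation = 1, coverage = 1e5,
                      dispersion = 0, seed = 3)
  gt <- makeStructure(sp)
  mu <- simulate4C(gt, 10, noiseless = TRUE)[[1]]
  expect_equal(sum(mu), 1e5)
  expect_equal(mu[11], 0)                       # viewpoint bin excluded
  d <- gt@distance[11, -11]
  expect_equal(order(mu[-11], decreasing = TRUE), order(d))
  # Monte-Carlo: mean sampled total within 2% of coverage
  tot <- vapply(1:200, function(s)
    sum(simulate4C(gt, 10, seed = s)[[1]]), numeric(1))
  expect_lt(abs(mean(tot) - 1e5) / 1e5, 0.02)
  # determinism in the seed
  expect_identical(simulate4C(gt, 10, seed = 42), simulate4C(gt, 10, seed = 42))
})

test_that("bin counts spread evenly over the fragment ends of each bin", {
  g <- makeGenome(60, 400, seed = 62)
  fm <- validFragments(digestGenome(g))
  counts <- c(10, 0, 7)
  reads <- binCountsToReads(counts, fm, "chrS", 4000)
  expect_equal(sum(reads$count), sum(counts[vapply(0:2, function(b)
    any(fragmentEnds(fm, "chrS")$end >= b * 4000 &
          fragmentEnds(fm, "chrS")$end < (b + 1) * 4000), logical(1))]))
  expect_true(all(reads$pos %in% fragmentEnds(fm, "chrS")$end))
  perBin <- tapply(reads$count, floor(reads$pos / 4000), sum)
  expect_equal(as.numeric(perBin["0"]), 10)
  # even spread: counts differ by at most 1 within a bin
  spread <- reads$count[floor(reads$pos / 4000) == 0]
  expect_lte(max(spread) - min(spread), 1)
})

test_that("fused landscapes keep parental boundaries and open the junction", {
  spA <- landscapeSpec(100, 1000, tads = list(c(0, 50), c(50, 100)),
                       insulation = 2, seed = 1)
  spB <- landscapeSpec(90, 1000, tads = list(c(0, 40), c(40, 90)),
                       insulation = 2, seed = 1)
  fused <- makeFusedLandscape(spA, spB, 75, 20)
  expect_equal(fused$spec@nBins, 145L)          # 75 + 70
  expect_equal(fused$truth@boundaries, c(50L, 95L))
  expect_equal(fused$fusedTad, c(50, 95))
  expect_equal(fused$junction, 75)
  # junction itself adds no insulation: distance across it follows the
  # plain kernel as long as no parental boundary is crossed
  expect_equal(fused$truth@distance[71, 81], sqrt(10))
  # breaks at existing boundaries are rejected
  expect_error(makeFusedLandscape(spA, spB, 50, 20), "existing boundary")
  expect_error(makeFusedLandscape(spA, spB, 75, 40), "existing boundary")
  # self-fusion: fused TAD width is the sum of the retained sub-TAD widths
  selfF <- makeFusedLandscape(spA, spA, 75, 25)
  expect_equal(diff(selfF$fusedTad), (75 - 50) + (50 - 25))
})

test_that("boundary recovery from true contacts is exact within one bin", {
  sp <- landscapeSpec(90, 5000, tads = list(c(0, 30), c(30, 60), c(60, 90)),
                      insulation = 2, seed = 5)
  gt <- makeStructure(sp)
  cm <- contactMatrix(1 / (gt@distance + diag(90)), 5000)
  bc <- consensusBoundaries(cm, tadSizes = 5000 * c(5, 8, 10, 12, 15))
  sel0 <- sort(bc@selected - 1)
  expect_equal(length(sel0), 2)
  expect_true(all(abs(sel0 - c(30, 60)) <= 1))
})

test_that("simulated profiles carry all layers and are seed-reproducible", {
  g <- makeGenome(80, 400, seed = 63)
  fm <- validFragments(digestGenome(g))
  L <- sum(width(fragments(fm)))
  sp <- landscapeSpec(20, floor(L / 20), insulation = 1, seed = 4)
  gt <- makeStructure(sp)
  profs <- simulateProfiles(gt, fm, "chrS", c(5, 15), seed = 9)
  expect_length(profs, 2)
  for (p in profs) {
    expect_gt(sum(p@raw), 0)
    expect_equal(length(p@z), length(p@ends))
    expect_equal(sum(p@rpm), 1e6)
  }
  profs2 <- simulateProfiles(gt, fm, "chrS", c(5, 15), seed = 9)
  expect_identical(profs[[1]]@raw, profs2[[1]]@raw)
})
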
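# shared small map: ~50 valid fragments, viewpoint mid-chromosome
localMap <- local({
  g <- makeGenome(50, 400, seed = 7)
  validFragments(digestGenome(g))
})
localEnds <- fragmentEnds(localMap, "chrS")
localVp <- viewpoint("vp", "chrS",
                     localEnds$fragStart[nrow(localEnds) %/% 2],
                     exclusionRadius = 2L)

test_that("reads are assigned only at exact valid fragment-end coordinates", {
  e <- localEnds$end
  unmasked <- which(!emptyProfile(localMap, localVp)@masked)
  a <- e[unmasked[2]]; b <- e[unmasked[5]]
  reads <- data.frame(chrom = "chrS",
                      pos = c(a, b, b + 1),   # last one hits nothing
                      count = c(3, 5, 7))
  prof <- assignReads(reads, localMap, localVp)
  expect_equal(sum(prof@raw), 8)              # conservation of assigned reads
  expect_equal(prof@raw[unmasked[2]], 3)
  expect_equal(prof@raw[unmasked[5]], 5)
  expect_equal(prof@discarded, 7L)
})

test_that("reads on an unknown chromosome raise an error naming it", {
  reads <- data.frame(chrom = "chrZZ", pos = 0, count = 1)
  expect_error(assignReads(reads, localMap, localVp), "chrZZ")
})

test_that("ends near the viewpoint are masked and zeroed", {
  prof <- emptyProfile(localMap, localVp)
  expect_true(any(prof@masked))
  vpEnd <- which(prof@fragStart <= localVp@position &
                   localVp@position < prof@fragEnd)
  expect_true(all(prof@masked[vpEnd]))
  reads <- data.frame(chrom = "chrS", pos = prof@ends[vpEnd[1]], count = 10)
  prof <- assignReads(reads, localMap, localVp)
  expect_equal(sum(prof@raw), 0)              # masked counts dropped
})

test_that("running-mean smoothing matches a direct window oracle", {
  n <- 80
  raw <- numeric(n); raw[37] <- 30
  sm <- runningMean(raw, 30)
  # direct oracle: window is 14 before + self + 15 after
  oracle <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 14):min(n, i + 15)
    mean(raw[w])
  }, numeric(1))
  expect_equal(sm, oracle)
  expect_equal(sm[37], 1.0)                   # interior full window
  # constants are preserved everywhere including the edges
  expect_equal(runningMean(rep(3.5, 25), 30), rep(3.5, 25))
  # window 1 is the identity
  x <- rnorm(20)
  expect_equal(runningMean(x, 1), x)
})

test_that("smoothing validates the window", {
  prof <- emptyProfile(localMap, localVp)
  prof@raw <- numeric(length(prof@ends))
  expect_error(smoothProfile(prof, 0), "window")
})

test_that("RPM normalisation sums to 1e6 and is scale invariant", {
  reads <- data.frame(chrom = "chrS", pos = localEnds$end, count = 1:nrow(localEnds))
  prof <- smoothProfile(assignReads(reads, localMap, localVp), 5)
  rpm1 <- normaliseRPM(prof)@rpm
  expect_equal(sum(rpm1), 1e6)
  reads2 <- transform(reads, count = count * 2)
  prof2 <- smoothProfile(assignReads(reads2, localMap, localVp), 5)
  expect_equal(normaliseRPM(prof2)@rpm, rpm1)
  # hand case: two values 1 and 3 -> quarters of a million
  expect_equal(1e6 * c(1, 3) / 4, c(250000, 750000))
  prof@smoothed <- rep(0, length(prof@ends))
  expect_error(normaliseRPM(prof), "all-zero")
})

test_that("Z-scores standardise with the population sd and honour masking", {
  prof <- emptyProfile(localMap, localVp)
  n <- length(prof@ends)
  prof@raw <- prof@smoothed <- numeric(n)
  prof@rpm <- numeric(n)
  um <- !prof@masked
  prof@rpm[um] <- rep(c(0, 10, 20), length.out = sum(um))
  z <- zscoreProfile(prof)@z
  expect_equal(mean(z[um]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z[um]^2)), 1, tolerance = 1e-12)
  expect_true(all(z[!um] == 0))
  # three-point hand case with population sd
  v <- c(0, 10, 20)
  expect_equal((v - mean(v)) / sqrt(mean((v - mean(v))^2)),
               c(-1, 0, 1) * sqrt(3 / 2))
  # constant profile -> all zero
  prof@rpm[um] <- 5
  expect_true(all(zscoreProfile(prof)@z == 0))
})

test_that("side fractions split flanks correctly and rescale invariantly", {
  prof <- emptyProfile(localMap, localVp)
  n <- length(prof@ends)
  prof@raw <- numeric(n)
  center <- localVp@position
  left <- prof@ends < center & prof@ends >= center - 20000
  right <- prof@ends >= center & prof@ends < center + 20000
  prof@raw[left] <- 44 / sum(left)
  prof@raw[right] <- 56 / sum(right)
  sf <- sideFractions(prof, center, 20000, c(center - 20000, center + 20000))
  expect_equal(sf$pctLeft, 44)
  expect_equal(sf$pctRight, 56)
  expect_equal(sf$pctLeft + sf$pctRight, 100)
  expect_equal(sf$pctDomain, 100)             # all counts inside the domain
  # uniform rescaling changes nothing
  prof2 <- prof; prof2@raw <- prof@raw * 17
  expect_equal(sideFractions(prof2, center, 20000,
                             c(center - 20000, center + 20000))[1:3],
               sf[1:3])
  # no counts -> flagged undefined
  prof3 <- prof; prof3@raw[] <- 0
  expect_false(sideFractions(prof3, center, 20000,
                             c(center, center + 1))$defined)
})

test_that("profiles round-trip through TSV and bedGraph export works", {
  reads <- data.frame(chrom = "chrS", pos = localEnds$end,
                      count = rpois(nrow(localEnds), 5))
  prof <- zscoreProfile(normaliseRPM(smoothProfile(
    assignReads(reads, localMap, localVp), 10)))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTSV(prof, p)
  back <- readProfileTSV(p)
  expect_equal(back@ends, prof@ends)
  expect_equal(back@raw, prof@raw)
  expect_equal(back@z, prof@z, tolerance = 1e-12)
  expect_equal(back@viewpoint@position, prof@viewpoint@position)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeProfileBedGraph(prof, "smoothed", bg)
  expect_gt(file.size(bg), 0)
})
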
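test_that("derivative length arithmetic matches hand enumeration", {
  g <- c(cA = paste(rep("A", 100), collapse = ""),
         cB = paste(rep("C", 200), collapse = ""))
  dg <- buildDerivative(g, breakpointSpec("cA", 60, "cB", 50))
  expect_equal(dg@length, 210)                     # 60 + 150
  ins22 <- paste(rep("T", 22), collapse = "")
  dg22 <- buildDerivative(g, breakpointSpec("cA", 60, "cB", 50, ins22))
  expect_equal(dg22@length, 232)                   # 22 bp junction insertion
  # whole-chromosome join
  dgAll <- buildDerivative(g, breakpointSpec("cA", 100, "cB", 0))
  expect_equal(dg@spec@chromA, "cA")
  expect_equal(dgAll@length, 300)
  expect_equal(dgAll@sequence, paste0(g[["cA"]], g[["cB"]]))
  expect_error(buildDerivative(g, breakpointSpec("cA", 101, "cB", 0)),
               "out of range")
})

test_that("derivative sequence splices the retained intervals and insertion", {
  g <- c(cA = "AAAATTTT", cB = "CCCCGGGG")
  dg <- buildDerivative(g, breakpointSpec("cA", 4, "cB", 4, "TG"))
  expect_equal(dg@sequence, "AAAATGGGGG")
  expect_equal(dg@segments$source, c("cA", "insertion", "cB"))
  expect_equal(dg@segments$derStart, c(0, 4, 6))
})

test_that("coordinate maps round-trip on retained positions", {
  g <- c(cA = paste(rep("A", 100), collapse = ""),
         cB = paste(rep("C", 200), collapse = ""))
  dg <- buildDerivative(g, breakpointSpec("cA", 60, "cB", 50, "TTTT"))
  expect_equal(nativeToDerivative(dg, "cA", 0), 0)
  expect_equal(nativeToDerivative(dg, "cB", 50), 64)  # posA + |insertion|
  expect_true(is.na(nativeToDerivative(dg, "cA", 60)))  # not retained
  expect_true(is.na(nativeToDerivative(dg, "cB", 49)))
  set.seed(1)
  pos <- c(sample(0:59, 20), 60 + nchar("TTTT") - 4 + sample(50:199, 20))
  # property: derivative -> native -> derivative is the identity
  der <- 0:(dg@length - 1)
  nat <- derivativeToNative(dg, der)
  back <- nativeToDerivative(dg, nat$chrom, nat$pos)
  onIns <- nat$chrom == "insertion"
  expect_equal(back[!onIns], der[!onIns])
  expect_equal(nat$chrom[61:64], rep("insertion", 4))
  expect_equal(nat$pos[61:64], 0:3)
  expect_error(derivativeToNative(dg, dg@length), "out of range")
})

test_that("derivative fragment map equals the native splice away from the junction", {
  gA <- makeGenome(30, 300, seed = 21, name = "cA")
  gB <- makeGenome(30, 300, seed = 22, name = "cB")
  g <- c(as.character(gA), as.character(gB))
  names(g) <- c("cA", "cB")
  posA <- 4123; posB <- 2050
  dg <- buildDerivative(g, breakpointSpec("cA", posA, "cB", posB))
  der <- digestGenome(as.character(derivativeSequence(dg)))
  nat <- digestGenome(g)
  derCuts <- start(fragments(der)) - 1
  cutsA <- start(fragments(nat)[seqnames(fragments(nat)) == "cA"]) - 1
  cutsB <- start(fragments(nat)[seqnames(fragments(nat)) == "cB"]) - 1
  expCuts <- sort(unique(c(cutsA[cutsA > 0 & cutsA < posA],
                           cutsB[cutsB >= posB] - posB + posA)))
  away <- abs(derCuts - posA) > 4                # new sites only near junction
  expect_true(all(derCuts[away & derCuts > 0] %in% expCuts))
})

test_that("dosage rescaling doubles only the far side and refuses re-entry", {
  gA <- makeGenome(25, 400, seed = 31, name = "cA")
  gB <- makeGenome(25, 400, seed = 32, name = "cB")
  g <- c(as.character(gA), as.character(gB))
  names(g) <- c("cA", "cB")
  posA <- 5000; posB <- 3000
  dg <- buildDerivative(g, breakpointSpec("cA", posA, "cB", posB), name = "der")
  map <- validFragments(digestGenome(as.character(derivativeSequence(dg))))
  e <- fragmentEnds(map, "der")
  vpPos <- e$fragStart[3]                        # viewpoint on the cA side
  vp <- viewpoint("v", "der", vpPos)
  reads <- data.frame(chrom = "der", pos = e$end, count = 1)
  prof <- assignReads(reads, map, vp)
  before <- prof@raw
  far <- prof@ends >= posA
  resc <- rescaleDerivative(prof, dg)
  expect_equal(resc@raw[far], 2 * before[far])
  expect_equal(resc@raw[!far], before[!far])
  # total after = original + far-side total
  expect_equal(sum(resc@raw), sum(before) + sum(before[far]))
  # zero far side stays zero
  prof0 <- prof; prof0@raw[far] <- 0
  expect_equal(rescaleDerivative(prof0, dg)@raw[far], numeric(sum(far)) * 0)
  # guarded against double application
  expect_error(rescaleDerivative(resc, dg), "second application")
})

test_that("rescaling errors when the viewpoint fragment spans the junction", {
  gA <- makeGenome(25, 400, seed = 31, name = "cA")
  gB <- makeGenome(25, 400, seed = 32, name = "cB")
  g <- c(as.character(gA), as.character(gB))
  names(g) <- c("cA", "cB")
  posA <- 5000; posB <- 3000
  dg <- buildDerivative(g, breakpointSpec("cA", posA, "cB", posB), name = "der")
  map <- validFragments(digestGenome(as.character(derivativeSequence(dg))))
  e <- fragmentEnds(map, "der")
  jf <- which(e$fragStart < posA & e$fragEnd > posA)
  skip_if(length(jf) == 0, "no junction-spanning valid fragment in fixture")
  vp <- viewpoint("v", "der", e$fragStart[jf[1]])
  reads <- data.frame(chrom = "der", pos = e$end, count = 1)
  prof <- assignReads(reads, map, vp)
  expect_error(rescaleDerivative(prof, dg), "junction fragment")
})

test_that("side balancing equalises flank means via the geometric mean", {
  g <- makeGenome(60, 400, seed = 41)
  map <- validFragments(digestGenome(g))
  e <- fragmentEnds(map, "chrS")
  L <- max(e$fragEnd)
  bp <- e$end[nrow(e) %/% 2]
  vp <- viewpoint("v", "chrS", e$fragStart[3])
  prof <- emptyProfile(map, vp)
  n <- length(prof@ends)
  prof@raw <- numeric(n)
  prof@smoothed <- ifelse(prof@ends < bp, 2, 4)
  out <- balanceSides(prof, bp, flank = L / 3)
  # convention: both sides scaled toward the geometric mean sqrt(2*4)
  expect_equal(unname(out$scalars["right"] / out$scalars["left"]), 0.5)
  expect_equal(unname(out$scalars["left"]), sqrt(2), tolerance = 1e-12)
  sm <- out$profile@smoothed
  expect_equal(mean(sm[prof@ends < bp]), mean(sm[prof@ends >= bp]))
  # already balanced -> identity scalars
  prof@smoothed <- rep(3, n)
  expect_equal(unname(balanceSides(prof, bp, L / 3)$scalars), c(1, 1))
  # random profiles: output flank means equal
  set.seed(5)
  prof@smoothed <- runif(n, 1, 9)
  out2 <- balanceSides(prof, bp, L / 3)
  e2 <- out2$profile@ends; s2 <- out2$profile@smoothed
  lw <- e2 >= bp - L / 3 & e2 < bp; rw <- e2 >= bp & e2 < bp + L / 3
  expect_equal(mean(s2[lw]), mean(s2[rw]), tolerance = 1e-10)
  prof@smoothed[prof@ends < bp] <- 0
  expect_error(balanceSides(prof, bp, L / 3), "zero mean")
})
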
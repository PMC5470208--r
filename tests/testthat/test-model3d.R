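# minimal restraint sets built directly for geometric cases
rsFromPairs <- function(n, pairs) {
  new("RestraintSet", nParticles = as.integer(n), pairs = pairs,
      dMin = 1, dMax = 100, dEv = 2, chrom = "r", start = 0, binSize = 1,
      vpBins = 1L)
}

test_that("restraint targets decrease with signal and stay in [dMin, dMax]", {
  g <- makeGenome(120, 400, seed = 51)
  fm <- validFragments(digestGenome(g))
  L <- sum(width(fragments(fm)))
  binSize <- floor(L / 30)
  sp <- landscapeSpec(30, binSize, insulation = 1, seed = 3)
  gt <- makeStructure(sp)
  profs <- simulateProfiles(gt, fm, "chrS", c(8, 20), noiseless = TRUE)
  rs <- buildRestraints(profs, 0, 30 * binSize, binSize, dMin = 2, dMax = 50,
                        zCut = -Inf)
  h <- rs@pairs[rs@pairs$kind == "harmonic", ]
  expect_true(all(h$d >= 2 - 1e-9 & h$d <= 50 + 1e-9))
  expect_true(any(abs(h$d - 2) < 1e-6))    # strongest bin maps to dMin
  expect_true(any(abs(h$d - 50) < 1e-6))   # weakest retained bin maps to dMax
  # monotone: for one viewpoint, higher binned signal -> shorter target
  vpBin <- rs@vpBins[1]
  hv <- h[h$i == vpBin | h$j == vpBin, ]
  other <- ifelse(hv$i == vpBin, hv$j, hv$i)
  sig <- tapply(profs[[1]]@rpm, floor(profs[[1]]@ends / binSize) + 1, mean)
  s <- log1p(as.numeric(sig[as.character(other)]))
  ok <- !is.na(s)
  expect_lt(cor(s[ok], hv$d[ok], method = "spearman"), -0.99)
  # adjacency is fully covered by connectivity restraints
  conn <- rs@pairs[rs@pairs$kind == "connectivity", ]
  expect_setequal(conn$i, seq_len(rs@nParticles - 1))
  expect_error(buildRestraints(profs, 0, 2 * binSize, binSize), "3 bins")
})

test_that("the optimizer solves exact geometries and is deterministic", {
  rs2 <- rsFromPairs(2, data.frame(i = 1L, j = 2L, d = 10, k = 1,
                                   kind = "connectivity"))
  m <- optimizeModel(rs2, 1)
  expect_equal(as.numeric(dist(m@coords)), 10, tolerance = 1e-3)
  expect_identical(optimizeModel(rs2, 1)@coords, m@coords)  # bit-identical
  expect_false(identical(optimizeModel(rs2, 2)@coords, m@coords))
  # collinear chain 5-5-10 admits a zero-energy embedding
  rs3 <- rsFromPairs(3, data.frame(
    i = c(1L, 2L, 1L), j = c(2L, 3L, 3L), d = c(5, 5, 10), k = 1,
    kind = c("connectivity", "connectivity", "harmonic")))
  m3 <- optimizeModel(rs3, 7)
  expect_equal(sort(as.numeric(dist(m3@coords))), c(5, 5, 10),
               tolerance = 1e-2)
  expect_lt(m3@score, 1e-3)
})

test_that("the optimizer never returns a state worse than its initialisation", {
  set.seed(52)
  pairs <- data.frame(i = 1:9, j = 2:10,
                      d = runif(9, 2, 8), k = 1, kind = "connectivity")
  rs <- rsFromPairs(10, pairs)
  for (seed in 1:5) {
    m <- optimizeModel(rs, seed, iterations = 30, cycles = 2)
    init <- withr::with_seed(seed, {
      side <- rs@dMax * 10^(1 / 3)
      matrix(runif(30, -side / 2, side / 2), 10, 3)
    })
    expect_lte(m@score, restraintEnergy(rs, init) + 1e-9)
    expect_equal(m@score, restraintEnergy(rs, m@coords), tolerance = 1e-6)
  }
})

test_that("ensembles keep the lowest-energy models with the right fraction", {
  rs3 <- rsFromPairs(3, data.frame(
    i = c(1L, 2L), j = c(2L, 3L), d = c(5, 5), k = 1, kind = "connectivity"))
  er <- runEnsemble(rs3, nModels = 10, nKeep = 10, baseSeed = 3,
                    iterations = 40, cycles = 1)
  expect_setequal(er@selected, 1:10)      # keep-all
  scores <- vapply(er@models, function(m) m@score, numeric(1))
  er2 <- runEnsemble(rs3, nModels = 10, nKeep = 3, baseSeed = 3,
                     iterations = 40, cycles = 1)
  expect_equal(sort(scores[er2@selected]), sort(scores)[1:3])
  # the published configuration keeps 200 of 50,000: a 0.4% fraction
  expect_equal(200 / 50000, 0.004)
  expect_equal(eval(formals(runEnsemble)$nKeep) /
                 eval(formals(runEnsemble)$nModels), 0.01)
})

test_that("mirror clustering separates enantiomers and keeps the majority", {
  set.seed(53)
  S <- matrix(rnorm(60, sd = 5), 20, 3)
  Sm <- S; Sm[, 1] <- -Sm[, 1]              # exact mirror image
  mk <- function(coords, score) new("Model3D", coords = coords, score = score,
                                    seed = 1L, converged = TRUE)
  models <- c(lapply(1:7, function(i) mk(S %*% randomRotation(), i)),
              lapply(1:3, function(i) mk(Sm %*% randomRotation(), 10 + i)))
  er <- new("EnsembleResult", models = models, selected = 1:10,
            clusters = integer(0), keptCluster = NA_integer_,
            mirrored = FALSE, chrom = "r", start = 0, binSize = 1)
  er <- clusterMirror(er)
  expect_equal(sort(tabulate(er@clusters, 2)), c(3, 7))
  expect_true(er@mirrored)
  expect_equal(sum(er@clusters == er@keptCluster), 7)  # majority kept
  # medoids are exact enantiomers: reflected superposition is ~0
  med <- vapply(1:2, function(g) which(er@clusters == g)[1], integer(1))
  expect_lt(superposeRMSD(models[[med[1]]]@coords, models[[med[2]]]@coords,
                          reflect = TRUE), 1e-6)
  # self-distance after superposition is zero
  expect_equal(superposeRMSD(S, S %*% randomRotation()), 0, tolerance = 1e-9)
})

test_that("identical ensembles collapse to a single cluster with a warning", {
  S <- matrix(rnorm(30), 10, 3)
  models <- lapply(1:4, function(i)
    new("Model3D", coords = S, score = 1, seed = 1L, converged = TRUE))
  er <- new("EnsembleResult", models = models, selected = 1:4,
            clusters = integer(0), keptCluster = NA_integer_,
            mirrored = FALSE, chrom = "r", start = 0, binSize = 1)
  expect_warning(er <- clusterMirror(er), "single cluster")
  expect_equal(er@keptCluster, 1L)
  expect_true(all(er@clusters == 1L))
})

test_that("virtual Hi-C is symmetric, rigid-motion invariant, and rank-inverting", {
  set.seed(54)
  mk <- function(coords) new("Model3D", coords = coords, score = 1,
                             seed = 1L, converged = TRUE)
  base <- matrix(rnorm(36, sd = 4), 12, 3)
  models <- lapply(1:5, function(i) mk(base + rnorm(36, sd = 0.2)))
  er <- new("EnsembleResult", models = models, selected = 1:5,
            clusters = rep(1L, 5), keptCluster = 1L, mirrored = FALSE,
            chrom = "r", start = 0, binSize = 1)
  vh <- virtualHiC(er, "distance")
  expect_equal(vh@values, t(vh@values))
  expect_true(all(diag(vh@values) == 0))
  # single-model cluster equals that model's own distance matrix
  er1 <- er; er1@selected <- 1L; er1@clusters <- 1L
  expect_equal(virtualHiC(er1, "distance")@values,
               as.matrix(dist(models[[1]]@coords)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # applying one rigid motion to every model leaves the vhic unchanged
  R <- randomRotation(); tr <- c(3, -2, 7)
  erR <- er
  erR@models <- lapply(models, function(m)
    mk(sweep(m@coords %*% R, 2, -tr)))
  expect_equal(virtualHiC(erR, "distance")@values, vh@values,
               tolerance = 1e-9)
  # contact mode inverts the distance ranking off the diagonal
  vc <- virtualHiC(er, "contact")
  off <- upper.tri(vh@values)
  expect_equal(cor(vc@values[off], vh@values[off], method = "spearman"), -1)
  expect_equal(unique(diag(vc@values)), max(vc@values[off]))
})
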
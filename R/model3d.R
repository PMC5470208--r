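#' Build spatial restraints from binned 4C profiles
#'
#' Uses 4C signal as a proxy of spatial distance: per viewpoint, the z-scored
#' signal is averaged into bins of \code{binSize} over the modelled region,
#' and every bin passing the Z-score cut gets a harmonic restraint to the
#' viewpoint bin with target distance affine in the min-max normalised binned
#' signal s: d = dMax - s * (dMax - dMin).  Stronger signal thus means
#' shorter target distance (signal inversely related to distance) while the
#' targets stay bounded in [dMin, dMax].  Consecutive bins get connectivity
#' restraints at dMin; every other pair gets an excluded-volume lower bound
#' at dEv.
#'
#' @param profiles list of \code{FourCProfile}s (rpm and z filled) on one
#'   chromosome.
#' @param regionStart,regionEnd modelled interval, 0-based half-open bp.
#' @param binSize particle size in bp.
#' @param dMin,dMax distance scale bounds (arbitrary units; defaults 1, 100).
#' @param zCut Z-score significance cut for restrained bins (default 0).
#' @param k harmonic force constant (default 1).
#' @param dEv excluded-volume lower bound (default 2 * dMin).
#' @param transform monotone increasing transform applied to the binned
#'   signal before min-max normalisation (default \code{log1p}: 4C signal
#'   decays over orders of magnitude, and without compression the distance
#'   map collapses all mid- and long-range bins onto dMax; use
#'   \code{identity} for the plain affine map).
#' @return a \code{RestraintSet}.
#' @export
buildRestraints <- function(profiles, regionStart, regionEnd, binSize,
                            dMin = 1, dMax = 100, zCut = 0, k = 1,
                            dEv = 2 * dMin, transform = log1p) {
  if (is(profiles, "FourCProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1, binSize > 0, regionEnd > regionStart)
  nP <- as.integer(ceiling((regionEnd - regionStart) / binSize))
  if (nP < 3) stop("modelled region smaller than 3 bins")
  chrom <- profiles[[1]]@chrom
  harmon <- list()
  vpBins <- integer(0)
  for (prof in profiles) {
    stopifnot(is(prof, "FourCProfile"), length(prof@rpm) > 0,
              length(prof@z) > 0)
    if (prof@chrom != chrom) stop("profiles on different chromosomes")
    vpPos <- prof@viewpoint@position
    if (vpPos < regionStart || vpPos >= regionEnd)
      stop("viewpoint ", prof@viewpoint@name, " outside the modelled region")
    vpBin <- as.integer(floor((vpPos - regionStart) / binSize)) + 1L
    vpBins <- c(vpBins, vpBin)
    b <- floor((prof@ends - regionStart) / binSize) + 1
    keep <- b >= 1 & b <= nP & !prof@masked
    sig <- tapply(prof@rpm[keep], b[keep], mean)
    zb <- tapply(prof@z[keep], b[keep], mean)
    bins <- as.integer(names(sig))
    sel <- zb > zCut & bins != vpBin
    bins <- bins[sel]; sig <- transform(as.numeric(sig[sel]))
    if (!length(bins)) next
    rng <- range(sig)
    s <- if (diff(rng) > 0) (sig - rng[1]) / diff(rng) else rep(1, length(sig))
    harmon[[length(harmon) + 1L]] <- data.frame(
      i = pmin(vpBin, bins), j = pmax(vpBin, bins),
      d = dMax - s * (dMax - dMin), k = k, kind = "harmonic",
      stringsAsFactors = FALSE)
  }
  harmon <- if (length(harmon)) do.call(rbind, harmon) else
    data.frame(i = integer(0), j = integer(0), d = numeric(0), k = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  if (nrow(harmon)) {
    # the same pair restrained from several viewpoints: average the targets
    key <- paste(harmon$i, harmon$j)
    harmon <- do.call(rbind, lapply(split(harmon, key), function(g)
      data.frame(i = g$i[1], j = g$j[1], d = mean(g$d), k = g$k[1],
                 kind = "harmonic", stringsAsFactors = FALSE)))
  }
  conn <- data.frame(i = seq_len(nP - 1L), j = seq_len(nP - 1L) + 1L,
                     d = dMin, k = k, kind = "connectivity",
                     stringsAsFactors = FALSE)
  taken <- c(paste(harmon$i, harmon$j), paste(conn$i, conn$j))
  allPairs <- which(upper.tri(matrix(0, nP, nP)), arr.ind = TRUE)
  keyAll <- paste(allPairs[, 1], allPairs[, 2])
  free <- !(keyAll %in% taken)
  ev <- data.frame(i = allPairs[free, 1], j = allPairs[free, 2],
                   d = dEv, k = k, kind = "excluded",
                   stringsAsFactors = FALSE)
  pairs <- rbind(harmon, conn, ev)
  rownames(pairs) <- NULL
  rs <- new("RestraintSet", nParticles = nP, pairs = pairs,
            dMin = as.numeric(dMin), dMax = as.numeric(dMax),
            dEv = as.numeric(dEv), chrom = chrom,
            start = as.numeric(regionStart), binSize = as.numeric(binSize),
            vpBins = unique(vpBins))
  validObject(rs)
  rs
}

#' Optimize one 3D model against a RestraintSet
#'
#' Coordinates are initialised uniformly at random in a cube of side
#' dMax * n^(1/3) from \code{seed}, and the total harmonic-violation energy is
#' minimised by gradient descent with adaptive step size plus annealing
#' perturbation cycles (perturbation noise also drawn from \code{seed}, so
#' the whole optimisation is a deterministic function of the restraints and
#' the seed).  The best-seen state is returned, so the final energy never
#' exceeds the energy at initialisation.
#'
#' @param rs a \code{RestraintSet}.
#' @param seed integer seed.
#' @param iterations gradient-descent iterations per cycle (default 250).
#' @param cycles number of annealing cycles (default 3).
#' @param lr initial step size (default 0.05).
#' @return a \code{Model3D} (converged = FALSE flags a run still improving in
#'   its final cycle).
#' @export
optimizeModel <- function(rs, seed, iterations = 250L, cycles = 3L,
                          lr = 0.05) {
  stopifnot(is(rs, "RestraintSet"))
  n <- rs@nParticles
  side <- rs@dMax * n^(1 / 3)
  rng <- withSeed(as.integer(seed), {
    list(init = matrix(stats::runif(3 * n, -side / 2, side / 2), n, 3),
         noise = matrix(stats::rnorm(max(1, (cycles - 1)) * n * 3),
                        max(1, (cycles - 1)) * n, 3))
  })
  amp <- 0.15 * rs@dMax * 0.5^(seq_len(max(1, cycles - 1)) - 1)
  res <- optimizeModelCpp(
    rng$init,
    as.integer(rs@pairs$i) - 1L, as.integer(rs@pairs$j) - 1L,
    as.numeric(rs@pairs$d), as.numeric(rs@pairs$k),
    as.integer(rs@pairs$kind == "excluded"),
    rng$noise, rep(as.integer(iterations), cycles), amp, lr)
  new("Model3D", coords = res$coords, score = res$score,
      seed = as.integer(seed), converged = res$converged)
}

# evaluate expr with a temporary RNG state seeded by seed
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Restraint energy of a coordinate set
#' @param rs a RestraintSet.
#' @param coords nParticles x 3 matrix.
#' @return total energy (harmonic violations squared times force constants).
#' @export
restraintEnergy <- function(rs, coords) {
  p <- rs@pairs
  d <- sqrt(rowSums((coords[p$i, , drop = FALSE] -
                     coords[p$j, , drop = FALSE])^2))
  viol <- d - p$d
  viol[p$kind == "excluded" & viol > 0] <- 0
  sum(p$k * viol^2)
}

#' Generate and select a model ensemble
#'
#' Runs \code{nModels} independent optimisations with seeds
#' \code{baseSeed .. baseSeed + nModels - 1} and selects the \code{nKeep}
#' lowest-energy models.  The reference configuration is 50,000 models with
#' the 200 top-scoring kept (keep fraction 0.4\%); the default here is the
#' desk-scale 2,000 / 20.
#'
#' @param rs a \code{RestraintSet}.
#' @param nModels ensemble size (default 2000).
#' @param nKeep top-scoring models kept (default 20).
#' @param baseSeed first seed of the seed ladder.
#' @param ... passed to \code{\link{optimizeModel}}.
#' @return an \code{EnsembleResult} with models and selected filled.
#' @export
runEnsemble <- function(rs, nModels = 2000L, nKeep = 20L, baseSeed = 1L, ...) {
  stopifnot(nKeep <= nModels, nModels >= 1)
  models <- lapply(seq_len(nModels) - 1L,
                   function(i) optimizeModel(rs, baseSeed + i, ...))
  scores <- vapply(models, function(m) m@score, numeric(1))
  selected <- order(scores)[seq_len(nKeep)]
  new("EnsembleResult", models = models, selected = as.integer(selected),
      clusters = integer(0), keptCluster = NA_integer_, mirrored = FALSE,
      chrom = rs@chrom, start = rs@start, binSize = rs@binSize)
}

#' RMSD after optimal rigid superposition (Kabsch, rotation only)
#'
#' Proper rotations only (no reflection), so enantiomers do NOT superpose to
#' zero; set \code{reflect = TRUE} to mirror P through the yz plane first.
#'
#' @param P,Q n x 3 coordinate matrices.
#' @param reflect reflect P before superposing.
#' @return root-mean-square deviation after centering and optimal rotation.
#' @export
superposeRMSD <- function(P, Q, reflect = FALSE) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  if (reflect) P[, 1] <- -P[, 1]
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((P %*% R - Q)^2)))
}

#' Mirror-aware two-way clustering of the selected ensemble
#'
#' Distance restraints cannot distinguish a structure from its mirror image,
#' so a selected ensemble typically splits into two enantiomeric populations.
#' Pairwise rotation-only superposition RMSDs over the selected models are
#' clustered by average linkage and cut at two clusters; the clusters are
#' declared mirror images if reflecting one cluster medoid and re-superposing
#' it onto the other reduces their RMSD by at least 50\%.  The most populated
#' cluster is kept (ties broken by the lower medoid score).
#'
#' @param er an \code{EnsembleResult} with selected filled (>= 2 models).
#' @return the EnsembleResult with clusters, keptCluster and mirrored filled.
#' @export
clusterMirror <- function(er) {
  stopifnot(is(er, "EnsembleResult"), length(er@selected) >= 2)
  sel <- er@models[er@selected]
  m <- length(sel)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    D[i, j] <- D[j, i] <- superposeRMSD(sel[[i]]@coords, sel[[j]]@coords)
  scale0 <- mean(vapply(sel, function(x)
    sqrt(mean(sweep(x@coords, 2, colMeans(x@coords))^2)), numeric(1)))
  if (max(D) <= 1e-9 * (1 + scale0)) {
    warning("all selected models identical; single cluster, mirror check skipped")
    er@clusters <- rep(1L, m)
    er@keptCluster <- 1L
    er@mirrored <- FALSE
    return(er)
  }
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"), 2)
  medoid <- vapply(1:2, function(g) {
    idx <- which(cl == g)
    idx[which.min(rowSums(D[idx, idx, drop = FALSE]))]
  }, integer(1))
  dd <- D[medoid[1], medoid[2]]
  rd <- superposeRMSD(sel[[medoid[1]]]@coords, sel[[medoid[2]]]@coords,
                      reflect = TRUE)
  er@mirrored <- dd > 0 && rd <= 0.5 * dd
  sizes <- tabulate(cl, 2)
  kept <- if (sizes[1] != sizes[2]) which.max(sizes) else {
    sc <- vapply(medoid, function(i) sel[[i]]@score, numeric(1))
    which.min(sc)
  }
  er@clusters <- as.integer(cl)
  er@keptCluster <- as.integer(kept)
  er
}

#' Virtual Hi-C from the kept model cluster
#'
#' Distance mode: entry (i, j) is the mean Euclidean distance between
#' particles i and j over the kept-cluster models.  Contact mode: the
#' reciprocal of the mean distance (suitable as directionality-index input),
#' with the diagonal set to the maximum off-diagonal contact.
#'
#' @param er an \code{EnsembleResult} with keptCluster filled.
#' @param mode "distance" or "contact".
#' @return a \code{ContactMatrix}.
#' @export
virtualHiC <- function(er, mode = c("distance", "contact")) {
  mode <- match.arg(mode)
  stopifnot(is(er, "EnsembleResult"))
  if (is.na(er@keptCluster)) stop("kept cluster not set; run clusterMirror first")
  keep <- er@selected[er@clusters == er@keptCluster]
  if (!length(keep)) stop("kept cluster is empty")
  mats <- lapply(er@models[keep], function(m)
    as.matrix(stats::dist(m@coords)))
  meanD <- Reduce(`+`, mats) / length(mats)
  v <- if (mode == "distance") meanD else {
    off <- meanD[upper.tri(meanD)]
    c0 <- 1 / pmax(meanD, 1e-9)
    diag(c0) <- max(1 / pmax(off, 1e-9))
    c0
  }
  contactMatrix(v, binSize = er@binSize, chrom = er@chrom, start = er@start)
}

#' Write ensemble models as XYZ-style TSV plus a score manifest
#' @param er an EnsembleResult.
#' @param dir output directory (created if needed).
#' @export
writeEnsembleTSV <- function(er, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- er@selected
  for (i in sel) {
    m <- er@models[[i]]
    df <- data.frame(particle = seq_len(nrow(m@coords)),
                     x = m@coords[, 1], y = m@coords[, 2], z = m@coords[, 3])
    utils::write.table(df, file.path(dir, sprintf("model_%05d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    model = sel,
    score = vapply(er@models[sel], function(m) m@score, numeric(1)),
    seed = vapply(er@models[sel], function(m) m@seed, integer(1)),
    cluster = if (length(er@clusters)) er@clusters else NA_integer_)
  utils::write.table(manifest, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

setMethod("show", "RestraintSet", function(object) {
  tb <- table(object@pairs$kind)
  cat(sprintf("RestraintSet: %d particles (%g bp bins on %s), %d restraints (%s)\n",
              object@nParticles, object@binSize, object@chrom,
              nrow(object@pairs),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d models, %d selected%s\n",
              length(object@models), length(object@selected),
              if (!is.na(object@keptCluster))
                sprintf(", kept cluster %d (%d models, mirrored=%s)",
                        object@keptCluster,
                        sum(object@clusters == object@keptCluster),
                        object@mirrored)
              else ""))
})
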
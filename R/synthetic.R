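#' Construct a LandscapeSpec
#'
#' Parameters of a synthetic TAD landscape.  Defaults emulate a 4C-scale
#' regulatory region: square-root polymer distance growth, a 2-fold
#' cross-boundary insulation penalty, distance-decay exponent 2 (so expected
#' counts fall off roughly as 1/|i-j|), 1e5 reads per viewpoint and mild
#' negative-binomial overdispersion.
#'
#' @param nBins number of bins.
#' @param binSize bin size in bp.
#' @param tads list of c(start, end) bin intervals (0-based half-open) tiling
#'   [0, nBins), or a data.frame(start, end).
#' @param insulation cross-boundary distance penalty factor >= 1 (default 2).
#' @param loops data.frame(i, j, strength): planted loops; strength > 1
#'   divides the pairwise distance.
#' @param alpha distance-decay exponent for 4C counts (default 2).
#' @param coverage expected total reads per viewpoint (default 1e5).
#' @param dispersion negative-binomial overdispersion; 0 means Poisson
#'   (default 0.1).
#' @param seed generator seed.
#' @return a \code{LandscapeSpec}.
#' @export
landscapeSpec <- function(nBins, binSize = 5000, tads = list(c(0, nBins)),
                          insulation = 2, loops = NULL, alpha = 2,
                          coverage = 1e5, dispersion = 0.1, seed = 1L) {
  if (is.list(tads) && !is.data.frame(tads))
    tads <- data.frame(start = vapply(tads, `[`, numeric(1), 1),
                       end = vapply(tads, `[`, numeric(1), 2))
  if (is.null(loops))
    loops <- data.frame(i = integer(0), j = integer(0), strength = numeric(0))
  sp <- new("LandscapeSpec", nBins = as.integer(nBins),
            binSize = as.numeric(binSize), tads = tads,
            insulation = as.numeric(insulation), loops = loops,
            alpha = as.numeric(alpha), coverage = as.numeric(coverage),
            dispersion = as.numeric(dispersion), seed = as.integer(seed))
  validObject(sp)
  sp
}

#' Generate a random genome with controlled restriction-site layout
#'
#' Builds a random sequence in which primary sites are planted at
#' geometrically spaced cuts around \code{meanFragmentLen} and a secondary
#' site is planted near the middle of every fragment (so nearly all fragments
#' are valid), while accidental occurrences of either site are scrubbed.
#' Digesting the output therefore yields a valid-fragment count within ~10%
#' of \code{nFragmentsTarget}.  Deterministic given the seed.
#'
#' @param nFragmentsTarget desired number of valid fragments (>= 1).
#' @param meanFragmentLen mean fragment length in bp (> 2x the site lengths).
#' @param seed integer seed.
#' @param primarySite,secondarySite recognition sequences (defaults
#'   GATC/GTAC).
#' @param name chromosome name.
#' @param minLen valid-fragment length threshold (default 40).
#' @return a one-record \code{DNAStringSet}.
#' @export
makeGenome <- function(nFragmentsTarget, meanFragmentLen = 500, seed = 1L,
                       primarySite = "GATC", secondarySite = "GTAC",
                       name = "chrS", minLen = 40) {
  if (nFragmentsTarget < 1) stop("nFragmentsTarget must be >= 1")
  lenP <- nchar(primarySite); lenS <- nchar(secondarySite)
  minGap <- max(2 * minLen, 4 * (lenP + lenS))
  if (meanFragmentLen <= minGap)
    stop("infeasible spacing: meanFragmentLen must exceed ", minGap)
  withSeed(as.integer(seed), {
    gaps <- minGap + stats::rgeom(nFragmentsTarget,
                                  1 / (meanFragmentLen - minGap + 1))
    cuts <- cumsum(gaps[-length(gaps)])
    L <- sum(gaps)
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # plant primary sites at the cuts, secondary near fragment midpoints
    bounds <- c(0, cuts, L)
    protected <- integer(0)
    for (c0 in cuts) {
      chars[(c0 + 1):(c0 + lenP)] <- strsplit(primarySite, "")[[1]]
      protected <- c(protected, (c0 + 1):(c0 + lenP))
    }
    for (f in seq_len(length(bounds) - 1)) {
      mid <- floor((bounds[f] + bounds[f + 1]) / 2)
      chars[(mid + 1):(mid + lenS)] <- strsplit(secondarySite, "")[[1]]
      protected <- c(protected, (mid + 1):(mid + lenS))
    }
    prot <- logical(L); prot[protected] <- TRUE
    # scrub accidental occurrences of either site
    for (pass in 1:25) {
      seq <- Biostrings::DNAString(paste(chars, collapse = ""))
      occ <- integer(0)
      for (site in unique(c(primarySite, secondarySite))) {
        st <- start(Biostrings::matchPattern(site, seq))
        w <- nchar(site)
        intended <- vapply(st, function(s) all(prot[s:(s + w - 1)]),
                           logical(1))
        occ <- c(occ, st[!intended])
        if (any(!intended)) {
          for (s in st[!intended]) {
            mutable <- setdiff(s:(s + w - 1), which(prot))
            if (!length(mutable)) next
            p <- mutable[1]
            chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
          }
        }
      }
      if (!length(occ)) break
    }
    out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(out) <- name
    out
  })
}

#' Ground-truth distances and 3D structure for a landscape
#'
#' Target pairwise distances follow an equilibrium-globule-like kernel,
#' d_ij = |i - j|^0.5 * insulation^(number of TAD boundaries crossed), with
#' planted loops dividing their pair's distance by the loop strength.  A 3D
#' embedding consistent with these distances is produced by classical scaling
#' followed by gradient-descent stress minimisation and stored alongside.
#'
#' @param spec a \code{LandscapeSpec}.
#' @return a \code{GroundTruth}.
#' @export
makeStructure <- function(spec) {
  stopifnot(is(spec, "LandscapeSpec"))
  n <- spec@nBins
  idx <- seq_len(n) - 1L
  d <- sqrt(abs(outer(idx, idx, "-")))
  bnd <- internalBoundaries(spec)
  if (length(bnd) && spec@insulation > 1) {
    lo <- outer(idx, idx, pmin); hi <- outer(idx, idx, pmax)
    crossings <- Reduce(`+`, lapply(bnd, function(b) (lo < b) & (b <= hi)))
    d <- d * spec@insulation^crossings
  }
  if (nrow(spec@loops)) for (r in seq_len(nrow(spec@loops))) {
    i <- spec@loops$i[r] + 1L; j <- spec@loops$j[r] + 1L
    d[i, j] <- d[i, j] / spec@loops$strength[r]
    d[j, i] <- d[i, j]
  }
  structure3d <- embedDistances(d)
  new("GroundTruth", boundaries = as.integer(bnd), loops = spec@loops,
      structure = structure3d, distance = d, spec = spec)
}

#' Internal TAD boundaries of a LandscapeSpec (0-based bin starts)
#' @param spec a LandscapeSpec.
#' @export
internalBoundaries <- function(spec) {
  b <- sort(spec@tads$start)
  b[b > 0]
}

# classical scaling init + all-pairs harmonic stress minimisation (in C++)
embedDistances <- function(d, iterations = 400L) {
  n <- nrow(d)
  init <- suppressWarnings(stats::cmdscale(d, k = 3))
  if (ncol(init) < 3)
    init <- cbind(init, matrix(0, n, 3 - ncol(init)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  res <- optimizeModelCpp(init, pairs[, 1] - 1L, pairs[, 2] - 1L,
                          d[pairs], rep(1, nrow(pairs)),
                          integer(nrow(pairs)),
                          matrix(0, n, 3), as.integer(iterations),
                          numeric(1), 0.01)
  res$coords
}

#' Simulate multi-viewpoint 4C bin counts from a ground truth
#'
#' Inverts the modelling assumption that 4C signal is inversely related to
#' spatial distance: expected counts at bin j for viewpoint bin v are
#' mu_j = coverage * d(v, j)^(-alpha) / sum_k d(v, k)^(-alpha) (the viewpoint
#' bin itself is excluded), drawn negative-binomial with the requested
#' overdispersion (Poisson when dispersion = 0).
#'
#' @param gt a \code{GroundTruth}.
#' @param viewpoints 0-based viewpoint bins.
#' @param seed RNG seed (default: the spec's).
#' @param noiseless return the expectations instead of sampling.
#' @return named list (one entry per viewpoint bin) of per-bin counts.
#' @export
simulate4C <- function(gt, viewpoints, seed = gt@spec@seed,
                       noiseless = FALSE) {
  stopifnot(is(gt, "GroundTruth"),
            all(viewpoints >= 0 & viewpoints < gt@spec@nBins))
  spec <- gt@spec
  out <- withSeed(as.integer(seed), {
    lapply(viewpoints, function(v) {
      d <- gt@distance[v + 1L, ]
      w <- d^(-spec@alpha)
      w[v + 1L] <- 0
      mu <- spec@coverage * w / sum(w[is.finite(w)])
      mu[!is.finite(mu)] <- 0
      if (noiseless) return(mu)
      if (spec@dispersion <= 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / spec@dispersion)
    })
  })
  names(out) <- as.character(viewpoints)
  out
}

#' Spread per-bin counts over valid fragment ends as a reads table
#'
#' Each bin's count is distributed round-robin (as evenly as integer counts
#' allow) over the valid fragment-end coordinates inside the bin.
#'
#' @param counts per-bin counts (bin 0 first).
#' @param map a filtered \code{FragmentMap}.
#' @param chrom chromosome of the region.
#' @param binSize bin size in bp.
#' @param regionStart 0-based start of bin 0 (default 0).
#' @return data.frame(chrom, pos, count) suitable for
#'   \code{\link{assignReads}}.
#' @export
binCountsToReads <- function(counts, map, chrom, binSize, regionStart = 0) {
  ends <- fragmentEnds(map, chrom = chrom)$end
  bin <- floor((ends - regionStart) / binSize)
  keep <- bin >= 0 & bin < length(counts)
  ends <- ends[keep]; bin <- bin[keep]
  rows <- lapply(which(counts > 0) - 1L, function(b) {
    e <- ends[bin == b]
    if (!length(e)) return(NULL)
    c0 <- counts[b + 1L]
    base <- c0 %/% length(e)
    extra <- c0 %% length(e)
    cnt <- rep(base, length(e)) + c(rep(1, extra), rep(0, length(e) - extra))
    data.frame(chrom = chrom, pos = e[cnt > 0], count = cnt[cnt > 0])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      count = numeric(0))
  out
}

#' Simulate full 4C profiles for a set of viewpoint bins
#'
#' Composes \code{\link{simulate4C}}, \code{\link{binCountsToReads}},
#' \code{\link{assignReads}}, smoothing, RPM normalisation and Z-scoring into
#' ready-to-model profiles.  Each viewpoint is anchored on the first valid
#' fragment starting in its bin.
#'
#' @param gt a \code{GroundTruth}.
#' @param map a filtered \code{FragmentMap} covering the region.
#' @param chrom chromosome name in the map.
#' @param viewpointBins 0-based viewpoint bins.
#' @param seed RNG seed (default: the spec's).
#' @param window smoothing window in ends (default 30).
#' @param noiseless use expected counts instead of sampling.
#' @return list of \code{FourCProfile}s (raw/smoothed/rpm/z filled).
#' @export
simulateProfiles <- function(gt, map, chrom, viewpointBins,
                             seed = gt@spec@seed, window = 30L,
                             noiseless = FALSE) {
  stopifnot(is(gt, "GroundTruth"))
  binSize <- gt@spec@binSize
  ends <- fragmentEnds(map, chrom = chrom)
  counts <- simulate4C(gt, viewpointBins, seed = seed, noiseless = noiseless)
  lapply(seq_along(viewpointBins), function(k) {
    v <- viewpointBins[k]
    cnt <- counts[[k]]
    if (noiseless) cnt <- round(cnt)
    reads <- binCountsToReads(cnt, map, chrom, binSize)
    hit <- which(ends$fragStart >= v * binSize &
                   ends$fragStart < (v + 1) * binSize)
    if (!length(hit))
      hit <- which.min(abs(ends$fragStart - (v + 0.5) * binSize))
    vp <- viewpoint(sprintf("vp%d", v), chrom, ends$fragStart[hit[1]])
    zscoreProfile(normaliseRPM(smoothProfile(assignReads(reads, map, vp),
                                             window)))
  })
}

#' Fuse two synthetic landscapes at intra-TAD breakpoints
#'
#' Builds the derivative landscape A[0, breakA) + B[breakB, end).  Both
#' breaks must be interior to a TAD (a break at an existing boundary is an
#' error).  The junction itself carries no insulation penalty, so the two
#' retained sub-TADs mix freely into a single fused TAD spanning from the
#' last A boundary upstream of breakA to the first (shifted) B boundary
#' downstream of breakB.
#'
#' @param specA,specB parental \code{LandscapeSpec}s.
#' @param breakA,breakB 0-based break bins (A keeps [0, breakA), B keeps
#'   [breakB, nBins)).
#' @return list(spec, truth, fusedTad = c(lo, hi), junction = breakA);
#'   truth is the regenerated \code{GroundTruth} of the fused region.
#' @export
makeFusedLandscape <- function(specA, specB, breakA, breakB) {
  stopifnot(is(specA, "LandscapeSpec"), is(specB, "LandscapeSpec"))
  bndA <- c(0, internalBoundaries(specA), specA@nBins)
  bndB <- c(0, internalBoundaries(specB), specB@nBins)
  if (breakA %in% bndA) stop("breakA falls on an existing boundary of A")
  if (breakB %in% bndB) stop("breakB falls on an existing boundary of B")
  if (breakA < 1 || breakA >= specA@nBins || breakB < 1 ||
      breakB >= specB@nBins) stop("break bins out of range")
  shift <- breakA - breakB
  nFused <- breakA + (specB@nBins - breakB)
  bounds <- sort(unique(c(internalBoundaries(specA)[internalBoundaries(specA) < breakA],
                          internalBoundaries(specB)[internalBoundaries(specB) > breakB] + shift)))
  edges <- c(0, bounds, nFused)
  tads <- data.frame(start = edges[-length(edges)], end = edges[-1])
  la <- specA@loops; la <- la[la$i < breakA & la$j < breakA, , drop = FALSE]
  lb <- specB@loops; lb <- lb[lb$i >= breakB & lb$j >= breakB, , drop = FALSE]
  lb$i <- lb$i + shift; lb$j <- lb$j + shift
  fused <- landscapeSpec(nBins = nFused, binSize = specA@binSize, tads = tads,
                         insulation = specA@insulation, loops = rbind(la, lb),
                         alpha = specA@alpha, coverage = specA@coverage,
                         dispersion = specA@dispersion, seed = specA@seed)
  lo <- max(c(0, bounds[bounds < breakA]))
  hi <- min(c(bounds[bounds >= breakA], nFused))
  list(spec = fused, truth = makeStructure(fused),
       fusedTad = c(lo, hi), junction = breakA)
}

#' Write a GroundTruth to disk (JSON summary + TSV matrices)
#' @param gt a GroundTruth.
#' @param dir output directory.
#' @export
writeGroundTruth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(boundaries = gt@boundaries, loops = gt@loops,
         nBins = gt@spec@nBins, binSize = gt@spec@binSize,
         insulation = gt@spec@insulation, alpha = gt@spec@alpha),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(gt@distance, file.path(dir, "true_distance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(gt@structure, file.path(dir, "true_structure.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: %d bins x %g bp, %d TADs, %d loops, insulation %g, alpha %g\n",
              object@nBins, object@binSize, nrow(object@tads),
              nrow(object@loops), object@insulation, object@alpha))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d bins, boundaries at {%s}, %d loops\n",
              object@spec@nBins,
              paste(object@boundaries, collapse = ", "),
              nrow(object@loops)))
})
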
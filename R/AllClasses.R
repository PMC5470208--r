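#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' FragmentMap: restriction-fragment coordinate system
#'
#' Ordered primary-enzyme restriction fragments per chromosome, the coordinate
#' backbone of all 4C operations.  Fragments are stored as a
#' \code{\link[GenomicRanges]{GRanges}} (1-based closed internally; all exported
#' coordinates are 0-based half-open) with metadata columns \code{index}
#' (0-based ordinal per chromosome), \code{blind} (no secondary-enzyme site
#' strictly inside) and \code{short} (length below \code{minLen}).
#'
#' @slot fragments GRanges of fragments with mcols index, blind, short.
#' @slot primarySite,secondarySite recognition sequences used for digestion.
#' @slot minLen minimum fragment length in bp (fragments below are flagged short).
#' @slot filtered TRUE if blind/short fragments have been removed.
#' @exportClass FragmentMap
setClass("FragmentMap", slots = c(
  fragments    = "GRanges",
  primarySite  = "character",
  secondarySite = "character",
  minLen       = "integer",
  filtered     = "logical"
))

setValidity("FragmentMap", function(object) {
  gr <- object@fragments
  need <- c("index", "blind", "short")
  if (!all(need %in% colnames(mcols(gr))))
    return("fragments must carry mcols index, blind, short")
  for (ch in unique(as.character(seqnames(gr)))) {
    f <- gr[seqnames(gr) == ch]
    f <- f[order(start(f))]
    if (!object@filtered) {
      if (any(diff(mcols(f)$index) != 1L) || mcols(f)$index[1] != 0L)
        return(sprintf("indices not consecutive from 0 on %s", ch))
      if (length(f) > 1 && any(end(f)[-length(f)] != start(f)[-1] - 1L))
        return(sprintf("fragments do not tile %s without gaps/overlaps", ch))
    }
  }
  TRUE
})

#' Viewpoint: a 4C anchor locus
#'
#' @slot name viewpoint identifier.
#' @slot chrom chromosome identifier.
#' @slot position anchor coordinate, 0-based bp.
#' @slot exclusionRadius number of valid fragments on each side of the
#'   viewpoint fragment whose ends are masked (self-ligation dead zone).
#' @exportClass Viewpoint
setClass("Viewpoint", slots = c(
  name = "character", chrom = "character",
  position = "numeric", exclusionRadius = "integer"
))

#' FourCProfile: per-viewpoint fragment-end 4C signal
#'
#' Holds the ordered valid-fragment-end coordinates of one chromosome (or
#' derivative) together with the signal layers filled in by the pipeline:
#' \code{raw} fragment-end read counts, \code{smoothed} running-mean signal,
#' \code{rpm} reads-per-million normalised signal and \code{z} Z-scores.
#' Unfilled layers are length-zero.
#'
#' @slot viewpoint the \code{Viewpoint} this profile belongs to.
#' @slot chrom chromosome the ends live on.
#' @slot ends strictly increasing 0-based fragment-end coordinates.
#' @slot fragIndex index of the valid fragment owning each end (leftmost owner
#'   at shared cut sites).
#' @slot fragStart,fragEnd 0-based half-open interval of the owning fragment.
#' @slot masked TRUE for ends inside the viewpoint exclusion zone.
#' @slot raw,smoothed,rpm,z signal layers, each |ends| long when filled.
#' @slot window smoothing window (number of ends).
#' @slot discarded reads that matched no valid fragment end.
#' @slot rescaled guard flag: derivative dosage rescaling already applied.
#' @exportClass FourCProfile
setClass("FourCProfile", slots = c(
  viewpoint = "Viewpoint", chrom = "character",
  ends = "numeric", fragIndex = "integer",
  fragStart = "numeric", fragEnd = "numeric",
  masked = "logical",
  raw = "numeric", smoothed = "numeric", rpm = "numeric", z = "numeric",
  window = "integer", discarded = "integer", rescaled = "logical"
))

setValidity("FourCProfile", function(object) {
  n <- length(object@ends)
  if (n > 1 && any(diff(object@ends) <= 0))
    return("ends must be strictly increasing")
  for (layer in c("raw", "smoothed", "rpm", "z")) {
    v <- slot(object, layer)
    if (length(v) && length(v) != n)
      return(sprintf("layer %s has length %d, expected %d", layer, length(v), n))
  }
  if (length(object@raw) && any(object@raw < 0))
    return("raw counts must be non-negative")
  if (length(object@masked) != n || length(object@fragIndex) != n)
    return("masked/fragIndex must match ends")
  TRUE
})

#' BreakpointSpec: a translocation junction
#'
#' Half-open junction convention: \code{posA} is exclusive on chromA (last
#' retained base + 1), \code{posB} inclusive on chromB (first retained base).
#' \code{insertion} holds any duplicated/novel sequence at the junction.
#'
#' @exportClass BreakpointSpec
setClass("BreakpointSpec", slots = c(
  chromA = "character", posA = "numeric",
  chromB = "character", posB = "numeric",
  insertion = "character"
))

setValidity("BreakpointSpec", function(object) {
  if (nchar(object@insertion) && grepl("[^ACGT]", object@insertion))
    return("insertion must be over {A,C,G,T}")
  if (object@posA < 0 || object@posB < 0) return("positions must be >= 0")
  TRUE
})

#' DerivativeGenome: fused-chromosome coordinate system
#'
#' Segment table mapping the derivative chromosome back to its native sources.
#' Segments exactly tile [0, length) in derivative coordinates.
#'
#' @slot spec the \code{BreakpointSpec}.
#' @slot segments data.frame(source, srcStart, srcEnd, derStart) in 0-based
#'   half-open coordinates; source "insertion" marks junction-inserted bases.
#' @slot length derivative length in bp.
#' @slot name derivative chromosome name.
#' @slot sequence derivative sequence (character; may be empty if built
#'   without sequences).
#' @exportClass DerivativeGenome
setClass("DerivativeGenome", slots = c(
  spec = "BreakpointSpec", segments = "data.frame",
  length = "numeric", name = "character", sequence = "character"
))

setValidity("DerivativeGenome", function(object) {
  s <- object@segments
  if (!all(c("source", "srcStart", "srcEnd", "derStart") %in% names(s)))
    return("segments must have source, srcStart, srcEnd, derStart")
  s <- s[order(s$derStart), , drop = FALSE]
  lens <- s$srcEnd - s$srcStart
  if (any(lens < 0)) return("segment srcEnd < srcStart")
  derEnd <- s$derStart + lens
  if (s$derStart[1] != 0 || derEnd[nrow(s)] != object@length ||
      (nrow(s) > 1 && any(derEnd[-nrow(s)] != s$derStart[-1])))
    return("segments must exactly tile [0, length)")
  TRUE
})

#' BackgroundFit: two-sided monotonic 4C background
#'
#' @slot values fitted background, non-decreasing up to the viewpoint end and
#'   non-increasing after it.
#' @slot residuals observed minus fitted.
#' @slot vpIndex index of the viewpoint end splitting the two arms.
#' @exportClass BackgroundFit
setClass("BackgroundFit", slots = c(
  values = "numeric", residuals = "numeric", vpIndex = "integer"
))

#' PeakSet: called 4C interaction peaks
#'
#' @slot peaks GRanges of merged peaks, mcols maxResidual and nEnds.
#' @slot threshold residual cutoff used (Q3 + 1.5 IQR).
#' @slot mergeGap merge distance in bp.
#' @exportClass PeakSet
setClass("PeakSet", slots = c(
  peaks = "GRanges", threshold = "numeric", mergeGap = "numeric"
))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  if (length(p) > 1) {
    if (is.unsorted(start(p))) return("peaks must be sorted")
    if (any(start(p)[-1] <= end(p)[-length(p)])) return("peaks must not overlap")
  }
  TRUE
})

#' ContactMatrix: binned square contact/distance matrix
#'
#' @slot values square symmetric non-negative matrix.
#' @slot binSize bin size in bp.
#' @slot chrom chromosome (or derivative) identifier.
#' @slot start 0-based start coordinate of bin 1.
#' @exportClass ContactMatrix
setClass("ContactMatrix", slots = c(
  values = "matrix", binSize = "numeric", chrom = "character", start = "numeric"
))

setValidity("ContactMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (any(!is.finite(v))) return("matrix must be finite")
  if (any(v < 0)) return("matrix must be non-negative")
  if (max(abs(v - t(v))) > 1e-6 * (1 + max(abs(v))))
    return("matrix must be symmetric")
  TRUE
})

#' DITrack: per-bin directionality index
#'
#' @slot di signed chi-square-style directionality index per bin.
#' @slot A,B upstream/downstream windowed contact sums per bin.
#' @slot windowBins bins summed per side (expected TAD size / bin size).
#' @exportClass DITrack
setClass("DITrack", slots = c(
  di = "numeric", A = "numeric", B = "numeric",
  windowBins = "integer", binSize = "numeric", chrom = "character",
  start = "numeric"
))

#' BoundaryConsensus: cross-iteration TAD-boundary consensus
#'
#' @slot candidates data.frame(bin, support, edge): candidate boundary bins
#'   (1-based), fraction of iterations supporting each, and an edge flag for
#'   bins within one window of the region end.
#' @slot selected bins meeting the support rule (or top-k).
#' @slot tadSizes expected TAD sizes (bp) iterated over.
#' @exportClass BoundaryConsensus
setClass("BoundaryConsensus", slots = c(
  candidates = "data.frame", selected = "integer",
  tadSizes = "numeric", binSize = "numeric"
))

#' RestraintSet: spatial restraints for 3D modelling
#'
#' @slot nParticles number of modelled bins.
#' @slot pairs data.frame(i, j, d, k, kind) with 1-based particle indices,
#'   target distance, force constant and kind in
#'   {"harmonic","connectivity","excluded"} ("excluded" is a lower bound).
#' @slot dMin,dMax distance scale bounds; dEv excluded-volume bound.
#' @slot vpBins viewpoint particle indices.
#' @exportClass RestraintSet
setClass("RestraintSet", slots = c(
  nParticles = "integer", pairs = "data.frame",
  dMin = "numeric", dMax = "numeric", dEv = "numeric",
  chrom = "character", start = "numeric", binSize = "numeric",
  vpBins = "integer"
))

setValidity("RestraintSet", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "d", "k", "kind") %in% names(p)))
    return("pairs must have columns i, j, d, k, kind")
  if (nrow(p) && (any(p$i >= p$j) || any(p$i < 1) || any(p$j > object@nParticles)))
    return("pairs must satisfy 1 <= i < j <= nParticles")
  h <- p$kind == "harmonic"
  if (any(p$d[h] < object@dMin - 1e-9) || any(p$d[h] > object@dMax + 1e-9))
    return("harmonic targets must lie in [dMin, dMax]")
  conn <- p[p$kind == "connectivity", , drop = FALSE]
  if (object@nParticles > 1 &&
      !all(seq_len(object@nParticles - 1) %in% conn$i[conn$j == conn$i + 1]))
    return("every adjacent pair must have a connectivity restraint")
  TRUE
})

#' Model3D: one optimized 3D chromatin model
#'
#' @slot coords nParticles x 3 coordinates (arbitrary units).
#' @slot score total restraint energy at the returned coordinates.
#' @slot seed RNG seed the model was generated from.
#' @slot converged FALSE if the optimizer hit its iteration cap while still
#'   improving.
#' @exportClass Model3D
setClass("Model3D", slots = c(
  coords = "matrix", score = "numeric", seed = "integer", converged = "logical"
))

setValidity("Model3D", function(object) {
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (object@score < 0) return("score must be >= 0")
  TRUE
})

#' EnsembleResult: optimized model ensemble and derived virtual Hi-C
#'
#' @slot models list of \code{Model3D}.
#' @slot selected indices of the top-scoring subset.
#' @slot clusters two-way cluster label per selected model (0 = unset).
#' @slot keptCluster most populated cluster label.
#' @slot mirrored TRUE if the two clusters are mirror images of each other.
#' @exportClass EnsembleResult
setClass("EnsembleResult", slots = c(
  models = "list", selected = "integer",
  clusters = "integer", keptCluster = "integer", mirrored = "logical",
  chrom = "character", start = "numeric", binSize = "numeric"
))

#' LandscapeSpec: synthetic TAD-landscape parameters
#'
#' @slot nBins,binSize region geometry.
#' @slot tads data.frame(start, end): TAD bin intervals, 0-based half-open,
#'   tiling [0, nBins).
#' @slot insulation cross-boundary distance penalty factor (>= 1).
#' @slot loops data.frame(i, j, strength): planted loops (0-based bins,
#'   strength > 1 divides the pairwise distance).
#' @slot alpha distance-decay exponent for simulated 4C counts.
#' @slot coverage expected total reads per viewpoint.
#' @slot dispersion negative-binomial overdispersion (0 = Poisson-like).
#' @slot seed generator seed.
#' @exportClass LandscapeSpec
setClass("LandscapeSpec", slots = c(
  nBins = "integer", binSize = "numeric", tads = "data.frame",
  insulation = "numeric", loops = "data.frame", alpha = "numeric",
  coverage = "numeric", dispersion = "numeric", seed = "integer"
))

setValidity("LandscapeSpec", function(object) {
  t <- object@tads[order(object@tads$start), , drop = FALSE]
  if (t$start[1] != 0 || t$end[nrow(t)] != object@nBins ||
      (nrow(t) > 1 && any(t$end[-nrow(t)] != t$start[-1])))
    return("tads must tile [0, nBins)")
  if (object@insulation < 1) return("insulation must be >= 1")
  if (nrow(object@loops) &&
      (any(object@loops$i < 0) || any(object@loops$j >= object@nBins)))
    return("loops must lie within the region")
  if (nrow(object@loops) && any(object@loops$strength <= 1))
    return("loop strength must be > 1")
  TRUE
})

#' GroundTruth: known structure behind a synthetic landscape
#'
#' @slot boundaries internal TAD-boundary bins (0-based bin starts).
#' @slot loops planted loops (as in the spec).
#' @slot structure nBins x 3 embedding consistent (by stress minimisation)
#'   with the distances.
#' @slot distance pairwise target distance matrix.
#' @slot spec the generating \code{LandscapeSpec}.
#' @exportClass GroundTruth
setClass("GroundTruth", slots = c(
  boundaries = "integer", loops = "data.frame",
  structure = "matrix", distance = "matrix", spec = "LandscapeSpec"
))
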
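#' Construct a Viewpoint
#'
#' @param name viewpoint identifier (e.g. the promoter the 4C bait sits in).
#' @param chrom chromosome identifier.
#' @param position anchor coordinate, 0-based bp.
#' @param exclusionRadius number of valid fragments on each side of the
#'   viewpoint fragment masked from analysis (self/adjacent ligation
#'   artefacts; default 2).
#' @return a \code{Viewpoint}.
#' @export
viewpoint <- function(name, chrom, position, exclusionRadius = 2L) {
  new("Viewpoint", name = as.character(name), chrom = as.character(chrom),
      position = as.numeric(position),
      exclusionRadius = as.integer(exclusionRadius))
}

setMethod("show", "Viewpoint", function(object) {
  cat(sprintf("Viewpoint %s at %s:%d (exclusion radius %d fragments)\n",
              object@name, object@chrom, as.integer(object@position),
              object@exclusionRadius))
})

#' Assign 4C reads to valid first-enzyme fragment ends
#'
#' A read whose 5' position equals a valid fragment-end coordinate exactly
#' increments that end; reads matching no valid end are counted in the
#' \code{discarded} tally.  Ends within \code{exclusionRadius} valid fragments
#' of the viewpoint fragment are zeroed and masked.
#'
#' @param reads data.frame with columns chrom, pos (0-based), count.
#' @param map a FragmentMap (filtered to valid fragments automatically).
#' @param vp a \code{Viewpoint}; its fragment must exist among the valid
#'   fragments.
#' @return a \code{FourCProfile} with the raw layer filled.
#' @export
assignReads <- function(reads, map, vp) {
  stopifnot(is(map, "FragmentMap"), is(vp, "Viewpoint"))
  if (!map@filtered) map <- validFragments(map)
  stopifnot(all(c("chrom", "pos", "count") %in% names(reads)))
  known <- unique(as.character(seqnames(fragments(map))))
  bad <- setdiff(unique(as.character(reads$chrom)), known)
  if (length(bad))
    stop("reads on unknown chromosome(s): ", paste(bad, collapse = ", "))
  prof <- emptyProfile(map, vp)
  r <- reads[reads$chrom == prof@chrom, , drop = FALSE]
  idx <- match(r$pos, prof@ends)
  hit <- !is.na(idx)
  raw <- numeric(length(prof@ends))
  if (any(hit)) {
    agg <- tapply(r$count[hit], idx[hit], sum)
    raw[as.integer(names(agg))] <- as.numeric(agg)
  }
  discarded <- sum(reads$count) - sum(r$count[hit])
  raw[prof@masked] <- 0
  prof@raw <- raw
  prof@discarded <- as.integer(discarded)
  validObject(prof)
  prof
}

#' Empty per-viewpoint profile over the valid fragment ends of a chromosome
#'
#' @param map a filtered FragmentMap.
#' @param vp a Viewpoint.
#' @return a FourCProfile with empty signal layers.
#' @export
emptyProfile <- function(map, vp) {
  if (!map@filtered) map <- validFragments(map)
  ends <- fragmentEnds(map, chrom = vp@chrom)
  inVp <- ends$fragStart <= vp@position & vp@position < ends$fragEnd
  if (!any(inVp))
    stop(sprintf("viewpoint %s at %s:%d is not inside any valid fragment",
                 vp@name, vp@chrom, as.integer(vp@position)))
  # rank fragments by position; mask ends of fragments within the radius
  fragOrd <- sort(unique(ends$fragIndex))
  vpFrag <- unique(ends$fragIndex[inVp])[1]
  vpRank <- match(vpFrag, fragOrd)
  ranks <- match(ends$fragIndex, fragOrd)
  masked <- abs(ranks - vpRank) <= vp@exclusionRadius
  new("FourCProfile", viewpoint = vp, chrom = vp@chrom,
      ends = ends$end, fragIndex = as.integer(ends$fragIndex),
      fragStart = ends$fragStart, fragEnd = ends$fragEnd,
      masked = masked, raw = numeric(0), smoothed = numeric(0),
      rpm = numeric(0), z = numeric(0), window = 30L,
      discarded = 0L, rescaled = FALSE)
}

#' Running-mean smoothing of a 4C profile
#'
#' Centered running mean over \code{window} fragment ends
#' (ceiling(w/2) - 1 before, self, remainder after), truncated at the
#' chromosome edges and renormalised by the actual window size there.
#'
#' @param profile a FourCProfile with the raw layer filled.
#' @param window number of ends averaged (default 30).
#' @return the profile with the smoothed layer filled.
#' @export
smoothProfile <- function(profile, window = 30L) {
  stopifnot(is(profile, "FourCProfile"), length(profile@raw) > 0)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  profile@smoothed <- runningMean(profile@raw, window)
  profile@window <- window
  profile
}

#' Centered running mean with edge truncation
#' @param x numeric vector.
#' @param window window size (number of elements).
#' @return numeric vector of the same length.
#' @export
runningMean <- function(x, window) {
  n <- length(x)
  before <- ceiling(window / 2) - 1L
  after <- window - before - 1L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Reads-per-million normalisation of the smoothed layer
#'
#' @param profile a FourCProfile with the smoothed layer filled.
#' @return the profile with rpm = smoothed * 1e6 / sum(smoothed).
#' @export
normaliseRPM <- function(profile) {
  stopifnot(is(profile, "FourCProfile"), length(profile@smoothed) > 0)
  tot <- sum(profile@smoothed)
  if (tot <= 0) stop("cannot normalise an all-zero profile")
  profile@rpm <- profile@smoothed * 1e6 / tot
  profile
}

#' Z-score the normalised layer
#'
#' Standardises rpm over unmasked ends with the population (n) standard
#' deviation; masked ends and constant profiles get z = 0.
#'
#' @param profile a FourCProfile with the rpm layer filled.
#' @return the profile with the z layer filled.
#' @export
zscoreProfile <- function(profile) {
  stopifnot(is(profile, "FourCProfile"), length(profile@rpm) > 0)
  z <- numeric(length(profile@rpm))
  v <- profile@rpm[!profile@masked]
  if (length(v)) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s > 0) z[!profile@masked] <- (profile@rpm[!profile@masked] - m) / s
  }
  profile@z <- z
  profile
}

#' Flanking and in-domain read fractions around a locus
#'
#' Percentage of summed raw counts in [center - flank, center) vs
#' [center, center + flank), and within the given domain intersected with the
#' flank window, each relative to the counts in the whole window
#' [center - flank, center + flank).
#'
#' @param profile a FourCProfile with raw filled.
#' @param center anchor coordinate (bp, 0-based).
#' @param flank window half-size in bp (> 0).
#' @param domain length-2 numeric: domain interval (0-based half-open) on the
#'   profile's chromosome.
#' @return list(pctLeft, pctRight, pctDomain, defined); \code{defined} is
#'   FALSE (and the percentages NA) when the window holds no counts.
#' @export
sideFractions <- function(profile, center, flank, domain) {
  stopifnot(is(profile, "FourCProfile"), length(profile@raw) > 0, flank > 0,
            length(domain) == 2, domain[1] < domain[2])
  e <- profile@ends
  raw <- profile@raw
  inWin <- e >= center - flank & e < center + flank
  tot <- sum(raw[inWin])
  if (tot == 0)
    return(list(pctLeft = NA_real_, pctRight = NA_real_,
                pctDomain = NA_real_, defined = FALSE))
  left <- sum(raw[inWin & e < center])
  dom <- sum(raw[inWin & e >= domain[1] & e < domain[2]])
  list(pctLeft = 100 * left / tot, pctRight = 100 * (tot - left) / tot,
       pctDomain = 100 * dom / tot, defined = TRUE)
}

#' Write one signal layer of a profile as bedGraph
#'
#' Each fragment end is written as a 1-bp interval; the track name combines
#' the viewpoint name and the layer.
#'
#' @param profile a FourCProfile.
#' @param layer one of "raw", "smoothed", "rpm", "z".
#' @param path output file.
#' @export
writeProfileBedGraph <- function(profile, layer = c("raw", "smoothed", "rpm", "z"),
                                 path) {
  layer <- match.arg(layer)
  v <- slot(profile, layer)
  if (!length(v)) stop("layer ", layer, " is not filled")
  gr <- GRanges(profile@chrom, IRanges(profile@ends + 1L, profile@ends + 1L),
                score = v)
  ucsc <- methods::new("UCSCData", gr,
                       trackLine = methods::new(
                         "GraphTrackLine",
                         name = paste(profile@viewpoint@name, layer,
                                      sep = "_"),
                         type = "bedGraph"))
  rtracklayer::export.bedGraph(ucsc, path)
  invisible(path)
}

#' @importClassesFrom rtracklayer UCSCData GraphTrackLine
NULL

#' Read a 4C reads table
#'
#' Accepts a 3-column TSV (chrom, pos, count; 0-based positions) or a BED file
#' whose score column carries the count (pos taken from the BED start).
#'
#' @param path input file.
#' @return data.frame(chrom, pos, count).
#' @export
readReadsTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 3) {
    names(df) <- c("chrom", "pos", "count")
  } else if (ncol(df) >= 5) {
    df <- df[, c(1, 2, 5)]
    names(df) <- c("chrom", "pos", "count")
  } else stop("expected 3-column TSV or >=5-column BED")
  df
}

setMethod("show", "FourCProfile", function(object) {
  layers <- c("raw", "smoothed", "rpm", "z")
  filled <- layers[vapply(layers, function(l) length(slot(object, l)) > 0,
                          logical(1))]
  cat(sprintf("FourCProfile [%s] on %s: %d ends (%d masked), layers: %s\n",
              object@viewpoint@name, object@chrom, length(object@ends),
              sum(object@masked),
              if (length(filled)) paste(filled, collapse = ", ") else "none"))
  if (length(object@raw))
    cat(sprintf("  total raw: %g  discarded: %d\n",
                sum(object@raw), object@discarded))
})
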
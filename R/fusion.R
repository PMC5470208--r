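#' Construct a BreakpointSpec
#'
#' Half-open junction convention: \code{posA} is the first chromA base NOT
#' retained (exclusive), \code{posB} the first chromB base retained
#' (inclusive).  Micro-homology at a junction is resolved by assigning the
#' ambiguous bases to chromA (i.e. they are counted inside posA).
#'
#' @param chromA,posA donor chromosome and 0-based cut (exclusive).
#' @param chromB,posB acceptor chromosome and 0-based cut (inclusive).
#' @param insertion optional sequence inserted at the junction.
#' @return a \code{BreakpointSpec}.
#' @export
breakpointSpec <- function(chromA, posA, chromB, posB, insertion = "") {
  new("BreakpointSpec", chromA = as.character(chromA), posA = as.numeric(posA),
      chromB = as.character(chromB), posB = as.numeric(posB),
      insertion = toupper(insertion))
}

#' Build the derivative (translocated) chromosome
#'
#' Derivative sequence = chromA[0, posA) + insertion + chromB[posB, end), with
#' a segment table giving the bidirectional coordinate map.
#'
#' @param genome named character vector or DNAStringSet containing chromA and
#'   chromB.
#' @param spec a \code{BreakpointSpec}.
#' @param name derivative chromosome name (default "der").
#' @return a \code{DerivativeGenome} (sequence included).
#' @export
buildDerivative <- function(genome, spec, name = "der") {
  stopifnot(is(spec, "BreakpointSpec"))
  genome <- .asDNAStringSet(genome)
  for (ch in c(spec@chromA, spec@chromB))
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
  lenA <- Biostrings::width(genome)[match(spec@chromA, names(genome))]
  lenB <- Biostrings::width(genome)[match(spec@chromB, names(genome))]
  if (spec@posA < 0 || spec@posA > lenA)
    stop("posA out of range for ", spec@chromA)
  if (spec@posB < 0 || spec@posB > lenB)
    stop("posB out of range for ", spec@chromB)
  ins <- spec@insertion
  insLen <- nchar(ins)
  seqA <- as.character(Biostrings::subseq(genome[[spec@chromA]], 1, spec@posA))
  seqB <- if (spec@posB < lenB)
    as.character(Biostrings::subseq(genome[[spec@chromB]], spec@posB + 1, lenB))
  else ""
  segs <- data.frame(
    source = c(spec@chromA, if (insLen) "insertion", spec@chromB),
    srcStart = c(0, if (insLen) 0, spec@posB),
    srcEnd = c(spec@posA, if (insLen) insLen, lenB),
    derStart = c(0, if (insLen) spec@posA, spec@posA + insLen),
    stringsAsFactors = FALSE
  )
  segs <- segs[segs$srcEnd > segs$srcStart, , drop = FALSE]
  if (nrow(segs) == 0) stop("derivative would be empty")
  dg <- new("DerivativeGenome", spec = spec, segments = segs,
            length = spec@posA + insLen + (lenB - spec@posB),
            name = name, sequence = paste0(seqA, ins, seqB))
  validObject(dg)
  dg
}

#' Derivative sequence as a DNAStringSet
#' @param dg a DerivativeGenome.
#' @return a one-record DNAStringSet named after the derivative.
#' @export
derivativeSequence <- function(dg) {
  stopifnot(is(dg, "DerivativeGenome"))
  out <- Biostrings::DNAStringSet(dg@sequence)
  names(out) <- dg@name
  out
}

#' Map a native coordinate onto the derivative
#'
#' @param dg a DerivativeGenome.
#' @param chrom,pos native chromosome and 0-based position.
#' @return derivative 0-based position, or NA if the position is not retained.
#' @export
nativeToDerivative <- function(dg, chrom, pos) {
  stopifnot(is(dg, "DerivativeGenome"))
  mapply(function(ch, p) {
    s <- dg@segments
    hit <- s$source == ch & p >= s$srcStart & p < s$srcEnd
    if (!any(hit)) return(NA_real_)
    i <- which(hit)[1]
    s$derStart[i] + (p - s$srcStart[i])
  }, chrom, pos, USE.NAMES = FALSE)
}

#' Map a derivative coordinate back to its native source
#'
#' @param dg a DerivativeGenome.
#' @param pos derivative 0-based position(s).
#' @return data.frame(chrom, pos); positions inside a junction insertion map
#'   to chrom "insertion" with the offset inside it.
#' @export
derivativeToNative <- function(dg, pos) {
  stopifnot(is(dg, "DerivativeGenome"))
  if (any(pos < 0 | pos >= dg@length))
    stop("derivative position out of range [0, ", dg@length, ")")
  s <- dg@segments[order(dg@segments$derStart), , drop = FALSE]
  i <- findInterval(pos, s$derStart)
  data.frame(chrom = s$source[i],
             pos = s$srcStart[i] + (pos - s$derStart[i]))
}

#' Junction coordinates of a derivative
#' @param dg a DerivativeGenome.
#' @return c(start, end): derivative interval occupied by the junction
#'   (zero-width when there is no insertion).
#' @export
junctionInterval <- function(dg) {
  insLen <- nchar(dg@spec@insertion)
  c(dg@spec@posA, dg@spec@posA + insLen)
}

#' Allele-dosage rescaling of a derivative 4C profile
#'
#' On a derivative chromosome, sequence on the viewpoint's native side also
#' exists on the intact homolog, while the far side (and any junction
#' insertion) is unique to the derivative allele.  Far-side raw counts are
#' therefore doubled to compensate.  Guarded against double application.
#'
#' @param profile a FourCProfile in derivative coordinates (raw filled).
#' @param dg the DerivativeGenome the profile lives on.
#' @return the rescaled profile (rescaled flag set).
#' @export
rescaleDerivative <- function(profile, dg) {
  stopifnot(is(profile, "FourCProfile"), is(dg, "DerivativeGenome"),
            length(profile@raw) > 0)
  if (profile@rescaled)
    stop("profile has already been dosage-rescaled; refusing a second application")
  jct <- junctionInterval(dg)
  vpPos <- profile@viewpoint@position
  vpIdx <- which(profile@fragStart <= vpPos & vpPos < profile@fragEnd)
  if (length(vpIdx) == 0) stop("viewpoint not on any profiled fragment")
  vpFrag <- c(profile@fragStart[vpIdx[1]], profile@fragEnd[vpIdx[1]])
  if (vpFrag[1] < jct[1] && vpFrag[2] > jct[2])
    stop("viewpoint sits on the junction fragment; side is undefined")
  src <- derivativeToNative(dg, vpPos)$chrom
  if (src == "insertion")
    stop("viewpoint inside the junction insertion; side is undefined")
  far <- if (src == dg@spec@chromA) profile@ends >= jct[1]
         else profile@ends < jct[2]
  profile@raw[far] <- profile@raw[far] * 2
  profile@rescaled <- TRUE
  profile
}

#' Balance smoothed 4C signal across a breakpoint
#'
#' Scales each side of the breakpoint toward the geometric mean of the mean
#' smoothed signal in the two flanking windows, so that after scaling the two
#' flank means are equal.  Symmetric in the two sides and order-independent.
#'
#' @param profile a FourCProfile with the smoothed layer filled.
#' @param breakpointPos breakpoint coordinate (bp, profile coordinates).
#' @param flank flanking window size in bp.
#' @return list(profile, scalars = c(left, right)); stale rpm/z layers are
#'   cleared.
#' @export
balanceSides <- function(profile, breakpointPos, flank) {
  stopifnot(is(profile, "FourCProfile"), length(profile@smoothed) > 0, flank > 0)
  e <- profile@ends
  leftWin <- e >= breakpointPos - flank & e < breakpointPos
  rightWin <- e >= breakpointPos & e < breakpointPos + flank
  if (!any(leftWin) || !any(rightWin))
    stop("no fragment ends in one of the flanking windows")
  mL <- mean(profile@smoothed[leftWin])
  mR <- mean(profile@smoothed[rightWin])
  if (mL <= 0 || mR <= 0) stop("zero mean signal in a flanking window")
  g <- sqrt(mL * mR)
  sL <- g / mL
  sR <- g / mR
  left <- e < breakpointPos
  profile@smoothed[left] <- profile@smoothed[left] * sL
  profile@smoothed[!left] <- profile@smoothed[!left] * sR
  profile@rpm <- numeric(0)
  profile@z <- numeric(0)
  list(profile = profile, scalars = c(left = sL, right = sR))
}

#' Write the derivative segment table as TSV
#' @param dg a DerivativeGenome.
#' @param path output file.
#' @export
writeSegmentsTSV <- function(dg, path) {
  utils::write.table(dg@segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "DerivativeGenome", function(object) {
  cat(sprintf("DerivativeGenome %s: %g bp = %s[0,%g) + %d bp insertion + %s[%g,...)\n",
              object@name, object@length, object@spec@chromA, object@spec@posA,
              nchar(object@spec@insertion), object@spec@chromB,
              object@spec@posB))
})
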
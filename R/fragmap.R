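#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each occurrence of the primary recognition site and
#' annotates the resulting fragments with the blind flag (no secondary site
#' strictly inside the fragment) and the short flag (length below
#' \code{minLen}).  Fragment boundaries are placed at the first base of each
#' primary-site occurrence; both sites must be palindromic so a forward-strand
#' literal scan (overlapping occurrences included) finds all cut sites.
#'
#' @param genome a named \code{DNAStringSet}, a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param primarySite,secondarySite recognition sequences over {A,C,G,T};
#'   defaults DpnII (GATC) and Csp6I (GTAC).
#' @param minLen fragments shorter than this are flagged short (default 40 bp).
#' @return a \code{\link{FragmentMap}}.
#' @examples
#' fm <- digestGenome(c(chrT = "AAAGATCCCCCGTACCCCCGATCAAA"))
#' fragments(fm)
#' @export
digestGenome <- function(genome, primarySite = "GATC", secondarySite = "GTAC",
                         minLen = 40L) {
  genome <- .asDNAStringSet(genome)
  if (length(genome) == 0 || any(Biostrings::width(genome) == 0))
    stop("genome must contain at least one non-empty sequence")
  if (anyDuplicated(names(genome)))
    stop("chromosome names must be unique")
  for (site in c(primarySite, secondarySite)) {
    if (!nzchar(site) || grepl("[^ACGT]", site))
      stop("recognition sites must be non-empty and over {A,C,G,T}: ", site)
    if (site != .revcomp(site))
      stop("recognition site is not palindromic: ", site)
  }
  grl <- lapply(seq_along(genome), function(k) {
    seq <- genome[[k]]
    chrom <- names(genome)[k]
    L <- length(seq)
    # 0-based first-base coordinates of all (overlapping) occurrences
    cuts <- start(Biostrings::matchPattern(primarySite, seq)) - 1L
    bnd <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
    bnd <- sort(bnd)
    st <- bnd[-length(bnd)]
    en <- bnd[-1]
    sec <- start(Biostrings::matchPattern(secondarySite, seq)) - 1L
    # blind iff no secondary-site start in [start+1, end-1)
    blind <- vapply(seq_along(st), function(i) {
      !any(sec >= st[i] + 1L & sec < en[i] - 1L)
    }, logical(1))
    GRanges(chrom, IRanges(st + 1L, en),
            index = seq_along(st) - 1L,
            blind = blind, short = (en - st) < minLen,
            seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                            Biostrings::width(genome)))
  })
  gr <- do.call(c, grl)
  new("FragmentMap", fragments = gr, primarySite = primarySite,
      secondarySite = secondarySite, minLen = as.integer(minLen),
      filtered = FALSE)
}

.asDNAStringSet <- function(genome) {
  if (length(genome) == 0)
    stop("genome must contain at least one non-empty sequence")
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("sequences must be named")
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet, named character vector, or FASTA path")
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Fragments of a FragmentMap as a GRanges
#' @param x a FragmentMap.
#' @return GRanges with mcols index, blind, short.
#' @export
fragments <- function(x) {
  stopifnot(is(x, "FragmentMap"))
  x@fragments
}

#' Filter a FragmentMap to valid (observable) fragments
#'
#' Retains exactly the fragments that are non-blind (contain a secondary-enzyme
#' site) and at least \code{minLen} bp long ("smaller than 40 bp" is read as
#' strict, so length-40 fragments are retained).  Original indices are kept in
#' the \code{index} column for traceability.  Idempotent.
#'
#' @param map a FragmentMap.
#' @return a filtered FragmentMap.
#' @export
validFragments <- function(map) {
  stopifnot(is(map, "FragmentMap"))
  gr <- map@fragments
  keep <- !mcols(gr)$blind & !mcols(gr)$short
  new("FragmentMap", fragments = gr[keep], primarySite = map@primarySite,
      secondarySite = map@secondarySite, minLen = map@minLen, filtered = TRUE)
}

#' Valid-fragment-end coordinate table
#'
#' Each valid fragment contributes its two primary-site end coordinates; cut
#' sites shared by two adjacent valid fragments collapse to a single end owned
#' by the leftmost fragment, so the coordinates are strictly increasing.
#'
#' @param map a (preferably filtered) FragmentMap.
#' @param chrom restrict to one chromosome (required if the map has several).
#' @return data.frame(end, fragIndex, fragStart, fragEnd), 0-based coordinates.
#' @export
fragmentEnds <- function(map, chrom = NULL) {
  gr <- fragments(map)
  if (!is.null(chrom)) gr <- gr[seqnames(gr) == chrom]
  if (length(gr) == 0) stop("no fragments", if (!is.null(chrom)) paste0(" on ", chrom))
  if (length(unique(as.character(seqnames(gr)))) > 1)
    stop("fragmentEnds needs a single chromosome; pass chrom=")
  gr <- gr[order(start(gr))]
  st0 <- start(gr) - 1L
  en0 <- end(gr)
  df <- data.frame(
    end = c(st0, en0),
    fragIndex = rep(mcols(gr)$index, 2L),
    fragStart = rep(st0, 2L),
    fragEnd = rep(en0, 2L)
  )
  df <- df[order(df$end, df$fragStart), , drop = FALSE]
  df[!duplicated(df$end), , drop = FALSE]
}

#' Write a FragmentMap as BED
#'
#' BED (0-based half-open) with name = fragment index, score = length, and two
#' extra columns with the blind and short flags.  A one-line summary (number of
#' fragments, blind, short) is emitted as a message.
#'
#' @param map a FragmentMap.
#' @param path output file.
#' @return invisibly, the summary data.frame.
#' @export
writeFragmentMapBED <- function(map, path) {
  gr <- fragments(map)
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L, end = end(gr),
    name = mcols(gr)$index, score = width(gr), strand = ".",
    blind = as.integer(mcols(gr)$blind), short = as.integer(mcols(gr)$short)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- data.frame(n = nrow(df), nBlind = sum(df$blind), nShort = sum(df$short))
  message(sprintf("fragment map: %d fragments (%d blind, %d short)",
                  s$n, s$nBlind, s$nShort))
  invisible(s)
}

setMethod("show", "FragmentMap", function(object) {
  gr <- object@fragments
  cat(sprintf("FragmentMap: %d fragments on %d chromosome(s) [%s/%s, minLen=%d]%s\n",
              length(gr), length(unique(as.character(seqnames(gr)))),
              object@primarySite, object@secondarySite, object@minLen,
              if (object@filtered) " (filtered)" else ""))
  if (!object@filtered)
    cat(sprintf("  blind: %d  short: %d\n",
                sum(mcols(gr)$blind), sum(mcols(gr)$short)))
})
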
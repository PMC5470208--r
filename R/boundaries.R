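#' Construct a ContactMatrix
#'
#' @param values square symmetric non-negative matrix.
#' @param binSize bin size in bp.
#' @param chrom chromosome (or derivative) name.
#' @param start 0-based coordinate of the first bin.
#' @return a \code{ContactMatrix}.
#' @export
contactMatrix <- function(values, binSize, chrom = "region", start = 0) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("ContactMatrix", values = (values + t(values)) / 2,
      binSize = as.numeric(binSize), chrom = as.character(chrom),
      start = as.numeric(start))
}

#' @describeIn contactMatrix number of bins.
#' @param x a ContactMatrix.
#' @export
nBins <- function(x) nrow(x@values)

#' Mean-imputed contact accessor
#'
#' Returns an accessor function f(i, j): stored value for in-range cells, the
#' global mean of the observed matrix for any out-of-range cell.  This is the
#' border imputation used by the directionality index, which needs windowed
#' sums extending past the ends of the analysed region.
#'
#' @param m a ContactMatrix.
#' @return function(i, j) (vectorised over i and j).
#' @export
imputedContacts <- function(m) {
  stopifnot(is(m, "ContactMatrix"))
  v <- m@values
  n <- nrow(v)
  mu <- mean(v)
  function(i, j) {
    out <- rep(mu, max(length(i), length(j)))
    ii <- rep_len(i, length(out)); jj <- rep_len(j, length(out))
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    out[ok] <- v[cbind(ii[ok], jj[ok])]
    out
  }
}

#' Directionality index of a contact matrix
#'
#' For each bin i, sums contacts to the w upstream bins (A) and w downstream
#' bins (B) and computes the signed chi-square-style statistic
#' DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E) with E = (A + B) / 2;
#' DI = 0 when A == B.  Windows reaching past the region borders use
#' mean-imputed contacts (\code{\link{imputedContacts}}).
#'
#' @param m a ContactMatrix.
#' @param windowBins bins summed per side (expected TAD size / bin size).
#' @return a \code{DITrack}.
#' @export
directionalityIndex <- function(m, windowBins) {
  stopifnot(is(m, "ContactMatrix"))
  w <- as.integer(windowBins)
  if (w < 1) stop("windowBins must be >= 1")
  n <- nBins(m)
  if (n < 2 * w + 1)
    stop(sprintf("matrix too small (%d bins) for windowBins = %d", n, w))
  acc <- imputedContacts(m)
  A <- B <- di <- numeric(n)
  for (i in seq_len(n)) {
    A[i] <- sum(acc(i, (i - w):(i - 1)))
    B[i] <- sum(acc(i, (i + 1):(i + w)))
    if (A[i] != B[i]) {
      E <- (A[i] + B[i]) / 2
      di[i] <- sign(B[i] - A[i]) * ((A[i] - E)^2 / E + (B[i] - E)^2 / E)
    }
  }
  new("DITrack", di = di, A = A, B = B, windowBins = w,
      binSize = m@binSize, chrom = m@chrom, start = m@start)
}

#' Call TAD boundaries from a DI track
#'
#' A boundary is placed at each bin b where the DI transitions from negative
#' to non-negative (di[b-1] < 0 <= di[b]) and both flanking extrema — the
#' most negative DI in the window before b and the most positive DI in the
#' window from b on — exceed \code{strength} standard deviations of the track
#' in magnitude.  Bins within one window of the region ends are flagged
#' "edge" (borders at the end of the analysed region may be artefacts of the
#' truncation).
#'
#' @param track a \code{DITrack}.
#' @param strength magnitude requirement in units of sd(di) (default 1).
#' @return data.frame(bin, leftMag, rightMag, edge); zero rows if no boundary.
#' @export
callBoundaries <- function(track, strength = 1.0) {
  stopifnot(is(track, "DITrack"))
  di <- track@di
  n <- length(di)
  w <- track@windowBins
  s <- stats::sd(di)
  empty <- data.frame(bin = integer(0), leftMag = numeric(0),
                      rightMag = numeric(0), edge = logical(0))
  if (is.na(s) || s == 0) return(empty)
  cand <- which(di[-n] < 0 & di[-1] >= 0) + 1L
  if (!length(cand)) return(empty)
  leftMag <- vapply(cand, function(b) -min(di[max(1L, b - w):(b - 1L)]),
                    numeric(1))
  rightMag <- vapply(cand, function(b) max(di[b:min(n, b + w - 1L)]),
                     numeric(1))
  keep <- leftMag >= strength * s & rightMag >= strength * s
  cand <- cand[keep]
  data.frame(bin = cand, leftMag = leftMag[keep], rightMag = rightMag[keep],
             edge = cand <= w | cand > n - w)
}

#' Default expected-TAD-size ladder
#'
#' Ten sizes log-spaced between 2x and 50x the bin size.
#'
#' @param binSize bin size in bp.
#' @param n number of sizes (default 10).
#' @return numeric vector of expected TAD sizes in bp.
#' @export
defaultTadSizes <- function(binSize, n = 10) {
  exp(seq(log(2 * binSize), log(50 * binSize), length.out = n))
}

#' Iterative expected-TAD-size boundary consensus
#'
#' Calls boundaries once per expected TAD size (window = round(size/binSize)
#' bins), clusters the candidate bins across iterations by single linkage
#' within \code{tolBins}, and scores each cluster by the fraction of
#' iterations that contain a member.  Selected boundaries are the non-edge
#' candidates with support >= \code{minSupport} (default: present in all
#' iterations), or the \code{topK} by support when \code{topK} is given.
#'
#' @param m a ContactMatrix.
#' @param tadSizes expected TAD sizes in bp (>= 2 values; each >= binSize).
#' @param minSupport minimum support fraction (default 1.0).
#' @param topK optional: select the top-k candidates by support instead.
#' @param tolBins single-linkage clustering tolerance in bins (default 1).
#' @param strength magnitude requirement passed to \code{callBoundaries}.
#' @return a \code{BoundaryConsensus}.
#' @export
consensusBoundaries <- function(m, tadSizes = defaultTadSizes(m@binSize),
                                minSupport = 1.0, topK = NULL, tolBins = 1L,
                                strength = 1.0) {
  stopifnot(is(m, "ContactMatrix"))
  if (length(tadSizes) < 2) stop("need at least 2 expected TAD sizes")
  if (any(tadSizes < m@binSize)) stop("expected TAD size below bin size")
  n <- nBins(m)
  ws <- unique(pmax(1L, as.integer(round(tadSizes / m@binSize))))
  ws <- ws[n >= 2L * ws + 1L]
  if (length(ws) < 2) stop("matrix too small for the requested TAD sizes")
  calls <- lapply(ws, function(w)
    callBoundaries(directionalityIndex(m, w), strength = strength))
  all <- do.call(rbind, lapply(seq_along(calls), function(k) {
    g <- calls[[k]]
    g$iter <- rep(k, nrow(g))
    g
  }))
  if (is.null(all) || nrow(all) == 0) {
    return(new("BoundaryConsensus",
               candidates = data.frame(bin = integer(0), support = numeric(0),
                                       edge = logical(0)),
               selected = integer(0), tadSizes = as.numeric(tadSizes),
               binSize = m@binSize))
  }
  ub <- sort(unique(all$bin))
  cl <- cumsum(c(1L, as.integer(diff(ub) > tolBins)))
  clusterOf <- cl[match(all$bin, ub)]
  cand <- do.call(rbind, lapply(split(all, clusterOf), function(g) {
    tb <- table(g$bin)
    rep_bin <- as.integer(names(tb)[which.max(tb)])
    data.frame(bin = rep_bin,
               support = length(unique(g$iter)) / length(calls),
               edge = g$edge[which(g$bin == rep_bin)[1]])
  }))
  cand <- cand[order(cand$bin), , drop = FALSE]
  rownames(cand) <- NULL
  eligible <- cand[!cand$edge, , drop = FALSE]
  sel <- if (!is.null(topK)) {
    o <- order(-eligible$support, eligible$bin)
    eligible$bin[o][seq_len(min(topK, nrow(eligible)))]
  } else eligible$bin[eligible$support >= minSupport]
  new("BoundaryConsensus", candidates = cand, selected = as.integer(sel),
      tadSizes = as.numeric(tadSizes), binSize = m@binSize)
}

#' Write a ContactMatrix as dense TSV
#'
#' Header row and column hold the 0-based bin start coordinates; a leading
#' comment line records chrom, binSize and start.
#'
#' @param m a ContactMatrix.
#' @param path output file.
#' @export
writeContactMatrixTSV <- function(m, path) {
  starts <- m@start + (seq_len(nBins(m)) - 1) * m@binSize
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s binSize=%g start=%g",
                     m@chrom, m@binSize, m@start), con)
  v <- m@values
  dimnames(v) <- list(starts, starts)
  utils::write.table(v, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a ContactMatrix written by \code{writeContactMatrixTSV}
#' @param path input file.
#' @return a \code{ContactMatrix}.
#' @export
readContactMatrixTSV <- function(path) {
  first <- readLines(path, n = 1)
  chrom <- "region"; binSize <- NA_real_; start <- 0
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[A-Za-z]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p); val <- sub(".*=", "", p)
      if (k == "chrom") chrom <- val
      if (k == "binSize") binSize <- as.numeric(val)
      if (k == "start") start <- as.numeric(val)
    }
  }
  v <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, comment.char = "#",
                                   check.names = FALSE))
  if (is.na(binSize)) {
    starts <- as.numeric(colnames(v))
    binSize <- if (length(starts) > 1) starts[2] - starts[1] else 1
    start <- starts[1]
  }
  contactMatrix(v, binSize = binSize, chrom = chrom, start = start)
}

#' Write a DI track as bedGraph
#' @param track a DITrack.
#' @param path output file.
#' @export
writeDIBedGraph <- function(track, path) {
  n <- length(track@di)
  st <- track@start + (seq_len(n) - 1) * track@binSize
  gr <- GRanges(track@chrom, IRanges(st + 1, st + track@binSize),
                score = track@di)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Write consensus boundaries as BED (support in the score column)
#' @param bc a BoundaryConsensus.
#' @param m the ContactMatrix the consensus was computed on.
#' @param path output file.
#' @export
writeBoundariesBED <- function(bc, m, path) {
  cand <- bc@candidates
  if (nrow(cand) == 0) { cat("", file = path); return(invisible(path)) }
  st <- m@start + (cand$bin - 1) * m@binSize
  df <- data.frame(chrom = m@chrom, start = st, end = st + m@binSize,
                   name = ifelse(cand$bin %in% bc@selected, "selected",
                                 ifelse(cand$edge, "edge", "candidate")),
                   score = round(1000 * cand$support), strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %d x %d bins of %g bp on %s (start %g)\n",
              nBins(object), nBins(object), object@binSize, object@chrom,
              object@start))
})

setMethod("show", "BoundaryConsensus", function(object) {
  cat(sprintf("BoundaryConsensus: %d candidate(s), %d selected over %d TAD sizes\n",
              nrow(object@candidates), length(object@selected),
              length(object@tadSizes)))
  if (nrow(object@candidates)) print(object@candidates)
})
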
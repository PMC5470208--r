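#' Pool Adjacent Violators Algorithm (unit weights)
#'
#' Least-squares isotonic regression: the Euclidean projection of \code{y}
#' onto the cone of non-decreasing (or non-increasing) vectors, computed by
#' pooling adjacent violating blocks into their means.
#'
#' @param y numeric vector.
#' @param increasing fit non-decreasing (TRUE) or non-increasing (FALSE).
#' @return fitted vector of the same length.
#' @export
pava <- function(y, increasing = TRUE) {
  n <- length(y)
  if (n <= 1) return(y)
  if (!increasing) return(rev(pava(rev(y), increasing = TRUE)))
  # stack of blocks: running means and sizes
  means <- numeric(n); sizes <- integer(n); top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    means[top] <- y[i]; sizes[top] <- 1L
    while (top > 1L && means[top - 1L] > means[top]) {
      w <- sizes[top - 1L] + sizes[top]
      means[top - 1L] <- (means[top - 1L] * sizes[top - 1L] +
                          means[top] * sizes[top]) / w
      sizes[top - 1L] <- w
      top <- top - 1L
    }
  }
  rep(means[seq_len(top)], sizes[seq_len(top)])
}

#' Two-sided monotonic 4C background by PAVA
#'
#' Fits a background that rises monotonically toward the viewpoint and falls
#' monotonically after it: the left arm (positions 1..vpIndex) is the
#' least-squares non-decreasing fit, the right arm (vpIndex..n) the
#' least-squares non-increasing fit, both by PAVA with unit weights.  The two
#' arms share the viewpoint position, where the background takes the larger of
#' the two arm values (the upper envelope keeps the fit unimodal).
#' Residuals are observed minus fitted.
#'
#' @param signal per-end signal ordered by position.
#' @param vpIndex index (1-based) of the viewpoint end.
#' @return a \code{BackgroundFit}.
#' @export
fitBackground <- function(signal, vpIndex) {
  n <- length(signal)
  vpIndex <- as.integer(vpIndex)
  if (vpIndex < 1 || vpIndex > n) stop("vpIndex out of range")
  left <- pava(signal[seq_len(vpIndex)], increasing = TRUE)
  right <- pava(signal[vpIndex:n], increasing = FALSE)
  values <- numeric(n)
  values[seq_len(vpIndex)] <- left
  values[vpIndex:n] <- right
  values[vpIndex] <- max(left[vpIndex], right[1])
  new("BackgroundFit", values = values, residuals = signal - values,
      vpIndex = vpIndex)
}

#' Convenience: background fit of a 4C profile layer
#'
#' @param profile a FourCProfile; the viewpoint end is located automatically.
#' @param layer signal layer to fit (default "smoothed").
#' @return a \code{BackgroundFit}.
#' @export
fit4CBackground <- function(profile, layer = c("smoothed", "raw", "rpm", "z")) {
  layer <- match.arg(layer)
  v <- slot(profile, layer)
  if (!length(v)) stop("layer ", layer, " is not filled")
  vpIndex <- which.min(abs(profile@ends - profile@viewpoint@position))
  fitBackground(v, vpIndex)
}

#' Tukey-fence residual threshold (Q3 + 1.5 IQR)
#'
#' Quantiles use linear interpolation between order statistics (R's default
#' type 7 convention).
#'
#' @param residuals numeric vector of at least 4 residuals.
#' @return the threshold Q3 + 1.5 * (Q3 - Q1).
#' @export
residualThreshold <- function(residuals) {
  if (length(residuals) < 4) stop("need at least 4 residuals")
  q <- stats::quantile(residuals, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Call interaction peaks from background residuals
#'
#' Ends with residual strictly above the threshold are candidates; runs of
#' consecutive candidate ends become peaks spanning the union of their
#' fragments' intervals, and peaks whose genomic gap is strictly less than
#' \code{mergeGap} are merged into a single unit.
#'
#' @param profile the FourCProfile the fit was computed on (supplies
#'   coordinates).
#' @param fit a \code{BackgroundFit} over the same ends.
#' @param mergeGap merge distance in bp (default 500).
#' @param threshold residual cutoff; defaults to
#'   \code{residualThreshold(fit@residuals)}.
#' @return a \code{PeakSet} (possibly empty).
#' @export
callPeaks <- function(profile, fit, mergeGap = 500,
                      threshold = residualThreshold(fit@residuals)) {
  stopifnot(is(profile, "FourCProfile"), is(fit, "BackgroundFit"),
            length(fit@residuals) == length(profile@ends))
  cand <- which(fit@residuals > threshold)
  if (length(cand) == 0)
    return(new("PeakSet", peaks = GRanges(), threshold = threshold,
               mergeGap = as.numeric(mergeGap)))
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  st <- vapply(runs, function(r) min(profile@fragStart[r]), numeric(1))
  en <- vapply(runs, function(r) max(profile@fragEnd[r]), numeric(1))
  mx <- vapply(runs, function(r) max(fit@residuals[r]), numeric(1))
  ne <- vapply(runs, length, integer(1))
  o <- order(st)
  st <- st[o]; en <- en[o]; mx <- mx[o]; ne <- ne[o]
  # merge runs whose genomic gap is < mergeGap
  grp <- cumsum(c(1L, as.integer(st[-1] - en[-length(en)] >= mergeGap)))
  st <- tapply(st, grp, min); en <- tapply(en, grp, max)
  mx <- tapply(mx, grp, max); ne <- tapply(ne, grp, sum)
  gr <- GRanges(profile@chrom, IRanges(as.numeric(st) + 1L, as.numeric(en)),
                maxResidual = as.numeric(mx), nEnds = as.integer(ne))
  new("PeakSet", peaks = gr, threshold = threshold,
      mergeGap = as.numeric(mergeGap))
}

#' Restrict a PeakSet to a domain interval
#'
#' Peaks entirely outside the interval are dropped; straddling peaks are
#' clipped at the interval limits.
#'
#' @param ps a PeakSet.
#' @param interval length-2 numeric, 0-based half-open.
#' @return the restricted PeakSet.
#' @export
restrictToDomain <- function(ps, interval) {
  stopifnot(is(ps, "PeakSet"), length(interval) == 2, interval[1] < interval[2])
  p <- ps@peaks
  if (length(p)) {
    win <- IRanges(interval[1] + 1L, interval[2])
    keep <- IRanges::overlapsAny(ranges(p), win)
    p <- p[keep]
    if (length(p)) ranges(p) <- IRanges::pintersect(
      ranges(p), rep(win, length(p)))
  }
  new("PeakSet", peaks = p, threshold = ps@threshold, mergeGap = ps@mergeGap)
}

#' Write a PeakSet as BED6
#'
#' name = peak rank by decreasing max residual; score = max residual linearly
#' scaled to [0, 1000].
#'
#' @param ps a PeakSet.
#' @param path output file.
#' @export
writePeaksBED <- function(ps, path) {
  p <- ps@peaks
  if (length(p) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  mx <- mcols(p)$maxResidual
  rng <- range(mx)
  score <- if (diff(rng) > 0) round(1000 * (mx - rng[1]) / diff(rng))
           else rep(1000L, length(mx))
  df <- data.frame(chrom = as.character(seqnames(p)), start = start(p) - 1L,
                   end = end(p), name = rank(-mx, ties.method = "first"),
                   score = score, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @importFrom GenomicRanges ranges ranges<-
setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peaks (residual threshold %.4g, merge gap %g bp)\n",
              length(object@peaks), object@threshold, object@mergeGap))
})
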
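# Brute-force least-squares projection onto the monotone cone.
# Enumerates every partition of 1..n into consecutive blocks, assigns each
# block its mean, keeps the monotone-feasible candidates and returns the one
# with minimal squared error.  The isotonic projection is itself such a
# candidate (its blocks carry block means), and every candidate is a monotone
# vector, so the minimiser equals the projection.  Exponential in n: use for
# n <= 10 only.
bruteIsotonic <- function(y, increasing = TRUE) {
  if (!increasing) return(rev(bruteIsotonic(rev(y), TRUE)))
  n <- length(y)
  if (n == 1) return(y)
  best <- NULL
  bestSSE <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    bounds <- c(0, cuts, n)
    means <- vapply(seq_len(length(bounds) - 1), function(b)
      mean(y[(bounds[b] + 1):bounds[b + 1]]), numeric(1))
    if (is.unsorted(means)) next
    fit <- rep(means, diff(bounds))
    sse <- sum((y - fit)^2)
    if (sse < bestSSE) { bestSSE <- sse; best <- fit }
  }
  best
}

# random proper rotation matrix (QR of a Gaussian, det fixed to +1)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# shared fused-landscape scenario: two 2-TAD parents broken inside a TAD
fusedScenario <- function(seed, insulation = 2.5, binSize = 5000) {
  spA <- landscapeSpec(40, binSize, tads = list(c(0, 20), c(20, 40)),
                       insulation = insulation, seed = seed)
  spB <- landscapeSpec(40, binSize, tads = list(c(0, 15), c(15, 40)),
                       insulation = insulation, seed = seed)
  makeFusedLandscape(spA, spB, 30, 5)
}
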
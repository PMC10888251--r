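# Independent test oracles, deliberately written without reusing any
# package internals.

# Directional-diagram sums by exhaustive enumeration: try every subset
# of n-1 directed edges and keep those forming a spanning tree directed
# toward the root.
bruteDirectionalSums <- function(k) {
  n <- length(k) / 2
  from <- to <- integer(0); w <- numeric(0)
  for (i in 1:n) {
    j <- if (i == n) 1L else i + 1L
    from <- c(from, i, j); to <- c(to, j, i)
    w <- c(w, k[2 * i - 1], k[2 * i])
  }
  sums <- numeric(n)
  combs <- utils::combn(length(w), n - 1)
  for (r in 1:n) {
    tot <- 0
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      if (any(from[sel] == r) || length(unique(from[sel])) != n - 1) next
      ok <- TRUE
      for (v in setdiff(1:n, r)) {
        cur <- v; steps <- 0
        repeat {
          nxt <- to[sel][from[sel] == cur]
          if (length(nxt) != 1) { ok <- FALSE; break }
          cur <- nxt; steps <- steps + 1
          if (cur == r || steps > n) break
        }
        if (!ok || cur != r) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + prod(w[sel])
    }
    sums[r] <- tot
  }
  sums
}

# the four-state denominator exactly as printed in the source (its
# fourth rooted sum repeats two terms of the first and is inconsistent
# with a spanning-tree enumeration)
printedSigmaTypo <- function(k) {
  S1 <- k[2]*k[4]*k[6] + k[2]*k[4]*k[7] + k[2]*k[5]*k[7] + k[3]*k[5]*k[7]
  S2 <- k[1]*k[5]*k[7] + k[4]*k[6]*k[8] + k[1]*k[4]*k[6] + k[1]*k[4]*k[7]
  S3 <- k[1]*k[3]*k[7] + k[2]*k[6]*k[8] + k[3]*k[6]*k[8] + k[1]*k[3]*k[6]
  S4 <- k[2]*k[4]*k[8] + k[1]*k[3]*k[5] + k[3]*k[5]*k[7] + k[2]*k[5]*k[7]
  S1 + S2 + S3 + S4
}

randomRates <- function(n) rateSet(10^stats::runif(2 * n, -2, 4))

# printed-precision comparison: agreement to +-1 unit in the last
# printed significant digit
expect_printed <- function(actual, printed) {
  d <- 7L
  for (dd in 1:7) if (signif(printed, dd) == printed) { d <- dd; break }
  ulp <- 10^(ceiling(log10(abs(printed))) - d)
  expect_lt(abs(actual - printed), ulp * (1 + 1e-9) + abs(printed) * 1e-12)
}
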
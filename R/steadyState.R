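#' @include AllClasses.R AllGenerics.R
NULL

# Edge bookkeeping for the unicyclic scheme: undirected edge e (1..n)
# joins states e and e+1 (cyclically); its forward direction carries
# k_{2e-1}, its backward direction k_{2e}.

# edges crossed when walking forward (i -> i+1 direction) from state v
# until reaching state r
.forwardEdges <- function(v, r, n) {
  if (v == r) return(integer(0))
  if (v < r) v:(r - 1L) else c(v:n, seq_len(r - 1L))
}

#' Directional diagram sums of a unicyclic scheme
#'
#' For each state i, the sum over all directed spanning trees of the
#' cycle rooted at state i of the product of edge rate constants (the
#' King-Altman/Hill directional diagrams). For a single cycle of n
#' states each rooted sum has exactly n terms, one per deleted cycle
#' edge. Trees are enumerated generically, not transcribed per n.
#'
#' @param rates a [RateSet]
#' @return list with `perState` (Sigma_1..Sigma_n) and `total` (Sigma)
#' @export
#' @examples
#' directionalSums(rateSet(c(1, 1, 1, 1)))  # 2-state: each sum = 2, total 4
directionalSums <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  n <- rates@nStates
  k <- rates@k
  kf <- k[2L * seq_len(n) - 1L]          # forward out of state v
  kb <- c(k[2L * n], k[2L * seq_len(n - 1L)])  # backward out of state v
  sums <- numeric(n)
  for (r in seq_len(n)) {
    terms <- numeric(n)
    for (drop in seq_len(n)) {
      # delete cycle edge 'drop'; every remaining vertex has a unique
      # path to the root r, contributing its edge directed toward r
      prod <- 1
      for (v in seq_len(n)[-r]) {
        prod <- prod *
          (if (drop %in% .forwardEdges(v, r, n)) kb[v] else kf[v])
      }
      terms[drop] <- prod
    }
    sums[r] <- sum(terms)
  }
  list(perState = sums, total = sum(sums))
}

#' Steady state by the diagram (spanning-tree) method
#'
#' Occupancies are ratios of directional diagram sums, p_i = Sigma_i /
#' Sigma; the net cycle flux is the difference of the forward and
#' backward rate-constant products over Sigma. J is negative when the
#' backward product dominates (net backward cycling).
#'
#' @param rates a [RateSet]
#' @return a [SteadyState]
#' @export
#' @examples
#' ss <- steadyState(referenceRateSet(loadEnzyme("tpi")))
#' flux(ss)   # about 14.4 1/s
steadyState <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  ds <- directionalSums(rates)
  n <- rates@nStates
  k <- rates@k
  fwd <- prod(k[2L * seq_len(n) - 1L])
  bwd <- prod(k[2L * seq_len(n)])
  new("SteadyState",
      occupancies = ds$perState / ds$total,
      flux = (fwd - bwd) / ds$total,
      diagramSums = ds$perState,
      diagramTotal = ds$total)
}

#' Steady state by the master-equation null space
#'
#' Independent verification path: solves the stationary master equation
#' W p = 0 (rate matrix of the unicyclic scheme) under the normalization
#' sum(p) = 1 with dense linear algebra, then takes J from the first
#' transition. Agrees with [steadyState()] to near machine precision.
#'
#' @param rates a [RateSet]
#' @return a [SteadyState]; the diagram-sum slots hold the normalized
#'   occupancies (the oracle never forms directional diagrams)
#' @export
steadyStateOracle <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  n <- rates@nStates
  k <- rates@k
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    W[j, i] <- W[j, i] + k[2L * i - 1L]   # i -> i+1 forward
    W[i, j] <- W[i, j] + k[2L * i]        # i+1 -> i backward
  }
  diag(W) <- diag(W) - colSums(W)
  if (any(rowSums(abs(W)) == 0))
    stop("singular rate matrix: a state has no transitions")
  A <- rbind(W[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1L), 1)
  p <- solve(A, b)
  # one step of iterative refinement: rate magnitudes spanning many
  # decades make A ill-conditioned and the raw solve loses digits
  p <- p + solve(A, b - A %*% p)
  p <- as.numeric(p)
  J <- k[1L] * p[1L] - k[2L] * p[2L]
  new("SteadyState", occupancies = p, flux = J,
      diagramSums = p, diagramTotal = 1)
}

#' Per-transition fluxes
#'
#' J_i = k_{2i-1} p_i - k_{2i} p_{i+1}; at steady state all n values
#' equal the cycle flux.
#'
#' @param rates a [RateSet]
#' @param ss the matching [SteadyState]
#' @return numeric vector of n transition fluxes, 1/s
#' @export
transitionFluxes <- function(rates, ss) {
  n <- rates@nStates
  p <- ss@occupancies
  pn <- c(p[-1L], p[1L])
  rates@k[2L * seq_len(n) - 1L] * p - rates@k[2L * seq_len(n)] * pn
}
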
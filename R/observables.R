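#' @include AllClasses.R AllGenerics.R steadyState.R
NULL

#' Thermodynamic force of each transition
#'
#' X_i/RT = ln(k_{2i-1} p_i / (k_{2i} p_{i+1})), indices cyclic. The
#' step forces sum to the total force algebraically (the occupancy
#' ratios telescope around the cycle).
#'
#' @param rates a [RateSet]
#' @param ss the matching [SteadyState]
#' @return numeric vector of n forces per RT, dimensionless
#' @export
stepForces <- function(rates, ss) {
  stopifnot(is(rates, "RateSet"), is(ss, "SteadyState"))
  p <- ss@occupancies
  if (any(p <= 0)) stop("zero occupancy: step forces undefined")
  n <- rates@nStates
  pn <- c(p[-1L], p[1L])
  log(rates@k[2L * seq_len(n) - 1L] * p) - log(rates@k[2L * seq_len(n)] * pn)
}

#' Total thermodynamic force of the cycle
#'
#' Xtot/RT = ln of the forward over the backward product of the
#' pseudo-first-order rate constants; positive when the cycle is driven
#' forward (net substrate-to-product conversion).
#'
#' @param rates a [RateSet]
#' @return Xtot/RT, dimensionless
#' @export
#' @examples
#' totalForce(referenceRateSet(loadEnzyme("tpi")))  # 0.685
totalForce <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  n <- rates@nStates
  sum(log(rates@k[2L * seq_len(n) - 1L])) -
    sum(log(rates@k[2L * seq_len(n)]))
}

#' Total and partial entropy production
#'
#' P = J * Xtot/RT in 1/s (entropy production per R, equivalently
#' dissipation per RT); P_i = J * X_i/RT attributes the total to
#' individual catalytic steps. P is non-negative for any rate set
#' because J and Xtot always share their sign in a single cycle.
#'
#' @param rates a [RateSet]
#' @param ss the matching [SteadyState]; computed when missing
#' @return list with `total` (P) and `perStep` (P_i), both 1/s
#' @export
entropyProduction <- function(rates, ss = steadyState(rates)) {
  J <- ss@flux
  Xi <- stepForces(rates, ss)
  list(total = J * sum(Xi), perStep = J * Xi)
}

.kcatClosed <- function(k, n) {
  switch(as.character(n),
    "2" = k[3],
    "3" = k[3] * k[5] / (k[3] + k[4] + k[5]),
    "4" = k[3] * k[5] * k[7] /
      (k[3] * k[5] + k[3] * k[6] + k[3] * k[7] +
       k[4] * k[6] + k[4] * k[7] + k[5] * k[7]),
    stop("unsupported number of states"))
}

.specificityClosed <- function(k, n, S) {
  switch(as.character(n),
    "2" = k[1] * k[3] / (S * (k[2] + k[3])),
    "3" = k[1] * k[3] * k[5] /
      (S * (k[2] * k[4] + k[2] * k[5] + k[3] * k[5])),
    "4" = k[1] * k[3] * k[5] * k[7] /
      (S * (k[2] * k[4] * k[6] + k[2] * k[4] * k[7] +
            k[2] * k[5] * k[7] + k[3] * k[5] * k[7])),
    stop("unsupported number of states"))
}

#' Forward catalytic (turnover) constant
#'
#' The closed-form kcat of the n-state reversible scheme: the limiting
#' forward cycling rate at saturating substrate and vanishing product.
#' For two states kcat = k3 exactly.
#'
#' @param rates a [RateSet]
#' @return kcat, 1/s
#' @export
#' @examples
#' kcat(referenceRateSet(loadEnzyme("pc1")))  # about 61 1/s
kcat <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  .kcatClosed(rates@k, rates@nStates)
}

#' Forward specificity (catalytic efficiency) constant
#'
#' kcat/KM from the n-state closed form. The substrate concentration in
#' the denominator cancels the concentration inside the pseudo-first-
#' order k1, so the result is a true second-order constant in
#' 1/(M s).
#'
#' @param rates a [RateSet]
#' @param env a [CycleEnvironment] supplying the substrate concentration
#'   with which k1 was built
#' @return kcat/KM, 1/(M s)
#' @export
specificity <- function(rates, env) {
  stopifnot(is(rates, "RateSet"), is(env, "CycleEnvironment"))
  if (env@substrate <= 0) stop("substrate concentration must be positive")
  .specificityClosed(rates@k, rates@nStates, env@substrate)
}

#' Michaelis constant
#'
#' KM = kcat / (kcat/KM), both taken from their unambiguous closed
#' forms. For the two-state scheme this reduces to the familiar
#' [S](k2 + k3)/k1 = (k2 + k3)/k1*.
#'
#' @param rates a [RateSet]
#' @param env a [CycleEnvironment] supplying the substrate concentration
#' @return KM, M
#' @export
kM <- function(rates, env) {
  kcat(rates) / specificity(rates, env)
}

#' Step and overall equilibrium constants
#'
#' K_i = k_{2i-1}/k_{2i} from the pseudo-first-order constants. Two
#' overall conventions coexist in the source tables: `kApp`, the product
#' of the K_i (concentration-dependent, equal to exp(Xtot/RT)), and
#' `kChem`, the same product with the second-order constants substituted
#' in the binding steps (concentration-independent). `kChem` requires
#' the parameter set; when `params` is missing it is returned as NA.
#'
#' @param rates a [RateSet]
#' @param params optional [EnzymeParams] supplying the second-order
#'   constants for `kChem`
#' @return list with `perStep` (K_1..K_n), `kApp` and `kChem`
#' @export
equilibriumConstants <- function(rates, params = NULL) {
  stopifnot(is(rates, "RateSet"))
  n <- rates@nStates
  k <- rates@k
  Ki <- k[2L * seq_len(n) - 1L] / k[2L * seq_len(n)]
  kApp <- prod(Ki)
  kChem <- NA_real_
  if (!is.null(params)) {
    stopifnot(is(params, "EnzymeParams"))
    kc <- k
    labs <- paste0("k", seq_len(2L * n))
    for (lab in names(params@secondOrder))
      kc[match(lab, labs)] <- params@secondOrder[[lab]]
    kChem <- prod(kc[2L * seq_len(n) - 1L]) / prod(kc[2L * seq_len(n)])
  }
  list(perStep = Ki, kApp = kApp, kChem = kChem)
}

#' Shannon entropy of the state occupancies
#'
#' @param ss a [SteadyState] (or a bare numeric probability vector)
#' @return -sum p_i ln p_i, nats
#' @export
#' @examples
#' shannonEntropy(c(0.25, 0.25, 0.25, 0.25))  # ln 4
shannonEntropy <- function(ss) {
  p <- if (is(ss, "SteadyState")) ss@occupancies else as.numeric(ss)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' All thermodynamic and kinetic observables of one cycle state
#'
#' Convenience constructor evaluating the full observable block for a
#' rate set: steady state, step and total forces, total and partial
#' entropy production, both equilibrium-constant conventions, kcat, KM,
#' kcat/KM and the Shannon entropy. Forward-defined performance
#' parameters are reported for either force sign, with the sign flagged.
#'
#' @param rates a [RateSet]
#' @param params an [EnzymeParams] (for the second-order constants behind
#'   `kChem`), or NULL
#' @param env a [CycleEnvironment]; defaults to the enzyme's reference
#'   environment when `params` is given
#' @param ss optional precomputed [SteadyState]
#' @return a [ThermoKinetic]
#' @export
#' @examples
#' thermoKinetics(referenceRateSet(loadEnzyme("tpi")), loadEnzyme("tpi"))
thermoKinetics <- function(rates, params = NULL,
                           env = if (!is.null(params)) params@environment else NULL,
                           ss = steadyState(rates)) {
  if (is.null(env))
    stop("an environment (or params carrying one) is required")
  Xi <- stepForces(rates, ss)
  X <- totalForce(rates)
  P <- entropyProduction(rates, ss)
  eq <- equilibriumConstants(rates, params)
  new("ThermoKinetic",
      stepForces = Xi,
      totalForce = X,
      entropyProduction = P$total,
      partialEntropy = P$perStep,
      stepEquilibrium = eq$perStep,
      kApp = eq$kApp,
      kChem = eq$kChem,
      kcat = kcat(rates),
      km = kM(rates, env),
      specificity = specificity(rates, env),
      shannonEntropy = shannonEntropy(ss),
      forceSign = if (X > 0) 1 else -1)
}
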
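#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Reaction environment of a catalytic cycle
#'
#' Concentrations (molar) of the free ligands surrounding one enzyme:
#' substrate, product, optionally a proton-transfer buffer (carbonic
#' anhydrase schemes only) and the total enzyme concentration. The
#' temperature is a free-text label: every force in the package is
#' expressed per RT, so temperature never enters numerically.
#'
#' @slot substrate substrate concentration, M
#' @slot product product concentration, M
#' @slot buffer buffer concentration, M, or NA when the scheme has no
#'   buffer-dependent step
#' @slot enzyme total enzyme concentration, M
#' @slot temperature free-text temperature label
#' @export
setClass("CycleEnvironment",
  representation(
    substrate = "numeric",
    product = "numeric",
    buffer = "numeric",
    enzyme = "numeric",
    temperature = "character"
  ),
  prototype(buffer = NA_real_, enzyme = NA_real_, temperature = "")
)

setValidity("CycleEnvironment", function(object) {
  msg <- character()
  for (sl in c("substrate", "product")) {
    v <- slot(object, sl)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", sl))
  }
  if (!is.na(object@buffer) && object@buffer < 0)
    msg <- c(msg, "'buffer' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Pseudo-first-order rate set of one cycle instance
#'
#' The 2n rate constants k_1..k_2n (all in 1/s) of an n-state reversible
#' catalytic cycle. Odd indices are forward transitions (state i to i+1),
#' even indices the matching backward transitions, states numbered
#' cyclically so that transition n returns to the free enzyme.
#'
#' @slot k numeric vector of length 2n, all strictly positive, 1/s
#' @slot nStates number of enzyme functional states (2, 3 or 4)
#' @export
setClass("RateSet",
  representation(k = "numeric", nStates = "integer")
)

setValidity("RateSet", function(object) {
  msg <- character()
  if (!object@nStates %in% c(2L, 3L, 4L))
    msg <- c(msg, "'nStates' must be 2, 3 or 4")
  if (length(object@k) != 2L * object@nStates)
    msg <- c(msg, sprintf("'k' must have length %d (= 2 x nStates)", 2L * object@nStates))
  if (any(!is.finite(object@k)) || any(object@k <= 0))
    msg <- c(msg, "all rate constants must be finite and strictly positive")
  if (length(msg)) msg else TRUE
})

#' Registered enzyme parameter set
#'
#' One enzyme's microscopic rate constants as curated from the literature:
#' second-order binding constants (1/(M s)) keyed by transition label with
#' the ligand (S, P or B) they bind, the remaining first-order constants
#' (1/s), the pseudo-first-order values exactly as printed in the source
#' table, and the reference environment.
#'
#' @slot name registry identifier
#' @slot fullName descriptive enzyme name
#' @slot nStates number of functional states (2, 3 or 4)
#' @slot schemeVariant "standard" or "ca_buffer" (fourth step second-order
#'   in buffer in both directions)
#' @slot secondOrder named numeric, second-order constants, 1/(M s)
#' @slot bindingLigand named character, ligand bound by each second-order
#'   transition ("S", "P" or "B")
#' @slot firstOrder named numeric, first-order constants, 1/s
#' @slot printedFirstOrder named numeric, pseudo-first-order values as
#'   printed for the binding transitions, 1/s
#' @slot environment a [CycleEnvironment]
#' @slot keqConvention which overall equilibrium constant the source table
#'   prints: "chem" (concentration-independent) or "app" (apparent,
#'   exp(Xtot/RT))
#' @slot reference named numeric of printed derived parameters
#'   (kcat, km, specificity, keqtot, xtot, p) kept for cross-checks
#' @export
setClass("EnzymeParams",
  representation(
    name = "character",
    fullName = "character",
    nStates = "integer",
    schemeVariant = "character",
    secondOrder = "numeric",
    bindingLigand = "character",
    firstOrder = "numeric",
    printedFirstOrder = "numeric",
    environment = "CycleEnvironment",
    keqConvention = "character",
    reference = "numeric"
  )
)

setValidity("EnzymeParams", function(object) {
  msg <- character()
  if (!object@nStates %in% c(2L, 3L, 4L))
    msg <- c(msg, "'nStates' must be 2, 3 or 4")
  if (!object@schemeVariant %in% c("standard", "ca_buffer"))
    msg <- c(msg, "'schemeVariant' must be \"standard\" or \"ca_buffer\"")
  labs <- paste0("k", seq_len(2L * object@nStates))
  have <- c(names(object@secondOrder), names(object@firstOrder))
  if (!setequal(have, labs))
    msg <- c(msg, sprintf("constants %s must be resolvable exactly once",
                          paste(labs, collapse = ", ")))
  if (any(object@secondOrder <= 0) || any(object@firstOrder <= 0))
    msg <- c(msg, "all rate constants must be strictly positive")
  if (!identical(names(object@secondOrder), names(object@bindingLigand)))
    msg <- c(msg, "'bindingLigand' must be named like 'secondOrder'")
  if (object@schemeVariant == "ca_buffer" &&
      !all(c("k7", "k8") %in% names(object@secondOrder)))
    msg <- c(msg, "ca_buffer variant requires second-order k7 and k8 (buffer)")
  if (length(msg)) msg else TRUE
})

#' Steady state of a catalytic cycle
#'
#' State occupancies and net cycle flux of a unicyclic scheme, together
#' with the directional-diagram (spanning-tree) sums used to form them.
#'
#' @slot occupancies stationary probabilities p_1..p_n (sum to 1)
#' @slot flux net cycle flux J per enzyme, 1/s; negative when the cycle
#'   runs backward
#' @slot diagramSums per-state directional sums Sigma_i
#' @slot diagramTotal Sigma = sum of the per-state sums
#' @export
setClass("SteadyState",
  representation(
    occupancies = "numeric",
    flux = "numeric",
    diagramSums = "numeric",
    diagramTotal = "numeric"
  )
)

setValidity("SteadyState", function(object) {
  msg <- character()
  if (abs(sum(object@occupancies) - 1) > 1e-9)
    msg <- c(msg, "occupancies must sum to 1")
  if (any(object@occupancies <= 0) || any(object@occupancies >= 1))
    msg <- c(msg, "every occupancy must lie strictly inside (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Thermodynamic and kinetic observables of a cycle state
#'
#' All per-RT thermodynamic quantities and Michaelis-Menten performance
#' parameters evaluated for one rate set at quasi-steady state.
#'
#' @slot stepForces X_i/RT per transition, dimensionless
#' @slot totalForce Xtot/RT, dimensionless
#' @slot entropyProduction P = J * Xtot/RT, 1/s
#' @slot partialEntropy P_i = J * X_i/RT, 1/s
#' @slot stepEquilibrium per-step equilibrium constants K_i = k_{2i-1}/k_{2i}
#' @slot kApp apparent overall equilibrium constant (pseudo-first-order
#'   convention; equals exp(totalForce))
#' @slot kChem concentration-independent overall equilibrium constant
#'   (second-order constants in the binding steps), NA when the defining
#'   second-order constants are unknown
#' @slot kcat forward turnover number, 1/s
#' @slot km Michaelis constant, M
#' @slot specificity kcat/KM, 1/(M s)
#' @slot shannonEntropy -sum p_i ln p_i, nats
#' @slot forceSign +1 when the total force is positive (net forward
#'   cycling), -1 otherwise; forward-defined kcat, KM and kcat/KM are
#'   reported for either sign
#' @export
setClass("ThermoKinetic",
  representation(
    stepForces = "numeric",
    totalForce = "numeric",
    entropyProduction = "numeric",
    partialEntropy = "numeric",
    stepEquilibrium = "numeric",
    kApp = "numeric",
    kChem = "numeric",
    kcat = "numeric",
    km = "numeric",
    specificity = "numeric",
    shannonEntropy = "numeric",
    forceSign = "numeric"
  )
)

#' Noise specification for rate-constant perturbation
#'
#' How random noise multiplies a rate set: the distribution (Box-Muller
#' normal with cosine or sine branch, or uniform on (0, 2)), an additive
#' shift applied to the normal deviate, whether one draw is shared by all
#' selected constants or each gets its own, which transitions are
#' perturbed, and which thermodynamic constraint is enforced afterwards.
#'
#' @slot distribution "normal_cos", "normal_sin" or "uniform"
#' @slot shift additive shift on the normal deviate (0, +1 or +2 in
#'   typical use); ignored for uniform noise
#' @slot drawPolicy "shared" (one multiplier for all masked constants) or
#'   "per_constant"
#' @slot mask integer indices of the perturbed transitions (into k_1..k_2n)
#' @slot constraint "none", "fixed_step_equilibria",
#'   "fixed_total_force" or "replace_nonpositive_with_observed"
#' @slot pair for "fixed_total_force": the two step (not transition)
#'   indices whose equilibrium constants co-vary
#' @slot seed integer RNG seed recorded with every sample
#' @export
setClass("NoiseSpec",
  representation(
    distribution = "character",
    shift = "numeric",
    drawPolicy = "character",
    mask = "integer",
    constraint = "character",
    pair = "integer",
    seed = "integer"
  ),
  prototype(distribution = "normal_cos", shift = 0, drawPolicy = "per_constant",
            constraint = "none", pair = integer(), seed = 1L)
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@distribution %in% c("normal_cos", "normal_sin", "uniform"))
    msg <- c(msg, "unknown distribution")
  if (!object@drawPolicy %in% c("shared", "per_constant"))
    msg <- c(msg, "drawPolicy must be \"shared\" or \"per_constant\"")
  if (!object@constraint %in% c("none", "fixed_step_equilibria",
                                "fixed_total_force",
                                "replace_nonpositive_with_observed"))
    msg <- c(msg, "unknown constraint")
  if (length(object@mask) == 0L)
    msg <- c(msg, "mask must select at least one transition")
  if (object@constraint == "fixed_total_force" &&
      (length(object@pair) != 2L || object@pair[1] == object@pair[2]))
    msg <- c(msg, "fixed_total_force requires two distinct step indices in 'pair'")
  if (length(msg)) msg else TRUE
})

#' Ordered table of sampled cycle states
#'
#' One row per quasi-steady state visited by a scan, a noisy sampler or
#' the stochastic simulator: the rate constants, occupancies, flux,
#' forces, entropy production, performance parameters and Shannon entropy
#' of that state, plus run provenance (generator, arguments, seed).
#'
#' @slot data data.frame, one row per step
#' @slot provenance named list describing how the table was generated
#' @export
setClass("SampleTable",
  representation(data = "data.frame", provenance = "list")
)

setValidity("SampleTable", function(object) {
  msg <- character()
  if (nrow(object@data) && !all(diff(object@data$step) > 0))
    msg <- c(msg, "'step' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Ordinary least-squares fit summary
#'
#' @slot slope fitted slope
#' @slot intercept fitted intercept (0 for a through-origin fit)
#' @slot rSquared coefficient of determination, 1 - SSres/SStot
#' @slot nPoints number of points entering the fit
#' @slot throughOrigin whether the intercept was constrained to zero
#' @export
setClass("FitResult",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    nPoints = "integer",
    throughOrigin = "logical"
  )
)

#' Configuration of the discrete stochastic simulator
#'
#' @slot countsScale molecules per molar unit (one global factor for all
#'   species)
#' @slot initialCounts named counts for free substrate ("S"), free product
#'   ("P") and free enzyme ("E"); complexes start empty
#' @slot tickDt time per tick, s; every per-molecule transition
#'   probability k * tickDt must stay at or below 0.1
#' @slot nTicks number of ticks to run
#' @slot noise optional [NoiseSpec] re-drawn every tick, or NULL
#' @slot seed integer RNG seed
#' @slot recordEvery record observables every this many ticks (counts are
#'   still updated every tick)
#' @export
setClass("AbmConfig",
  representation(
    countsScale = "numeric",
    initialCounts = "numeric",
    tickDt = "numeric",
    nTicks = "integer",
    noise = "ANY",
    seed = "integer",
    recordEvery = "integer"
  ),
  prototype(noise = NULL, seed = 1L, recordEvery = 1L)
)

setValidity("AbmConfig", function(object) {
  msg <- character()
  if (object@countsScale <= 0) msg <- c(msg, "'countsScale' must be positive")
  if (object@tickDt <= 0) msg <- c(msg, "'tickDt' must be positive")
  if (!all(c("S", "P", "E") %in% names(object@initialCounts)))
    msg <- c(msg, "'initialCounts' needs entries S, P and E")
  if (!is.null(object@noise) && !is(object@noise, "NoiseSpec"))
    msg <- c(msg, "'noise' must be NULL or a NoiseSpec")
  if (length(msg)) msg else TRUE
})

#' Result of a stochastic simulation run
#'
#' @slot table a [SampleTable] of per-tick observables (thinned by
#'   `recordEvery`)
#' @slot counts matrix of species counts, one row per recorded tick
#' @slot clampEvents number of ticks on which a drawn transition count had
#'   to be clamped to the available molecules
#' @slot netConversions net number of substrate-to-product completions
#'   over the whole run
#' @slot config the [AbmConfig] used
#' @export
setClass("AbmResult",
  representation(
    table = "SampleTable",
    counts = "matrix",
    clampEvents = "numeric",
    netConversions = "numeric",
    config = "AbmConfig"
  )
)
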
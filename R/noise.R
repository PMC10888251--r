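#' @include AllClasses.R AllGenerics.R
NULL

#' Box-Muller transform with optional shift
#'
#' Maps two uniform deviates from (0, 1) to a standard normal deviate,
#' g = sqrt(-2 ln s1) cos(2 pi s2) (or the sine branch), plus an
#' additive shift. Shifts of +1 or +2 move the bulk of the distribution
#' to positive multipliers so that perturbed rate constants stay
#' positive.
#'
#' @param s1,s2 uniform deviates; s1 must be strictly positive
#' @param shift additive shift (default 0)
#' @param variant "cos" or "sin" branch
#' @return the (shifted) normal deviate, vectorized over s1/s2
#' @export
#' @examples
#' boxMuller(exp(-1/2), 0)      # exactly 1
#' boxMuller(1, 0.3, shift = 2) # exactly 2
boxMuller <- function(s1, s2, shift = 0, variant = c("cos", "sin")) {
  variant <- match.arg(variant)
  if (any(s1 <= 0)) stop("s1 must be strictly positive (log of zero)")
  r <- sqrt(-2 * log(s1))
  ang <- if (variant == "cos") cospi(2 * s2) else sinpi(2 * s2)
  r * ang + shift
}

#' Construct a noise specification
#'
#' @param distribution "normal_cos", "normal_sin" or "uniform"
#'   (multiplication by U(0, 2); mean-one, range documented as a
#'   configurable convention)
#' @param shift additive shift on the normal deviate
#' @param drawPolicy "shared" (one multiplier for every masked constant;
#'   noise then cancels in all rate-constant ratios) or "per_constant"
#' @param mask transition indices to perturb, as integers or "k7"-style
#'   labels
#' @param constraint "none", "fixed_step_equilibria", "fixed_total_force"
#'   or "replace_nonpositive_with_observed"
#' @param pair for "fixed_total_force": the two step indices whose
#'   equilibrium constants co-vary
#' @param seed integer RNG seed recorded with every sample
#' @return a [NoiseSpec]
#' @export
#' @examples
#' noiseSpec(mask = "k7", shift = 2, drawPolicy = "shared",
#'           constraint = "fixed_step_equilibria")
noiseSpec <- function(distribution = "normal_cos", shift = 0,
                      drawPolicy = "per_constant", mask,
                      constraint = "none", pair = integer(), seed = 1L) {
  if (is.character(mask)) mask <- as.integer(sub("^k", "", mask))
  new("NoiseSpec", distribution = distribution, shift = shift,
      drawPolicy = drawPolicy, mask = as.integer(mask),
      constraint = constraint, pair = as.integer(pair),
      seed = as.integer(seed))
}

# one batch of multipliers for the masked constants, consuming the
# caller's RNG stream
.drawMultipliers <- function(spec) {
  m <- if (spec@drawPolicy == "shared") 1L else length(spec@mask)
  g <- switch(spec@distribution,
    uniform = stats::runif(m, 0, 2),
    normal_cos = boxMuller(stats::runif(m), stats::runif(m), spec@shift, "cos"),
    normal_sin = boxMuller(stats::runif(m), stats::runif(m), spec@shift, "sin"))
  if (spec@drawPolicy == "shared") rep(g, length(spec@mask)) else g
}

#' Apply constrained multiplicative noise to a rate set
#'
#' Masked constants are multiplied by noise draws (one shared draw or
#' one per constant), then the requested thermodynamic constraint is
#' enforced:
#' \describe{
#'   \item{fixed_step_equilibria}{every backward constant is recomputed
#'     as k_{2i} = k_{2i-1} / K_i(observed), so all step equilibrium
#'     constants - and hence the total force - keep their observed
#'     values;}
#'   \item{fixed_total_force}{after the perturbation changes the product
#'     of step equilibrium constants by a factor f, the backward
#'     constant of the partner step (`pair[2]`) is multiplied by f,
#'     restoring ln(prod K_i) exactly while the two step equilibrium
#'     constants trade off;}
#'   \item{replace_nonpositive_with_observed}{any constant whose
#'     multiplier is not strictly positive reverts to its observed
#'     value;}
#'   \item{none}{raw multiplication; a nonpositive result is an error
#'     (use a shift or the replacement rule instead).}
#' }
#' Constants outside the mask are returned bit-identically. Under the
#' equilibria- and force-preserving constraints a draw that would leave
#' the positive orthant (possible even with a +2 shift, with about 2
#' percent probability per constant) is rejected and redrawn, which
#' stays reproducible under the caller's seed.
#'
#' The caller controls the RNG state (set.seed with `spec@seed` before a
#' sampling loop); [noisySample()] does this automatically.
#'
#' @param rates the current [RateSet] to perturb
#' @param observed the reference [RateSet] providing fallback values and
#'   observed equilibrium constants
#' @param spec a [NoiseSpec]
#' @return a perturbed [RateSet]
#' @export
applyNoise <- function(rates, observed, spec) {
  stopifnot(is(rates, "RateSet"), is(observed, "RateSet"), is(spec, "NoiseSpec"))
  n <- rates@nStates
  if (any(spec@mask < 1L) || any(spec@mask > 2L * n))
    stop("mask indices outside 1..2n")
  kObs <- observed@k
  fwd <- 2L * seq_len(n) - 1L
  bwd <- 2L * seq_len(n)

  for (attempt in seq_len(1000L)) {
    k <- rates@k
    g <- .drawMultipliers(spec)
    k[spec@mask] <- k[spec@mask] * g

    if (spec@constraint == "fixed_step_equilibria") {
      KiObs <- kObs[fwd] / kObs[bwd]
      k[bwd] <- k[fwd] / KiObs
    } else if (spec@constraint == "fixed_total_force") {
      j <- spec@pair[2]
      KiNow <- k[fwd] / k[bwd]
      KiObs <- kObs[fwd] / kObs[bwd]
      f <- prod(KiNow) / prod(KiObs)
      # restore ln(prod K) by scaling the partner step's backward
      # constant; e.g. noise on k2 (step 1) is compensated through k8
      # (step 4), the substrate-release/product-binding pairing
      k[2L * j] <- k[2L * j] * f
    } else if (spec@constraint == "replace_nonpositive_with_observed") {
      bad <- spec@mask[g <= 0]
      k[bad] <- kObs[bad]
    } else {
      if (any(k[spec@mask] <= 0))
        stop("noise drove a rate constant nonpositive under constraint ",
             "\"none\"; use a positive shift or the replacement constraint")
    }
    # the equilibria-preserving constraints cannot repair a draw that
    # left the positive orthant: reject it and redraw (deterministic
    # under the caller's seed)
    if (all(k > 0)) return(rateSet(k))
  }
  stop("could not draw an all-positive constrained rate set in 1000 attempts")
}
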
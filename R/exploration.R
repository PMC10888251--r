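#' @include AllClasses.R AllGenerics.R steadyState.R observables.R noise.R
NULL

# one fully evaluated quasi-steady state as a named numeric vector
.rowNames <- function(n) {
  c("step",
    paste0("k", seq_len(2L * n)),
    paste0("p", seq_len(n)),
    "J",
    paste0("X", seq_len(n)),
    "Xtot", "P",
    paste0("P", seq_len(n)),
    "kcat", "KM", "specificity", "shannon", "forceSign",
    "S", "Pconc")
}

.computeRow <- function(step, rates, env) {
  n <- rates@nStates
  ss <- steadyState(rates)
  Xi <- stepForces(rates, ss)
  X <- totalForce(rates)
  J <- ss@flux
  kc <- kcat(rates)
  sp <- specificity(rates, env)
  out <- c(step, rates@k, ss@occupancies, J, Xi, X, J * X, J * Xi,
           kc, kc / sp, sp, shannonEntropy(ss), if (X > 0) 1 else -1,
           env@substrate, env@product)
  names(out) <- .rowNames(n)
  out
}

.makeTable <- function(rows, provenance) {
  df <- as.data.frame(do.call(rbind, rows))
  new("SampleTable", data = df, provenance = provenance)
}

#' Deterministic stepwise scan of rate constants
#'
#' Sets the target transition constant(s) to start + m * step for
#' m = 0 .. nSteps-1, evaluating the full observable block at each
#' quasi-steady state. With `coupleFixedK` the partner constant of the
#' same catalytic step is rescaled each row so that the step's
#' equilibrium constant keeps its reference value (and therefore the
#' total force never moves): the classic perfect-proportionality
#' construction in the efficiency-dissipation plane.
#'
#' @param params an [EnzymeParams]
#' @param targets transition indices or "k7"-style labels to step
#' @param start first value, 1/s (must be positive)
#' @param step increment per row, 1/s (must be positive)
#' @param nSteps number of rows
#' @param coupleFixedK rescale each target's partner constant to hold
#'   the step equilibrium constant fixed
#' @param base optional starting [RateSet]; defaults to the printed
#'   reference rate set
#' @return a [SampleTable]
#' @export
#' @examples
#' tab <- stepwiseScan(loadEnzyme("tpi"), "k7", start = 10, step = 10,
#'                     nSteps = 100)
#' max(sampleData(tab)$specificity)
stepwiseScan <- function(params, targets, start, step, nSteps,
                         coupleFixedK = FALSE,
                         base = referenceRateSet(params)) {
  stopifnot(is(params, "EnzymeParams"), start > 0, step > 0, nSteps >= 1)
  if (is.character(targets)) targets <- as.integer(sub("^k", "", targets))
  n <- base@nStates
  if (any(targets < 1L) || any(targets > 2L * n))
    stop("target indices outside 1..2n")
  kObs <- base@k
  env <- params@environment
  rows <- vector("list", nSteps)
  for (m in seq_len(nSteps)) {
    k <- kObs
    val <- start + (m - 1) * step
    if (val <= 0) stop("scan drove a target constant nonpositive")
    k[targets] <- val
    if (coupleFixedK) {
      for (t in targets) {
        s <- ceiling(t / 2)
        Kobs <- kObs[2L * s - 1L] / kObs[2L * s]
        if (t %% 2L == 1L) k[2L * s] <- k[t] / Kobs else
          k[2L * s - 1L] <- k[t] * Kobs
      }
    }
    rows[[m]] <- .computeRow(m - 1L, rateSet(k), env)
  }
  .makeTable(rows, list(generator = "stepwiseScan", enzyme = params@name,
                        targets = targets, start = start, step = step,
                        nSteps = nSteps, coupleFixedK = coupleFixedK))
}

#' Concentration scan at fixed substrate-plus-product pool
#'
#' Decreases the substrate and increases the product concentration
#' stepwise while conserving their sum (the batch-reactor mass-
#' conservation approximation for ligands), rebuilding the pseudo-
#' first-order binding constants from the second-order constants at
#' every row. The total force falls monotonically as the product
#' accumulates.
#'
#' @param params an [EnzymeParams]
#' @param nSteps number of rows (row 0 is the starting state)
#' @param delta concentration decrement per row, M; default walks
#'   [S] down to near zero across the scan
#' @param conserveSum keep [S] + [P] at its initial value (the only
#'   supported mode; present as an explicit, checkable flag)
#' @return a [SampleTable]
#' @export
concentrationScan <- function(params, nSteps,
                              delta = NULL, conserveSum = TRUE) {
  stopifnot(is(params, "EnzymeParams"), nSteps >= 1, isTRUE(conserveSum))
  env0 <- params@environment
  pool <- env0@substrate + env0@product
  if (pool <= 0) stop("conserved scan needs [S]0 + [P]0 > 0")
  if (is.null(delta)) delta <- env0@substrate / (nSteps + 1)
  rows <- vector("list", nSteps)
  for (m in seq_len(nSteps)) {
    S <- env0@substrate - (m - 1) * delta
    P <- pool - S
    if (S <= 0 || P <= 0)
      stop("scan drove a concentration nonpositive; reduce delta or nSteps")
    env <- cycleEnvironment(S, P, buffer = env0@buffer,
                            enzyme = env0@enzyme,
                            temperature = env0@temperature)
    rows[[m]] <- .computeRow(m - 1L, buildRateSet(params, env), env)
  }
  .makeTable(rows, list(generator = "concentrationScan",
                        enzyme = params@name, nSteps = nSteps,
                        delta = delta, conserveSum = conserveSum))
}

#' Constrained noisy sampling of quasi-steady states
#'
#' Draws `nSteps` independent constrained noisy rate sets around the
#' observed one (see [applyNoise()]) and evaluates the full observable
#' block at each quasi-steady state. The RNG is seeded from
#' `spec@seed`, so a rerun with the same specification is bit-identical.
#'
#' @param params an [EnzymeParams]
#' @param spec a [NoiseSpec]
#' @param nSteps number of samples
#' @param requirePositiveForce reject draws with non-positive total
#'   force (redrawing up to 1000 times per step)
#' @param base,observed starting and fallback [RateSet]s; default to the
#'   printed reference rate set
#' @return a [SampleTable]
#' @export
noisySample <- function(params, spec, nSteps, requirePositiveForce = FALSE,
                        base = referenceRateSet(params), observed = base) {
  stopifnot(is(params, "EnzymeParams"), is(spec, "NoiseSpec"), nSteps >= 1)
  env <- params@environment
  rows <- vector("list", nSteps)
  set.seed(spec@seed)
  for (m in seq_len(nSteps)) {
    for (attempt in seq_len(1000L)) {
      r <- applyNoise(base, observed, spec)
      if (!requirePositiveForce || totalForce(r) > 0) break
      if (attempt == 1000L)
        stop("could not draw a positive-force sample in 1000 attempts")
    }
    rows[[m]] <- .computeRow(m - 1L, r, env)
  }
  .makeTable(rows, list(generator = "noisySample", enzyme = params@name,
                        noise = list(distribution = spec@distribution,
                                     shift = spec@shift,
                                     drawPolicy = spec@drawPolicy,
                                     mask = spec@mask,
                                     constraint = spec@constraint,
                                     pair = spec@pair),
                        seed = spec@seed, nSteps = nSteps,
                        requirePositiveForce = requirePositiveForce))
}

#' Best sampled state under a criterion
#'
#' @param table a [SampleTable]
#' @param criterion "max_specificity", "max_entropy_production" or
#'   "max_kcat"; ties break to the earliest step
#' @return the winning row as a one-row data.frame
#' @export
bestPoint <- function(table, criterion = c("max_specificity",
                                           "max_entropy_production",
                                           "max_kcat")) {
  stopifnot(is(table, "SampleTable"))
  criterion <- match.arg(criterion)
  df <- table@data
  if (!nrow(df)) stop("empty sample table")
  col <- switch(criterion, max_specificity = "specificity",
                max_entropy_production = "P", max_kcat = "kcat")
  df[which.max(df[[col]]), , drop = FALSE]
}

#' Ordinary least-squares fit on sampled columns
#'
#' Fits y ~ x across the (optionally force-filtered) rows of a sample
#' table. R squared is 1 - SSres/SStot with the centered total sum of
#' squares for the free-intercept fit and the uncentered one for the
#' through-origin fit (the usual `lm` conventions), so it always lies
#' in [0, 1].
#'
#' @param table a [SampleTable]
#' @param x,y column names (defaults: entropy production "P" on x,
#'   "specificity" on y - the efficiency-dissipation plane)
#' @param throughOrigin constrain the intercept to zero
#' @param filter "all", "positive_force" or "negative_force" row subset
#' @return a [FitResult]
#' @export
linearFit <- function(table, x = "P", y = "specificity",
                      throughOrigin = FALSE,
                      filter = c("all", "positive_force", "negative_force")) {
  stopifnot(is(table, "SampleTable"))
  filter <- match.arg(filter)
  df <- table@data
  keep <- switch(filter, all = rep(TRUE, nrow(df)),
                 positive_force = df$forceSign > 0,
                 negative_force = df$forceSign < 0)
  xv <- df[[x]][keep]; yv <- df[[y]][keep]
  if (length(xv) < 2L) stop("need at least two points after filtering")
  if (stats::sd(xv) == 0) stop("degenerate fit: x has no variance")
  fit <- if (throughOrigin) stats::lm(yv ~ 0 + xv) else stats::lm(yv ~ xv)
  ssRes <- sum(stats::resid(fit)^2)
  ssTot <- if (throughOrigin) sum(yv^2) else sum((yv - mean(yv))^2)
  new("FitResult",
      slope = unname(stats::coef(fit)[["xv"]]),
      intercept = if (throughOrigin) 0 else unname(stats::coef(fit)[["(Intercept)"]]),
      rSquared = 1 - ssRes / ssTot,
      nPoints = length(xv),
      throughOrigin = throughOrigin)
}

#' Fold improvement of a sampled state over the observed one
#'
#' Ratios best/observed for the specificity constant, entropy
#' production, kcat and flux, plus the efficiency-per-dissipation fold
#' factor (specificity fold over dissipation fold).
#'
#' @param observed,best one-row data.frames as returned by
#'   [bestPoint()] (or rows of [sampleData()])
#' @return named numeric vector of fold factors
#' @export
foldReport <- function(observed, best) {
  need <- c("specificity", "P", "kcat", "J")
  for (nm in need) {
    if (is.null(observed[[nm]]) || is.null(best[[nm]]))
      stop(sprintf("both rows must carry a '%s' column", nm))
    if (observed[[nm]] == 0) stop(sprintf("observed '%s' is zero", nm))
  }
  folds <- vapply(need, function(nm) best[[nm]][1] / observed[[nm]][1],
                  numeric(1))
  c(folds, efficiencyPerDissipation = unname(folds["specificity"] / folds["P"]))
}

#' Observable block of a reference state as a sample row
#'
#' Evaluates the observed (printed) state of an enzyme in the same row
#' layout as the scan and sampler tables, for use as the baseline of
#' [foldReport()].
#'
#' @param params an [EnzymeParams]
#' @return a one-row data.frame
#' @export
referenceRow <- function(params) {
  stopifnot(is(params, "EnzymeParams"))
  as.data.frame(t(.computeRow(0L, referenceRateSet(params),
                              params@environment)))
}
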
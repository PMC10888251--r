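#' @include AllClasses.R AllGenerics.R registry.R steadyState.R observables.R noise.R exploration.R
NULL

#' Construct a stochastic-simulator configuration
#'
#' @param countsScale molecules per molar unit (one global factor); e.g.
#'   1e9 maps a count of 40 to 40 nM... any positive factor, provided it
#'   is used consistently for every species
#' @param initialCounts named vector with entries S, P and E (free
#'   substrate, free product, free enzyme); complexes start at zero
#' @param tickDt time per tick, s
#' @param nTicks number of ticks
#' @param noise optional [NoiseSpec] applied to the nominal rates every
#'   tick, or NULL
#' @param seed integer RNG seed
#' @param recordEvery record observables/counts every this many ticks
#' @return an [AbmConfig]
#' @export
abmConfig <- function(countsScale, initialCounts, tickDt, nTicks,
                      noise = NULL, seed = 1L, recordEvery = 1L) {
  new("AbmConfig", countsScale = countsScale,
      initialCounts = initialCounts, tickDt = tickDt,
      nTicks = as.integer(nTicks), noise = noise,
      seed = as.integer(seed), recordEvery = as.integer(recordEvery))
}

# scheme bookkeeping shared by init/tick:
# - state labels, per-transition free-ligand deltas (S and P), and the
#   per-state ligand-holding weights h_i that make
#   S + P + sum(h_i * complex_i) invariant
.abmScheme <- function(params) {
  n <- params@nStates
  labels <- switch(paste(n, params@schemeVariant),
    "2 standard" = c("E", "ES"),
    "3 standard" = c("E", "ES", "EP"),
    "4 standard" = c("E", "ES", "EZ", "EP"),
    "4 ca_buffer" = c("E", "ES", "EX", "EZ"),
    stop("unsupported scheme"))
  n2 <- 2L * n
  sDelta <- pDelta <- integer(n2)
  labs <- paste0("k", seq_len(n2))
  for (lab in names(params@secondOrder)) {
    t <- match(lab, labs)
    lig <- params@bindingLigand[[lab]]
    partner <- if (t %% 2L == 1L) t + 1L else t - 1L
    if (lig == "S") { sDelta[t] <- -1L; sDelta[partner] <- 1L }
    if (lig == "P") { pDelta[t] <- -1L; pDelta[partner] <- 1L }
    # buffer is treated as an unchanging reservoir (well-buffered)
  }
  # source state of each transition: odd 2i-1 leaves state i, even 2i
  # leaves state i+1 (cyclic)
  src <- integer(n2); dst <- integer(n2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    src[2L * i - 1L] <- i; dst[2L * i - 1L] <- j
    src[2L * i] <- j;      dst[2L * i] <- i
  }
  h <- integer(n)  # ligand-holding weight per state, propagated around
  for (i in seq_len(n - 1L)) {
    t <- 2L * i - 1L
    h[i + 1L] <- h[i] - (sDelta[t] + pDelta[t])
  }
  list(n = n, labels = labels, sDelta = sDelta, pDelta = pDelta,
       src = src, dst = dst, hold = h)
}

# nominal pseudo-first-order rates from current free-ligand
# concentrations (raw numeric; may contain zeros when a ligand is absent)
.abmRates <- function(params, S, P) {
  n2 <- 2L * params@nStates
  labs <- paste0("k", seq_len(n2))
  B <- params@environment@buffer
  k <- numeric(n2)
  for (i in seq_len(n2)) {
    lab <- labs[i]
    if (lab %in% names(params@secondOrder)) {
      conc <- switch(params@bindingLigand[[lab]], S = S, P = P, B = B)
      k[i] <- params@secondOrder[[lab]] * conc
    } else k[i] <- params@firstOrder[[lab]]
  }
  k
}

#' Initialize a stochastic simulation state
#'
#' Installs the integer molecule counts (all enzymes free), derives the
#' concentrations counts/countsScale, and builds the nominal rate set
#' from them.
#'
#' @param params an [EnzymeParams]
#' @param config an [AbmConfig]
#' @return a named list with `tick`, `counts` (named: S, P, then one
#'   entry per enzyme state), `rates` (raw numeric) and `conversions`
#' @export
#' @examples
#' st <- abmInit(loadEnzyme("tpi"),
#'               abmConfig(1e9, c(S = 40000, P = 64, E = 50), 1e-6, 10))
#' st$counts
abmInit <- function(params, config) {
  stopifnot(is(params, "EnzymeParams"), is(config, "AbmConfig"))
  validObject(config)
  if (config@initialCounts[["E"]] <= 0) stop("enzyme count must be positive")
  sch <- .abmScheme(params)
  counts <- c(S = unname(config@initialCounts[["S"]]),
              P = unname(config@initialCounts[["P"]]),
              stats::setNames(c(config@initialCounts[["E"]],
                                rep(0, sch$n - 1L)), sch$labels))
  S <- counts[["S"]] / config@countsScale
  P <- counts[["P"]] / config@countsScale
  list(tick = 0L, counts = counts, rates = .abmRates(params, S, P),
       conversions = 0, clamps = 0)
}

#' Advance a stochastic simulation by one tick
#'
#' For every enzyme state the numbers of molecules taking its forward
#' and backward transitions are drawn from one multinomial with
#' per-molecule probabilities k * tickDt (pseudo-first-order rates
#' recomputed from the current free-ligand counts). Updates are applied
#' simultaneously; draws that would consume more free ligand than is
#' available are clamped (and counted). Enzyme and ligand conservation
#' hold exactly by construction. Consumes the caller's RNG stream.
#'
#' @param state a state list from [abmInit()] or a previous tick
#' @param params an [EnzymeParams]
#' @param config an [AbmConfig]
#' @return the updated state list
#' @export
abmTick <- function(state, params, config) {
  sch <- .abmScheme(params)
  n <- sch$n
  counts <- state$counts
  S <- counts[["S"]] / config@countsScale
  P <- counts[["P"]] / config@countsScale
  k <- .abmRates(params, S, P)
  if (!is.null(config@noise) && all(k > 0)) {
    k <- applyNoise(rateSet(k), rateSet(k), config@noise)@k
  }
  pTrans <- k * config@tickDt
  if (max(pTrans) > 0.1)
    stop(sprintf(paste0("stability bound violated: max transition ",
                        "probability %.3g > 0.1 per tick; reduce tickDt"),
                 max(pTrans)))
  # out of state v: forward transition 2v-1, backward transition 2(v-1)
  # (cyclically: state 1 goes backward through transition 2n)
  events <- numeric(2L * n)
  for (v in seq_len(n)) {
    cv <- counts[[sch$labels[v]]]
    if (cv <= 0) next
    tf <- 2L * v - 1L
    tb <- if (v == 1L) 2L * n else 2L * (v - 1L)
    pf <- pTrans[tf]; pb <- pTrans[tb]
    draw <- stats::rmultinom(1L, cv, c(pf, pb, 1 - pf - pb))
    events[tf] <- draw[1L]; events[tb] <- draw[2L]
  }
  # clamp ligand consumption to the available free molecules
  for (lig in c("S", "P")) {
    delta <- if (lig == "S") sch$sDelta else sch$pDelta
    consuming <- which(delta == -1L)
    need <- sum(events[consuming])
    avail <- counts[[lig]]
    if (need > avail) {
      state$clamps <- state$clamps + 1
      # shrink consuming draws proportionally, largest first
      excess <- need - avail
      for (t in order(events[consuming], decreasing = TRUE)) {
        cut <- min(events[consuming[t]], excess)
        events[consuming[t]] <- events[consuming[t]] - cut
        excess <- excess - cut
        if (excess <= 0) break
      }
    }
  }
  new <- counts
  for (t in seq_len(2L * n)) {
    if (events[t] == 0) next
    from <- sch$labels[sch$src[t]]; to <- sch$labels[sch$dst[t]]
    new[[from]] <- new[[from]] - events[t]
    new[[to]] <- new[[to]] + events[t]
    new[["S"]] <- new[["S"]] + sch$sDelta[t] * events[t]
    new[["P"]] <- new[["P"]] + sch$pDelta[t] * events[t]
  }
  state$conversions <- state$conversions +
    sum(events[sch$pDelta == 1L]) - sum(events[sch$pDelta == -1L])
  state$counts <- new
  state$rates <- k
  state$tick <- state$tick + 1L
  state
}

#' Run the discrete stochastic simulator
#'
#' Seeds the RNG from the configuration, advances `nTicks` ticks, and
#' records the count trajectory plus - whenever all nominal rates are
#' positive - the full quasi-steady-state observable block evaluated
#' from the nominal rates at the current concentrations (the
#' deterministic closed forms applied tick by tick, not estimates from
#' the stochastic counts).
#'
#' @param params an [EnzymeParams]
#' @param config an [AbmConfig]
#' @return an [AbmResult]
#' @export
#' @examples
#' res <- abmRun(loadEnzyme("tpi"),
#'               abmConfig(1e9, c(S = 40000, P = 64, E = 50),
#'                         tickDt = 1e-6, nTicks = 200, recordEvery = 50))
#' res
abmRun <- function(params, config) {
  stopifnot(is(params, "EnzymeParams"), is(config, "AbmConfig"))
  set.seed(config@seed)
  state <- abmInit(params, config)
  sch <- .abmScheme(params)
  nRec <- length(seq(0L, config@nTicks, by = config@recordEvery))
  countsMat <- matrix(NA_real_, nRec, length(state$counts),
                      dimnames = list(NULL, names(state$counts)))
  rows <- vector("list", nRec)
  rec <- 0L
  record <- function(state) {
    rec <<- rec + 1L
    countsMat[rec, ] <<- state$counts
    k <- state$rates
    rows[[rec]] <<- if (all(k > 0)) {
      env <- cycleEnvironment(state$counts[["S"]] / config@countsScale,
                              state$counts[["P"]] / config@countsScale,
                              buffer = params@environment@buffer,
                              enzyme = params@environment@enzyme)
      .computeRow(state$tick, rateSet(k), env)
    } else {
      stats::setNames(c(state$tick, rep(NA_real_,
                                        length(.rowNames(sch$n)) - 1L)),
                      .rowNames(sch$n))
    }
  }
  record(state)
  for (t in seq_len(config@nTicks)) {
    state <- abmTick(state, params, config)
    if (t %% config@recordEvery == 0L) record(state)
  }
  table <- .makeTable(rows[seq_len(rec)],
                      list(generator = "abmRun", enzyme = params@name,
                           seed = config@seed, nTicks = config@nTicks,
                           tickDt = config@tickDt,
                           countsScale = config@countsScale))
  new("AbmResult", table = table, counts = countsMat[seq_len(rec), , drop = FALSE],
      clampEvents = state$clamps, netConversions = state$conversions,
      config = config)
}

#' Stochastic estimate of the per-enzyme cycle flux
#'
#' Net substrate-to-product conversions per enzyme per second over a
#' run: the quantity that converges to the deterministic cycle flux J
#' at large counts.
#'
#' @param result an [AbmResult]
#' @return flux estimate, 1/s per enzyme
#' @export
abmFluxEstimate <- function(result) {
  stopifnot(is(result, "AbmResult"))
  cfg <- result@config
  eTotal <- cfg@initialCounts[["E"]]
  result@netConversions / (eTotal * cfg@nTicks * cfg@tickDt)
}

#' Transient-corrected stochastic flux estimate
#'
#' [abmFluxEstimate()] averages over the whole run and therefore carries
#' a downward offset from the initial pipeline fill (enzymes start free,
#' so product release lags while the complexes populate). This variant
#' estimates the per-enzyme flux from the linear slope of the free
#' product count over the later part of the run, after the occupancies
#' have relaxed, which removes the offset.
#'
#' @param result an [AbmResult] whose counts were recorded at a regular
#'   interval
#' @param discard fraction of the recorded trajectory to drop from the
#'   start (default 0.5)
#' @return flux estimate, 1/s per enzyme
#' @export
abmFluxSlope <- function(result, discard = 0.5) {
  stopifnot(is(result, "AbmResult"), discard >= 0, discard < 1)
  cfg <- result@config
  Pct <- result@counts[, "P"]
  if (length(Pct) < 4L) stop("too few recorded ticks for a slope estimate")
  t <- (seq_along(Pct) - 1) * cfg@recordEvery * cfg@tickDt
  keep <- seq_along(Pct) > discard * length(Pct)
  slope <- unname(stats::coef(stats::lm(Pct[keep] ~ t[keep]))[2])
  slope / cfg@initialCounts[["E"]]
}
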
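tpiCfg <- function(...) {
  abmConfig(countsScale = 1e9, initialCounts = c(S = 40000, P = 64, E = 50),
            tickDt = 1e-6, ...)
}

test_that("initialization installs counts and concentrations consistently", {
  tpi <- loadEnzyme("tpi")
  st <- abmInit(tpi, tpiCfg(nTicks = 10L))
  expect_identical(unname(st$counts[c("S", "P", "E")]), c(40000, 64, 50))
  expect_identical(unname(st$counts[c("ES", "EZ", "EP")]), rep(0, 3))
  # counts over scale reproduce the reference concentrations (40 uM etc.)
  expect_equal(st$counts[["S"]] / 1e9, 4e-5)
  expect_equal(st$counts[["P"]] / 1e9, 6.4e-8)
  # nominal rates at those concentrations equal the built rate set
  expect_equal(st$rates, unname(rateConstants(buildRateSet(tpi))),
               tolerance = 1e-12)
  expect_error(abmInit(tpi, abmConfig(1e9, c(S = 1, P = 1, E = 0),
                                      1e-6, 1L)), "enzyme count")
})

test_that("an absent product zeroes the backward binding propensity", {
  tpi <- loadEnzyme("tpi")
  st <- abmInit(tpi, abmConfig(1e9, c(S = 40000, P = 0, E = 50), 1e-6, 10L))
  expect_identical(st$rates[8], 0)       # k8 = k8* x [P] = 0
  expect_true(all(st$rates[1:7] > 0))
})

test_that("enzyme and ligand conservation hold exactly at every tick", {
  tpi <- loadEnzyme("tpi")
  res <- abmRun(tpi, tpiCfg(nTicks = 2000L, seed = 8L, recordEvery = 100L))
  m <- res@counts
  expect_true(all(rowSums(m[, c("E", "ES", "EZ", "EP")]) == 50))
  expect_true(all(rowSums(m[, c("S", "P", "ES", "EZ", "EP")]) == 40064))
  expect_true(all(m >= 0))
  # the three-state and buffer schemes conserve as well
  pc1 <- loadEnzyme("pc1")
  resP <- abmRun(pc1, abmConfig(1e9, c(S = 30000, P = 200, E = 40),
                                tickDt = 5e-7, nTicks = 1000L, seed = 2L,
                                recordEvery = 200L))
  mp <- resP@counts
  expect_true(all(rowSums(mp[, c("E", "ES", "EP")]) == 40))
  expect_true(all(rowSums(mp[, c("S", "P", "ES", "EP")]) == 30200))
  ca1 <- loadEnzyme("ca1")
  resC <- abmRun(ca1, abmConfig(1e7, c(S = 12000, P = 240000, E = 100),
                                tickDt = 1e-8, nTicks = 500L, seed = 3L,
                                recordEvery = 100L))
  mc <- resC@counts
  expect_true(all(rowSums(mc[, c("E", "ES", "EX", "EZ")]) == 100))
  # in the buffer scheme only the ES complex holds a ligand
  expect_true(all(rowSums(mc[, c("S", "P", "ES")]) == 252000))
})

test_that("runs are reproducible under a fixed seed", {
  tpi <- loadEnzyme("tpi")
  a <- abmRun(tpi, tpiCfg(nTicks = 500L, seed = 77L, recordEvery = 50L))
  b <- abmRun(tpi, tpiCfg(nTicks = 500L, seed = 77L, recordEvery = 50L))
  expect_identical(a@counts, b@counts)
  expect_identical(a@netConversions, b@netConversions)
  c2 <- abmRun(tpi, tpiCfg(nTicks = 500L, seed = 78L, recordEvery = 50L))
  expect_false(identical(a@counts, c2@counts))
})

test_that("the stability bound rejects overly long ticks", {
  tpi <- loadEnzyme("tpi")
  st <- abmInit(tpi, tpiCfg(nTicks = 1L))
  cfgBad <- abmConfig(1e9, c(S = 40000, P = 64, E = 50), tickDt = 1e-3,
                      nTicks = 1L)
  expect_error(abmTick(st, tpi, cfgBad), "tickDt")
})

test_that("complexes populate sequentially along the cycle", {
  tpi <- loadEnzyme("tpi")
  res <- abmRun(tpi, tpiCfg(nTicks = 4000L, seed = 14L, recordEvery = 1L))
  m <- res@counts
  firstAbove <- function(sp) which(m[, sp] > 0)[1]
  expect_lte(firstAbove("ES"), firstAbove("EZ"))
  expect_lte(firstAbove("EZ"), firstAbove("EP"))
})

test_that("per-tick observables are the deterministic block at current concentrations", {
  tpi <- loadEnzyme("tpi")
  res <- abmRun(tpi, tpiCfg(nTicks = 200L, seed = 5L, recordEvery = 100L))
  df <- sampleData(res@table)
  i <- nrow(df)
  r <- rateSet(as.numeric(df[i, paste0("k", 1:8)]))
  env <- cycleEnvironment(df$S[i], df$Pconc[i])
  expect_equal(df$specificity[i], specificity(r, env), tolerance = 1e-12)
  expect_equal(df$J[i], flux(steadyState(r)), tolerance = 1e-12)
})

test_that("stochastic flux converges to the deterministic solver at large counts", {
  tpi <- loadEnzyme("tpi")
  Jdet <- flux(steadyState(referenceRateSet(tpi)))
  est <- vapply(1:4, function(s) {
    cfg <- abmConfig(1e12, c(S = 4e7, P = 64000, E = 50000),
                     tickDt = 1e-6, nTicks = 4000L, seed = s,
                     recordEvery = 50L)
    abmFluxSlope(abmRun(tpi, cfg))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - Jdet), 3 * se + 0.02 * Jdet)
})

test_that("per-tick noise perturbs the trajectory but keeps conservation", {
  tpi <- loadEnzyme("tpi")
  ns <- noiseSpec(mask = 1:8, shift = 0,
                  constraint = "replace_nonpositive_with_observed",
                  seed = 1L)
  # shorter ticks: a noisy multiplier can push the fastest transition
  # several-fold above its nominal rate
  res <- abmRun(tpi, abmConfig(1e9, c(S = 40000, P = 64, E = 50),
                               tickDt = 5e-8, nTicks = 500L, seed = 6L,
                               recordEvery = 100L, noise = ns))
  m <- res@counts
  expect_true(all(rowSums(m[, c("E", "ES", "EZ", "EP")]) == 50))
  expect_true(all(rowSums(m[, c("S", "P", "ES", "EZ", "EP")]) == 40064))
})
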
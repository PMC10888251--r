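test_that("the product-release scan reproduces the printed efficiency ceiling", {
  tpi <- loadEnzyme("tpi")
  tab <- stepwiseScan(tpi, "k7", start = 10, step = 10, nSteps = 1000)
  df <- sampleData(tab)
  expect_identical(nrow(df), 1000L)
  expect_equal(max(df$specificity), 1.25e6, tolerance = 1e-9)
  expect_equal(df$k7[which.max(df$specificity)], 10000)
  # the positive-force branch is tightly linear in the
  # efficiency-dissipation plane
  fit <- linearFit(tab, filter = "positive_force")
  expect_equal(fit@rSquared, 0.95216, tolerance = 1e-4)  # frozen
  expect_identical(fit@nPoints, 799L)
  bp <- bestPoint(tab, "max_specificity")
  expect_equal(bp$k7, 10000)
})

test_that("holding the step equilibrium fixed gives perfect proportionality", {
  tpi <- loadEnzyme("tpi")
  tab <- stepwiseScan(tpi, "k7", start = 100, step = 100, nSteps = 200,
                      coupleFixedK = TRUE)
  df <- sampleData(tab)
  # K4 pinned at its observed 156.25 on every row, force never moves
  expect_equal(df$k7 / df$k8, rep(156.25, 200), tolerance = 1e-12)
  expect_equal(df$Xtot, rep(df$Xtot[1], 200), tolerance = 1e-12)
  # proportionality between efficiency and dissipation: exact to plot
  # precision (the ratio retains a sub-percent drift because the other
  # six constants do not rescale with the k7-k8 pair)
  fit <- linearFit(tab, throughOrigin = TRUE)
  expect_gt(fit@rSquared, 0.99999)
  ref <- referenceRow(tpi)
  ratio <- df$specificity / df$P
  expect_lt(diff(range(ratio)) / mean(ratio), 0.02)
  expect_equal(mean(ratio), ref$specificity / ref$P, tolerance = 0.02)
})

test_that("fixed-K scans co-scale flux, kcat, efficiency and dissipation", {
  tpi <- loadEnzyme("tpi")
  tab <- stepwiseScan(tpi, "k1", start = 200, step = 200, nSteps = 50,
                      coupleFixedK = TRUE)
  df <- sampleData(tab)
  ref <- referenceRow(tpi)
  foldJ <- df$J / ref$J
  expect_equal(df$P / ref$P, foldJ, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(df$kcat / ref$kcat, foldJ)))  # kcat is not flux
})

test_that("every sampled row can be recomputed from its stored rates", {
  tpi <- loadEnzyme("tpi")
  tab <- stepwiseScan(tpi, "k7", start = 500, step = 500, nSteps = 10)
  df <- sampleData(tab)
  env <- tpi@environment
  for (i in c(1, 5, 10)) {
    r <- rateSet(as.numeric(df[i, paste0("k", 1:8)]))
    ss <- steadyState(r)
    expect_equal(df$J[i], flux(ss), tolerance = 1e-12)
    expect_equal(df$P[i], flux(ss) * totalForce(r), tolerance = 1e-12)
    expect_equal(df$specificity[i], specificity(r, env), tolerance = 1e-12)
    expect_equal(as.numeric(df[i, paste0("p", 1:4)]), occupancies(ss),
                 tolerance = 1e-12)
  }
})

test_that("the conserved concentration scan behaves monotonically", {
  tpi <- loadEnzyme("tpi")
  tab <- concentrationScan(tpi, nSteps = 100)
  df <- sampleData(tab)
  pool <- 4e-5 + 6.4e-8
  expect_equal(df$S + df$Pconc, rep(pool, 100), tolerance = 1e-15)
  expect_true(all(diff(df$Xtot) < 0))
  # row 0 is the printed reference state
  expect_printed(df$specificity[1], 7.86e5)
  expect_printed(df$Xtot[1], 0.685)
  expect_printed(df$P[1], 9.9)
  expect_error(concentrationScan(tpi, nSteps = 100, delta = 1e-3),
               "nonpositive")
})

test_that("shared-draw fixed-K noise cancels in the efficiency/dissipation ratio", {
  tpi <- loadEnzyme("tpi")
  spec <- noiseSpec(mask = c(1, 3, 5, 7), shift = 2, drawPolicy = "shared",
                    constraint = "fixed_step_equilibria", seed = 21)
  tab <- noisySample(tpi, spec, 200)
  df <- sampleData(tab)
  ratio <- df$specificity / df$P
  ref <- referenceRow(tpi)
  expect_equal(ratio, rep(ref$specificity / ref$P, 200), tolerance = 1e-10)
  expect_gt(sd(df$specificity) / mean(df$specificity), 0.1)  # noise did act
  fit <- linearFit(tab, throughOrigin = TRUE)
  expect_gt(fit@rSquared, 1 - 1e-12)
  # with every K pinned and one shared draw, the whole rate set rescales,
  # so flux, kcat, efficiency and dissipation share one fold per row
  foldJ <- df$J / ref$J
  expect_equal(df$kcat / ref$kcat, foldJ, tolerance = 1e-9)
  expect_equal(df$specificity / ref$specificity, foldJ, tolerance = 1e-9)
  expect_equal(df$P / ref$P, foldJ, tolerance = 1e-9)
})

test_that("paired-K sampling at fixed force shows an interior dissipation maximum", {
  # noise on the substrate-release constant k2 trades the first step's
  # equilibrium constant off against the product-binding step's (via
  # k8), leaving the total force untouched; dissipation then peaks at
  # an intermediate K4, not at the sampled extremes
  tpi <- loadEnzyme("tpi")
  spec <- noiseSpec(mask = 2, shift = 2, constraint = "fixed_total_force",
                    pair = c(1L, 4L), seed = 33)
  tab <- noisySample(tpi, spec, 2000)
  df <- sampleData(tab)
  expect_equal(df$Xtot, rep(totalForce(referenceRateSet(tpi)), 2000),
               tolerance = 1e-10)
  expect_gt(diff(range(df$k7 / df$k8)), 1)   # K4 really was perturbed
  K4 <- df$k7 / df$k8
  ord <- order(K4)
  peak <- which.max(df$P[ord])
  # interior, not at either sampled extreme (the left flank is thin:
  # the positive-truncated shifted normal rarely draws small enough
  # multipliers to land below the optimum near K4 of about 10)
  expect_gt(peak, 2)
  expect_lt(peak, length(ord) - 50)
  expect_lt(df$P[ord][1], 0.5 * df$P[ord][peak])              # rises in
  expect_lt(mean(utils::tail(df$P[ord], 100)), df$P[ord][peak])  # falls off
})

test_that("best-point extraction is deterministic and well-defined", {
  tpi <- loadEnzyme("tpi")
  one <- stepwiseScan(tpi, "k7", start = 4000, step = 1, nSteps = 1)
  expect_identical(bestPoint(one, "max_specificity")$step,
                   sampleData(one)$step[1])
  tab <- stepwiseScan(tpi, "k7", start = 10, step = 10, nSteps = 100)
  bp <- bestPoint(tab, "max_entropy_production")
  expect_equal(bp$P, max(sampleData(tab)$P))
  # ties break to the earliest step
  df <- sampleData(tab); df$specificity <- rep(1, nrow(df))
  tied <- new("SampleTable", data = df, provenance = list())
  expect_identical(bestPoint(tied, "max_specificity")$step, df$step[1])
  expect_error(bestPoint(new("SampleTable",
                             data = df[0, ], provenance = list())),
               "empty")
})

test_that("linear fits respect their conventions and filters", {
  df <- data.frame(step = 0:9, P = 1:10,
                   specificity = 2 * (1:10) + 5,
                   forceSign = rep(c(-1, 1), 5))
  tab <- new("SampleTable", data = df, provenance = list())
  fit <- linearFit(tab)
  expect_equal(fit@slope, 2, tolerance = 1e-12)
  expect_equal(fit@intercept, 5, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_lte(linearFit(tab, filter = "positive_force")@nPoints, nrow(df))
  const <- df; const$P <- 1
  expect_error(linearFit(new("SampleTable", data = const,
                             provenance = list())), "variance")
})

test_that("fold reports compare best and observed states", {
  tpi <- loadEnzyme("tpi")
  ref <- referenceRow(tpi)
  same <- foldReport(ref, ref)
  expect_equal(unname(same[c("specificity", "P", "kcat", "J")]),
               rep(1, 4))
  tab <- stepwiseScan(tpi, "k7", start = 10, step = 10, nSteps = 1000)
  best <- bestPoint(tab, "max_specificity")
  fr <- foldReport(ref, best)
  expect_equal(unname(fr["specificity"]), 1.25e6 / ref$specificity,
               tolerance = 1e-9)
  expect_gt(fr[["P"]], 1)
})

test_that("tables round-trip through CSV with their manifest", {
  tpi <- loadEnzyme("tpi")
  tab <- stepwiseScan(tpi, "k7", start = 10, step = 10, nSteps = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".manifest.json"))), add = TRUE)
  writeSampleTable(tab, path)
  back <- readSampleTable(path)
  expect_equal(sampleData(back), sampleData(tab), tolerance = 1e-12)
  expect_identical(provenance(back)$generator, "stepwiseScan")
  expect_true(file.exists(paste0(path, ".manifest.json")))
})
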
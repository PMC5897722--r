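test_that("generator is reproducible and honours the design counts", {
  d <- simDesign(nProbes = 500, fracAging = 0.2, seed = 42)
  s1 <- simulateControlTimecourse(d)
  s2 <- simulateControlTimecourse(d)
  expect_identical(exprsMatrix(s1$pe), exprsMatrix(s2$pe))
  expect_identical(s1$truth@agingProbeIds, s2$truth@agingProbeIds)

  expect_length(s1$truth@agingProbeIds, 100)
  expect_equal(dim(exprsMatrix(s1$pe)), c(500L, 4L * 5L))
  expect_length(intersect(s1$truth@agingProbeIds,
                          s1$truth@mutantSpecificIds), 0)

  dDrop <- simDesign(nProbes = 50, dropFirstAgeRep = TRUE, seed = 1)
  expect_equal(ncol(simulateControlTimecourse(dDrop)$pe), 19L)

  expect_error(simDesign(repsPerCell = 1), "repsPerCell")
  expect_error(simDesign(ages = c(10, 3, 30, 45)), "increasing")
  expect_error(simDesign(accelFactor = 0), "accelFactor")
})

test_that("null design has no age dependence beyond noise", {
  d <- simDesign(nProbes = 300, fracAging = 0, noiseSd = 0.25, seed = 9)
  sim <- simulateControlTimecourse(d)
  expect_length(sim$truth@agingProbeIds, 0)
  values <- exprsMatrix(sim$pe)
  ages <- SummarizedExperiment::colData(sim$pe)$age_days
  # per-probe spread of age-group means stays at the noise scale
  groupMeans <- vapply(unique(ages), function(a)
    rowMeans(values[, ages == a, drop = FALSE]), numeric(nrow(values)))
  spread <- apply(groupMeans, 1, function(r) max(r) - min(r))
  expect_lt(median(spread), 4 * d@noiseSd / sqrt(d@repsPerCell))
})

test_that("aging-probe trajectories track the generating parameters", {
  d <- simDesign(nProbes = 400, fracAging = 0.25, slopeSd = 0.05,
                 noiseSd = 0.25, seed = 1)
  sim <- simulateControlTimecourse(d)
  values <- exprsMatrix(sim$pe)
  ages <- SummarizedExperiment::colData(sim$pe)$age_days
  # per-(probe, age) sample means deviate from b0 + slope*age on the scale
  # of noiseSd/sqrt(reps): ~95% within 2 SE, none beyond 5 SE
  se <- d@noiseSd / sqrt(d@repsPerCell)
  z <- sapply(unique(ages), function(a) {
    obs <- rowMeans(values[sim$truth@agingProbeIds, ages == a, drop = FALSE])
    exp <- sim$truth@baseline[sim$truth@agingProbeIds] +
      sim$truth@slopes[sim$truth@agingProbeIds] * a
    (obs - exp) / se
  })
  expect_gt(mean(abs(z) < 2), 0.90)
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 0.1)
  # population contrast day 45 vs day 3 is slope * 42 by construction
  p <- sim$truth@agingProbeIds[1]
  mu45 <- sim$truth@baseline[p] + sim$truth@slopes[p] * 45
  mu3 <- sim$truth@baseline[p] + sim$truth@slopes[p] * 3
  expect_equal(unname(mu45 - mu3), unname(sim$truth@slopes[p] * 42))
})

test_that("mutant generation evaluates aging trends at the effective age", {
  d <- simDesign(nProbes = 400, fracAging = 0.25, accelFactor = 2,
                 noiseSd = 0.2, seed = 4)
  sim <- simulateControlTimecourse(d)
  mut <- simulateMutantSamples(d, sim$truth, chronAge = 10, nReps = 40)
  aging <- sim$truth@agingProbeIds
  expected <- sim$truth@baseline[aging] + sim$truth@slopes[aging] * 20
  observed <- rowMeans(exprsMatrix(mut)[aging, ])
  expect_lt(max(abs(observed - expected)), 4 * d@noiseSd / sqrt(40))
  # mutant-specific probes carry their planted shift
  ms <- sim$truth@mutantSpecificIds
  shift <- rowMeans(exprsMatrix(mut)[ms, ]) - sim$truth@baseline[ms]
  expect_true(all(abs(shift - sim$truth@mutantOffsets) < 4 * d@noiseSd / sqrt(40)))
  expect_true(all(abs(sim$truth@mutantOffsets) >= log2(1.5)))
})

test_that("an acceleration factor of 1 reproduces the control law", {
  fails <- 0L
  for (seed in 1:10) {
    d <- simDesign(nProbes = 300, fracAging = 0.25, accelFactor = 1,
                   nMutantSpecific = 0, seed = seed)
    sim <- simulateControlTimecourse(d)
    mut <- simulateMutantSamples(d, sim$truth, chronAge = 10)
    ctrl <- simulateMutantSamples(d, sim$truth, chronAge = 10,
                                  genotype = "fresh_control")
    ks <- suppressWarnings(
      ks.test(as.vector(exprsMatrix(mut)), as.vector(exprsMatrix(ctrl))))
    if (ks$p.value < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("batch assignment plants recoverable offsets and duplicates the tech rep", {
  d <- simDesign(nProbes = 300, batchOffsetSd = 0.3, seed = 7)
  sim <- simulateControlTimecourse(d)
  batch2 <- colnames(sim$pe)[11:20]
  ba <- assignBatches(sim$pe, d, batch2Samples = batch2, truth = sim$truth)
  meta <- SummarizedExperiment::colData(ba$pe)
  expect_equal(ncol(ba$pe), ncol(sim$pe) + 1L)
  expect_equal(sum(meta$is_tech_rep), 2L)
  expect_setequal(as.character(meta$batch[meta$is_tech_rep]), c("b1", "b2"))
  expect_identical(ba$truth@batchOffsets, ba$batchOffsets)

  # tech-rep difference estimates the stored offsets within technical noise
  tech <- colnames(ba$pe)[meta$is_tech_rep]
  b1 <- tech[meta$batch[match(tech, colnames(ba$pe))] == "b1"]
  b2 <- setdiff(tech, b1)
  est <- exprsMatrix(ba$pe)[, b2] - exprsMatrix(ba$pe)[, b1]
  expect_gt(cor(est, ba$batchOffsets), 0.95)
  expect_lt(max(abs(est - ba$batchOffsets)), 5 * 0.05)

  # single-batch design is a no-op
  noop <- assignBatches(sim$pe, d, batch2Samples = character(0))
  expect_identical(exprsMatrix(noop$pe), exprsMatrix(sim$pe))
})
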
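test_that("baseline subtraction removes a constant batch shift exactly", {
  set.seed(1)
  base <- matrix(rnorm(40, 9), 10, 4,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  # batch 2 = copies of s1 (tech rep) and s4, both shifted by +0.3
  values <- cbind(base, s1b2 = base[, "s1"] + 0.3, s5 = base[, "s4"] + 0.3)
  pe <- peFromMatrix(values, age = c(3, 3, 10, 10, 3, 10),
                     batch = c(rep("b1", 4), "b2", "b2"),
                     techRep = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- subtractBatchBaseline(pe)
  expect_false("s1b2" %in% colnames(out))            # duplicate dropped
  expect_equal(exprsMatrix(out)[, "s5"], base[, "s4"])  # -0.3 applied
  expect_equal(S4Vectors::metadata(out)$batchBaselineOffsets$b2,
               rep(0.3, 10), ignore_attr = TRUE)
})

test_that("baseline subtraction is identity for one batch and errors without a tech rep", {
  set.seed(2)
  m <- matrix(rnorm(20, 9), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  pe <- peFromMatrix(m)
  expect_identical(exprsMatrix(subtractBatchBaseline(pe)), m)

  pe2 <- peFromMatrix(m, batch = c("b1", "b1", "b2", "b2"),
                      techRep = c(TRUE, FALSE, FALSE, FALSE))
  expect_error(subtractBatchBaseline(pe2), "batch 'b2'")
})

test_that("baseline subtraction centres planted batch offsets on zero", {
  d <- simDesign(nProbes = 400, fracAging = 0, batchOffsetSd = 0.4, seed = 3)
  sim <- simulateControlTimecourse(d)
  batch2 <- colnames(sim$pe)[11:20]
  ba <- assignBatches(sim$pe, d, batch2Samples = batch2)
  out <- subtractBatchBaseline(ba$pe)
  meta <- SummarizedExperiment::colData(out)
  diffs <- rowMeans(exprsMatrix(out)[, meta$batch == "b2"]) -
    rowMeans(exprsMatrix(out)[, meta$batch == "b1"])
  # planted offsets (SD 0.4) are gone; residual scatter is at the SE of a
  # 10-sample mean difference plus technical noise
  expect_lt(abs(mean(diffs)), 0.05)
  expect_lt(sd(diffs), 0.2)
  expect_lt(cor(diffs, ba$batchOffsets), 0.3)
})

test_that("quantile normalization matches the rank-wise mean definition", {
  m <- cbind(a = c(2, 4, 6), b = c(3, 5, 7))
  rownames(m) <- paste0("p", 1:3)
  out <- quantileNormalize(m)
  expect_equal(unname(out), cbind(c(2.5, 4.5, 6.5), c(2.5, 4.5, 6.5)))

  set.seed(4)
  m2 <- matrix(rnorm(200, 9), 40, 5,
               dimnames = list(paste0("p", 1:40), paste0("s", 1:5)))
  n1 <- quantileNormalize(m2)
  # identical columns in, identical out; sorted columns identical across samples
  expect_equal(quantileNormalize(cbind(a = m2[, 1], b = m2[, 1]))[, "a"],
               m2[, 1], ignore_attr = TRUE)
  sorted <- apply(n1, 2, sort)
  expect_equal(max(sorted - sorted[, 1]), 0, tolerance = 1e-12)
  # idempotence
  expect_equal(quantileNormalize(n1), n1, tolerance = 1e-12)
})

test_that("noise floor: override, flat relationship, and planted changepoint", {
  set.seed(5)
  means <- runif(3000, 5.5, 12)
  cv <- 0.03 + pmax(0, 7 - means) * 0.06     # inflated CV below mean 7
  values <- t(vapply(seq_along(means), function(i)
    rnorm(12, means[i], cv[i] * means[i]), numeric(12)))
  dimnames(values) <- list(sprintf("p%04d", seq_along(means)),
                           sprintf("s%02d", 1:12))

  fixed <- fitNoiseFloor(values, override = 7.5)
  expect_equal(fixed@floorValue, 7.5)
  expect_equal(fixed@method, "fixed")
  expect_gt(nrow(fixed@diagnostics), 0)

  fitted <- fitNoiseFloor(values)
  expect_equal(fitted@method, "lowess")
  expect_lt(abs(fitted@floorValue - 7), 0.5)

  flat <- t(vapply(seq_along(means), function(i)
    rnorm(12, means[i], 0.04 * means[i]), numeric(12)))
  dimnames(flat) <- dimnames(values)
  flatFloor <- fitNoiseFloor(flat)
  expect_equal(flatFloor@floorValue, min(rowMeans(flat)))

  expect_error(fitNoiseFloor(matrix(5, 20, 4,
    dimnames = list(paste0("p", 1:20), paste0("s", 1:4)))), "degenerate")
})

test_that("noise-floor application clamps, discards, and never inflates", {
  values <- rbind(low = c(6.0, 6.2, 7.1), mid = c(7.0, 8.0, 8.5),
                  high = c(9, 10, 11))
  colnames(values) <- paste0("s", 1:3)
  pe <- peFromMatrix(values)
  out <- applyNoiseFloor(pe, 7.5)
  expect_false("low" %in% rownames(out))         # max below floor: discarded
  expect_equal(unname(exprsMatrix(out)["mid", ]), c(7.5, 8.0, 8.5))
  expect_equal(S4Vectors::metadata(out)$nProbesRemoved, 1L)
  # kept values are exactly the clamped originals (never decreased below
  # floor, never increased above the original)
  expect_equal(exprsMatrix(out), pmax(values[rownames(out), ], 7.5))
  # all values above the floor: identity
  out2 <- applyNoiseFloor(pe, 5)
  expect_identical(exprsMatrix(out2), values)
  set.seed(6)
  m <- matrix(rnorm(100, 8, 1), 20, 5,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:5)))
  o <- applyNoiseFloor(peFromMatrix(m), 7.5)
  kept <- rownames(o)
  expect_true(all(apply(m[kept, ], 1, max) > 7.5))
  expect_true(all(setdiff(rownames(m), kept) %in%
                    rownames(m)[apply(m, 1, max) <= 7.5]))
})

test_that("sample exclusion drops listed columns only", {
  set.seed(7)
  m <- matrix(rnorm(20, 9), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  pe <- peFromMatrix(m)
  out <- excludeSamples(pe, "s2")
  expect_equal(colnames(out), c("s1", "s3", "s4"))
  expect_warning(excludeSamples(pe, "nope"), "unknown sample")
})
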
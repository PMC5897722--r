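test_that("row-wise ANOVA and Tukey match the stats oracles", {
  set.seed(21)
  g <- factor(rep(c("a", "b", "c"), c(4, 5, 5)))
  m <- matrix(rnorm(20 * 14, 8), 20, 14,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:14)))
  m[1:5, g == "c"] <- m[1:5, g == "c"] + 1.2    # some truly shifted probes
  # fdr = 1 disables gatekeeping so every probe is Tukey-tested
  de <- callAffected(m, classes = g, fdr = 1)
  for (i in c(1, 3, 9, 17)) {
    fit <- aov(m[i, ] ~ g)
    expect_equal(de$anova_p[i], summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
    tk <- TukeyHSD(fit)$g
    expect_equal(de$`tukey_p.a.vs.b`[i], tk["b-a", "p adj"], tolerance = 1e-8)
    expect_equal(de$`tukey_p.a.vs.c`[i], tk["c-a", "p adj"], tolerance = 1e-8)
    expect_equal(de$`log2fc.a.vs.c`[i],
                 mean(m[i, g == "a"]) - mean(m[i, g == "c"]),
                 tolerance = 1e-12)
  }
  expect_equal(de$anova_q, p.adjust(de$anova_p, "BH"))
  expect_error(callAffected(m, classes = factor(rep(c("a", "b"), c(1, 13)))),
               "< 2 replicates")
})

test_that("null simulation yields (almost) no affected calls; planted shifts are found", {
  set.seed(22)
  g <- factor(rep(c("ctrl", "mut"), each = 5))
  null <- matrix(rnorm(1000 * 10, 8, 0.25), 1000, 10,
                 dimnames = list(sprintf("p%04d", 1:1000), paste0("s", 1:10)))
  deNull <- callAffected(null, classes = g)
  expect_lte(length(affectedProbes(deNull)), 5)

  planted <- null
  idx <- 1:50
  planted[idx, g == "mut"] <- planted[idx, g == "mut"] + 1.0
  de <- callAffected(planted, classes = g,
                     contrasts = list(c("mut", "ctrl")))
  hits <- affectedProbes(de, "mut.vs.ctrl")
  # with 5 replicates per group the per-probe variance estimate is noisy
  # (df = 8), so a 1.0 log2 shift at noise SD 0.25 clears the BH gate for
  # most but not all planted probes
  expect_gte(mean(rownames(planted)[idx] %in% hits), 0.8)
  expect_lte(length(setdiff(hits, rownames(planted)[idx])),
             ceiling(0.05 * length(hits)))
  # fold changes are mutant minus control and centred on the planted shift
  expect_true(all(de$`log2fc.mut.vs.ctrl`[idx] > 0))
  expect_equal(mean(de$`log2fc.mut.vs.ctrl`[idx]), 1.0, tolerance = 0.1)
})

test_that("affected flag is gatekept and monotone in |log2fc|", {
  set.seed(23)
  g <- factor(rep(c("ctrl", "mut"), each = 5))
  m <- matrix(rnorm(200 * 10, 8, 0.25), 200, 10,
              dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:10)))
  m[1:40, g == "mut"] <- m[1:40, g == "mut"] +
    rep(c(0.2, 0.45, 0.7, 1.2), each = 10)
  de <- callAffected(m, classes = g, contrasts = list(c("mut", "ctrl")))
  # gatekeeping: probes failing the ANOVA gate carry NA post hoc p-values
  expect_true(all(is.na(de$`tukey_p.mut.vs.ctrl`[de$anova_q >= 0.05])))
  # sub-threshold fold changes are never called affected
  small <- abs(de$`log2fc.mut.vs.ctrl`) < log2(1.5)
  expect_false(any(de$`affected.mut.vs.ctrl`[small]))
})

test_that("overlap test reproduces the Yates closed form and set bookkeeping", {
  u <- sprintf("g%03d", 1:200)
  A <- u[1:100]             # a + b = 100
  B <- u[c(1:30, 101:110)]  # a = 30 overlap, c = 10
  ov <- overlapTest(A, B, u)
  expect_equal(ov$nAB, 30)
  expect_equal(ov$chi2Yates,
               200 * (abs(30 * 90 - 70 * 10) - 200 / 2)^2 /
                 (100 * 100 * 40 * 160),
               tolerance = 1e-10)
  expect_equal(ov$pValue, pchisq(ov$chi2Yates, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(overlapTest(A, B, 0), "empty universe")
})

test_that("Yates correction never exceeds the uncorrected statistic", {
  set.seed(24)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 30) + 5, 2)
    yates <- suppressWarnings(chisq.test(tab, correct = TRUE)$statistic)
    raw <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_lte(yates, raw + 1e-12)
  }
})

test_that("concordance handles identity, sign flip, and shared-index logic", {
  fc <- c(p1 = 1.2, p2 = -0.8, p3 = 0.4, p4 = -2)
  same <- concordance(fc, fc)
  expect_equal(same$r2, 1)
  expect_equal(same$pctConcordant, 100)
  flip <- concordance(fc, -fc)
  expect_equal(flip$r2, 1)
  expect_equal(flip$pctConcordant, 0)
  expect_error(concordance(fc[1:2], fc[1:2]), ">= 3 shared")
  mixed <- concordance(fc, c(p1 = 0.5, p2 = -0.1, p3 = -0.2, p4 = -1))
  expect_equal(mixed$pctConcordant, 75)
})

test_that("rescue classification follows the full/partial/none rules", {
  mkDE <- function(ids, fc, affected, contrast) {
    tab <- S4Vectors::DataFrame(probe_id = ids, anova_p = 0.001,
                                anova_q = 0.001)
    tab[[paste0("tukey_p.", contrast)]] <- 0.001
    tab[[paste0("log2fc.", contrast)]] <- fc
    tab[[paste0("affected.", contrast)]] <- affected
    tab
  }
  ids <- c("pFull", "pPartial", "pNone", "pSignFlip")
  deNull <- mkDE(ids, c(2.0, 2.0, 2.0, 2.0), rep(TRUE, 4), "null.vs.ctrl")
  deResc <- mkDE(ids, c(0.1, 0.8, 2.5, -0.9),
                 c(FALSE, TRUE, TRUE, TRUE), "resc.vs.ctrl")
  rc <- classifyRescue(deNull, deResc, "null.vs.ctrl", "resc.vs.ctrl")
  expect_equal(rc$status, c("full", "partial", "none", "partial"))
  expect_equal(S4Vectors::metadata(rc)$pctRescued, 75)

  # probe present only in the null table: warning, status none
  deResc2 <- mkDE(ids[1:3], c(0.1, 0.8, 2.5), c(FALSE, TRUE, TRUE),
                  "resc.vs.ctrl")
  expect_warning(rc2 <- classifyRescue(deNull, deResc2, "null.vs.ctrl",
                                       "resc.vs.ctrl"), "absent")
  expect_equal(rc2$status[rc2$probe_id == "pSignFlip"], "none")
})
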
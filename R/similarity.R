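# Profile similarity: correlate each mutant sample with each control sample
# over the probes affected by both aging and the mutation, grouped by control
# age.

#' Intersect aging-related and mutant-affected probe sets
#'
#' @param aging an `AgingGeneTable` from [selectAgingGenes()].
#' @param affected a `DEResult` from [callAffected()] (any contrast counts) or
#'   a character vector of probe ids.
#' @param contrast optional contrast name restricting the affected set.
#' @return Character vector of probe ids flagged in both tables; an empty
#'   intersection is an error (downstream correlations are undefined).
#' @export
intersectProbeSet <- function(aging, affected, contrast = NULL) {
  a <- agingProbes(aging)
  b <- if (is.character(affected)) affected
       else affectedProbes(affected, contrast)
  out <- intersect(a, b)
  if (length(out) == 0)
    stop("empty intersection of aging-related and affected probes")
  out
}

#' Correlate mutant profiles with control profiles across ages
#'
#' Computes the Pearson correlation over `probeSet` for every (mutant sample,
#' control sample) pair, groups the r values by control age, and tests for an
#' age effect with one-way ANOVA plus Tukey-HSD. With `onMeans = TRUE` the
#' mean mutant profile is correlated with the per-age mean control profile
#' instead (one r per control age; no ANOVA).
#'
#' @param pe a [PhysioExperiment-class] holding both groups.
#' @param probeSet probe ids to correlate over (>= 3).
#' @param mutantSamples,controlSamples column ids of the two groups.
#' @param onMeans compare group mean profiles instead of individual samples.
#' @return A [SimilarityResult-class].
#' @export
profileCorrelations <- function(pe, probeSet, mutantSamples, controlSamples,
                                onMeans = FALSE) {
  if (length(probeSet) < 3) stop("need >= 3 probes in the probe set")
  values <- exprsMatrix(pe)
  if (!all(probeSet %in% rownames(values)))
    stop("probe set contains ids absent from the matrix")
  stopifnot(all(mutantSamples %in% colnames(values)),
            all(controlSamples %in% colnames(values)))
  ctrlAges <- colData(pe)[controlSamples, "age_days"]
  sub <- values[probeSet, , drop = FALSE]

  if (onMeans) {
    mutMean <- rowMeans(sub[, mutantSamples, drop = FALSE])
    ages <- sort(unique(ctrlAges))
    r <- vapply(ages, function(a) {
      cm <- rowMeans(sub[, controlSamples[ctrlAges == a], drop = FALSE])
      stats::cor(mutMean, cm)
    }, numeric(1))
    pairs <- data.frame(mutant = "mean", control = paste0("mean_d", ages),
                        control_age = ages, r = r)
    perAge <- data.frame(control_age = ages, mean_r = r, sem_r = NA_real_,
                         n_pairs = 1L)
    return(methods::new("SimilarityResult", probeSet = probeSet,
                        pairs = pairs, perAge = perAge, anovaP = NA_real_,
                        tukey = data.frame()))
  }

  cmat <- stats::cor(sub[, mutantSamples, drop = FALSE],
                     sub[, controlSamples, drop = FALSE])
  pairs <- data.frame(
    mutant = rep(mutantSamples, times = length(controlSamples)),
    control = rep(controlSamples, each = length(mutantSamples)),
    control_age = rep(ctrlAges, each = length(mutantSamples)),
    r = as.vector(cmat))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  ages <- sort(unique(ctrlAges))
  perAge <- do.call(rbind, lapply(ages, function(a) {
    v <- pairs$r[pairs$control_age == a]
    data.frame(control_age = a, mean_r = mean(v), sem_r = sem(v),
               n_pairs = length(v))
  }))
  anovaP <- NA_real_
  tukey <- data.frame()
  if (length(ages) >= 2 && all(perAge$n_pairs >= 2)) {
    g <- factor(pairs$control_age)
    fit <- stats::aov(pairs$r ~ g)
    anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey <- as.data.frame(stats::TukeyHSD(fit)$g)
  }
  methods::new("SimilarityResult", probeSet = probeSet, pairs = pairs,
               perAge = perAge, anovaP = anovaP, tukey = tukey)
}
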
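# Synthetic multi-age expression experiments with planted ground truth.
# Aging probes follow b0 + slope * age on the log2 scale; noise is
# homoscedastic Gaussian. Low-end censoring belongs to the preprocessing
# stage, not the generator.

.rowSds <- function(x) {
  n <- ncol(x)
  sqrt(rowSums((x - rowMeans(x))^2) / (n - 1L))
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' All randomness in the package flows from one integer seed; each stage draws
#' from a child seed computed from the stage name so stages can be rerun
#' independently yet reproducibly.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return An integer below 2^31.
#' @export
childSeed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 100003L
  as.integer((as.numeric(seed) * 10007 + h) %% (.Machine$integer.max - 1L))
}

.sampleIds <- function(prefix, ages, reps) {
  unlist(lapply(seq_along(ages), function(i)
    sprintf("%s_d%g_r%d", prefix, ages[i], seq_len(reps[i]))))
}

#' Simulate a control aging time course
#'
#' Generates a probe x sample log2 expression matrix in which a planted subset
#' of probes changes linearly with age (balanced up/down directions) and the
#' rest are flat, plus the ground truth needed to validate every downstream
#' stage.
#'
#' @param design a [SimDesign-class].
#' @param tissue,genotype annotations written into the sample metadata.
#' @return A list with elements `pe` ([PhysioExperiment-class]) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' sim <- simulateControlTimecourse(simDesign(nProbes = 200, seed = 7))
#' sim$pe
#' @export
simulateControlTimecourse <- function(design, tissue = "head",
                                      genotype = "control") {
  methods::validObject(design)
  set.seed(design@seed)
  n <- design@nProbes
  probes <- sprintf("probe_%05d", seq_len(n))
  nAging <- round(design@fracAging * n)
  aging <- if (nAging > 0) sort(sample(n, nAging)) else integer(0)

  baseline <- stats::rnorm(n, mean = 9, sd = 1.5)
  slopes <- numeric(n)
  if (nAging > 0) {
    mag <- if (is.na(design@slopeValue)) abs(stats::rnorm(nAging, 0, design@slopeSd))
           else rep(design@slopeValue, nAging)
    sgn <- sample(rep(c(1, -1), length.out = nAging))
    slopes[aging] <- mag * sgn
  }
  nonAging <- setdiff(seq_len(n), aging)
  nMut <- min(design@nMutantSpecific, length(nonAging))
  mutIdx <- if (nMut > 0) sort(sample(nonAging, nMut)) else integer(0)
  mutOffsets <- if (nMut > 0)
    design@mutantShift * sample(c(1, -1), nMut, replace = TRUE)
  else numeric(0)

  reps <- rep(design@repsPerCell, length(design@ages))
  if (design@dropFirstAgeRep) reps[1] <- reps[1] - 1L
  sampleAges <- rep(design@ages, reps)
  ids <- .sampleIds(paste0(genotype, "_", tissue), design@ages, reps)

  mu <- outer(slopes, sampleAges) + baseline
  values <- mu + stats::rnorm(length(mu), 0, design@noiseSd)
  dimnames(values) <- list(probes, ids)

  meta <- data.frame(sample_id = ids, tissue = tissue, genotype = genotype,
                     age_days = sampleAges, batch = "b1",
                     is_tech_rep = FALSE)
  names(slopes) <- names(baseline) <- probes
  truth <- methods::new("SimTruth",
                        agingProbeIds = probes[aging], slopes = slopes,
                        baseline = baseline,
                        mutantSpecificIds = probes[mutIdx],
                        mutantOffsets = stats::setNames(mutOffsets, probes[mutIdx]),
                        batchOffsets = numeric(0))
  list(pe = PhysioExperiment(values, meta), truth = truth)
}

#' Simulate mutant samples with accelerated effective age
#'
#' Mutants are drawn from the control generative model evaluated at the
#' effective age `accelFactor * chronAge`, with additional fixed log2 shifts
#' on the mutant-specific (non-aging) probes, so that an accelerated-aging
#' signal and a trend-independent mutant signature can be disentangled
#' downstream.
#'
#' @param design a [SimDesign-class] (its `accelFactor` slot maps
#'   chronological to effective age).
#' @param truth the [SimTruth-class] from [simulateControlTimecourse()].
#' @param chronAge chronological age in days of the mutant samples.
#' @param nReps number of replicates (default `design@repsPerCell`).
#' @param genotype,tissue annotations for the sample metadata.
#' @param applyMutantOffsets apply the mutant-specific shifts (default TRUE).
#' @return A [PhysioExperiment-class] of mutant samples.
#' @export
simulateMutantSamples <- function(design, truth, chronAge,
                                  nReps = design@repsPerCell,
                                  genotype = "mutant", tissue = "head",
                                  applyMutantOffsets = TRUE) {
  methods::validObject(design)
  set.seed(childSeed(design@seed, paste0("mutant_", genotype, "_", chronAge)))
  probes <- names(truth@slopes)
  effAge <- design@accelFactor * chronAge
  mu <- truth@baseline + truth@slopes * effAge
  if (applyMutantOffsets && length(truth@mutantSpecificIds))
    mu[truth@mutantSpecificIds] <- mu[truth@mutantSpecificIds] +
      truth@mutantOffsets
  ids <- sprintf("%s_%s_d%g_r%d", genotype, tissue, chronAge, seq_len(nReps))
  values <- matrix(mu, nrow = length(probes), ncol = nReps) +
    stats::rnorm(length(probes) * nReps, 0, design@noiseSd)
  dimnames(values) <- list(probes, ids)
  meta <- data.frame(sample_id = ids, tissue = tissue, genotype = genotype,
                     age_days = chronAge, batch = "b1", is_tech_rep = FALSE)
  PhysioExperiment(values, meta)
}

#' Split samples into two hybridization batches with a shared technical
#' replicate
#'
#' Applies per-probe offsets to the designated batch-2 columns and duplicates
#' one batch-1 sample into batch 2 (offset plus technical noise only), the
#' design used to estimate and remove batch effects downstream.
#'
#' @param pe a [PhysioExperiment-class].
#' @param design the [SimDesign-class] (supplies `batchOffsetSd` and the
#'   seed).
#' @param batch2Samples sample ids assigned to batch 2; empty means a
#'   single-batch design and `pe` is returned unchanged.
#' @param techRepSample batch-1 sample duplicated into batch 2 as the common
#'   technical replicate (default: first batch-1 sample). Must not itself be
#'   in `batch2Samples`.
#' @param techNoiseSd SD of the technical (re-hybridization) noise on the
#'   duplicated column; technical replicates are much less variable than
#'   biological ones.
#' @param truth optional [SimTruth-class]; if given, an updated copy with the
#'   drawn `batchOffsets` is returned.
#' @return A list with `pe` (with batch annotations and the duplicated
#'   technical replicate, id suffixed `_b2`), `batchOffsets`, and `truth`
#'   (possibly updated).
#' @export
assignBatches <- function(pe, design, batch2Samples,
                          techRepSample = NULL, techNoiseSd = 0.05,
                          truth = NULL) {
  if (length(batch2Samples) == 0)
    return(list(pe = pe, batchOffsets = numeric(0), truth = truth))
  stopifnot(all(batch2Samples %in% colnames(pe)))
  batch1 <- setdiff(colnames(pe), batch2Samples)
  if (is.null(techRepSample)) techRepSample <- batch1[1]
  if (!techRepSample %in% batch1)
    stop("technical replicate must be a batch-1 sample")
  set.seed(childSeed(design@seed, "batches"))
  values <- exprsMatrix(pe)
  offsets <- stats::rnorm(nrow(values), 0, design@batchOffsetSd)
  names(offsets) <- rownames(values)

  values[, batch2Samples] <- values[, batch2Samples] + offsets
  techCol <- values[, techRepSample] + offsets +
    stats::rnorm(nrow(values), 0, techNoiseSd)
  values <- cbind(values, techCol)
  colnames(values)[ncol(values)] <- paste0(techRepSample, "_b2")

  meta <- as.data.frame(colData(pe))
  meta$sample_id <- colnames(pe)
  meta$batch <- ifelse(meta$sample_id %in% batch2Samples, "b2", "b1")
  meta$is_tech_rep <- meta$sample_id == techRepSample
  techMeta <- meta[meta$sample_id == techRepSample, , drop = FALSE]
  techMeta$sample_id <- paste0(techRepSample, "_b2")
  techMeta$batch <- "b2"
  meta <- rbind(meta, techMeta)

  if (!is.null(truth)) truth@batchOffsets <- offsets
  list(pe = PhysioExperiment(values, meta), batchOffsets = offsets,
       truth = truth)
}
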
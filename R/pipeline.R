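# End-to-end orchestration over synthetic data: simulate -> batches ->
# preprocess -> aging -> differential expression -> clock -> similarity ->
# summary. All randomness derives from one seed via childSeed().

#' Run the full physiological-age pipeline on a synthetic experiment
#'
#' Generates a control time course and day-`mutantAge` mutant samples from
#' `design`, splits the mutants into a second hybridization batch sharing a
#' technical replicate with batch 1, corrects and normalizes the matrix,
#' applies the noise floor, selects aging-related probes on the controls,
#' calls mutant-affected probes, selects classifiers and fits the age clock
#' on the controls, predicts physiological ages for all samples, and runs the
#' profile-similarity stage over the aging-by-affected probe intersection.
#'
#' @param design a [SimDesign-class]; its `accelFactor` drives the mutant
#'   effective age and `floorTrue` the default noise-floor override.
#' @param mutantAge chronological age (days) of the mutant samples.
#' @param B permutation rounds for the aging null.
#' @param k neighbour count for the LOO classifier selection.
#' @param fdr,tukeyAlpha,foldChange differential-expression thresholds.
#' @param floorOverride noise floor (log2); `NULL` fits it by lowess.
#' @param seed master seed; fanned out to per-stage child seeds.
#' @param outDir optional directory; per-stage TSV/CSV/JSON artifacts and a
#'   `summary.json` are written when given.
#' @return A list with the per-stage objects (`pe`, `truth`, `agingTable`,
#'   `de`, `classifiers`, `clock`, `predictions`, `acceleration`,
#'   `similarity`) and a plain-list `summary` (counts, overlap statistics,
#'   per-group physiological ages, seed and configuration).
#' @export
runPipeline <- function(design = simDesign(), mutantAge = 10, B = 20L,
                        k = 3L, fdr = 0.05, tukeyAlpha = 0.05,
                        foldChange = 1.5, floorOverride = design@floorTrue,
                        seed = design@seed, outDir = NULL) {
  design@seed <- as.integer(childSeed(seed, "simulate"))
  sim <- simulateControlTimecourse(design)
  mut <- simulateMutantSamples(design, sim$truth, chronAge = mutantAge)
  combined <- PhysioExperiment(
    cbind(exprsMatrix(sim$pe), exprsMatrix(mut)),
    rbind(cbind(sample_id = colnames(sim$pe),
                as.data.frame(colData(sim$pe))),
          cbind(sample_id = colnames(mut), as.data.frame(colData(mut)))))

  ba <- assignBatches(combined, design, batch2Samples = colnames(mut),
                      truth = sim$truth)
  pe <- subtractBatchBaseline(ba$pe)
  pe <- quantileNormalize(pe)
  floor <- fitNoiseFloor(pe, override = floorOverride)
  pe <- applyNoiseFloor(pe, floor)

  isControl <- colData(pe)$genotype == "control"
  controls <- pe[, isControl]
  null <- buildPermNull(controls, B = B, seed = childSeed(seed, "aging"))
  agingTable <- selectAgingGenes(controls, null = null)

  deContrast <- paste0("mutant_", mutantAge, ".vs.control_", mutantAge)
  de <- callAffected(pe, contrasts = list(c(paste0("mutant_", mutantAge),
                                            paste0("control_", mutantAge))),
                     fdr = fdr, tukeyAlpha = tukeyAlpha,
                     foldChange = foldChange)

  classifiers <- looKnnSelect(controls, k = k, fdr = fdr,
                              tukeyAlpha = tukeyAlpha,
                              foldChange = foldChange)
  nClassifiers <- sum(classifiers$is_classifier)
  if (nClassifiers < 2)
    stop("pipeline stage 'clock': fewer than 2 classifier probes selected")
  clock <- fitAgeClock(controls, classifiers)
  preds <- predictPhysioAge(clock, pe)
  groups <- interaction(colData(pe)$genotype, colData(pe)$age_days,
                        sep = "_d", drop = TRUE)
  accel <- summarizeAcceleration(preds, groups)

  simres <- tryCatch({
    probeSet <- intersectProbeSet(agingTable, de, contrast = deContrast)
    profileCorrelations(pe, probeSet,
                        mutantSamples = colnames(pe)[!isControl],
                        controlSamples = colnames(pe)[isControl])
  }, error = function(e) {
    warning("similarity stage skipped: ", conditionMessage(e))
    NULL
  })

  ov <- overlapTest(agingProbes(agingTable),
                    affectedProbes(de, deContrast), nrow(pe))
  summary <- list(
    seed = seed,
    config = list(nProbes = design@nProbes, ages = design@ages,
                  repsPerCell = design@repsPerCell,
                  accelFactor = design@accelFactor, mutantAge = mutantAge,
                  B = B, k = k, fdr = fdr, foldChange = foldChange,
                  floor = floor@floorValue),
    preprocess = list(nProbesRemoved = S4Vectors::metadata(pe)$nProbesRemoved,
                      nProbesKept = nrow(pe)),
    aging = list(nAging = sum(agingTable$is_aging),
                 nullBand = c(null@lo, null@hi)),
    diffexpr = list(contrast = deContrast,
                    nAffected = length(affectedProbes(de, deContrast))),
    overlap = ov[c("nUniverse", "nA", "nB", "nAB", "chi2Yates", "pValue")],
    clock = list(nClassifiers = nClassifiers,
                 looAccuracy = S4Vectors::metadata(classifiers)$looAccuracy,
                 selectedPcs = clock@selectedPcs),
    acceleration = accel$summary,
    similarity = if (is.null(simres)) NULL else simres@perAge)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeExpression(pe, file.path(outDir, "normalized.tsv"))
    writeSampleMeta(pe, file.path(outDir, "meta.csv"))
    utils::write.table(as.data.frame(agingTable),
                       file.path(outDir, "aging_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(de), file.path(outDir, "de.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeAgeClock(clock, file.path(outDir, "clock.json"))
    utils::write.table(as.data.frame(preds),
                       file.path(outDir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }

  list(pe = pe, truth = ba$truth, agingTable = agingTable, de = de,
       classifiers = classifiers, clock = clock, predictions = preds,
       acceleration = accel, similarity = simres, summary = summary)
}
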
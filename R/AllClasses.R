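#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

.requiredMetaCols <- c("tissue", "genotype", "age_days", "batch", "is_tech_rep")

#' Expression experiment container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' probe x sample matrix of log2 expression values in the `"exprs"` assay,
#' with the sample annotations the pipeline needs (`tissue`, `genotype`,
#' `age_days`, `batch`, `is_tech_rep`) as `colData` columns.
#'
#' @export
setClass("PhysioExperiment", contains = "SummarizedExperiment")

setValidity("PhysioExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "'exprs' must be numeric")
    if (anyNA(v)) msg <- c(msg, "'exprs' must not contain missing values")
  }
  missingCols <- setdiff(.requiredMetaCols, colnames(colData(object)))
  if (length(missingCols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missingCols, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PhysioExperiment
#'
#' @param values numeric probe x sample matrix of log2 expression, with probe
#'   ids as rownames and sample ids as colnames.
#' @param meta `data.frame` (or `DataFrame`) of sample annotations, one row per
#'   column of `values`, containing at least `tissue`, `genotype`, `age_days`,
#'   `batch` and `is_tech_rep`. A `sample_id` column, if present, is used to
#'   align rows to matrix columns; otherwise rownames are used.
#' @return A [PhysioExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 9), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4), tissue = "head",
#'                    genotype = "control", age_days = c(3, 3, 10, 10),
#'                    batch = "b1", is_tech_rep = FALSE)
#' pe <- PhysioExperiment(m, meta)
#' @export
PhysioExperiment <- function(values, meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe ids as rownames and sample ids as colnames")
  meta <- as.data.frame(meta)
  ids <- if ("sample_id" %in% colnames(meta)) as.character(meta$sample_id)
         else rownames(meta)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sample metadata must carry unique sample ids")
  if (!setequal(ids, colnames(values)))
    stop("sample ids in metadata do not match matrix columns")
  meta <- meta[match(colnames(values), ids), , drop = FALSE]
  rownames(meta) <- colnames(values)
  meta$sample_id <- NULL
  se <- SummarizedExperiment(assays = list(exprs = values),
                             colData = S4Vectors::DataFrame(meta))
  methods::new("PhysioExperiment", se)
}

#' Extract the log2 expression matrix
#' @param pe a [PhysioExperiment-class].
#' @return numeric probe x sample matrix.
#' @export
exprsMatrix <- function(pe) SummarizedExperiment::assay(pe, "exprs")

setMethod("show", "PhysioExperiment", function(object) {
  cd <- colData(object)
  cat("PhysioExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  tissues:  ", paste(unique(cd$tissue), collapse = ", "), "\n")
  cat("  genotypes:", paste(unique(cd$genotype), collapse = ", "), "\n")
  cat("  ages (d): ", paste(sort(unique(cd$age_days)), collapse = ", "), "\n")
  cat("  batches:  ", paste(unique(cd$batch), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------

#' Simulation design
#'
#' Parameters of the synthetic expression time course. Defaults mirror the
#' study design the package targets: ages 3/10/30/45 days, five replicates per
#' (genotype, age) cell, a fifth of probes carrying monotone (linear on log2)
#' age trends with balanced directions, homoscedastic Gaussian noise, a
#' detection floor near 7.5 log2 units and a multiplicative aging-acceleration
#' factor for mutants.
#'
#' @slot nProbes number of probes.
#' @slot fracAging fraction of probes with true age trends.
#' @slot ages age classes in days, strictly increasing.
#' @slot repsPerCell replicates per (genotype, age) cell.
#' @slot slopeSd SD of per-gene log2-per-day slope magnitudes.
#' @slot slopeValue optional fixed |slope| (log2/day); `NA` draws from
#'   `N(0, slopeSd)` magnitudes.
#' @slot noiseSd residual log2 SD.
#' @slot batchOffsetSd SD of per-probe batch-2 offsets.
#' @slot floorTrue latent detection floor (log2 units).
#' @slot accelFactor multiplicative factor mapping chronological to effective
#'   age for mutants.
#' @slot nMutantSpecific number of non-aging mutant-affected probes.
#' @slot mutantShift log2 magnitude of mutant-specific shifts (>= log2(1.5)).
#' @slot dropFirstAgeRep drop one replicate from the first age class (mirrors
#'   the removed outlier sample in the head design).
#' @slot seed integer seed.
#' @export
setClass("SimDesign", representation(
  nProbes = "integer", fracAging = "numeric", ages = "numeric",
  repsPerCell = "integer", slopeSd = "numeric", slopeValue = "numeric",
  noiseSd = "numeric", batchOffsetSd = "numeric", floorTrue = "numeric",
  accelFactor = "numeric", nMutantSpecific = "integer",
  mutantShift = "numeric", dropFirstAgeRep = "logical", seed = "integer"))

setValidity("SimDesign", function(object) {
  msg <- character()
  if (object@nProbes < 1) msg <- c(msg, "nProbes must be positive")
  if (object@fracAging < 0 || object@fracAging > 1)
    msg <- c(msg, "fracAging must be in [0, 1]")
  if (length(object@ages) < 2 || any(diff(object@ages) <= 0) ||
      any(object@ages <= 0))
    msg <- c(msg, "ages must be strictly increasing and positive")
  if (object@repsPerCell < 2)
    msg <- c(msg, "repsPerCell must be >= 2 (variance undefined downstream)")
  if (object@accelFactor <= 0) msg <- c(msg, "accelFactor must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@nMutantSpecific < 0)
    msg <- c(msg, "nMutantSpecific must be non-negative")
  if (!is.na(object@mutantShift) && object@mutantShift < log2(1.5))
    msg <- c(msg, "mutantShift must be >= log2(1.5) to be discoverable")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimDesign constructor with study-design defaults.
#' @param nProbes,fracAging,ages,repsPerCell,slopeSd,slopeValue,noiseSd
#'   see slots.
#' @param batchOffsetSd,floorTrue,accelFactor,nMutantSpecific,mutantShift
#'   see slots.
#' @param dropFirstAgeRep,seed see slots.
#' @export
simDesign <- function(nProbes = 2000L, fracAging = 0.2,
                      ages = c(3, 10, 30, 45), repsPerCell = 5L,
                      slopeSd = 0.05, slopeValue = NA_real_, noiseSd = 0.25,
                      batchOffsetSd = 0.3, floorTrue = 7.5, accelFactor = 1,
                      nMutantSpecific = 50L, mutantShift = 1.0,
                      dropFirstAgeRep = FALSE, seed = 1L) {
  methods::new("SimDesign", nProbes = as.integer(nProbes),
               fracAging = fracAging, ages = as.numeric(ages),
               repsPerCell = as.integer(repsPerCell), slopeSd = slopeSd,
               slopeValue = slopeValue, noiseSd = noiseSd,
               batchOffsetSd = batchOffsetSd, floorTrue = floorTrue,
               accelFactor = accelFactor,
               nMutantSpecific = as.integer(nMutantSpecific),
               mutantShift = mutantShift, dropFirstAgeRep = dropFirstAgeRep,
               seed = as.integer(seed))
}

setMethod("show", "SimDesign", function(object) {
  cat("SimDesign:", object@nProbes, "probes,",
      round(object@fracAging * object@nProbes), "aging; ages",
      paste(object@ages, collapse = "/"), "d x", object@repsPerCell,
      "reps\n  slope",
      if (is.na(object@slopeValue)) paste0("~N(0,", object@slopeSd, ")")
      else paste0("+/-", object@slopeValue),
      "log2/d; noise SD", object@noiseSd, "; accel", object@accelFactor,
      "; seed", object@seed, "\n")
})

#' Ground truth of a simulated experiment
#'
#' @slot agingProbeIds probes carrying true age trends.
#' @slot slopes named per-probe log2/day slopes (zero off the aging set).
#' @slot baseline named per-probe intercepts (expression at age 0).
#' @slot mutantSpecificIds non-aging probes shifted in mutants.
#' @slot mutantOffsets named log2 shifts for `mutantSpecificIds`.
#' @slot batchOffsets named per-probe batch-2 offsets (filled by
#'   [assignBatches()]).
#' @export
setClass("SimTruth", representation(
  agingProbeIds = "character", slopes = "numeric", baseline = "numeric",
  mutantSpecificIds = "character", mutantOffsets = "numeric",
  batchOffsets = "numeric"))

setValidity("SimTruth", function(object) {
  if (length(intersect(object@agingProbeIds, object@mutantSpecificIds)))
    "agingProbeIds and mutantSpecificIds must be disjoint" else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@slopes), "probes;",
      length(object@agingProbeIds), "aging,",
      length(object@mutantSpecificIds), "mutant-specific;",
      if (length(object@batchOffsets)) "batch offsets set\n"
      else "no batch offsets\n")
})

# ---------------------------------------------------------------------------

#' Permutation null for polyserial aging-gene selection
#'
#' Summary of polyserial correlation estimates obtained after randomizing the
#' age labels: estimates are pooled over all probes and permutation rounds and
#' the selection band is `nullMean` +/- 2 `nullSd`.
#'
#' @slot B number of label randomizations.
#' @slot nullMean,nullSd mean and SD of pooled null estimates.
#' @slot lo,hi two-standard-deviation selection cutoffs.
#' @slot nEstimates number of pooled null estimates.
#' @slot seed integer seed used for the permutations.
#' @export
setClass("PermNull", representation(
  B = "integer", nullMean = "numeric", nullSd = "numeric",
  lo = "numeric", hi = "numeric", nEstimates = "integer", seed = "integer"))

setValidity("PermNull", function(object) {
  if (object@lo >= object@hi) "lo must be < hi" else TRUE
})

setMethod("show", "PermNull", function(object) {
  cat(sprintf(
    "PermNull: B=%d (%d pooled estimates), mean=%.4f, sd=%.4f, band=[%.4f, %.4f]\n",
    object@B, object@nEstimates, object@nullMean, object@nullSd,
    object@lo, object@hi))
})

#' Noise-floor estimate
#'
#' @slot floorValue log2 expression value below which signal is treated as
#'   indistinguishable from noise.
#' @slot method `"fixed"` (user override) or `"lowess"` (fitted).
#' @slot diagnostics per-probe mean, CV and lowess fit used for the call.
#' @export
setClass("NoiseFloor", representation(
  floorValue = "numeric", method = "character", diagnostics = "data.frame"))

setValidity("NoiseFloor", function(object) {
  msg <- character()
  if (!object@method %in% c("fixed", "lowess"))
    msg <- c(msg, "method must be 'fixed' or 'lowess'")
  if (nrow(object@diagnostics) &&
      (object@floorValue < min(object@diagnostics$mean) - 1e-8 ||
       object@floorValue > max(object@diagnostics$mean) + 1e-8))
    msg <- c(msg, "floorValue outside the observed expression range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NoiseFloor", function(object) {
  cat(sprintf("NoiseFloor: %.3f log2 units (method=%s, %d probes)\n",
              object@floorValue, object@method, nrow(object@diagnostics)))
})

# ---------------------------------------------------------------------------

#' Transcriptomic age clock
#'
#' A linear model of chronological age (days) on principal components of
#' classifier-probe expression, fitted on control samples. Candidate
#' components are seeded from the PCA of the training matrix and retained by
#' forward stepwise AIC minimisation.
#'
#' @slot probeIds classifier probes, in training order.
#' @slot center per-probe training means used for centering.
#' @slot loadings probe x candidate-PC loading matrix.
#' @slot candidatePcs number of candidate components offered to the stepwise
#'   search.
#' @slot selectedPcs indices of components retained by AIC.
#' @slot coefficients intercept followed by per-selected-PC weights.
#' @slot aicTrace AIC after each accepted stepwise move (first entry:
#'   intercept-only model).
#' @slot trainingIds,trainingAges training sample ids and their ages.
#' @export
setClass("AgeClock", representation(
  probeIds = "character", center = "numeric", loadings = "matrix",
  candidatePcs = "integer", selectedPcs = "integer", coefficients = "numeric",
  aicTrace = "numeric", trainingIds = "character", trainingAges = "numeric"))

setValidity("AgeClock", function(object) {
  msg <- character()
  if (!all(object@selectedPcs %in% seq_len(object@candidatePcs)))
    msg <- c(msg, "selectedPcs must be a subset of the candidate PCs")
  if (!all(is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (length(object@coefficients) != length(object@selectedPcs) + 1L)
    msg <- c(msg, "coefficients must be intercept + one weight per selected PC")
  if (length(object@center) != length(object@probeIds))
    msg <- c(msg, "center must align with probeIds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AgeClock", function(object) {
  cat("AgeClock:", length(object@probeIds), "classifier probes;",
      object@candidatePcs, "candidate PCs,",
      length(object@selectedPcs), "selected (",
      paste(object@selectedPcs, collapse = ","), ")\n")
  cat(sprintf("  trained on %d samples, ages %s d; final AIC %.2f\n",
              length(object@trainingIds),
              paste(sort(unique(object@trainingAges)), collapse = "/"),
              utils::tail(object@aicTrace, 1)))
})

#' Profile-similarity result
#'
#' Pearson correlations of each mutant sample with each control sample over a
#' shared probe set, grouped by control age.
#'
#' @slot probeSet probe ids the correlations were computed over.
#' @slot pairs one row per (mutant, control) pair with the control age and r.
#' @slot perAge per-control-age mean, SEM and pair count.
#' @slot anovaP one-way ANOVA p-value of r across control ages (NA if not
#'   estimable).
#' @slot tukey pairwise Tukey-HSD table across control ages.
#' @export
setClass("SimilarityResult", representation(
  probeSet = "character", pairs = "data.frame", perAge = "data.frame",
  anovaP = "numeric", tukey = "data.frame"))

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult:", nrow(object@pairs), "pairs over",
      length(object@probeSet), "probes\n")
  df <- object@perAge
  for (i in seq_len(nrow(df)))
    cat(sprintf("  control age %g d: r = %.3f +/- %.3f (n=%d)\n",
                df$control_age[i], df$mean_r[i], df$sem_r[i], df$n_pairs[i]))
  if (is.finite(object@anovaP))
    cat(sprintf("  ANOVA across ages: p = %.3g\n", object@anovaP))
})
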
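# Cross-batch baseline correction, quantile normalization and noise-floor
# filtering. Order of operations follows standard microarray practice:
# baseline subtraction (per-probe, anchored on the shared technical
# replicate), then joint quantile normalization over all samples, then
# low-end filtering.

#' Remove cross-batch baseline differences using the common technical
#' replicate
#'
#' For every non-reference batch, the per-probe offset is estimated as the
#' difference between that batch's technical-replicate column and the
#' reference batch's technical-replicate column, and subtracted from every
#' column of the batch. The redundant non-reference technical-replicate
#' columns (identical to the reference copy after correction, up to machine
#' precision) are then dropped.
#'
#' @param pe a [PhysioExperiment-class] whose `colData` marks the shared
#'   technical replicate (`is_tech_rep`) in every batch.
#' @param referenceBatch batch whose scale is kept (default: batch of the
#'   first sample, conventionally the one holding the control time course).
#' @return A corrected [PhysioExperiment-class]; per-batch offsets are stored
#'   in `metadata(pe)$batchBaselineOffsets`.
#' @export
subtractBatchBaseline <- function(pe, referenceBatch = NULL) {
  meta <- colData(pe)
  batches <- unique(as.character(meta$batch))
  if (length(batches) < 2) return(pe)
  if (is.null(referenceBatch)) referenceBatch <- as.character(meta$batch[1])
  if (!referenceBatch %in% batches)
    stop("reference batch '", referenceBatch, "' not present")
  techRepOf <- function(b) {
    idx <- which(meta$batch == b & meta$is_tech_rep)
    if (length(idx) == 0)
      stop("no technical replicate in batch '", b, "'")
    idx[1]
  }
  values <- exprsMatrix(pe)
  refCol <- values[, techRepOf(referenceBatch)]
  dropCols <- character(0)
  offsets <- list()
  for (b in setdiff(batches, referenceBatch)) {
    iTech <- techRepOf(b)
    delta <- values[, iTech] - refCol
    inBatch <- which(as.character(meta$batch) == b)
    values[, inBatch] <- values[, inBatch] - delta
    offsets[[b]] <- delta
    dropCols <- c(dropCols, colnames(pe)[iTech])
  }
  keep <- setdiff(colnames(pe), dropCols)
  metaOut <- as.data.frame(meta[keep, , drop = FALSE])
  metaOut$sample_id <- keep
  out <- PhysioExperiment(values[, keep, drop = FALSE], metaOut)
  S4Vectors::metadata(out)$batchBaselineOffsets <- offsets
  out
}

#' Quantile-normalize an expression matrix
#'
#' Every column is mapped onto the common distribution given by the row-wise
#' mean of per-column sorted values; within-column ranks are preserved and
#' tied values receive the mean of the normalized values at their rank
#' positions. The transform is idempotent.
#'
#' @param pe a [PhysioExperiment-class] or a numeric matrix with at least two
#'   columns.
#' @return An object of the same type as the input.
#' @export
quantileNormalize <- function(pe) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (ncol(values) < 2) stop("quantile normalization needs >= 2 samples")
  normed <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(normed) <- dimnames(values)
  if (methods::is(pe, "SummarizedExperiment")) {
    SummarizedExperiment::assay(pe, "exprs") <- normed
    pe
  } else normed
}

#' Estimate the low-end noise floor from the CV-versus-mean relationship
#'
#' Computes, per probe, the mean and coefficient of variation (SD/mean of the
#' log2 values) across samples, smooths CV against mean with lowess, anchors a
#' straight line on the upper half of the mean range (where signal dominates),
#' and reports the largest mean in the lower half at which the lowess curve
#' deviates from that line by more than `tolFactor` times the residual SD of
#' the high-end fit. A flat CV-mean relationship yields the minimum observed
#' mean (nothing to censor).
#'
#' @param pe a [PhysioExperiment-class] or numeric matrix (>= 10 probes).
#' @param override optional fixed floor (log2 units); returned as-is with
#'   `method = "fixed"`, diagnostics still populated.
#' @param span lowess smoother span.
#' @param tolFactor deviation tolerance in units of the high-end residual SD.
#' @return A [NoiseFloor-class].
#' @export
fitNoiseFloor <- function(pe, override = NULL, span = 0.3, tolFactor = 2) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (nrow(values) < 10) stop("noise-floor fitting needs >= 10 probes")
  m <- rowMeans(values)
  s <- .rowSds(values)
  if (max(m) - min(m) < 1e-10 || all(s < 1e-12))
    stop("degenerate (constant) expression matrix")
  cv <- s / m
  lo <- stats::lowess(m, cv, f = span)
  diag <- data.frame(mean = lo$x, cv = cv[order(m)], lowess = lo$y)
  if (!is.null(override)) {
    return(methods::new("NoiseFloor", floorValue = override,
                        method = "fixed", diagnostics = diag))
  }
  mid <- min(m) + 0.5 * (max(m) - min(m))
  high <- lo$x >= mid
  # the line is anchored on the raw high-end (mean, CV) points so that tol
  # reflects the sampling scatter of per-probe CV estimates, not the (much
  # smaller) roughness of the smooth itself
  fit <- stats::lm(y ~ x, data = data.frame(x = m[m >= mid], y = cv[m >= mid]))
  tol <- tolFactor * stats::sd(stats::residuals(fit))
  pred <- stats::predict(fit, newdata = data.frame(x = lo$x))
  dev <- abs(lo$y - pred)
  cand <- which(dev > tol & !high)
  floorValue <- if (length(cand)) max(lo$x[cand]) else min(m)
  methods::new("NoiseFloor", floorValue = floorValue, method = "lowess",
               diagnostics = diag)
}

#' Clamp values to the noise floor and drop uninformative probes
#'
#' Values below the floor are set to the floor; probes with no sample above
#' the floor are discarded as non-informative.
#'
#' @param pe a [PhysioExperiment-class].
#' @param floor a [NoiseFloor-class] or a numeric floor value.
#' @return A filtered [PhysioExperiment-class]; the ids and count of removed
#'   probes are stored in `metadata()$probesRemoved` /
#'   `metadata()$nProbesRemoved`.
#' @export
applyNoiseFloor <- function(pe, floor) {
  f <- if (methods::is(floor, "NoiseFloor")) floor@floorValue else floor
  values <- exprsMatrix(pe)
  keep <- apply(values, 1, max) > f
  removed <- rownames(values)[!keep]
  pe <- pe[keep, ]
  values <- values[keep, , drop = FALSE]
  values[values < f] <- f
  SummarizedExperiment::assay(pe, "exprs") <- values
  S4Vectors::metadata(pe)$probesRemoved <- removed
  S4Vectors::metadata(pe)$nProbesRemoved <- length(removed)
  pe
}

#' Drop samples by id
#'
#' Cohort-level outlier samples (identified by inspection of box plots or
#' PCA, not algorithmically) are excluded via an explicit list.
#'
#' @param pe a [PhysioExperiment-class].
#' @param exclude character sample ids to drop.
#' @return The [PhysioExperiment-class] without the excluded samples.
#' @export
excludeSamples <- function(pe, exclude) {
  unknown <- setdiff(exclude, colnames(pe))
  if (length(unknown))
    warning("unknown sample id(s): ", paste(unknown, collapse = ", "))
  pe[, setdiff(colnames(pe), exclude)]
}
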
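# Plain-text interchange: expression as TSV (probes x samples), sample
# metadata as CSV, models and summaries as JSON.

#' Read a probe x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids.
#' Ragged rows, duplicate ids and non-numeric cells are parse errors that
#' name the offending row/column.
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- length(fields[[1]])
  bad <- which(lengths(fields) != nc)
  if (length(bad))
    stop("ragged row at line ", bad[1], ": expected ", nc, " fields, got ",
         lengths(fields)[bad[1]])
  sampleIds <- fields[[1]][-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id: ", sampleIds[duplicated(sampleIds)][1])
  probeIds <- vapply(fields[-1], `[`, character(1), 1)
  if (anyDuplicated(probeIds))
    stop("duplicate probe id: ", probeIds[duplicated(probeIds)][1])
  values <- matrix(NA_real_, length(probeIds), length(sampleIds),
                   dimnames = list(probeIds, sampleIds))
  for (i in seq_along(probeIds)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric or missing cell at line ", i + 1, ", column ", j + 1,
           " (probe ", probeIds[i], ", sample ", sampleIds[j], ")")
    }
    values[i, ] <- v
  }
  values
}

#' Write a probe x sample expression matrix as TSV
#'
#' @param values numeric matrix (or [PhysioExperiment-class]).
#' @param path output path.
#' @param digits significant digits (default 15: read/write round-trips are
#'   value-identical to near machine precision).
#' @export
writeExpression <- function(values, path, digits = 15) {
  if (methods::is(values, "SummarizedExperiment"))
    values <- exprsMatrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1, function(r)
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns `sample_id`, `tissue`, `genotype`,
#'   `age_days`, `batch`, `is_tech_rep`.
#' @return `data.frame` of sample annotations.
#' @export
readSampleMeta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", .requiredMetaCols)
  missing <- setdiff(need, colnames(meta))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  meta$is_tech_rep <- as.logical(meta$is_tech_rep)
  meta
}

#' Write sample metadata as CSV
#' @param pe a [PhysioExperiment-class] or a metadata `data.frame`.
#' @param path output path.
#' @export
writeSampleMeta <- function(pe, path) {
  meta <- if (methods::is(pe, "SummarizedExperiment")) {
    df <- as.data.frame(colData(pe))
    cbind(sample_id = colnames(pe), df)
  } else pe
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an expression matrix and metadata into a PhysioExperiment
#' @param exprPath expression TSV path (see [readExpression()]).
#' @param metaPath metadata CSV path (see [readSampleMeta()]).
#' @return A [PhysioExperiment-class].
#' @export
readPhysioExperiment <- function(exprPath, metaPath) {
  PhysioExperiment(readExpression(exprPath), readSampleMeta(metaPath))
}

#' Serialize an age clock to JSON
#' @param clock an [AgeClock-class].
#' @param path output path.
#' @export
writeAgeClock <- function(clock, path) {
  obj <- list(probe_ids = clock@probeIds, center = clock@center,
              loadings = clock@loadings, candidate_pcs = clock@candidatePcs,
              selected_pcs = clock@selectedPcs,
              coefficients = clock@coefficients, aic_trace = clock@aicTrace,
              training_ids = clock@trainingIds,
              training_ages = clock@trainingAges)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an age clock from JSON
#' @param path path written by [writeAgeClock()].
#' @return An [AgeClock-class].
#' @export
readAgeClock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- as.matrix(obj$loadings)
  rownames(loadings) <- obj$probe_ids
  methods::new("AgeClock", probeIds = as.character(obj$probe_ids),
               center = stats::setNames(as.numeric(obj$center), obj$probe_ids),
               loadings = loadings,
               candidatePcs = as.integer(obj$candidate_pcs),
               selectedPcs = as.integer(obj$selected_pcs),
               coefficients = as.numeric(obj$coefficients),
               aicTrace = as.numeric(obj$aic_trace),
               trainingIds = as.character(obj$training_ids),
               trainingAges = as.numeric(obj$training_ages))
}
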
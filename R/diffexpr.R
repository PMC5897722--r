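# Per-probe one-way ANOVA (vectorised), BH correction, Tukey-HSD post hoc
# tests with gatekeeping, fold-change rule, and the probe-set overlap /
# concordance / rescue statistics.

# Vectorised one-way ANOVA over matrix rows. Returns F and p plus the group
# means and mean-square-within needed for Tukey-Kramer contrasts.
.rowAnova <- function(values, classes) {
  g <- droplevels(factor(classes))
  k <- nlevels(g)
  n <- ncol(values)
  counts <- as.vector(table(g))
  if (k < 2) stop("need >= 2 sample classes")
  if (any(counts < 2)) stop("class(es) with < 2 replicates: ",
                            paste(levels(g)[counts < 2], collapse = ", "))
  groupMeans <- vapply(levels(g), function(l)
    rowMeans(values[, g == l, drop = FALSE]), numeric(nrow(values)))
  grand <- rowMeans(values)
  ssb <- as.vector((groupMeans - grand)^2 %*% counts)
  sst <- rowSums((values - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msw <- unname(ssw / (n - k))
  f <- unname(ssb / (k - 1)) / msw
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(F = f, p = p, groupMeans = groupMeans, msw = msw,
       counts = stats::setNames(counts, levels(g)), df = n - k, k = k)
}

# Tukey-Kramer p-value for one pairwise contrast, given the row ANOVA
# pieces; `rows` restricts evaluation (ptukey is expensive)
.tukeyP <- function(an, a, b, rows = seq_along(an$msw)) {
  se <- sqrt(an$msw[rows] / 2 * (1 / an$counts[a] + 1 / an$counts[b]))
  q <- abs(an$groupMeans[rows, a] - an$groupMeans[rows, b]) / se
  stats::ptukey(q, nmeans = an$k, df = an$df, lower.tail = FALSE)
}

.contrastName <- function(ct) paste0(ct[1], ".vs.", ct[2])

#' Call probes affected between sample classes
#'
#' Per-probe one-way ANOVA with sample class as the factor, Benjamini-
#' Hochberg correction across probes, and Tukey-HSD post hoc tests for the
#' requested pairwise contrasts. Post hoc tests are gatekept: probes failing
#' the corrected ANOVA threshold are not Tukey-tested (their post hoc values
#' are `NA`). A probe is `affected` for a contrast when the corrected ANOVA
#' p < `fdr`, the Tukey p < `tukeyAlpha`, and the absolute difference of
#' class means is at least `log2(foldChange)` on the log2 scale.
#'
#' @param pe a [PhysioExperiment-class] or numeric matrix.
#' @param classes factor of sample classes; defaults to the
#'   genotype-by-age cell `interaction(genotype, age_days)` from `colData`.
#' @param contrasts list of length-2 character vectors `c(A, B)` of class
#'   levels; fold changes are `mean(A) - mean(B)` (mutant minus control by
#'   convention). Default: all pairwise contrasts.
#' @param fdr BH-corrected ANOVA threshold.
#' @param tukeyAlpha post hoc p-value threshold.
#' @param foldChange fold-change threshold on the natural scale.
#' @return A [S4Vectors::DataFrame] (`DEResult`) with `probe_id`, `anova_p`,
#'   `anova_q` and, per contrast `A.vs.B`, columns `tukey_p.A.vs.B`,
#'   `log2fc.A.vs.B` and `affected.A.vs.B`.
#' @export
callAffected <- function(pe, classes = NULL, contrasts = NULL, fdr = 0.05,
                         tukeyAlpha = 0.05, foldChange = 1.5) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(classes)) {
    cd <- colData(pe)
    classes <- interaction(cd$genotype, cd$age_days, sep = "_", drop = TRUE)
  }
  g <- droplevels(factor(classes))
  if (is.null(contrasts)) {
    contrasts <- utils::combn(levels(g), 2, simplify = FALSE)
  }
  bad <- !vapply(contrasts, function(ct)
    all(ct %in% levels(g)) && length(ct) == 2, logical(1))
  if (any(bad)) stop("contrast level(s) not among the sample classes")

  an <- .rowAnova(values, g)
  q <- stats::p.adjust(an$p, method = "BH")
  pass <- !is.na(q) & q < fdr
  lfcMin <- log2(foldChange)

  tab <- S4Vectors::DataFrame(probe_id = rownames(values),
                              anova_p = an$p, anova_q = q)
  for (ct in contrasts) {
    nm <- .contrastName(ct)
    tp <- rep(NA_real_, nrow(values))
    if (any(pass)) tp[pass] <- .tukeyP(an, ct[1], ct[2], rows = which(pass))
    lfc <- unname(an$groupMeans[, ct[1]] - an$groupMeans[, ct[2]])
    tab[[paste0("tukey_p.", nm)]] <- tp
    tab[[paste0("log2fc.", nm)]] <- lfc
    tab[[paste0("affected.", nm)]] <-
      pass & !is.na(tp) & tp < tukeyAlpha & abs(lfc) >= lfcMin
  }
  rownames(tab) <- rownames(values)
  S4Vectors::metadata(tab) <- list(classes = g, contrasts = contrasts,
                                   fdr = fdr, tukeyAlpha = tukeyAlpha,
                                   foldChange = foldChange)
  tab
}

#' Probes affected in at least one contrast
#' @param de a `DEResult` from [callAffected()].
#' @param contrast optional contrast name (`"A.vs.B"`); default any contrast.
#' @return Character vector of probe ids.
#' @export
affectedProbes <- function(de, contrast = NULL) {
  cols <- grep("^affected\\.", colnames(de), value = TRUE)
  if (!is.null(contrast)) {
    cols <- paste0("affected.", contrast)
    if (!cols %in% colnames(de)) stop("no such contrast: ", contrast)
  }
  flag <- Reduce(`|`, lapply(cols, function(cc) de[[cc]]))
  as.character(de$probe_id[flag])
}

#' Test the significance of an overlap between two probe sets
#'
#' Builds the 2x2 membership table (in/out of A by in/out of B) over a common
#' universe and applies the chi-square test with Yates' continuity
#' correction (1 df, two-sided).
#'
#' @param setA,setB character probe-id sets, subsets of the universe.
#' @param universe character vector of universe ids, or its size.
#' @return A list (`OverlapStats`) with `nUniverse`, `nA`, `nB`, `nAB`,
#'   `chi2Yates`, `pValue` and the underlying `table`.
#' @export
overlapTest <- function(setA, setB, universe) {
  nU <- if (is.numeric(universe) && length(universe) == 1) as.integer(universe)
        else length(unique(universe))
  if (nU < 1) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  nA <- length(setA); nB <- length(setB)
  if (nA > nU || nB > nU) stop("sets larger than the universe")
  nAB <- length(intersect(setA, setB))
  tab <- matrix(c(nAB, nA - nAB, nB - nAB, nU - nA - nB + nAB), nrow = 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  if (any(tab < 0)) stop("inconsistent set sizes for the given universe")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(nUniverse = nU, nA = nA, nB = nB, nAB = nAB,
       chi2Yates = unname(ct$statistic), pValue = unname(ct$p.value),
       table = tab)
}

#' Concordance of per-probe effect sizes between two conditions
#'
#' @param effectsA,effectsB named numeric vectors of per-probe log2 fold
#'   changes over a shared probe index (names are intersected).
#' @return A list with `r2` (squared Pearson correlation) and
#'   `pctConcordant` (percent of shared probes with matching fold-change
#'   sign), plus `n` shared probes.
#' @export
concordance <- function(effectsA, effectsB) {
  shared <- intersect(names(effectsA), names(effectsB))
  if (length(shared) < 3) stop("need >= 3 shared probes")
  a <- effectsA[shared]; b <- effectsB[shared]
  list(r2 = stats::cor(a, b)^2,
       pctConcordant = 100 * mean(sign(a) == sign(b)),
       n = length(shared))
}

#' Classify rescue of mutant-affected probes
#'
#' For each probe affected in the null-versus-control comparison: `full`
#' rescue when the probe is no longer affected in rescue-versus-control;
#' `partial` when it is still affected (>= 1.5-fold from control) but its
#' expression trended toward control (smaller |log2 fold change| with the
#' same sign, or a sign loss); `none` otherwise.
#'
#' @param deNull,deRescue `DEResult` tables from [callAffected()], both
#'   computed against the same control class.
#' @param contrastNull,contrastRescue contrast names (`"A.vs.B"`) in the
#'   respective tables.
#' @return A [S4Vectors::DataFrame] (`RescueCall`) over the null-affected
#'   probes with columns `probe_id`, `log2fc_null`, `log2fc_rescue` and
#'   `status`.
#' @export
classifyRescue <- function(deNull, deRescue, contrastNull, contrastRescue) {
  affN <- paste0("affected.", contrastNull)
  affR <- paste0("affected.", contrastRescue)
  if (!affN %in% colnames(deNull)) stop("no such contrast: ", contrastNull)
  if (!affR %in% colnames(deRescue)) stop("no such contrast: ", contrastRescue)
  ids <- as.character(deNull$probe_id[deNull[[affN]]])
  missing <- setdiff(ids, as.character(deRescue$probe_id))
  if (length(missing))
    warning(length(missing), " null-affected probe(s) absent from the rescue",
            " table; their status is 'none'")
  fcN <- stats::setNames(deNull[[paste0("log2fc.", contrastNull)]],
                         as.character(deNull$probe_id))[ids]
  idxR <- match(ids, as.character(deRescue$probe_id))
  fcR <- deRescue[[paste0("log2fc.", contrastRescue)]][idxR]
  affectedR <- deRescue[[affR]][idxR]
  trendToControl <- !is.na(fcR) &
    (abs(fcR) < abs(fcN) | sign(fcR) != sign(fcN))
  status <- rep("none", length(ids))
  status[!is.na(affectedR) & !affectedR] <- "full"
  status[!is.na(affectedR) & affectedR & trendToControl] <- "partial"
  status[is.na(affectedR)] <- "none"
  out <- S4Vectors::DataFrame(probe_id = ids, log2fc_null = unname(fcN),
                              log2fc_rescue = fcR, status = status)
  S4Vectors::metadata(out)$pctRescued <-
    if (length(ids)) 100 * mean(status %in% c("full", "partial")) else NA_real_
  out
}
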
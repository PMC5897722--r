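# The transcriptomic age clock: leave-one-out k-NN feature stability on
# control samples, a PC-seeded AIC-optimised linear model of age, and
# physiological-age / acceleration prediction.

# Deterministic k-NN: majority vote among the k nearest training columns
# (Euclidean distance), ties broken by the larger summed inverse distance,
# then by the single smallest distance.
.knnPredict <- function(train, labels, test, k = 3L) {
  d <- sqrt(colSums((train - test)^2))
  nn <- order(d)[seq_len(min(k, length(d)))]
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    w <- vapply(top, function(cl) {
      dd <- d[nn][labels[nn] == cl]
      sum(1 / pmax(dd, .Machine$double.eps))
    }, numeric(1))
    top <- top[w == max(w)]
    if (length(top) > 1) {
      best <- vapply(top, function(cl) min(d[nn][labels[nn] == cl]), numeric(1))
      top <- top[which.min(best)]
    }
  }
  top[1]
}

#' Select aging classifier probes by leave-one-out k-NN feature stability
#'
#' One round per control sample: the sample is held out, the differential-
#' expression procedure of [callAffected()] is run on the remaining samples
#' with age class as the factor, and the probes affected in at least one
#' pairwise class comparison become the round's feature set. The held-out
#' sample is then classified to an age class by k-nearest neighbours
#' (Euclidean distance on log2 values over the round's features). Probes
#' selected in 100% of rounds are the aging classifiers.
#'
#' @param pe a [PhysioExperiment-class] of control samples.
#' @param ages age class labels; defaults to `colData(pe)$age_days`.
#' @param k neighbour count (`k < n_samples`); majority vote with a
#'   distance-weighted tie-break.
#' @param fdr,tukeyAlpha,foldChange thresholds passed to [callAffected()].
#' @return A [S4Vectors::DataFrame] (`ClassifierSet`) with `probe_id`,
#'   `selection_freq` and `is_classifier`; `metadata()` carries
#'   `looAccuracy`, `nRounds`, `failedRounds` and the per-round predictions.
#' @export
looKnnSelect <- function(pe, ages = NULL, k = 3L, fdr = 0.05,
                         tukeyAlpha = 0.05, foldChange = 1.5) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(ages)) ages <- colData(pe)$age_days
  ages <- as.numeric(ages)
  nS <- ncol(values)
  if (k >= nS) stop("k must be smaller than the number of samples")
  if (any(table(ages) < 2)) stop("need >= 2 replicates per age class")

  selCount <- stats::setNames(numeric(nrow(values)), rownames(values))
  predicted <- rep(NA_character_, nS)
  failed <- integer(0)
  for (i in seq_len(nS)) {
    restVals <- values[, -i, drop = FALSE]
    restAges <- ages[-i]
    de <- callAffected(restVals, classes = factor(restAges), fdr = fdr,
                       tukeyAlpha = tukeyAlpha, foldChange = foldChange)
    feats <- affectedProbes(de)
    if (length(feats) == 0) {
      failed <- c(failed, i)
      warning("LOO round ", i, " yielded zero features; recorded as failed")
      next
    }
    selCount[feats] <- selCount[feats] + 1
    predicted[i] <- .knnPredict(restVals[feats, , drop = FALSE],
                                as.character(restAges),
                                values[feats, i], k = k)
  }
  freq <- selCount / nS
  out <- S4Vectors::DataFrame(probe_id = rownames(values),
                              selection_freq = freq,
                              is_classifier = freq == 1)
  rownames(out) <- rownames(values)
  ok <- !is.na(predicted)
  S4Vectors::metadata(out) <- list(
    looAccuracy = if (any(ok)) mean(predicted[ok] == as.character(ages)[ok])
                  else NA_real_,
    nRounds = nS, failedRounds = failed, predicted = predicted, k = k)
  out
}

#' Classifier probe ids
#' @param classifierSet the `ClassifierSet` from [looKnnSelect()].
#' @return Character vector of probes selected in every LOO round.
#' @export
classifierProbes <- function(classifierSet) {
  as.character(classifierSet$probe_id[classifierSet$is_classifier])
}

#' Fit the PC-seeded, AIC-optimised linear age clock
#'
#' Classifier-probe expression of the control samples is centred by the
#' training means and decomposed by PCA. Candidate components are those
#' needed to reach `varianceCap` cumulative variance, capped at
#' `n_samples - 2`. Components enter a linear model of numeric age (days) by
#' forward stepwise selection, each step adding the component that most
#' decreases AIC, stopping when no addition decreases it.
#'
#' @param pe a [PhysioExperiment-class] of control samples (>= 4 samples,
#'   >= 3 distinct ages).
#' @param classifiers a `ClassifierSet` from [looKnnSelect()], or a character
#'   vector of probe ids (>= 2).
#' @param ages numeric training ages; defaults to `colData(pe)$age_days`.
#' @param varianceCap cumulative-variance rule for seeding candidate PCs.
#' @return An [AgeClock-class].
#' @export
fitAgeClock <- function(pe, classifiers, ages = NULL, varianceCap = 0.95) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(ages)) ages <- colData(pe)$age_days
  ages <- as.numeric(ages)
  probes <- if (is.character(classifiers)) classifiers
            else classifierProbes(classifiers)
  if (length(probes) < 2) stop("need >= 2 classifier probes")
  if (!all(probes %in% rownames(values)))
    stop("classifier probe(s) absent from the matrix")
  if (ncol(values) < 4) stop("need >= 4 training samples")
  if (length(unique(ages)) < 3) stop("need >= 3 distinct age values")

  x <- t(values[probes, , drop = FALSE])
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  varExpl <- pc$sdev^2 / sum(pc$sdev^2)
  nCand <- which(cumsum(varExpl) >= varianceCap)[1]
  if (is.na(nCand)) nCand <- length(varExpl)
  nCand <- max(1L, min(nCand, nrow(x) - 2L))
  scores <- pc$x[, seq_len(nCand), drop = FALSE]

  sel <- integer(0)
  fit <- stats::lm(ages ~ 1)
  aicTrace <- stats::AIC(fit)
  repeat {
    cand <- setdiff(seq_len(nCand), sel)
    if (length(cand) == 0) break
    aics <- vapply(cand, function(j) {
      stats::AIC(stats::lm(ages ~ scores[, c(sel, j), drop = FALSE]))
    }, numeric(1))
    if (min(aics) >= utils::tail(aicTrace, 1)) break
    j <- cand[which.min(aics)]
    sel <- c(sel, j)
    fit <- stats::lm(ages ~ scores[, sel, drop = FALSE])
    aicTrace <- c(aicTrace, stats::AIC(fit))
  }
  coefs <- if (length(sel)) stats::coef(fit) else stats::coef(fit)["(Intercept)"]
  methods::new("AgeClock", probeIds = probes, center = center,
               loadings = pc$rotation[, seq_len(nCand), drop = FALSE],
               candidatePcs = nCand, selectedPcs = as.integer(sel),
               coefficients = unname(coefs), aicTrace = aicTrace,
               trainingIds = colnames(values), trainingAges = ages)
}

#' Predict physiological age and aging acceleration
#'
#' Centres the classifier rows of the input with the clock's training means,
#' projects onto the training PC loadings, and applies the linear
#' coefficients. Predictions are not clipped to the training age range.
#' Acceleration is `100 * (physiological - chronological) / chronological`
#' and is defined only for positive chronological ages.
#'
#' @param clock an [AgeClock-class].
#' @param pe a [PhysioExperiment-class] or numeric matrix containing all
#'   clock probes.
#' @param chronAges chronological ages in days; defaults to
#'   `colData(pe)$age_days` (may be `NULL` for a bare matrix, in which case
#'   acceleration is `NA`).
#' @return A [S4Vectors::DataFrame] (`AgePrediction`) with `sample_id`,
#'   `chron_age`, `physio_age` and `accel_pct`.
#' @export
predictPhysioAge <- function(clock, pe, chronAges = NULL) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(chronAges) && methods::is(pe, "SummarizedExperiment"))
    chronAges <- colData(pe)$age_days
  missing <- setdiff(clock@probeIds, rownames(values))
  if (length(missing))
    stop("clock probe(s) missing from the input: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  x <- t(values[clock@probeIds, , drop = FALSE])
  xc <- sweep(x, 2, clock@center)
  pred <- if (length(clock@selectedPcs)) {
    scores <- xc %*% clock@loadings[, clock@selectedPcs, drop = FALSE]
    clock@coefficients[1] + as.vector(scores %*% clock@coefficients[-1])
  } else rep(clock@coefficients[1], nrow(x))
  chron <- if (is.null(chronAges)) rep(NA_real_, nrow(x))
           else as.numeric(chronAges)
  accel <- ifelse(!is.na(chron) & chron > 0, 100 * (pred - chron) / chron,
                  NA_real_)
  S4Vectors::DataFrame(sample_id = colnames(values), chron_age = chron,
                       physio_age = pred, accel_pct = accel)
}

#' Summarize physiological-age predictions by group
#'
#' Per-group mean and SEM of physiological age and acceleration, with a
#' one-way ANOVA and Tukey multiple-testing correction across groups applied
#' to the predictions themselves (when at least two groups are present).
#'
#' @param preds an `AgePrediction` table from [predictPhysioAge()].
#' @param groups factor-like grouping vector aligned with `preds` rows.
#' @return A list with `summary` (per-group data.frame), `anovaP` and
#'   `tukey` (pairwise Tukey-HSD table, `NULL` for a single group).
#' @export
summarizeAcceleration <- function(preds, groups) {
  g <- droplevels(factor(groups))
  if (length(g) != nrow(preds)) stop("'groups' must align with 'preds'")
  if (any(table(g) < 2)) warning("group(s) with < 2 predictions")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  physio <- as.numeric(preds$physio_age)
  accel <- as.numeric(preds$accel_pct)
  summ <- do.call(rbind, lapply(levels(g), function(l) {
    i <- g == l
    data.frame(group = l, n = sum(i),
               mean_physio = mean(physio[i]), sem_physio = sem(physio[i]),
               mean_accel = mean(accel[i]), sem_accel = sem(accel[i]))
  }))
  if (nlevels(g) < 2)
    return(list(summary = summ, anovaP = NA_real_, tukey = NULL))
  fit <- stats::aov(physio ~ g)
  tk <- as.data.frame(stats::TukeyHSD(fit)$g)
  list(summary = summ,
       anovaP = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = tk)
}
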
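# Aging-gene discovery: polyserial correlation of expression with ordinal age
# class, calibrated against a randomized-age permutation null with +/- 2 SD
# cutoffs.

.ordinalCodes <- function(y, coding = c("rank", "days")) {
  coding <- match.arg(coding)
  f <- factor(y)
  if (nlevels(f) < 2) stop("need >= 2 distinct ordinal classes")
  if (coding == "rank") as.integer(f) else as.numeric(as.character(f))
}

# scale factor turning Pearson r(x, codes) into the two-step polyserial
# estimate: sqrt((n-1)/n) * sd(codes) / sum(dnorm(thresholds)). Thresholds
# come from the cumulative class proportions, so the factor depends only on
# the label multiset and is shared by every probe and every permutation.
.polyserialScale <- function(codes) {
  n <- length(codes)
  p <- cumsum(table(codes) / n)
  tau <- stats::qnorm(p[-length(p)])
  sqrt((n - 1) / n) * stats::sd(codes) / sum(stats::dnorm(tau))
}

#' Two-step polyserial correlation
#'
#' Estimates the correlation between a continuous variable and the latent
#' standard normal variable assumed to underlie an ordinal variable. The
#' two-step estimator rescales the Pearson correlation of `x` with the
#' integer-coded classes by `sd(codes) / sum(dnorm(tau_k))`, where the
#' thresholds `tau_k` are normal quantiles of the cumulative class
#' proportions. The result is clipped to `[-1, 1]`.
#'
#' @param x continuous vector.
#' @param y ordinal class vector (factor-like); with `coding = "rank"` classes
#'   are coded 1..K in sorted order, with `"days"` the numeric class values
#'   are used directly.
#' @param coding ordinal coding scheme.
#' @return The polyserial correlation estimate.
#' @examples
#' set.seed(1)
#' age <- rep(c(3, 10, 30, 45), each = 5)
#' x <- 0.05 * age + rnorm(20, sd = 0.3)
#' polyserialRho(x, age)
#' @export
polyserialRho <- function(x, y, coding = c("rank", "days")) {
  codes <- .ordinalCodes(y, coding)
  if (stats::sd(x) == 0) stop("'x' is constant; polyserial undefined")
  rho <- stats::cor(x, codes) * .polyserialScale(codes)
  max(-1, min(1, rho))
}

# vectorised over the rows of a matrix; returns NA for constant rows
.rowPolyserial <- function(values, codes, scale = .polyserialScale(codes)) {
  rho <- suppressWarnings(as.vector(stats::cor(t(values), codes))) * scale
  pmin(1, pmax(-1, rho))
}

#' Build the randomized-age permutation null for aging-gene selection
#'
#' For each of `B` rounds, one permutation of the age labels over samples is
#' drawn (shared by all probes, preserving the inter-gene correlation
#' structure of the null) and the polyserial correlation is recomputed for
#' every probe. All `B * nrow` estimates are pooled; the selection band is
#' the pooled mean +/- 2 SD.
#'
#' @param pe a [PhysioExperiment-class] (ages taken from `colData`) or a
#'   numeric matrix.
#' @param ages ordinal age labels; defaults to `colData(pe)$age_days`.
#' @param B number of label randomizations.
#' @param seed integer seed.
#' @param coding ordinal coding scheme, see [polyserialRho()].
#' @param perProbe permute labels independently per probe instead of sharing
#'   one permutation per round.
#' @return A [PermNull-class].
#' @export
buildPermNull <- function(pe, ages = NULL, B = 20L, seed = 1L,
                          coding = c("rank", "days"), perProbe = FALSE) {
  stopifnot(B >= 1)
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(ages)) ages <- colData(pe)$age_days
  codes <- .ordinalCodes(ages, coding)
  scale <- .polyserialScale(codes)
  set.seed(seed)
  pooled <- unlist(lapply(seq_len(B), function(b) {
    if (perProbe) {
      rho <- apply(values, 1, function(x)
        suppressWarnings(stats::cor(x, sample(codes))) * scale)
      pmin(1, pmax(-1, rho))
    } else {
      .rowPolyserial(values, sample(codes), scale)
    }
  }))
  pooled <- pooled[is.finite(pooled)]
  mu <- mean(pooled)
  sdv <- stats::sd(pooled)
  methods::new("PermNull", B = as.integer(B), nullMean = mu, nullSd = sdv,
               lo = mu - 2 * sdv, hi = mu + 2 * sdv,
               nEstimates = length(pooled), seed = as.integer(seed))
}

#' Select aging-related probes against a permutation null
#'
#' A probe is flagged aging-related when its polyserial correlation with age
#' class falls outside the null band `[lo, hi]`; the direction is the sign of
#' the estimate.
#'
#' @inheritParams buildPermNull
#' @param null a [PermNull-class] built on the same expression universe.
#' @return A [S4Vectors::DataFrame] (`AgingGeneTable`) with columns
#'   `probe_id`, `rho`, `direction` and `is_aging`; the null is attached as
#'   `metadata()$permNull`.
#' @export
selectAgingGenes <- function(pe, ages = NULL, null,
                             coding = c("rank", "days")) {
  values <- if (methods::is(pe, "SummarizedExperiment")) exprsMatrix(pe) else pe
  if (is.null(ages)) ages <- colData(pe)$age_days
  codes <- .ordinalCodes(ages, coding)
  rho <- .rowPolyserial(values, codes)
  isAging <- !is.na(rho) & (rho < null@lo | rho > null@hi)
  tab <- S4Vectors::DataFrame(
    probe_id = rownames(values), rho = rho,
    direction = ifelse(rho >= 0, "up", "down"),
    is_aging = isAging)
  rownames(tab) <- rownames(values)
  S4Vectors::metadata(tab)$permNull <- null
  tab
}

#' Probe ids flagged as aging-related
#' @param agingTable the `AgingGeneTable` from [selectAgingGenes()].
#' @return Character vector of probe ids.
#' @export
agingProbes <- function(agingTable) {
  as.character(agingTable$probe_id[agingTable$is_aging])
}
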
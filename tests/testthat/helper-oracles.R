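# Independent oracles and small fixture builders used across the suite.

# Draw (x, y) from a latent bivariate normal with correlation rho, with the
# second coordinate discretized into ordinal classes at the given cumulative
# proportions.
genLatentOrdinal <- function(n, rho, props) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- c(-Inf, qnorm(cumsum(props)[-length(props)]), Inf)
  list(x = z1, y = cut(z2, cuts, labels = FALSE))
}

# Maximum-likelihood polyserial correlation by direct likelihood
# maximization: thresholds fixed at the empirical normal quantiles of the
# class proportions, x standardized by its sample moments, and the
# conditional ordinal likelihood optimized over rho alone. Written
# independently of the package's two-step estimator.
mlPolyserial <- function(x, y) {
  f <- factor(y)
  ky <- as.integer(f)
  n <- length(x)
  z <- (x - mean(x)) / (sd(x) * sqrt((n - 1) / n))
  p <- cumsum(tabulate(ky) / n)
  tau <- qnorm(p[-length(p)])
  tl <- c(-Inf, tau)[ky]
  tu <- c(tau, Inf)[ky]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- pnorm((tu - rho * z) / s) - pnorm((tl - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  optimize(nll, c(-0.999, 0.999))$minimum
}

# Minimal PhysioExperiment around a bare matrix
peFromMatrix <- function(values, age = rep(1, ncol(values)),
                         genotype = "control", batch = "b1",
                         techRep = rep(FALSE, ncol(values))) {
  PhysioExperiment(values, data.frame(
    sample_id = colnames(values), tissue = "head", genotype = genotype,
    age_days = age, batch = batch, is_tech_rep = techRep))
}

# i.i.d. Gaussian null matrix over the study's sample layout:
# ages 3/10/30/45 days with 4 replicates at day 3 and 5 elsewhere (19 samples)
nullStudyMatrix <- function(nProbes, mean = 9, sd = 0.5) {
  ages <- rep(c(3, 10, 30, 45), c(4, 5, 5, 5))
  m <- matrix(rnorm(nProbes * length(ages), mean, sd), nProbes,
              dimnames = list(sprintf("p%04d", seq_len(nProbes)),
                              sprintf("s%02d", seq_along(ages))))
  list(values = m, ages = ages)
}
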
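# Synthetic genotype / phenotype generator: sparse causal architecture,
# generalised-gamma log-time errors indexed by theta, fixed log-scale
# heritability, controlled right censoring.

#' Simulate unlinked genotypes
#'
#' Binomial(2, f) allele counts at independent markers with allele
#' frequencies drawn uniformly from `maf_range`; monomorphic columns are
#' resampled so every marker is polymorphic.
#'
#' @param n individuals.
#' @param m markers.
#' @param maf_range allele-frequency range (default 0.05 to 0.5).
#' @param chr_length_bp genome span used to assign evenly spaced positions
#'   (marker metadata for clumping; markers remain unlinked).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               chr_length_bp = 50e6) {
  f <- runif(m, maf_range[1], maf_range[2])
  G <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
  for (j in seq_len(m)) {
    while (length(unique(G[, j])) < 2) G[, j] <- rbinom(n, 2L, f[j])
  }
  genotype_matrix(G, ids = sprintf("sim%05d", seq_len(m)),
                  chr = rep(1L, m),
                  pos = round(seq(1, chr_length_bp, length.out = m)))
}

# standardised draw of log(GeneralisedGamma): for theta > 0 the raw variate
# is log(Gamma(1/theta^2, 1)) / theta, standardised with its closed-form
# digamma/trigamma moments; theta = 0 is the Gaussian limit.
rloggengamma_std <- function(n, theta) {
  if (theta < 0) stop("theta must be >= 0")
  if (theta == 0) return(rnorm(n))
  k <- 1 / theta^2
  raw <- log(rgamma(n, shape = k)) / theta
  (raw - digamma(k) / theta) / sqrt(trigamma(k) / theta^2)
}

#' Simulate time-to-event phenotypes from a generalised-gamma family
#'
#' Draws sparse causal effects \eqn{\beta \sim N(0, \sigma^2_G/p)} at `p`
#' random markers, forms genetic values \eqn{g = X\beta} on standardised
#' genotypes, and sets \eqn{\log y_i = \mu_0 + g_i + e_i} where \eqn{e_i}
#' is a standardised log generalised-gamma draw with index `theta`
#' (`theta = 1`: Gumbel error, i.e. Weibull times; `theta = 0`: Gaussian
#' error, i.e. log-normal times) scaled to variance
#' \eqn{\mathrm{Var}(g)(1-h^2)/h^2}, fixing the log-scale heritability at
#' `h2`. All individuals are returned uncensored; apply
#' [apply_censoring()] afterwards.
#'
#' @param geno a [genotype_matrix()].
#' @param p_causal number of causal markers.
#' @param h2 target log-scale heritability in (0, 1).
#' @param theta generalised-gamma index, `theta >= 0`.
#' @param mu0 intercept on the log-time scale. The default 3.6 puts the
#'   onset scale around `exp(3.6)` (about 37) time units, well inside the
#'   sampler's intercept limits.
#' @param sigma2G variance of the causal-effect architecture; the default
#'   pairs `h2` with a true Weibull shape of 4
#'   (\eqn{\sigma^2_G = h^2/(1-h^2)\,\pi^2/(6\cdot 16)}).
#' @param clumps optional [ld_clump()] regions: causal effects are then
#'   placed on the index SNPs of `p_causal` randomly selected clumps (the
#'   LD-aware design), instead of uniformly random markers.
#' @return list with `data` (a [survival_data()]) and `truth` (causal
#'   indices, true `beta`, genetic values `g`, uncensored times, realized
#'   heritability, and the error scale used).
#' @export
simulate_phenotypes <- function(geno, p_causal, h2 = 0.5, theta = 1,
                                mu0 = 3.6,
                                sigma2G = h2 / (1 - h2) * pi^2 / (6 * 16),
                                clumps = NULL) {
  stopifnot(p_causal <= geno$m, h2 > 0, h2 < 1)
  causal <- if (is.null(clumps)) {
    sort(sample.int(geno$m, p_causal))
  } else {
    idx <- attr(clumps, "index")
    if (is.null(idx) || p_causal > length(idx))
      stop("clumps must be ld_clump() output with at least p_causal clumps")
    sort(sample(idx, p_causal))
  }
  beta <- numeric(geno$m)
  beta[causal] <- rnorm(p_causal, 0, sqrt(sigma2G / p_causal))
  g <- as.vector(geno_std(geno, causal) %*% beta[causal])
  vg <- var(g)
  err_sd <- sqrt(vg * (1 - h2) / h2)
  e <- rloggengamma_std(geno$n, theta) * err_sd
  logy <- mu0 + g + e
  data <- survival_data(exp(logy), failure = rep(1L, geno$n))
  list(data = data,
       truth = list(causal = causal, beta = beta, g = g,
                    time_uncensored = exp(logy),
                    h2_realized = vg / var(logy),
                    mu0 = mu0, theta = theta, err_sd = err_sd,
                    alpha_true = pi / (err_sd * sqrt(6))))
}

#' Impose right censoring
#'
#' A uniformly chosen fraction of individuals is censored: their failure
#' indicator is set to 0 and the recorded time replaced by a uniform draw on
#' (0, y). The realized censoring fraction is exactly
#' `floor(fraction * n) / n`. The scheme is isolated here so an alternative
#' censoring-time mechanism can be swapped in.
#'
#' @param data an uncensored [survival_data()].
#' @param fraction censoring fraction in \[0, 1).
#' @return a new [survival_data()]; attribute `"censored"` holds the indices.
#' @export
apply_censoring <- function(data, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(data)
  n <- data$n
  k <- floor(fraction * n)
  idx <- sample.int(n, k)
  time <- data$time
  failure <- data$failure
  time[idx] <- runif(k, 0, time[idx])
  failure[idx] <- 0L
  out <- survival_data(time, failure, data$trunc, data$covariates, data$id)
  attr(out, "censored") <- sort(idx)
  out
}

#' One-call simulation of a complete study
#'
#' Convenience wrapper: genotypes, phenotypes, censoring.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotypes
#' @param censoring censoring fraction.
#' @return list with `genotypes`, `data`, `truth`.
#' @export
simulate_survival_study <- function(n, m, p_causal, h2 = 0.5, theta = 1,
                                    censoring = 0, maf_range = c(0.05, 0.5),
                                    mu0 = 3.6) {
  geno <- simulate_genotypes(n, m, maf_range)
  ph <- simulate_phenotypes(geno, p_causal, h2, theta, mu0)
  data <- apply_censoring(ph$data, censoring)
  list(genotypes = geno, data = data, truth = ph$truth)
}

#' Write a simulated study to disk
#'
#' Emits PLINK bed/bim/fam, a phenotype file (`FID IID time failure`) and a
#' truth file (`marker_id true_beta`) so external tools can be benchmarked
#' on identical data.
#'
#' @param sim output of [simulate_survival_study()].
#' @param prefix path prefix for all files.
#' @return `prefix`, invisibly.
#' @export
write_study <- function(sim, prefix) {
  write_plink(sim$genotypes, prefix)
  ph <- data.frame(FID = seq_len(sim$data$n), IID = seq_len(sim$data$n),
                   time = sim$data$time, failure = sim$data$failure)
  write.table(ph, paste0(prefix, ".pheno"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- data.frame(marker_id = sim$genotypes$ids, true_beta = sim$truth$beta)
  write.table(tr, paste0(prefix, ".truth"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
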
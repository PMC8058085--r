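# Small in-code fixtures shared across test files.

# tiny uncensored-or-censored Weibull data set with known shape/scale
tiny_weibull_data <- function(n = 20, shape = 4, scale = 40,
                              censor_frac = 0.2, seed = 101) {
  set.seed(seed)
  y <- rweibull(n, shape, scale)
  d <- rep(1L, n)
  k <- floor(censor_frac * n)
  if (k > 0) {
    idx <- sample.int(n, k)
    y[idx] <- runif(k, 0, y[idx])
    d[idx] <- 0L
  }
  survival_data(y, d)
}

# random genotype counts with optional missing calls
tiny_geno <- function(n = 50, m = 5, maf = c(0.1, 0.5), miss = 0,
                      seed = 202) {
  set.seed(seed)
  f <- runif(m, maf[1], maf[2])
  G <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
  if (miss > 0) G[sample(length(G), round(miss * length(G)))] <- NA
  for (j in seq_len(m)) {
    cj <- G[, j]
    while (length(unique(cj[!is.na(cj)])) < 2) {
      cj <- rbinom(n, 2L, f[j])
      G[, j] <- cj
    }
  }
  genotype_matrix(G)
}

# dense-oracle evaluation of the slab marginal over beta, common (per-T)
# scale, by adaptive numerical integration of the reparametrised integrand
dense_slab_marginal <- function(geno, j, data, weights, alpha, Ck, sigma2G) {
  x <- geno_std(geno, j)
  sdx <- sum(data$failure * x)
  g <- function(s) vapply(s, function(si) {
    b <- si * sqrt(2 * Ck * sigma2G)
    A <- sum(weights * (1 - exp(-alpha * x * b)))
    exp(-alpha * b * sdx + A - si^2)
  }, numeric(1))
  integrate(g, -Inf, Inf, rel.tol = 1e-10)$value
}
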
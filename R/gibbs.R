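# The Gibbs sampler: prior specification, grouped layout, conjugate updates,
# and the serial / bulk-synchronous-parallel drivers over the compiled engine.

#' Prior hyperparameters
#'
#' Weakly informative defaults: gamma prior on the shape with
#' `alpha0 = kappa0 = 0.01`; inverse-gamma prior on each group genetic
#' variance with `alpha_sigma = 1`, `beta_sigma = 1e-4`; zero-mean normal
#' priors with variance 100 on the intercept and covariate effects; Dirichlet
#' concentration 1 on the mixture proportions.
#'
#' @param alpha0,kappa0 gamma prior parameters of the Weibull shape.
#' @param alpha_sigma,beta_sigma inverse-gamma prior of the genetic variance.
#' @param sigma2_mu,sigma2_delta normal prior variances of intercept and
#'   covariate effects.
#' @param dirichlet_p Dirichlet concentration (scalar, recycled).
#' @export
bw_hyper <- function(alpha0 = 0.01, kappa0 = 0.01, alpha_sigma = 1,
                     beta_sigma = 1e-4, sigma2_mu = 100, sigma2_delta = 100,
                     dirichlet_p = 1) {
  h <- list(alpha0 = alpha0, kappa0 = kappa0, alpha_sigma = alpha_sigma,
            beta_sigma = beta_sigma, sigma2_mu = sigma2_mu,
            sigma2_delta = sigma2_delta, dirichlet_p = dirichlet_p)
  if (any(unlist(h) <= 0)) stop("all hyperparameters must be positive")
  h
}

#' Marker grouping with group-specific mixtures
#'
#' Assigns every marker to one of a set of disjoint groups, each with its own
#' mixture constants, proportions and genetic variance.
#'
#' @param group_of_marker integer/factor of length `m` mapping markers to
#'   groups; `NULL` puts every marker in one group.
#' @param m number of markers.
#' @param mixtures numeric vector of slab constants shared by all groups, or
#'   a list with one vector per group.
#' @return list of class `bw_layout` with `group` (1-based integer),
#'   `n_groups`, `labels`, and `mixtures` (list of [mixture_spec()]).
#' @export
group_layout <- function(m, group_of_marker = NULL,
                         mixtures = c(1e-5, 1e-4, 1e-3, 1e-2)) {
  if (is.null(group_of_marker)) group_of_marker <- rep(1L, m)
  if (length(group_of_marker) != m)
    stop("group_of_marker must have one entry per marker")
  f <- factor(group_of_marker)
  g <- as.integer(f)
  ng <- nlevels(f)
  if (any(tabulate(g, ng) == 0)) stop("every group must be nonempty")
  if (!is.list(mixtures) || inherits(mixtures, "bw_mixture"))
    mixtures <- rep(list(mixtures), ng)
  if (length(mixtures) != ng)
    stop("need one mixture constant vector per group")
  specs <- lapply(mixtures, function(mx)
    if (inherits(mx, "bw_mixture")) mx else mixture_spec(mx))
  structure(list(group = g, n_groups = ng, labels = levels(f),
                 mixtures = specs),
            class = "bw_layout")
}

#' Initial Markov-chain state
#'
#' Everything starts out of the model: all mixture indicators 0, marker and
#' covariate effects 0. The intercept starts at the mean of the log sample;
#' the shape at \eqn{\sqrt{\pi^2/(6\,\mathrm{Var}(\log y))}} (the inversion
#' of the Gumbel variance identity); each group genetic variance at
#' `Var(log y) / m` split equally across groups.
#'
#' @param data a [survival_data()] object.
#' @param m number of markers.
#' @param layout a [group_layout()].
#' @export
init_state <- function(data, m, layout = group_layout(m)) {
  v <- var(data$log_time)
  if (!is.finite(v) || v <= 0) stop("zero phenotypic variance")
  list(mu = mean(data$log_time),
       alpha = sqrt(pi^2 / (6 * v)),
       sigma2G = rep(v / m / layout$n_groups, layout$n_groups),
       pi = lapply(layout$mixtures, `[[`, "pi"),
       beta = rep(0, m),
       gamma = rep(0L, m),
       delta = rep(0, if (is.null(data$covariates)) 0 else ncol(data$covariates)))
}

#' Conjugate update of the group genetic variances
#'
#' Draws each \eqn{\sigma^2_{G\varphi}} from its inverse-gamma conditional
#' with shape \eqn{\alpha_\sigma + \tfrac12 m_\varphi} (markers of the group
#' currently in the model) and scale
#' \eqn{\beta_\sigma + \tfrac12\sum_{j} \beta_j^2 / C_{\gamma_j}}.
#'
#' @param beta,gamma current effects and mixture indicators.
#' @param layout a [group_layout()].
#' @param hyper a [bw_hyper()].
#' @export
update_sigma2_G <- function(beta, gamma, layout, hyper = bw_hyper()) {
  vapply(seq_len(layout$n_groups), function(g) {
    jj <- which(layout$group == g & gamma > 0)
    Ck <- layout$mixtures[[g]]$constants
    scale <- hyper$beta_sigma +
      if (length(jj)) 0.5 * sum(beta[jj]^2 / Ck[gamma[jj]]) else 0
    scale / rgamma(1, shape = hyper$alpha_sigma + 0.5 * length(jj))
  }, numeric(1))
}

#' Dirichlet update of the mixture proportions
#'
#' Per group, draws \eqn{\pi \sim \mathrm{Dirichlet}(p_L + occupancy)} where
#' the occupancy counts include the spike.
#'
#' @inheritParams update_sigma2_G
#' @return list of proportion vectors, one per group.
#' @export
update_pi <- function(gamma, layout, hyper = bw_hyper()) {
  lapply(seq_len(layout$n_groups), function(g) {
    jj <- layout$group == g
    L <- layout$mixtures[[g]]$L
    counts <- tabulate(gamma[jj] + 1L, L + 1L)
    a <- hyper$dirichlet_p + counts
    x <- rgamma(length(a), shape = a)
    x / sum(x)
  })
}

# shared engine driver --------------------------------------------------------
run_engine <- function(geno, data, layout, hyper, iterations, burnin,
                       thinning, quad_points, workers, sync_rate, seed,
                       control = list()) {
  stopifnot(inherits(geno, "bw_geno"), inherits(data, "bw_surv"))
  if (geno$n != data$n) stop("genotype and phenotype sample sizes differ")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  ctl <- list(update_mu = TRUE, update_alpha = TRUE, update_delta = TRUE,
              update_pi = TRUE, update_sigma = TRUE,
              mu_lo = 2, mu_hi = 5, alpha_lo = 0, alpha_hi = 40,
              delta_halfwidth = 10 * sqrt(hyper$sigma2_delta))
  ctl[names(control)] <- control

  Z <- data$covariates
  if (is.null(Z)) Z <- matrix(0, data$n, 0)
  zc <- colMeans(Z); zs <- apply(Z, 2, sd)
  if (ncol(Z)) {
    if (any(zs <= 0)) stop("constant covariate column")
    Z <- scale(Z, center = zc, scale = zs)   # z-scored, recorded in run log
  }

  # per-marker constants: sum_i d_i x_ij from the carrier index sets
  d <- data$failure
  dtot <- sum(d)
  sumdx <- vapply(seq_len(geno$m), function(j) {
    s1 <- sum(d[geno$idx1[[j]]]); s2 <- sum(d[geno$idx2[[j]]])
    dm <- sum(d[geno$idxm[[j]]])
    (s1 + 2 * s2 - geno$xbar[j] * (dtot - dm)) / geno$sd[j]
  }, numeric(1))

  init <- init_state(data, geno$m, layout)
  if (init$mu < ctl$mu_lo || init$mu > ctl$mu_hi)
    warning(sprintf(
      "mean log time %.2f lies outside the intercept sampling limits (%g, %g)",
      init$mu, ctl$mu_lo, ctl$mu_hi))
  init$mu <- min(max(init$mu, ctl$mu_lo + 0.05), ctl$mu_hi - 0.05)
  init$alpha <- min(max(init$alpha, 0.05), ctl$alpha_hi - 0.05)
  rule <- hermite_rule(quad_points)

  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_gibbs(data$log_time, as.integer(d),
                   data$log_trunc - data$log_time, Z,
                   lapply(geno$idx1, function(i) as.integer(i - 1L)),
                   lapply(geno$idx2, function(i) as.integer(i - 1L)),
                   lapply(geno$idxm, function(i) as.integer(i - 1L)),
                   geno$xbar, geno$sd, sumdx,
                   as.integer(layout$group - 1L),
                   lapply(layout$mixtures, `[[`, "constants"),
                   hyper, rule$points, rule$weights,
                   as.integer(iterations), as.integer(burnin),
                   as.integer(thinning), as.integer(workers),
                   as.integer(sync_rate),
                   list(mu = init$mu, alpha = init$alpha,
                        sigma2G = init$sigma2G, pi = init$pi),
                   ctl)

  pis <- raw$pi
  names(pis) <- layout$labels
  structure(list(
    mu = as.numeric(raw$mu), alpha = as.numeric(raw$alpha),
    delta = raw$delta[, seq_len(ncol(Z)), drop = FALSE],
    sigma2G = raw$sigma2G, pi = pis,
    beta = raw$beta, gamma = raw$gamma,
    n_retained = raw$retained,
    iterations = iterations, burnin = burnin, thinning = thinning,
    workers = workers, sync_rate = sync_rate, seed = seed,
    quad_points = quad_points, hyper = hyper, layout = layout,
    covariate_center = zc, covariate_scale = zs,
    marker_ids = geno$ids
  ), class = "bw_samples")
}

#' Serial Gibbs sampler
#'
#' One chain of the serial sampling algorithm: per iteration the intercept,
#' covariate effects and shape are drawn by derivative-free adaptive
#' rejection sampling with residual add-back/subtract; markers are visited in
#' a fresh random order, each getting a mixture indicator from the
#' quadrature marginal likelihoods and, when included, an effect drawn from
#' its slab conditional; the mixture proportions and group variances close
#' the iteration. Fixing the seed makes the output bit-reproducible.
#'
#' @param geno a [genotype_matrix()].
#' @param data a [survival_data()].
#' @param layout a [group_layout()]; defaults to a single group with slab
#'   constants `1e-5, 1e-4, 1e-3, 1e-2`.
#' @param hyper a [bw_hyper()].
#' @param iterations,burnin,thinning chain length controls; retained draws
#'   number `(iterations - burnin) / thinning`.
#' @param quad_points Gauss-Hermite points for the marginal likelihoods.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param control list overriding sampler internals (sampling limits
#'   `mu_lo`, `mu_hi`, `alpha_lo`, `alpha_hi`, `delta_halfwidth`; logical
#'   `update_*` switches that freeze individual blocks, used for validation
#'   experiments).
#' @return a `bw_samples` object: retained draws of `mu`, `alpha`, `delta`,
#'   `sigma2G`, `pi` plus dense `beta` (markers x samples) and `gamma`
#'   matrices and the run configuration.
#' @export
gibbs_serial <- function(geno, data, layout = group_layout(geno$m),
                         hyper = bw_hyper(), iterations = 2000,
                         burnin = floor(iterations / 2), thinning = 5,
                         quad_points = 25, seed = NULL, control = list()) {
  run_engine(geno, data, layout, hyper, iterations, burnin, thinning,
             quad_points, workers = 1L, sync_rate = 1L, seed = seed,
             control = control)
}

#' Bulk-synchronous-parallel Gibbs sampler
#'
#' The sampler of [gibbs_serial()] with the marker sweep split across
#' `workers` logical workers holding contiguous marker blocks. Within a
#' synchronisation window each worker processes `sync_rate` of its markers
#' against the window-start residual state while accumulating its residual
#' message; at the barrier all messages are applied and the exponentiated
#' residuals refreshed. With `workers = 1, sync_rate = 1` the draw sequence
#' is identical to the serial sampler under the same seed.
#'
#' @inheritParams gibbs_serial
#' @param workers number of logical workers `T`.
#' @param sync_rate markers each worker processes between barriers `u`.
#' @export
gibbs_bsp <- function(geno, data, layout = group_layout(geno$m),
                      hyper = bw_hyper(), iterations = 2000,
                      burnin = floor(iterations / 2), thinning = 5,
                      quad_points = 25, workers = 1L, sync_rate = 1L,
                      seed = NULL, control = list()) {
  if (workers < 1 || workers > geno$m) stop("invalid worker count")
  if (sync_rate < 1) stop("sync_rate must be >= 1")
  run_engine(geno, data, layout, hyper, iterations, burnin, thinning,
             quad_points, workers = workers, sync_rate = sync_rate,
             seed = seed, control = control)
}

#' @export
print.bw_samples <- function(x, ...) {
  cat(sprintf(
    "bw_samples: %d retained draws (%d iterations, burn-in %d, thinning %d)\n",
    x$n_retained, x$iterations, x$burnin, x$thinning))
  cat(sprintf("  %d markers, %d group(s), workers=%d, sync_rate=%d\n",
              nrow(x$beta), length(x$sigma2G[1, ]), x$workers, x$sync_rate))
  invisible(x)
}
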
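# Weibull/Gumbel reparametrisation, censored + left-truncated likelihood,
# and the four conditional log-posteriors targeted by rejection sampling.

#' Moments of the log event time under the Gumbel reparametrisation
#'
#' For a Weibull time with linear predictor \eqn{\eta_i} on the log scale and
#' shape \eqn{\alpha}, the log time is Gumbel with
#' \eqn{E(\log Y_i) = \eta_i} and \eqn{Var(\log Y_i) = \pi^2/(6\alpha^2)}.
#' The mean depends only on the linear predictor and the variance only on the
#' shape, which is what lets the model separate location (markers,
#' covariates, intercept) from residual spread.
#'
#' @param mu_lin linear predictor \eqn{\mu + x'\beta + z'\delta} (any length).
#' @param alpha Weibull shape, must be positive.
#' @return list with `mean` (= `mu_lin`) and `variance` (= `pi^2/(6 alpha^2)`).
#' @export
#' @examples
#' gumbel_log_moments(0, pi / sqrt(6))$variance  # == 1
gumbel_log_moments <- function(mu_lin, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  list(mean = mu_lin, variance = pi^2 / (6 * alpha^2))
}

#' Censored, left-truncated Weibull log-likelihood
#'
#' Evaluates the log of the right-censored, left-truncated likelihood,
#' additive over individuals:
#' \deqn{d\log\alpha - Kd + (\alpha-1)\sum_i d_i \log y_i
#'   - \alpha \sum_i d_i \eta_i - \sum_i e^{v_i} + \sum_i e^{u_i}}
#' with \eqn{v_i = \alpha(\log y_i - \eta_i) - K},
#' \eqn{u_i = \alpha(\log a_i - \eta_i) - K} and \eqn{e^{u_i} = 0} where the
#' truncation age is zero. Constant factors that cancel in Gibbs ratios are
#' kept so absolute values are testable.
#'
#' @param data a [survival_data()] object.
#' @param mu,alpha,beta,delta model parameters as in [build_residuals()].
#' @param geno a [genotype_matrix()] (needed only when `beta` has non-zeros).
#' @param Z covariate matrix for `delta`; defaults to `data$covariates`.
#' @return a single number; errors if any intermediate is non-finite, naming
#'   the offending individual.
#' @export
bw_loglik <- function(data, mu, alpha, beta = NULL, delta = NULL,
                      geno = NULL, Z = data$covariates) {
  r <- build_residuals(data, geno, mu, alpha, beta, delta, Z)
  K <- euler_gamma()
  terms <- data$failure * (log(alpha) - K + (alpha - 1) * data$log_time -
                             alpha * (data$log_time - r$eps)) -
    r$exp_event + r$exp_trunc
  bad <- which(!is.finite(terms))
  if (length(bad))
    stop(sprintf("non-finite likelihood contribution for individual %d",
                 bad[1]))
  sum(terms)
}

# shared data-dependent term: sum_i [exp(u_i) - exp(v_i)] as a function of a
# candidate value of one parameter, all others held at `resid`'s state.

#' Conditional log-posterior of the Weibull shape
#'
#' Returns a callable evaluating, up to an additive constant,
#' \deqn{(\alpha_0 + d - 1)\log\alpha + \alpha[\sum_i d_i \epsilon_i -
#'   \kappa_0] + \sum_i(e^{u_i(\alpha)} - e^{v_i(\alpha)})}
#' where \eqn{\epsilon_i} are the current full residuals. Log-concave in
#' \eqn{\alpha}; queries at non-positive shape return `-Inf`.
#'
#' @param data a [survival_data()] object.
#' @param eps current residual vector (log time minus full linear predictor).
#' @param hyper a [bw_hyper()] list (uses `alpha0`, `kappa0`).
#' @return function of one argument.
#' @export
log_post_alpha <- function(data, eps, hyper = bw_hyper()) {
  K <- euler_gamma()
  d <- data$d
  sde <- sum(data$failure * eps)
  lshift <- data$log_trunc - data$log_time   # log(a_i / y_i), -Inf if a_i = 0
  function(a) {
    if (!is.finite(a) || a <= 0) return(-Inf)
    ev <- exp(pmin(a * eps - K, 700))
    fc <- ifelse(is.finite(lshift), 1 - exp(a * lshift), 1)
    (hyper$alpha0 + d - 1) * log(a) + a * (sde - hyper$kappa0) - sum(ev * fc)
  }
}

#' Conditional log-posterior of the intercept
#'
#' The residuals must have the intercept added back (`eps_plus = eps + mu`).
#' Evaluates \eqn{-\alpha d \mu + \sum_i(e^{u_i} - e^{v_i}) -
#' \mu^2/(2\sigma^2_\mu)} up to a constant.
#'
#' @param data a [survival_data()] object.
#' @param eps_plus residuals with the intercept removed from the predictor.
#' @param alpha current shape.
#' @param hyper a [bw_hyper()] list (uses `sigma2_mu`).
#' @export
log_post_mu <- function(data, eps_plus, alpha, hyper = bw_hyper()) {
  K <- euler_gamma()
  d <- data$d
  lshift <- data$log_trunc - data$log_time
  w_plus <- exp(pmin(alpha * eps_plus - K, 700)) *
    ifelse(is.finite(lshift), 1 - exp(alpha * lshift), 1)
  W <- sum(w_plus)
  function(m) -alpha * d * m - exp(-alpha * m) * W - m^2 / (2 * hyper$sigma2_mu)
}

#' Conditional log-posterior of one covariate effect
#'
#' @param data a [survival_data()] object.
#' @param eps_plus residuals with covariate `q`'s effect added back.
#' @param alpha current shape.
#' @param z the covariate column.
#' @param hyper a [bw_hyper()] list (uses `sigma2_delta`).
#' @export
log_post_delta <- function(data, eps_plus, alpha, z, hyper = bw_hyper()) {
  K <- euler_gamma()
  lshift <- data$log_trunc - data$log_time
  w_plus <- exp(pmin(alpha * eps_plus - K, 700)) *
    ifelse(is.finite(lshift), 1 - exp(alpha * lshift), 1)
  sdz <- sum(data$failure * z)
  function(dq)
    -alpha * dq * sdz - sum(w_plus * exp(-alpha * z * dq)) -
      dq^2 / (2 * hyper$sigma2_delta)
}

#' Conditional log-posterior of one marker effect in slab k
#'
#' Residuals must be current with the marker's effect removed. Includes the
#' Gaussian shrinkage term \eqn{-\beta_j^2/(2 C_k \sigma^2_G)}; the Dirac
#' spike (`k = 0`) is never sampled, its effects are exactly zero.
#'
#' @param data a [survival_data()] object.
#' @param geno,j marker.
#' @param weights current residual weights \eqn{e^{v_i} - e^{u_i}} (marker
#'   `j` removed).
#' @param alpha current shape.
#' @param Ck mixture constant of the slab.
#' @param sigma2G group genetic variance.
#' @export
log_post_beta <- function(data, geno, j, weights, alpha, Ck, sigma2G) {
  if (Ck <= 0) stop("spike effects are exactly zero and are never sampled")
  ps <- compute_partial_sums(geno, j, weights)
  sdx <- sum(data$failure * geno_std(geno, j))
  s <- geno$sd[j]; xb <- geno$xbar[j]
  function(b) {
    e <- alpha * b / s
    -alpha * b * sdx -
      exp(xb * e) * (ps$V0 + exp(-e) * ps$V1 + exp(-2 * e) * ps$V2) -
      b^2 / (2 * Ck * sigma2G)
  }
}
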
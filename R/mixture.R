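# Gauss-Hermite quadrature rule, mixture specification, and the marginal
# likelihoods that drive spike/slab component selection.

# per-session cache of Hermite rules, keyed by m
.hermite_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite quadrature rule
#'
#' Roots \eqn{t_r} of the m-th Hermite polynomial and weights \eqn{w_r}
#' (weight function \eqn{e^{-t^2}}; the weights sum to \eqn{\sqrt\pi}).
#' Rules are computed once per `m` and cached.
#'
#' @param m number of quadrature points (model default 25).
#' @return list with `points`, `weights`, `m`.
#' @export
hermite_rule <- function(m = 25L) {
  key <- as.character(m)
  if (is.null(.hermite_cache[[key]])) {
    gh <- pracma::gaussHermite(m)
    .hermite_cache[[key]] <- list(points = gh$x, weights = gh$w, m = m)
  }
  .hermite_cache[[key]]
}

#' Mixture specification for one marker group
#'
#' @param constants strictly increasing positive slab constants
#'   \eqn{C_1 < \dots < C_L}; slab `k` has prior variance
#'   \eqn{C_k \sigma^2_G}.
#' @param pi mixture proportions of length `L + 1` (spike first), summing
#'   to 1.
#' @export
mixture_spec <- function(constants, pi = NULL) {
  constants <- as.numeric(constants)
  if (any(constants <= 0) || is.unsorted(constants, strictly = TRUE))
    stop("mixture constants must be strictly increasing and positive")
  L <- length(constants)
  if (is.null(pi)) pi <- c(0.99, rep(0.01 / L, L))
  if (length(pi) != L + 1 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be length L+1, nonnegative, summing to 1")
  structure(list(constants = constants, pi = pi, L = L),
            class = "bw_mixture")
}

#' Quadrature scale for the slab marginal likelihood
#'
#' \deqn{\hat\sigma_k = \frac{1}{\sqrt 2\sqrt{1 + \alpha^2 C_k \sigma^2_G
#'   \sum_i x_{ij}^2 (e^{v_i} - e^{u_i})}}}
#'
#' @param alpha Weibull shape.
#' @param Ck slab constant.
#' @param sigma2G group genetic variance.
#' @param weighted_sum \eqn{\sum_i x_{ij}^2 (e^{v_i} - e^{u_i})}, e.g. from
#'   [sparse_sigma_hat_term()].
#' @export
sigma_hat <- function(alpha, Ck, sigma2G, weighted_sum) {
  rad <- 1 + alpha^2 * Ck * sigma2G * weighted_sum
  if (rad <= 0)
    stop("negative radicand in sigma_hat: residual state is corrupted")
  1 / (sqrt(2) * sqrt(rad))
}

#' Slab marginal likelihood (common scale)
#'
#' Adaptive Gauss-Hermite approximation of the slab-k marginal likelihood of
#' marker `j`, on the common scale on which the Dirac spike is exactly
#' \eqn{\sqrt\pi}: the shared factor
#' \eqn{T = \exp\{\sum_i(e^{u_i} - e^{v_i})\}} and \eqn{Q\sqrt{2\sigma^2_G}}
#' are divided out. The expansion point is fixed at 0 (effects are symmetric
#' about zero), and the weighted sum is accumulated in log space with a
#' max-shift so large exponent differences cannot overflow.
#'
#' @param geno,j marker.
#' @param data a [survival_data()] object (failure indicators).
#' @param weights residual weights \eqn{e^{v_i} - e^{u_i}} with marker `j`
#'   removed.
#' @param alpha,Ck,sigma2G model state.
#' @param rule a [hermite_rule()].
#' @param log return the log marginal (default `FALSE`).
#' @export
marginal_likelihood_slab <- function(geno, j, data, weights, alpha, Ck,
                                     sigma2G, rule = hermite_rule(),
                                     log = FALSE) {
  ps <- compute_partial_sums(geno, j, weights)
  sdx <- sum(data$failure * geno_std(geno, j))
  lm <- cpp_marker_logmarg(ps$V0, ps$V1, ps$V2, ps$Vnm, sdx,
                           geno$sd[j], geno$xbar[j], alpha, sigma2G,
                           Ck, rule$points, rule$weights)[2]
  if (log) lm else exp(lm)
}

#' Dirac-spike marginal likelihood (common scale)
#'
#' The \eqn{C_0 \to 0^+} limit of the slab marginal: on the common scale it
#' is exactly \eqn{\sqrt\pi} (the data factor
#' \eqn{\exp\{\sum_i(e^{u_i} - e^{v_i})\}} is the shared normaliser `T` and
#' cancels).
#'
#' @param normalised divide by `T` (default `TRUE`, the scale used
#'   everywhere in the sampler). With `normalised = FALSE` the raw value
#'   \eqn{\sqrt\pi\exp\{\sum_i(e^{u_i} - e^{v_i})\}} is returned.
#' @param weights residual weights, only used when `normalised = FALSE`.
#' @param log return the log value.
#' @export
marginal_likelihood_spike <- function(weights = NULL, normalised = TRUE,
                                      log = FALSE) {
  lv <- 0.5 * base::log(pi)
  if (!normalised) {
    if (is.null(weights)) stop("weights needed for the unnormalised value")
    lv <- lv - sum(weights)
  }
  if (log) lv else exp(lv)
}

#' Posterior mixture-membership probabilities for one marker
#'
#' Combines the spike and slab marginal likelihoods with the current mixture
#' proportions into the posterior probability that marker `j` belongs to
#' each component (spike first). Probabilities are formed by a max-shifted
#' softmax over log marginals, so simultaneous underflow of all slabs can
#' never produce `NaN`.
#'
#' @inheritParams marginal_likelihood_slab
#' @param spec a [mixture_spec()] (constants and current proportions).
#' @return numeric vector of length `L + 1` summing to 1.
#' @export
inclusion_probabilities <- function(geno, j, data, weights, alpha, sigma2G,
                                    spec, rule = hermite_rule()) {
  ps <- compute_partial_sums(geno, j, weights)
  sdx <- sum(data$failure * geno_std(geno, j))
  lm <- cpp_marker_logmarg(ps$V0, ps$V1, ps$V2, ps$Vnm, sdx,
                           geno$sd[j], geno$xbar[j], alpha, sigma2G,
                           spec$constants, rule$points, rule$weights)
  lp <- ifelse(spec$pi > 0, base::log(spec$pi), -Inf) + lm
  p <- exp(lp - max(lp))
  p / sum(p)
}
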
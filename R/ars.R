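# Derivative-free adaptive rejection sampling: R-facing wrapper over the
# compiled sampler, plus the model's hard sampling limits.

#' Adaptive rejection sampling from a log-concave density
#'
#' Draws from the normalised restriction of `exp(log_density)` to
#' `[lower, upper]` using the derivative-free envelope construction: secants
#' of the log-density form the squeeze (lower hull), and their extensions
#' form the piecewise-linear upper hull; rejected proposals refine the
#' envelope. A detected concavity violation (target below the lower hull
#' beyond tolerance) is an error.
#'
#' @param log_density function of one numeric argument, concave on
#'   `[lower, upper]` (an additive constant is irrelevant).
#' @param init numeric vector of at least 3 initial abscissae; the usual
#'   recipe is `mode_proxy + c(-c, 0, c)` for a small positive `c`.
#' @param lower,upper finite sampling limits.
#' @param n number of draws (envelope rebuilt per draw; draws are exact and
#'   independent).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- ars_sample(function(z) -z^2 / 2, c(-1, 0, 1), -5, 5, 100)
ars_sample <- function(log_density, init, lower, upper, n = 1L) {
  stopifnot(is.function(log_density), length(init) >= 3L,
            is.finite(lower), is.finite(upper), lower < upper)
  cpp_ars_draw(function(x) as.numeric(log_density(x)),
               as.numeric(init), lower, upper, as.integer(n))
}

#' Hard sampling limits for the model conditionals
#'
#' The derivative-free sampler needs finite support. The intercept is
#' restricted to (2, 5) on the log-time scale (about 7.4 to 148 time units
#' after exponentiation), the shape to (0, 40); a marker effect is sampled
#' within its previous value \eqn{\pm 2\sqrt{C_k \sigma^2_G}}, which adapts
#' to the mixture; covariate effects get a wide default of the prior mean
#' \eqn{\pm 10} prior standard deviations.
#'
#' @param kind one of `"mu"`, `"alpha"`, `"beta"`, `"delta"`.
#' @param beta_old previous marker effect (for `kind = "beta"`).
#' @param Ck,sigma2G slab constant and group variance (for `kind = "beta"`).
#' @param hyper a [bw_hyper()] list (for `kind = "delta"`).
#' @return numeric `c(lower, upper)`.
#' @export
#' @examples
#' sampling_bounds("mu")
#' sampling_bounds("beta", beta_old = 0.1, Ck = 0.01, sigma2G = 0.25)
sampling_bounds <- function(kind = c("mu", "alpha", "beta", "delta"),
                            beta_old = 0, Ck = NULL, sigma2G = NULL,
                            hyper = bw_hyper()) {
  kind <- match.arg(kind)
  switch(kind,
    mu = c(2, 5),
    alpha = c(0, 40),
    beta = {
      if (is.null(Ck) || is.null(sigma2G))
        stop("beta bounds need Ck and sigma2G")
      hw <- 2 * sqrt(Ck * sigma2G)
      c(beta_old - hw, beta_old + hw)
    },
    delta = c(-10, 10) * sqrt(hyper$sigma2_delta)
  )
}
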
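# The user-facing model fit: formula interface, S3 object and methods.

#' Fit a Bayesian spike-and-slab Weibull model to a censored age-at-onset
#' phenotype
#'
#' Whole-genome accelerated failure time regression: the log event time is
#' Gumbel with mean \eqn{\mu + x_i'\beta + z_i'\delta} and variance
#' \eqn{\pi^2/(6\alpha^2)}; marker effects carry a (grouped) Dirac
#' spike-and-slab mixture prior \eqn{\beta_j \sim \pi_0\delta_0 + \sum_k
#' \pi_k N(0, C_k\sigma^2_G)}. Right censoring and left truncation enter the
#' likelihood exactly.
#'
#' @param formula a survival formula, e.g. `Surv(time, status) ~ 1` or
#'   `Surv(time, status) ~ sex + pc1`. A counting-process left-hand side
#'   `Surv(start, stop, status)` encodes left truncation (entry age
#'   `start`). Covariates are z-scored internally.
#' @param data data frame holding the formula variables.
#' @param genotypes a [genotype_matrix()].
#' @param groups optional marker-to-group assignment (vector of length `m`)
#'   giving each group its own mixture, proportions and genetic variance.
#' @param mixtures slab constants; a vector shared by all groups or a list
#'   per group. Defaults to `1e-5, 1e-4, 1e-3, 1e-2` (ungrouped); a grouped
#'   analysis conventionally uses `1e-4, ..., 1e-1`.
#' @param iterations,burnin,thinning chain controls (default: burn-in half
#'   the chain, thinning 5).
#' @param chains number of independent chains (seeds `seed`, `seed + 1`,
#'   ...).
#' @param quad_points Gauss-Hermite points for the marginal likelihoods
#'   (default 25).
#' @param workers,sync_rate bulk-synchronous-parallel controls; the defaults
#'   run the serial algorithm.
#' @param hyper a [bw_hyper()].
#' @param seed integer seed making the fit reproducible.
#' @param keep_genotypes store the genotype object in the fit (needed by
#'   [ppwv()] and training-set prediction; default `TRUE`).
#' @param control passed to [gibbs_serial()].
#'
#' @return An object of class `bayesw`: the call, the per-chain `bw_samples`,
#'   pooled posterior summaries, the heritability samples (see
#'   [heritability()]) and per-marker posterior inclusion probabilities.
#' @seealso [summary.bayesw()], [predict.bayesw()], [heritability()],
#'   [pip()], [ppwv()]
#' @export
#' @examples
#' set.seed(7)
#' sim <- simulate_survival_study(n = 150, m = 60, p_causal = 5, h2 = 0.5)
#' df <- data.frame(time = sim$data$time, status = sim$data$failure)
#' fit <- bayesw(survival::Surv(time, status) ~ 1, df, sim$genotypes,
#'               mixtures = c(0.01, 0.1), iterations = 300, seed = 1)
#' fit
bayesw <- function(formula, data, genotypes, groups = NULL,
                   mixtures = c(1e-5, 1e-4, 1e-3, 1e-2),
                   iterations = 2000, burnin = floor(iterations / 2),
                   thinning = 5, chains = 1, quad_points = 25,
                   workers = 1, sync_rate = 1, hyper = bw_hyper(),
                   seed = NULL, keep_genotypes = TRUE, control = list()) {
  cl <- match.call()
  stopifnot(inherits(genotypes, "bw_geno"))
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!inherits(y, "Surv")) stop("the formula left-hand side must be a Surv object")
  ytype <- attr(y, "type")
  if (ytype == "right") {
    time <- y[, "time"]; status <- y[, "status"]; trunc <- 0
  } else if (ytype == "counting") {
    time <- y[, "stop"]; status <- y[, "status"]; trunc <- y[, "start"]
  } else stop("only right-censored or counting (left-truncated) Surv supported")
  X <- model.matrix(terms(mf), mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  sdata <- survival_data(time, status, trunc,
                         covariates = if (ncol(X)) X else NULL)

  layout <- group_layout(genotypes$m, groups, mixtures)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  runs <- lapply(seq_len(chains), function(ch) {
    run_engine(genotypes, sdata, layout, hyper, iterations, burnin,
               thinning, quad_points, workers, sync_rate,
               seed = seed + ch - 1L, control = control)
  })

  beta_all <- do.call(cbind, lapply(runs, `[[`, "beta"))
  gamma_all <- do.call(cbind, lapply(runs, `[[`, "gamma"))
  alpha_all <- unlist(lapply(runs, `[[`, "alpha"))
  sig_all <- do.call(rbind, lapply(runs, `[[`, "sigma2G"))
  # realized genetic variance per retained draw (see heritability())
  Xs <- geno_std(genotypes)
  G <- Xs %*% beta_all
  vg <- apply(G, 2, var)
  verr <- pi^2 / (6 * alpha_all^2)
  fit <- structure(list(
    call = cl, formula = formula, chains = runs, n_chains = chains,
    data = sdata, layout = layout, mixtures = mixtures,
    genotypes = if (keep_genotypes) genotypes else NULL,
    marker_ids = genotypes$ids,
    geno_stats = list(xbar = genotypes$xbar, sd = genotypes$sd),
    beta = beta_all, gamma = gamma_all,
    alpha = alpha_all, mu = unlist(lapply(runs, `[[`, "mu")),
    delta = do.call(rbind, lapply(runs, `[[`, "delta")),
    sigma2G = sig_all,
    h2 = vg / (vg + verr),
    h2_hyper = rowSums(sig_all) / (rowSums(sig_all) + verr),
    var_g = vg,
    pip = rowMeans(gamma_all > 0),
    seed = seed
  ), class = "bayesw")
  fit
}

#' Posterior inclusion probabilities of a fit
#'
#' Fraction of retained draws in which each marker sits in any non-spike
#' component.
#'
#' @param fit a [bayesw()] fit.
#' @return named numeric vector, one entry per marker.
#' @export
pip <- function(fit) {
  stopifnot(inherits(fit, "bayesw"))
  setNames(fit$pip, fit$marker_ids)
}

#' Log-scale SNP heritability
#'
#' Per retained draw, the share of log-time variance attributable to the
#' markers: \eqn{h^2_t = V_{G,t}/(V_{G,t} + \pi^2/(6\alpha_t^2))}, where the
#' Gumbel error variance comes from the sampled shape. By default
#' \eqn{V_{G,t}} is the realized genetic variance, the variance over
#' individuals of \eqn{X\beta_t}; `genetic_variance = "hyper"` instead uses
#' the sampled variance hyperparameter \eqn{\sum_\varphi
#' \sigma^2_{G\varphi}}. The realized version is invariant to the placement
#' of the slab-constant grid and is the default (see the methods vignette).
#'
#' @param fit a [bayesw()] fit.
#' @param genetic_variance `"realized"` (default) or `"hyper"`.
#' @param level central credible-interval level.
#' @return list of class `bw_h2` with `samples`, `mean`, `ci`.
#' @export
heritability <- function(fit, genetic_variance = c("realized", "hyper"),
                         level = 0.95) {
  stopifnot(inherits(fit, "bayesw"))
  genetic_variance <- match.arg(genetic_variance)
  h <- if (genetic_variance == "realized") fit$h2 else fit$h2_hyper
  a <- (1 - level) / 2
  structure(list(samples = h, mean = mean(h),
                 ci = unname(quantile(h, c(a, 1 - a))),
                 level = level, genetic_variance = genetic_variance),
            class = "bw_h2")
}

#' @export
print.bw_h2 <- function(x, ...) {
  cat(sprintf("Log-scale SNP heritability (%s): %.3f [%.3f, %.3f] (%.0f%% CI)\n",
              x$genetic_variance, x$mean, x$ci[1], x$ci[2], 100 * x$level))
  invisible(x)
}

#' @export
print.bayesw <- function(x, ...) {
  cat("Bayesian spike-and-slab Weibull regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  %d individuals (%d events), %d markers, %d chain(s) x %d draws\n",
              x$data$n, x$data$d, nrow(x$beta), x$n_chains,
              ncol(x$beta) / x$n_chains))
  cat(sprintf("  posterior mean shape %.3f, intercept %.3f, h2 %.3f\n",
              mean(x$alpha), mean(x$mu), mean(x$h2)))
  cat(sprintf("  markers in model (posterior mean): %.1f\n",
              mean(colSums(x$gamma > 0))))
  invisible(x)
}

#' @export
summary.bayesw <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  qs <- function(v) c(mean = mean(v), sd = sd(v),
                      lwr = unname(quantile(v, a)),
                      upr = unname(quantile(v, 1 - a)))
  hyp <- rbind(alpha = qs(object$alpha), mu = qs(object$mu),
               h2 = qs(object$h2),
               var_g = qs(object$var_g),
               n_markers = qs(colSums(object$gamma > 0)))
  if (length(object$delta))
    hyp <- rbind(hyp, t(vapply(seq_len(ncol(object$delta)), function(q)
      qs(object$delta[, q]), numeric(4))))
  groups <- t(vapply(seq_len(ncol(object$sigma2G)), function(g)
    qs(object$sigma2G[, g]), numeric(4)))
  rownames(groups) <- paste0("sigma2G[", object$layout$labels, "]")
  out <- list(call = object$call, table = hyp, groups = groups,
              level = level,
              top = head(sort(pip(object), decreasing = TRUE), 10))
  class(out) <- "summary.bayesw"
  out
}

#' @export
print.summary.bayesw <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\nPosterior summaries (%.0f%% central intervals):\n",
              100 * x$level))
  print(round(x$table, 4))
  cat("\nGroup genetic variances:\n")
  print(signif(x$groups, 4))
  cat("\nTop posterior inclusion probabilities:\n")
  print(round(x$top, 3))
  invisible(x)
}

#' @export
coef.bayesw <- function(object, ...) {
  setNames(rowMeans(object$beta), object$marker_ids)
}

#' @export
#' @method residuals bayesw
residuals.bayesw <- function(object, ...) {
  if (is.null(object$genotypes))
    stop("fit was run with keep_genotypes = FALSE")
  r <- build_residuals(object$data, object$genotypes, mean(object$mu),
                       mean(object$alpha), rowMeans(object$beta),
                       if (length(object$delta)) colMeans(object$delta),
                       Z = scale_covariates(object))
  r$eps
}

scale_covariates <- function(fit, Z = fit$data$covariates) {
  if (is.null(Z)) return(NULL)
  scale(Z, center = fit$chains[[1]]$covariate_center,
        scale = fit$chains[[1]]$covariate_scale)
}

#' Predict genetic values and event times from a fit
#'
#' `type = "genetic"` returns the genomic predictor \eqn{\hat g = X\beta}:
#' per retained draw the standardised genotypes are multiplied with that
#' draw's effects, and the point predictor is the per-individual mean across
#' draws (`posterior = TRUE` returns the full draw matrix). New genotypes
#' are standardised with their own cohort means/SDs and matched to the
#' training markers by identifier. `type = "interval"` additionally draws
#' one Weibull event time per posterior draw from the implied survival
#' function and returns central posterior-predictive time intervals.
#'
#' @param object a [bayesw()] fit.
#' @param genotypes a [genotype_matrix()] for the prediction cohort
#'   (default: the training genotypes).
#' @param covariates covariate matrix for the prediction cohort (original
#'   scale; standardised with the training centring). Required at
#'   `type = "interval"` when the model has covariates.
#' @param type `"genetic"` or `"interval"`.
#' @param level credible level of the prediction interval.
#' @param posterior return per-draw values instead of summaries.
#' @param ... unused.
#' @return For `"genetic"`: numeric vector (or matrix with
#'   `posterior = TRUE`). For `"interval"`: data frame with `fit` (posterior
#'   median time), `lwr`, `upr`.
#' @export
predict.bayesw <- function(object, genotypes = NULL, covariates = NULL,
                           type = c("genetic", "interval"), level = 0.95,
                           posterior = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(genotypes)) {
    genotypes <- object$genotypes
    if (is.null(genotypes))
      stop("fit was run with keep_genotypes = FALSE; supply genotypes")
  }
  idx <- match(object$marker_ids, genotypes$ids)
  if (anyNA(idx))
    stop("prediction genotypes lack trained markers: ",
         paste(head(object$marker_ids[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) ", ...")
  Xs <- geno_std(genotypes, idx)
  G <- Xs %*% object$beta                       # individuals x draws
  if (type == "genetic") {
    if (posterior) return(G)
    return(rowMeans(G))
  }
  S <- ncol(G); n <- nrow(G)
  zoff <- 0
  if (length(object$delta)) {
    if (is.null(covariates))
      stop("model has covariates; supply 'covariates' for interval prediction")
    Zs <- scale_covariates(object, as.matrix(covariates))
    zoff <- Zs %*% t(object$delta)             # n x S
  }
  K <- euler_gamma()
  logb <- sweep(G + zoff, 2, object$mu + K / object$alpha, "+")
  # one Weibull draw per posterior draw: y = b * (-log U)^(1/alpha)
  U <- matrix(runif(n * S), n, S)
  logy <- logb + sweep(log(-log(U)), 2, 1 / object$alpha, "*")
  a <- (1 - level) / 2
  qs <- t(apply(logy, 1, quantile, probs = c(0.5, a, 1 - a)))
  data.frame(fit = exp(qs[, 1]), lwr = exp(qs[, 2]), upr = exp(qs[, 3]))
}

#' @export
plot.bayesw <- function(x, which = c("h2", "alpha", "mu", "ngamma"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  oldpar <- graphics::par(mfrow = c(length(which), 1),
                          mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(oldpar))
  tr <- list(h2 = x$h2, alpha = x$alpha, mu = x$mu,
             ngamma = colSums(x$gamma > 0))
  lab <- c(h2 = "heritability", alpha = "shape alpha", mu = "intercept mu",
           ngamma = "markers in model")
  for (w in which) {
    graphics::plot(tr[[w]], type = "l", ylab = lab[w], xlab = "retained draw",
                   main = "")
  }
  invisible(x)
}
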
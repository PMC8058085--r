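# Post-processing: LD clumping, region-based significance (PPWV), and
# evaluation metrics (precision-recall, FDR vs PIP, Harrell's C, martingale
# residuals).

#' Greedy LD clumping
#'
#' Partitions markers into clumps around index SNPs: markers are ranked (by
#' a supplied score, e.g. posterior inclusion probability, or by minor
#' allele frequency when no fit is available), the best unassigned marker
#' becomes an index, and every unassigned marker within `window_bp` whose
#' squared correlation with the index reaches `r2_threshold` joins its
#' clump. Index SNPs of different clumps therefore correlate below the
#' threshold within the window.
#'
#' @param geno a [genotype_matrix()] with positions.
#' @param window_bp physical window (default 10 Mb).
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param rank optional per-marker ranking score (higher first); default
#'   MAF.
#' @return named list of marker-index vectors, class `bw_regions`, with
#'   attribute `index` (the index SNP of each clump) and provenance
#'   `"ld_clump"`.
#' @export
ld_clump <- function(geno, window_bp = 10e6, r2_threshold = 0.1,
                     rank = NULL) {
  m <- geno$m
  if (is.null(rank)) rank <- pmin(geno$xbar / 2, 1 - geno$xbar / 2)
  ord <- order(rank, decreasing = TRUE)
  Xs <- geno_std(geno)
  n <- geno$n
  assigned <- logical(m)
  regions <- list(); index <- integer(0)
  for (j in ord) {
    if (assigned[j]) next
    wnd <- which(!assigned & geno$chr == geno$chr[j] &
                   abs(geno$pos - geno$pos[j]) <= window_bp)
    r2 <- as.vector(crossprod(Xs[, wnd, drop = FALSE], Xs[, j]) / (n - 1))^2
    members <- wnd[r2 >= r2_threshold | wnd == j]
    members <- sort(unique(c(j, members)))
    assigned[members] <- TRUE
    regions[[length(regions) + 1L]] <- members
    index <- c(index, j)
  }
  names(regions) <- geno$ids[index]
  structure(regions, index = index, provenance = "ld_clump",
            class = "bw_regions")
}

#' Cap region size by random subsampling
#'
#' Regions larger than `cap` markers are randomly thinned to `cap`, making
#' large (e.g. gene-window) regions comparable.
#'
#' @param regions a list of marker-index vectors (e.g. [ld_clump()] output).
#' @param cap maximum markers per region (default 250).
#' @export
region_cap_subsample <- function(regions, cap = 250) {
  out <- lapply(regions, function(r)
    if (length(r) > cap) sort(sample(r, cap)) else r)
  attributes(out) <- attributes(regions)
  out
}

#' Posterior probability of the window variance (PPWV)
#'
#' For each region and retained draw, the genetic variance of the region is
#' the variance over individuals of \eqn{X_{region}\beta_{region}}; its
#' share of that draw's total genetic variance is compared against each
#' threshold, and the PPWV is the fraction of draws in which the share
#' reaches the threshold. Default thresholds are 1/100,000, 1/10,000 and
#' 1/1000 of the total genetic variance.
#'
#' @param fit a [bayesw()] fit (with stored genotypes).
#' @param regions a `bw_regions` list (or any named list of marker indices).
#' @param thresholds variance-share thresholds.
#' @return data frame (region, threshold, ppwv), class `bw_ppwv`; PPWV is
#'   monotone non-increasing in the threshold within a region.
#' @export
ppwv <- function(fit, regions, thresholds = c(1e-5, 1e-4, 1e-3)) {
  stopifnot(inherits(fit, "bayesw"))
  if (!length(regions)) stop("no regions supplied")
  if (any(lengths(regions) == 0)) stop("empty region")
  geno <- fit$genotypes
  if (is.null(geno)) stop("fit was run with keep_genotypes = FALSE")
  vtot <- fit$var_g
  vtot[vtot == 0] <- .Machine$double.eps
  share <- vapply(regions, function(r) {
    Xr <- geno_std(geno, r)
    # region covariance once, then beta' Sigma beta per draw
    Sg <- crossprod(scale(Xr, scale = FALSE)) / (geno$n - 1)
    B <- fit$beta[r, , drop = FALSE]
    colSums(B * (Sg %*% B)) / vtot
  }, numeric(ncol(fit$beta)))
  out <- expand.grid(region = names(regions), threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$ppwv <- mapply(function(rg, th) mean(share[, rg] >= th),
                     out$region, out$threshold)
  class(out) <- c("bw_ppwv", "data.frame")
  out
}

#' Precision-recall curve for marker (or region) discovery
#'
#' At every score cut: precision = TP/(TP+FP) (= 1 - FDR) and recall =
#' TP/(TP+FN), with causal status given by `truth`.
#'
#' @param scores per-marker or per-region scores (e.g. PIP or PPWV).
#' @param truth logical (or 0/1) causal status, same length.
#' @param cuts score cuts; default all distinct score values.
#' @return data frame (cut, tp, fp, fn, precision, recall).
#' @export
precision_recall <- function(scores, truth, cuts = NULL) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (is.null(cuts)) cuts <- sort(unique(scores))
  res <- t(vapply(cuts, function(ct) {
    sel <- scores >= ct
    tp <- sum(sel & truth); fp <- sum(sel & !truth)
    fn <- sum(!sel & truth)
    c(tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / (tp + fn))
  }, numeric(5)))
  data.frame(cut = cuts, res)
}

#' False discovery rate along a PIP grid
#'
#' Mean FDR of selecting all markers with PIP at or above each grid value;
#' grid points above the maximum observed PIP yield no selection and are
#' reported as `NA`.
#'
#' @param pip posterior inclusion probabilities.
#' @param truth causal status.
#' @param grid PIP cuts (default `seq(0, 1, 0.05)`).
#' @export
fdr_vs_pip <- function(pip, truth, grid = seq(0, 1, 0.05)) {
  truth <- as.logical(truth)
  fdr <- vapply(grid, function(ct) {
    sel <- pip >= ct
    if (!any(sel)) return(NA_real_)
    sum(sel & !truth) / sum(sel)
  }, numeric(1))
  data.frame(cut = grid, fdr = fdr)
}

#' Harrell's concordance statistic
#'
#' Among usable pairs (the member with the earlier recorded time had the
#' event), the fraction in which the predictor orders the pair correctly,
#' counting ties as one half. The convention is that a larger predictor
#' means longer predicted survival.
#'
#' @param predictor per-individual predictions (higher = later event).
#' @param time recorded times.
#' @param failure 0/1 event indicators.
#' @export
#' @examples
#' harrell_c(c(3, 2, 1), time = c(5, 4, 1), failure = c(1, 1, 1))  # 1
harrell_c <- function(predictor, time, failure) {
  n <- length(time)
  stopifnot(length(predictor) == n, length(failure) == n)
  conc <- 0; usable <- 0
  for (i in seq_len(n)) {
    if (failure[i] != 1) next
    later <- which(time > time[i])
    usable <- usable + length(later)
    conc <- conc + sum(predictor[i] < predictor[later]) +
      0.5 * sum(predictor[i] == predictor[later])
  }
  if (usable == 0) stop("no usable pairs (no comparable event times)")
  conc / usable
}

#' Martingale residuals under a proportional-hazards baseline
#'
#' \eqn{\hat M_i = d_i - \hat\Lambda_0(t_i) e^{z_i'\hat\gamma}} with the
#' Nelson-Aalen (Breslow) baseline cumulative hazard and \eqn{\hat\gamma}
#' from a Cox partial-likelihood fit on the covariates (zero when there are
#' none). Used to residualise a phenotype on fixed covariates before
#' marker-level regression comparisons.
#'
#' @param time recorded times.
#' @param failure 0/1 event indicators.
#' @param covariates optional covariate matrix.
#' @return per-individual residuals.
#' @export
martingale_residuals <- function(time, failure, covariates = NULL) {
  n <- length(time)
  risk <- rep(1, n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    fit <- survival::coxph(survival::Surv(time, failure) ~ covariates,
                           ties = "breslow")
    risk <- exp(as.vector(covariates %*% coef(fit)))
  }
  # Breslow/Nelson-Aalen baseline: sum over event times s <= t of
  # (#events at s) / (sum of risk scores at risk at s)
  ev <- sort(unique(time[failure == 1]))
  denom <- vapply(ev, function(s) sum(risk[time >= s]), numeric(1))
  dcount <- vapply(ev, function(s) sum(time == s & failure == 1), numeric(1))
  haz <- cumsum(dcount / denom)
  L0 <- vapply(time, function(t) {
    k <- findInterval(t, ev)
    if (k == 0) 0 else haz[k]
  }, numeric(1))
  failure - L0 * risk
}
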
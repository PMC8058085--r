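#' Sparse genotype matrix
#'
#' Stores hard-called 0/1/2 allele counts through per-marker carrier index
#' sets (individuals with count 1, count 2, and missing) plus per-marker
#' means and standard deviations. The standardised column
#' \eqn{x_{ij} = (\xi_{ij} - \bar\xi_j)/s_j} then takes one of three values
#' per marker, which is what makes the sparse partial-sum algebra of the
#' sampler possible. Missing genotypes are mean-imputed, i.e. standardised to
#' exactly 0, and never enter a carrier set.
#'
#' @param counts integer/numeric matrix of allele counts (individuals x
#'   markers); `NA` marks missing calls.
#' @param ids,chr,pos,a1,a2 optional marker metadata (identifier, chromosome,
#'   base-pair position, alleles).
#' @param drop_monomorphic drop markers whose non-missing counts have zero
#'   variance (default `TRUE`; otherwise such markers are an error).
#'
#' @return An object of class `bw_geno` with elements `n`, `m`, `idx1`,
#'   `idx2`, `idxm` (lists of 1-based index vectors), `xbar`, `sd`, and the
#'   metadata vectors. Dense standardised columns can be recovered with
#'   [geno_std()] / [as.matrix()].
#' @export
genotype_matrix <- function(counts, ids = NULL, chr = NULL, pos = NULL,
                            a1 = NULL, a2 = NULL, drop_monomorphic = TRUE) {
  counts <- as.matrix(counts)
  n <- nrow(counts); m <- ncol(counts)
  if (m == 0L) stop("no markers supplied")
  ok <- counts %in% c(0, 1, 2) | is.na(counts)
  if (!all(ok)) stop("genotype counts must be 0, 1, 2 or NA")
  if (is.null(ids)) ids <- if (!is.null(colnames(counts))) colnames(counts)
                           else paste0("snp", seq_len(m))
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("B", m)

  xbar <- colMeans(counts, na.rm = TRUE)
  sdv <- apply(counts, 2, sd, na.rm = TRUE)
  nmiss <- colSums(is.na(counts))
  bad <- !is.finite(sdv) | sdv <= 0 | nmiss == n
  if (any(bad)) {
    if (!drop_monomorphic)
      stop(sprintf("%d monomorphic or all-missing marker(s)", sum(bad)))
    message(sprintf("dropping %d monomorphic or all-missing marker(s)",
                    sum(bad)))
    keep <- !bad
    counts <- counts[, keep, drop = FALSE]
    ids <- ids[keep]; chr <- chr[keep]; pos <- pos[keep]
    a1 <- a1[keep]; a2 <- a2[keep]
    xbar <- xbar[keep]; sdv <- sdv[keep]
    m <- ncol(counts)
    if (m == 0L) stop("no polymorphic markers left")
  }
  idx1 <- vector("list", m); idx2 <- vector("list", m); idxm <- vector("list", m)
  for (j in seq_len(m)) {
    cj <- counts[, j]
    idx1[[j]] <- which(!is.na(cj) & cj == 1)
    idx2[[j]] <- which(!is.na(cj) & cj == 2)
    idxm[[j]] <- which(is.na(cj))
  }
  structure(list(n = n, m = m, idx1 = idx1, idx2 = idx2, idxm = idxm,
                 xbar = unname(xbar), sd = unname(sdv),
                 ids = as.character(ids), chr = chr, pos = as.numeric(pos),
                 a1 = a1, a2 = a2),
            class = "bw_geno")
}

#' @export
print.bw_geno <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers\n", x$n, x$m))
  cat(sprintf("  MAF range %.3f-%.3f, %d markers with missing calls\n",
              min(pmin(x$xbar / 2, 1 - x$xbar / 2)),
              max(pmin(x$xbar / 2, 1 - x$xbar / 2)),
              sum(lengths(x$idxm) > 0)))
  invisible(x)
}

#' @export
dim.bw_geno <- function(x) c(x$n, x$m)

#' Dense standardised genotype column(s)
#'
#' Reconstructs the standardised column \eqn{(\xi - \bar\xi_j)/s_j} from the
#' carrier index sets; missing entries are exactly 0 (mean imputation).
#'
#' @param geno a [genotype_matrix()].
#' @param j marker indices (default all).
#' @return numeric matrix `n x length(j)`.
#' @export
geno_std <- function(geno, j = seq_len(geno$m)) {
  out <- matrix(0, geno$n, length(j))
  for (k in seq_along(j)) {
    jj <- j[k]
    x <- rep(-geno$xbar[jj] / geno$sd[jj], geno$n)
    x[geno$idx1[[jj]]] <- (1 - geno$xbar[jj]) / geno$sd[jj]
    x[geno$idx2[[jj]]] <- (2 - geno$xbar[jj]) / geno$sd[jj]
    x[geno$idxm[[jj]]] <- 0
    out[, k] <- x
  }
  colnames(out) <- geno$ids[j]
  out
}

#' @export
#' @rdname geno_std
#' @param x a `bw_geno` object.
#' @param ... unused.
as.matrix.bw_geno <- function(x, ...) geno_std(x)

#' Raw allele counts for selected markers
#' @inheritParams geno_std
#' @return integer matrix with `NA` for missing calls.
#' @export
geno_counts <- function(geno, j = seq_len(geno$m)) {
  out <- matrix(0L, geno$n, length(j))
  for (k in seq_along(j)) {
    jj <- j[k]
    ct <- rep(0L, geno$n)
    ct[geno$idx1[[jj]]] <- 1L
    ct[geno$idx2[[jj]]] <- 2L
    ct[geno$idxm[[jj]]] <- NA_integer_
    out[, k] <- ct
  }
  colnames(out) <- geno$ids[j]
  out
}

# ---- sparse partial-sum algebra ---------------------------------------------

#' Partial sums of residual weights over genotype classes
#'
#' For marker `j` and per-individual weights \eqn{e^{v_i} - e^{u_i}} (event
#' minus truncation exponentials), returns the three genotype-class sums
#' \eqn{V_0, V_1, V_2} used by every sparse update, plus the missing-class
#' sum and totals.
#'
#' @param geno a [genotype_matrix()].
#' @param j marker index.
#' @param weights numeric vector of per-individual residual weights.
#' @return list with `V0`, `V1`, `V2`, `Vmiss`, `Vnm` (= V0+V1+V2) and
#'   `Vtot` (= Vnm + Vmiss, the dense total over all individuals).
#' @export
compute_partial_sums <- function(geno, j, weights) {
  stopifnot(length(weights) == geno$n)
  V1 <- sum(weights[geno$idx1[[j]]])
  V2 <- sum(weights[geno$idx2[[j]]])
  Vmiss <- sum(weights[geno$idxm[[j]]])
  Vtot <- sum(weights)
  V0 <- Vtot - V1 - V2 - Vmiss
  list(V0 = V0, V1 = V1, V2 = V2, Vmiss = Vmiss,
       Vnm = V0 + V1 + V2, Vtot = Vtot)
}

#' Sparse weighted sum of squared standardised genotypes
#'
#' Computes \eqn{\sum_i x_{ij}^2 (e^{v_i} - e^{u_i})} from the partial sums:
#' \deqn{\frac{1}{s_j^2}\left[(1-2\bar\xi_j)V_1 + 4(1-\bar\xi_j)V_2 +
#'   \bar\xi_j^2 (V_0+V_1+V_2)\right].}
#' This is the data term of the quadrature scale \eqn{\hat\sigma_k}.
#'
#' @param geno,j as in [compute_partial_sums()].
#' @param partial output of [compute_partial_sums()].
#' @export
sparse_sigma_hat_term <- function(geno, j, partial) {
  xb <- geno$xbar[j]; s2 <- geno$sd[j]^2
  ((1 - 2 * xb) * partial$V1 + 4 * (1 - xb) * partial$V2 +
      xb^2 * partial$Vnm) / s2
}

#' Sparse evaluation of the quadrature-node weighted sum
#'
#' Computes \eqn{\sum_i (e^{v_i} - e^{u_i})(1 - e^{-\alpha x_{ij} c})} for a
#' step `c` in the marker effect, using only the three genotype-class sums:
#' \deqn{V_{nm} - e^{\alpha\bar\xi_j c/s_j}\left[V_0 + e^{-\alpha c/s_j}V_1 +
#'   e^{-2\alpha c/s_j}V_2\right].}
#'
#' @param geno,j,partial as in [sparse_sigma_hat_term()].
#' @param alpha Weibull shape.
#' @param step the effect-size step `c` (e.g. a quadrature node mapped to the
#'   effect scale).
#' @export
sparse_quadrature_sum <- function(geno, j, partial, alpha, step) {
  e <- alpha * step / geno$sd[j]
  partial$Vnm - exp(geno$xbar[j] * e) *
    (partial$V0 + exp(-e) * partial$V1 + exp(-2 * e) * partial$V2)
}

# ---- residual container -----------------------------------------------------

#' Build model residuals from scratch
#'
#' Computes \eqn{\epsilon_i = \log y_i - \mu - x_i'\beta - z_i'\delta}, the
#' event exponentials \eqn{e^{v_i}} with \eqn{v_i = \alpha\epsilon_i - K}, and
#' the truncation exponentials \eqn{e^{u_i}} (exactly 0 where the truncation
#' age is 0).
#'
#' @param data a [survival_data()] object.
#' @param geno a [genotype_matrix()]; may be `NULL` when `beta` is zero.
#' @param mu intercept (log-time scale).
#' @param alpha Weibull shape, must be positive.
#' @param beta per-marker effects (default all zero).
#' @param delta covariate effects (on the possibly standardised covariates
#'   supplied in `Z`).
#' @param Z covariate matrix used with `delta`; defaults to
#'   `data$covariates`.
#' @return list of class `bw_resid` with `eps`, `exp_event`, `exp_trunc` and
#'   `weight` (= `exp_event - exp_trunc`).
#' @export
build_residuals <- function(data, geno = NULL, mu, alpha, beta = NULL,
                            delta = NULL, Z = data$covariates) {
  if (alpha <= 0) stop("alpha must be positive")
  eps <- data$log_time - mu
  if (!is.null(beta) && any(beta != 0)) {
    nz <- which(beta != 0)
    eps <- eps - as.vector(geno_std(geno, nz) %*% beta[nz])
  }
  if (!is.null(delta) && length(delta))
    eps <- eps - as.vector(Z %*% delta)
  v <- alpha * eps - euler_gamma()
  v <- pmin(v, 700)
  exp_event <- exp(v)
  # u_i differs from v_i only through log(a_i) replacing log(y_i)
  lshift <- data$log_trunc - data$log_time
  exp_trunc <- ifelse(is.finite(lshift), exp_event * exp(alpha * lshift), 0)
  structure(list(eps = eps, exp_event = exp_event, exp_trunc = exp_trunc,
                 weight = exp_event - exp_trunc), class = "bw_resid")
}

#' Sparse single-marker residual update
#'
#' Updates residuals after changing one marker effect from `beta_old` to
#' `beta_new`, touching only the carrier index sets plus a shared scalar
#' shift (the \eqn{-\bar\xi_j/s_j} part of the standardised column is common
#' to all non-missing individuals). The exponentials are refreshed with the
#' multiplicative three-factor form rather than recomputed from `eps`.
#'
#' @param resid a `bw_resid` object consistent with `beta_old`.
#' @param geno,j marker.
#' @param beta_new,beta_old marker effect before/after.
#' @param alpha Weibull shape.
#' @return the updated `bw_resid`.
#' @export
sparse_residual_update <- function(resid, geno, j, beta_new, beta_old, alpha) {
  db <- beta_new - beta_old
  if (db == 0) return(resid)
  s <- geno$sd[j]; xb <- geno$xbar[j]
  i1 <- geno$idx1[[j]]; i2 <- geno$idx2[[j]]; im <- geno$idxm[[j]]
  # eps <- eps - x_j * db, decomposed as shared shift + carrier corrections
  resid$eps <- resid$eps + xb * db / s
  resid$eps[i1] <- resid$eps[i1] - db / s
  resid$eps[i2] <- resid$eps[i2] - 2 * db / s
  resid$eps[im] <- resid$eps[im] - xb * db / s
  g0 <- exp(alpha * xb * db / s)
  f1 <- exp(-alpha * db / s)
  resid$exp_event <- resid$exp_event * g0
  resid$exp_event[i1] <- resid$exp_event[i1] * f1
  resid$exp_event[i2] <- resid$exp_event[i2] * f1^2
  resid$exp_event[im] <- resid$exp_event[im] / g0
  nz <- resid$exp_trunc > 0
  if (any(nz)) {
    resid$exp_trunc <- resid$exp_trunc * g0
    resid$exp_trunc[i1] <- resid$exp_trunc[i1] * f1
    resid$exp_trunc[i2] <- resid$exp_trunc[i2] * f1^2
    resid$exp_trunc[im] <- resid$exp_trunc[im] / g0
    resid$exp_trunc[!nz] <- 0
  }
  resid$weight <- resid$exp_event - resid$exp_trunc
  resid
}
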
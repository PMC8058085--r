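# Post-processing: clumping, PPWV, prediction, metrics.

# small fitted model reused across several tests
fit_small <- local({
  set.seed(81)
  sim <- simulate_survival_study(n = 600, m = 120, p_causal = 6, h2 = 0.5)
  df <- data.frame(time = sim$data$time, status = sim$data$failure)
  fit <- bayesw(survival::Surv(time, status) ~ 1, df, sim$genotypes,
                mixtures = c(0.01, 0.1), iterations = 600, seed = 4)
  list(sim = sim, fit = fit)
})

test_that("heritability follows its defining ratio", {
  fit <- fit_small$fit
  h <- heritability(fit)
  expect_true(all(h$samples >= 0 & h$samples <= 1))
  expect_equal(h$mean, mean(fit$var_g / (fit$var_g + pi^2 / (6 * fit$alpha^2))))
  # hyper variant: equal variance components give exactly one half
  fake <- fit
  fake$sigma2G <- matrix(pi^2 / (6 * fit$alpha^2), length(fit$alpha), 1)
  fake$h2_hyper <- rowSums(fake$sigma2G) /
    (rowSums(fake$sigma2G) + pi^2 / (6 * fit$alpha^2))
  expect_equal(unique(round(heritability(fake, "hyper")$samples, 12)), 0.5)
  # genetic variance -> 0 gives h2 -> 0
  fake$sigma2G <- matrix(1e-300, length(fit$alpha), 1)
  fake$h2_hyper <- rowSums(fake$sigma2G) /
    (rowSums(fake$sigma2G) + pi^2 / (6 * fit$alpha^2))
  expect_lt(heritability(fake, "hyper")$mean, 1e-290)
})

test_that("LD clumping separates correlated from independent markers", {
  # 3 markers: 1 and 2 nearly duplicated (r2 ~ 0.9), 3 independent
  set.seed(82)
  n <- 500
  g1 <- rbinom(n, 2, 0.4)
  g2 <- g1; flip <- sample(n, 25); g2[flip] <- rbinom(25, 2, 0.4)
  g3 <- rbinom(n, 2, 0.4)
  geno <- genotype_matrix(cbind(g1, g2, g3), pos = c(100, 200, 300))
  expect_gt(cor(g1, g2)^2, 0.5)
  cl <- ld_clump(geno, window_bp = 1e6, r2_threshold = 0.1)
  expect_equal(length(cl), 2L)
  expect_equal(sort(unname(lengths(cl))), c(1L, 2L))
  # r2 threshold 1: every marker its own clump
  cl1 <- ld_clump(geno, r2_threshold = 1)
  expect_equal(length(cl1), 3L)
  expect_true(all(lengths(cl1) == 1L))
  # every marker assigned exactly once
  expect_equal(sort(unname(unlist(cl))), 1:3)
  expect_identical(attr(cl, "provenance"), "ld_clump")
  # defaults as documented
  expect_equal(formals(ld_clump)$window_bp, 10e6)
  expect_equal(formals(ld_clump)$r2_threshold, 0.1)
})

test_that("PPWV behaves at its extremes and is monotone in the threshold", {
  fit <- fit_small$fit
  causal <- fit_small$sim$truth$causal
  nulls <- setdiff(seq_len(120), causal)[1:10]
  # region holding every marker with signal vs a pure-null region
  regions <- structure(list(all_signal = causal, none = nulls),
                       class = "bw_regions")
  tab <- ppwv(fit, regions, thresholds = c(1e-5, 1e-3, 0.05))
  all_sig <- tab$ppwv[tab$region == "all_signal"]
  expect_true(all(all_sig[tab$threshold[tab$region == "all_signal"] <= 1e-3]
                  > 0.95))
  expect_true(all(diff(all_sig[order(tab$threshold[tab$region ==
                                                     "all_signal"])]) <= 0))
  # a region whose effects are exactly zero in every draw
  zero_j <- which(rowSums(fit$beta != 0) == 0)[1:3]
  expect_false(anyNA(zero_j))
  tab0 <- ppwv(fit, list(z = zero_j), thresholds = 1e-5)
  expect_equal(tab0$ppwv, 0)
  expect_error(ppwv(fit, list()), "no regions")
  expect_error(ppwv(fit, list(a = integer(0))), "empty region")
})

test_that("disjoint full partition of uncorrelated markers explains ~all variance", {
  fit <- fit_small$fit
  parts <- split(seq_len(120), rep(1:6, each = 20))
  geno <- fit$genotypes
  draws <- which(fit$var_g > 1e-10)
  share_sum <- rowSums(vapply(parts, function(r) {
    Xr <- geno_std(geno, r)
    Sg <- crossprod(scale(Xr, scale = FALSE)) / (geno$n - 1)
    B <- fit$beta[r, draws, drop = FALSE]
    colSums(B * (Sg %*% B)) / fit$var_g[draws]
  }, numeric(length(draws))))
  expect_lt(median(abs(share_sum - 1)), 0.05)
})

test_that("region capping subsamples reproducibly", {
  regions <- list(big = 1:300, small = 1:10)
  set.seed(5); capped1 <- region_cap_subsample(regions, cap = 250)
  set.seed(5); capped2 <- region_cap_subsample(regions, cap = 250)
  expect_equal(length(capped1$big), 250L)
  expect_identical(capped1$small, 1:10)
  expect_identical(capped1, capped2)
  expect_true(all(capped1$big %in% regions$big))
})

test_that("precision-recall matches a confusion-matrix enumeration", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 15))
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.2, runif(15, 0, 0.5))
  pr <- precision_recall(scores, truth, cuts = c(0.5, 0.05))
  # brute force at cut 0.5
  sel <- scores >= 0.5
  expect_equal(pr$precision[1], sum(sel & truth) / sum(sel))
  expect_equal(pr$recall[1], sum(sel & truth) / 5)
  # perfect scores
  prp <- precision_recall(c(rep(1, 4), rep(0, 6)),
                          c(rep(TRUE, 4), rep(FALSE, 6)), cuts = 0.5)
  expect_equal(prp$precision, 1)
  expect_equal(prp$recall, 1)
  # all-zero scores: recall 0 at any positive cut
  expect_equal(precision_recall(rep(0, 10), truth = rep(c(TRUE, FALSE), 5),
                                cuts = 0.5)$recall, 0)
})

test_that("FDR-vs-PIP follows the printed definitions", {
  pipv <- c(0.95, 0.9, 0.6, 0.3, 0.1, 0.05)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  out <- fdr_vs_pip(pipv, truth, grid = c(0, 0.5, 0.92, 0.99))
  expect_equal(out$fdr[1], 3 / 6)          # everything selected
  expect_equal(out$fdr[2], 1 / 3)
  expect_equal(out$fdr[3], 0)
  expect_true(is.na(out$fdr[4]))           # above the maximum PIP
})

test_that("Harrell's C matches enumeration and the survival package", {
  # perfectly concordant, uncensored
  expect_equal(harrell_c(c(10, 20, 30), c(1, 2, 3), c(1, 1, 1)), 1)
  # random predictor on exchangeable data is ~ 1/2
  set.seed(83)
  expect_lt(abs(harrell_c(rnorm(600), rexp(600), rep(1, 600)) - 0.5), 0.05)
  # hand-enumerated 5-individual set with one censored observation
  tm <- c(2, 4, 5, 7, 9); dd <- c(1, 1, 0, 1, 1); pr <- c(1, 3, 2, 5, 4)
  # usable pairs: i with d=1 and t_i < t_j
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:5) {
    if (dd[i] == 1 && tm[i] < tm[j]) {
      den <- den + 1
      num <- num + (pr[i] < pr[j]) + 0.5 * (pr[i] == pr[j])
    }
  }
  expect_equal(harrell_c(pr, tm, dd), num / den)
  # cross-check against survival::concordance on censored data
  set.seed(84)
  n <- 150
  lp <- rnorm(n)
  y <- rweibull(n, 2, exp(lp / 2))
  d <- rbinom(n, 1, 0.7)
  ours <- harrell_c(lp, y, d)
  ref <- survival::concordance(survival::Surv(y, d) ~ lp)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(harrell_c(1, 5, 0), "usable")
})

test_that("martingale residuals match Nelson-Aalen hand computation", {
  # single individual with an event: Lambda(t) = 1 -> residual 0
  expect_equal(martingale_residuals(5, 1), 0)
  # all censored: residuals are -Lambda0(t) <= 0, here 0 (no events)
  expect_true(all(martingale_residuals(c(2, 3), c(0, 0)) == 0))
  # three distinct event times, no covariates: Lambda0 = 1/3, 1/3+1/2, ...
  r <- martingale_residuals(c(1, 2, 3), c(1, 1, 1))
  expect_equal(r, c(1 - 1 / 3, 1 - (1 / 3 + 1 / 2), 1 - (1 / 3 + 1 / 2 + 1)),
               tolerance = 1e-12)
  # censored individuals get -Lambda0(t)
  r2 <- martingale_residuals(c(1, 2, 3), c(1, 0, 1))
  expect_equal(r2[2], -1 / 3, tolerance = 1e-12)
  # with covariates: agree with survival's martingale residuals (Breslow)
  set.seed(85)
  n <- 120
  z <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- rweibull(n, 2, exp(0.3 * z[, 1]))
  d <- rbinom(n, 1, 0.8)
  ours <- martingale_residuals(y, d, z)
  cox <- survival::coxph(survival::Surv(y, d) ~ z, ties = "breslow")
  ref <- residuals(cox, type = "martingale")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
  # residuals sum to ~0 when events are modelled
  expect_lt(abs(sum(ours)), 1e-6)
})

test_that("genomic prediction is linear in the effect draws", {
  fit <- fit_small$fit
  geno <- fit_small$sim$genotypes
  G <- predict(fit, geno, posterior = TRUE)
  expect_equal(rowMeans(G), predict(fit, geno), tolerance = 1e-12)
  # predictor of the posterior-mean effects equals mean of predictions
  expect_equal(as.vector(geno_std(geno) %*% rowMeans(fit$beta)),
               predict(fit, geno), tolerance = 1e-10)
  # zero effects predict exactly zero
  fit0 <- fit; fit0$beta <- fit$beta * 0
  expect_true(all(predict(fit0, geno) == 0))
  # single-draw chain: predictor equals that draw's X beta
  fit1 <- fit; fit1$beta <- fit$beta[, 7, drop = FALSE]
  expect_equal(predict(fit1, geno),
               as.vector(geno_std(geno) %*% fit$beta[, 7]), tolerance = 1e-12)
  # marker mismatch is an informative error
  g2 <- fit_small$sim$genotypes; g2$ids[1] <- "absent"
  expect_error(predict(fit, g2), "lack trained markers")
})

test_that("posterior predictive intervals nest with the level", {
  fit <- fit_small$fit
  geno <- fit_small$sim$genotypes
  set.seed(86)
  iv50 <- predict(fit, geno, type = "interval", level = 0.5)
  set.seed(86)
  iv95 <- predict(fit, geno, type = "interval", level = 0.95)
  expect_true(all(iv95$lwr <= iv50$lwr + 1e-9))
  expect_true(all(iv95$upr >= iv50$upr - 1e-9))
  expect_true(all(iv95$lwr > 0))
})

test_that("prediction beats marginal per-marker estimates on held-out data", {
  set.seed(87)
  sim <- fit_small$sim
  fit <- fit_small$fit
  new <- simulate_genotypes(400, 120)
  new$ids <- sim$genotypes$ids
  g_true <- as.vector(geno_std(new) %*% sim$truth$beta)
  pred <- predict(fit, new)
  # marginal (single-marker OLS on martingale-like log residuals) oracle
  Xs <- geno_std(sim$genotypes)
  yc <- scale(sim$data$log_time)
  bmarg <- as.vector(crossprod(Xs, yc) / (sim$data$n - 1))
  pmarg <- as.vector(geno_std(new) %*% bmarg)
  expect_gt(cor(pred, g_true), cor(pmarg, g_true))
  expect_gt(cor(pred, g_true), 0.5)
})
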
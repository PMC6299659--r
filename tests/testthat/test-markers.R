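sim_regression <- function(n = 200, p = 100, n_causal = 10, h2 = 0.5,
                           seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(sprintf("i%03d", 1:n), sprintf("M%03d", 1:p)))
  b <- c(rnorm(n_causal, 0, 1), rep(0, p - n_causal))
  g <- drop((X - 1) %*% b)
  e <- rnorm(n, 0, sd(g) * sqrt((1 - h2) / h2))
  y <- g + e
  y <- (y - mean(y)) / sd(y)
  names(y) <- rownames(X)
  list(y = y, geno = genotype_matrix(X), b = b, g = g)
}

test_that("mcmc settings enforce chain bookkeeping", {
  s <- mcmc_settings(preset = "paper")
  expect_equal(s$n_kept, 100)
  s2 <- mcmc_settings(preset = "desk")
  expect_equal(s2$n_kept, 1000)
  expect_warning(mcmc_settings(n_iter = 500, burn_in = 400, thin = 10),
                 ">= 50")
  expect_error(mcmc_settings(n_iter = 100, burn_in = 200), "burn_in")
})

test_that("BRR with degenerate priors matches the closed-form ridge", {
  d <- sim_regression(seed = 3)
  s2m <- 0.02; s2e <- 0.5
  pr <- prior_spec(df_a = 1e8, S_m = s2m * 1e8, df_e = 1e8, S_e = s2e * 1e8)
  eff <- fit_brr(d$y, d$geno, prior = pr,
                 mcmc = mcmc_settings(seed = 12), store_effects = TRUE)
  Xc <- d$geno$dosage - 1
  ridge <- drop(solve(crossprod(Xc) + diag(s2e / s2m, ncol(Xc)),
                      crossprod(Xc, d$y - mean(d$y))))
  expect_gt(cor(eff$effects, ridge), 0.99)
  # Monte Carlo error is a small fraction of each effect's posterior sd
  post_sd <- apply(eff$samples, 2, sd)
  expect_gt(mean(abs(eff$effects - ridge) < 0.5 * pmax(post_sd, 1e-4)), 0.95)
  expect_lt(max(abs(eff$effects - ridge)), 0.05)
})

test_that("zero signal shrinks every effect to zero", {
  set.seed(4)
  d <- sim_regression(seed = 4)
  y0 <- setNames(rep(0, length(d$y)), names(d$y))
  y0 <- y0 + rnorm(length(y0), 0, 1e-8)  # avoid a degenerate variance
  eff <- fit_brr(y0, d$geno, mcmc = mcmc_settings(seed = 5))
  expect_lt(max(abs(eff$effects)), 1e-4)
})

test_that("BLASSO at enormous fixed lambda shrinks everything", {
  d <- sim_regression(seed = 6)
  pr <- prior_spec(lambda_shape = 1e9, lambda_rate = 1e9 / 1e6)
  eff <- fit_blasso(d$y, d$geno, prior = pr, mcmc = mcmc_settings(seed = 7))
  expect_lt(max(abs(eff$effects)), 1e-2)
})

test_that("BLASSO separates planted sparse effects from null markers", {
  d <- sim_regression(n = 400, p = 600, n_causal = 5, h2 = 0.5, seed = 8)
  eff <- fit_blasso(d$y, d$geno, mcmc = mcmc_settings(seed = 9))
  causal <- abs(eff$effects[1:5])
  null <- abs(eff$effects[-(1:5)])
  expect_gt(median(causal), 5 * median(null))
})

test_that("BRR recovers dense signal and agrees with BLASSO GEBVs", {
  d <- sim_regression(n = 400, p = 300, n_causal = 300, h2 = 0.5, seed = 10)
  brr <- fit_brr(d$y, d$geno, mcmc = mcmc_settings(seed = 11))
  bl <- fit_blasso(d$y, d$geno, mcmc = mcmc_settings(seed = 12))
  expect_gt(cor(brr$effects, d$b), 0.4)
  g1 <- gebv_from_effects(brr, d$geno)
  g2 <- gebv_from_effects(bl, d$geno)
  expect_gt(cor(g1, g2), 0.95)
})

test_that("samplers are reproducible from (seed, settings)", {
  d <- sim_regression(seed = 13)
  a <- fit_brr(d$y, d$geno, mcmc = mcmc_settings(seed = 99))
  b <- fit_brr(d$y, d$geno, mcmc = mcmc_settings(seed = 99))
  expect_identical(a$effects, b$effects)
  expect_identical(a$sigma2_e_chain, b$sigma2_e_chain)
})

test_that("gaussian kernel evaluates exactly on toy genotypes", {
  dos <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(2, 1, 2))
  colnames(dos) <- c("m1", "m2", "m3")
  g <- genotype_matrix(dos)
  K <- gaussian_kernel(g, h = 0.25, scale_distance = FALSE)
  expect_equal(K["a", "b"], 1)            # identical rows
  expect_equal(K["a", "c"], exp(-0.25 * 4))  # one locus, dosage gap 2
  expect_equal(diag(K), c(a = 1, b = 1, c = 1))
  Kh <- gaussian_kernel(g, h = 1e-9, scale_distance = FALSE)
  expect_gt(min(Kh), 0.999999)
  expect_error(gaussian_kernel(g, h = -1), "positive")
})

test_that("RKHS prediction flows through kernel rows", {
  # identity kernel: unphenotyped individuals have no information
  n <- 60
  K <- diag(n)
  dimnames(K) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
  set.seed(14)
  y <- setNames(rnorm(40), sprintf("i%02d", 1:40))
  fit <- fit_rkhs(y, K, mcmc = mcmc_settings(seed = 15))
  expect_lt(max(abs(fit$gvalues[41:60])), 1e-8)

  # duplicated phenotyped individuals get near-equal genetic values
  d <- sim_regression(n = 120, p = 200, n_causal = 200, h2 = 0.6, seed = 16)
  dos <- rbind(d$geno$dosage, dup = d$geno$dosage[1, ])
  rownames(dos)[121] <- "dup"
  g2 <- genotype_matrix(dos)
  K2 <- gaussian_kernel(g2)
  y2 <- c(d$y, dup = unname(d$y[1]))
  fit2 <- fit_rkhs(y2, K2, mcmc = mcmc_settings(seed = 17))
  tol <- 3 * max(fit2$gvalues_sd) / sqrt(fit2$n_kept) + 1e-6
  expect_lt(abs(fit2$gvalues["dup"] - fit2$gvalues[1]), max(tol, 0.02))

  # kernel regression tracks kinship BLUP on polygenic data
  K3 <- gaussian_kernel(d$geno, h = 0.1)
  fit3 <- fit_rkhs(d$y, K3, mcmc = mcmc_settings(seed = 18))
  kb <- kinship_blup(d$y, g_matrix(d$geno))
  expect_gt(cor(fit3$gvalues[names(kb$gebv)], kb$gebv), 0.9)
})

test_that("GEBV assembly is exact linear algebra", {
  d <- sim_regression(seed = 19)
  eff <- fit_brr(d$y, d$geno, mcmc = mcmc_settings(seed = 20))
  # all-zero effects give all-zero GEBVs
  eff0 <- eff
  eff0$effects[] <- 0
  expect_true(all(gebv_from_effects(eff0, d$geno) == 0))
  # single unit effect reproduces the -1/0/1 coding
  eff1 <- eff
  eff1$effects[] <- 0
  eff1$effects[1] <- 1
  expect_equal(unname(gebv_from_effects(eff1, d$geno)),
               unname(d$geno$dosage[, 1] - 1))
  # marker-wise accumulation equals the matrix product path
  manual <- rowSums(sapply(seq_along(eff$effects), function(j) {
    (d$geno$dosage[, j] - 1) * eff$effects[j]
  }))
  expect_lt(max(abs(manual - gebv_from_effects(eff, d$geno))), 1e-12)
  # marker mismatch is fatal with a set-difference report
  gshort <- genotype_matrix(d$geno$dosage[, 1:50])
  expect_error(gebv_from_effects(eff, gshort), "marker mismatch")
})

test_that("Geweke diagnostics are calibrated and catch drift", {
  set.seed(21)
  z <- replicate(300, {
    convergence_check(rnorm(500))$z
  })
  expect_gt(mean(abs(z) < 3), 0.97)
  drift <- cumsum(rep(0.05, 500)) + rnorm(500)
  d <- convergence_check(drift)
  expect_true(d$flagged)
  cst <- convergence_check(rep(1, 200))
  expect_true(cst$degenerate)
  # plots land in the requested directory
  dir <- withr::local_tempdir()
  convergence_check(cbind(a = rnorm(100), b = rnorm(100)), plot_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("trace_a.png",
                                               "trace_b.png")))))
})
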
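# Direct GLS/BLUP oracle: beta from generalized least squares on
# V = Z K Z' s2a + I s2e, BLUPs u = s2a K Z' V^-1 (y - X beta).
gls_blup_oracle <- function(X, Z, y, K, s2a, s2e) {
  V <- Z %*% K %*% t(Z) * s2a + diag(s2e, length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * K %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), u = drop(u))
}

random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1)
  q <- sample(4:8, 1)
  p <- sample(1:2, 1)
  X <- if (p == 2) cbind(1, rnorm(n)) else matrix(1, n, 1)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), sample(seq_len(q), n, TRUE))] <- 1
  B <- matrix(rnorm(q * q), q)
  K <- crossprod(B) / q + diag(0.5, q)
  dimnames(K) <- list(sprintf("i%02d", 1:q), sprintf("i%02d", 1:q))
  y <- rnorm(n)
  list(X = X, Z = Z, y = y, K = K)
}

test_that("MME solutions equal the GLS/BLUP oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    s2a <- runif(1, 0.5, 2); s2e <- runif(1, 0.5, 2)
    mme <- solve_mme(inst$X, inst$Z, inst$y, solve(inst$K), s2e / s2a)
    orc <- gls_blup_oracle(inst$X, inst$Z, inst$y, inst$K, s2a, s2e)
    expect_lt(max(abs(mme$beta - orc$beta)), 1e-8)
    expect_lt(max(abs(mme$u - orc$u)), 1e-8)
  }
})

test_that("infinite shrinkage drives BLUPs to zero", {
  inst <- random_instance(100)
  mme <- solve_mme(inst$X, inst$Z, inst$y, diag(ncol(inst$Z)), 1e8)
  expect_lt(max(abs(mme$u)), 1e-5)
})

test_that("duplicating an observation equals doubling its weight", {
  inst <- random_instance(200)
  X <- inst$X; Z <- inst$Z; y <- inst$y; Ki <- solve(inst$K)
  a <- 1.3
  dup <- solve_mme(rbind(X, X[1, ]), rbind(Z, Z[1, ]), c(y, y[1]), Ki, a)
  # weighted normal equations with weight 2 on row 1
  w <- c(2, rep(1, length(y) - 1))
  C <- rbind(cbind(t(X * w) %*% X, t(X * w) %*% Z),
             cbind(t(Z * w) %*% X, t(Z * w) %*% Z + Ki * a))
  rhs <- c(t(X * w) %*% y, t(Z * w) %*% y)
  sol <- solve(C, rhs)
  expect_lt(max(abs(c(dup$beta, dup$u) - sol)), 1e-8)
})

test_that("structured and dense REML paths agree, including EBVs", {
  sim <- small_sim()
  A_dense <- sim$A
  attr(A_dense, "lowrank") <- NULL
  spec <- model_spec("pilodyn", "A", "joint", "unstructured")
  f1 <- fit_reml(sim$pheno, sim$A, spec, se = FALSE)
  f2 <- fit_reml(sim$pheno, A_dense, spec, se = FALSE)
  expect_equal(f1$vc$loglik, f2$vc$loglik, tolerance = 1e-6)
  expect_equal(f1$vc$sigma2_a1, f2$vc$sigma2_a1, tolerance = 1e-4)
  expect_gt(cor(f1$ebv_joint, f2$ebv_joint), 0.999999)
  expect_equal(f1$block_blup, f2$block_blup, tolerance = 1e-6)
})

test_that("null additive variance is estimated at the boundary", {
  sim <- small_sim()
  ids <- sim$pheno$tree[sim$pheno$site == "S1"]
  ph <- null_pheno(ids, seed = 42)
  fit <- fit_reml(ph, sim$A, model_spec("y", "A", "site1"), se = FALSE)
  expect_lte(as.numeric(heritability(fit)), 0.02)
})

test_that("kinship_blup matches solve_mme at the same variance ratio", {
  sim <- small_sim()
  ph <- sim$pheno[sim$pheno$site == "S1", ]
  fitj <- fit_reml(sim$pheno, sim$A,
                   model_spec("pilodyn", "A", "joint", "unstructured"),
                   se = FALSE)
  yp <- adjust_phenotypes(sim$pheno, fitj)
  tr <- sim$pheno$tree[1:200]
  vs <- sim$pheno$tree[201:260]
  allv <- c(tr, vs)
  kb <- kinship_blup(yp[tr], sim$A[allv, allv])
  Z <- matrix(0, length(tr), length(allv),
              dimnames = list(NULL, allv))
  Z[cbind(seq_along(tr), match(tr, allv))] <- 1
  mme <- solve_mme(matrix(1, length(tr), 1), Z, yp[tr],
                   invert_relmatrix(sim$A[allv, allv]), kb$alpha)
  expect_lt(max(abs(kb$gebv[allv] - mme$u[allv])), 1e-6)
})

test_that("heritability arithmetic matches variance-component tables", {
  expect_equal(round(as.numeric(
    heritability(list(sigma2_a = 690.8, sigma2_e = 5260.5))), 2), 0.12)
  expect_equal(round(as.numeric(
    heritability(list(sigma2_a = 2.3, sigma2_e = 3.2))), 2), 0.42)
  expect_equal(as.numeric(heritability(list(sigma2_a = 1, sigma2_e = 1))), 0.5)
  expect_error(heritability(list(sigma2_a = 0, sigma2_e = 0)), "undefined")
})

test_that("type-B correlation endpoints and undefined cases", {
  expect_equal(type_b_correlation(list(sigma2_a1 = 2, sigma2_a2 = 8,
                                       sigma_a12 = 4)), 1.0)
  expect_equal(type_b_correlation(list(sigma2_a1 = 2, sigma2_a2 = 8,
                                       sigma_a12 = 0)), 0.0)
  tb <- type_b_correlation(list(sigma2_a1 = 0, sigma2_a2 = 1, sigma_a12 = 0))
  expect_true(is.na(tb) && isTRUE(attr(tb, "undefined")))
})

test_that("boundary LRT of type-B against 1 behaves at both extremes", {
  cfg <- sim_config(n_parents = 30, n_families = 60, progeny_range = c(6, 8),
                    n_markers = 600, n_qtl = 400, seed = 515,
                    trait_specs = list(trait_spec("height", 0.40, 0.30,
                                                  700, 77)))
  sim <- simulate_trial(cfg)
  sim$A <- a_matrix(sim$ped)
  # strong G x E trait: correlation-1 null should be rejected
  tb <- type_b_test(sim$pheno, sim$A, "height", se = FALSE)
  expect_gte(tb$statistic, 0)
  expect_lt(tb$p_value, 0.05)
  expect_lt(tb$type_b, 0.8)
  # identical likelihoods give statistic 0 and p = 0.5
  fake <- tb$full
  lrt0 <- lrt_type_b_vs_one(
    structure(list(model = "joint_us",
                   vc = list(loglik = fake$vc$loglik)), class = "gs_fit"),
    structure(list(model = "joint_us_r1",
                   vc = list(loglik = fake$vc$loglik)), class = "gs_fit"))
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 0.5)
})

test_that("phenotype adjustment removes blocks and standardizes per site", {
  sim <- small_sim()
  fit <- fit_reml(sim$pheno, sim$A,
                  model_spec("height", "A", "joint", "unstructured"),
                  se = FALSE)
  yp <- adjust_phenotypes(sim$pheno, fit)
  for (s in unique(sim$pheno$site)) {
    expect_lt(abs(mean(yp[sim$pheno$site == s])), 1e-10)
    expect_equal(var(yp[sim$pheno$site == s]), 1, tolerance = 1e-10)
  }

  # an injected +10 sd offset on one well-filled block (~30 trees) is
  # removed to within shrinkage tolerance
  cfg <- sim_config(n_parents = 15, n_families = 25, progeny_range = c(5, 7),
                    n_markers = 300, n_qtl = 150, seed = 616,
                    n_blocks_per_site = 5,
                    trait_specs = list(trait_spec("height", 0.3, 0.5,
                                                  700, 77)))
  sim2 <- simulate_trial(cfg)
  A2 <- a_matrix(sim2$ped)
  ph <- sim2$pheno
  target_blk <- ph$block[1]
  sd1 <- sd(ph$height[ph$site == "S1"])
  ph$height[ph$block == target_blk] <-
    ph$height[ph$block == target_blk] + 10 * sd1
  fit2 <- fit_reml(ph, A2,
                   model_spec("height", "A", "joint", "unstructured"),
                   se = FALSE)
  yp2 <- adjust_phenotypes(ph, fit2)
  resid_blk <- mean(yp2[ph$block == target_blk])
  expect_lt(abs(resid_blk), 0.5)
})
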
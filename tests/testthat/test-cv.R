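test_that("k-fold splits partition the ids with balanced folds", {
  ids <- sprintf("t%03d", 1:100)
  folds <- make_kfold(ids, k = 10, seed = 1)
  expect_true(all(lengths(lapply(folds, `[[`, "validate")) == 10))
  vals <- unlist(lapply(folds, `[[`, "validate"))
  expect_setequal(vals, ids)
  expect_equal(anyDuplicated(vals), 0)

  ids3 <- sprintf("t%03d", 1:103)
  folds3 <- make_kfold(ids3, k = 10, seed = 2)
  sizes <- lengths(lapply(folds3, `[[`, "validate"))
  expect_true(all(sizes %in% c(10, 11)))
  expect_equal(sum(sizes), 103)
  for (f in folds3) {
    expect_length(intersect(f$train, f$validate), 0)
  }
})

test_that("ratio splits round the training size half up", {
  ids <- sprintf("t%04d", 1:1000)
  s9 <- make_ratio_split(ids, 9, seed = 3)
  expect_length(s9$train, 900)
  expect_length(s9$validate, 100)
  s1 <- make_ratio_split(ids, 1, seed = 4)
  expect_length(s1$train, 500)
  ids1370 <- sprintf("t%04d", 1:1370)
  s3 <- make_ratio_split(ids1370, 3, seed = 5)
  expect_length(s3$train, 1028)
  expect_length(s3$validate, 342)
})

test_that("relatedness splits respect their family-structure contracts", {
  sim <- small_sim()
  ids <- sim$pheno$tree
  fam_of <- setNames(sim$pheno$family, sim$pheno$tree)

  for (r in 1:5) {
    fs <- make_relatedness_split(sim$ped, ids, "full_sib", seed = r)
    tf <- unique(fam_of[fs$train]); vf <- unique(fam_of[fs$validate])
    big <- names(which(table(fam_of) >= 2))
    expect_true(all(big %in% tf) && all(big %in% vf))
  }

  fams <- attr(sim$ped, "families")
  hs <- make_relatedness_split(sim$ped, ids, "half_sib", seed = 6)
  tf <- unique(fam_of[hs$train]); vf <- unique(fam_of[hs$validate])
  expect_length(intersect(tf, vf), 0)   # no family split across sets
  dam_of <- setNames(fams$parent1, fams$family)
  expect_true(all(dam_of[vf] %in% dam_of[tf]))  # shared dam with training

  un <- make_relatedness_split(sim$ped, ids, "unrelated", seed = 7)
  tp <- attr(un, "train_parents"); vp <- attr(un, "validate_parents")
  expect_length(intersect(tp, vp), 0)
  par_tr <- unique(c(fams$parent1[fams$family %in% unique(fam_of[un$train])],
                     fams$parent2[fams$family %in% unique(fam_of[un$train])]))
  par_vs <- unique(c(fams$parent1[fams$family %in% unique(fam_of[un$validate])],
                     fams$parent2[fams$family %in% unique(fam_of[un$validate])]))
  expect_length(intersect(par_tr, par_vs), 0)
})

test_that("family and within-family subsampling honour their sizes", {
  sim <- small_sim()
  ids <- sim$pheno$tree
  fam_of <- setNames(sim$pheno$family, sim$pheno$tree)
  n_fam <- length(unique(fam_of))

  all_f <- subsample_families(ids, sim$ped, n_families = n_fam, seed = 1)
  expect_setequal(unique(fam_of[c(all_f$train, all_f$validate)]),
                  unique(fam_of))
  expect_error(subsample_families(ids, sim$ped, n_families = n_fam + 1),
               "available")

  sub <- subsample_families(ids, sim$ped, n_families = 10, seed = 2)
  expect_length(unique(fam_of[sub$train]), 10)

  # trees-per-family: training size equals the direct enumeration
  for (npf in c(3, 5, 20)) {
    st <- subsample_trees(ids, sim$ped, n_per_family = npf, seed = 3)
    expected <- sum(pmin(table(fam_of), npf))
    expect_length(st$train, expected)
    expect_length(st$validate, length(ids) - expected)
  }
})

test_that("single-marker selection finds planted effects and uses TS only", {
  # unstructured population so marker correlations cannot mask the signal
  set.seed(30)
  n <- 250; p <- 400
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(sprintf("u%03d", 1:n), sprintf("M%05d", 1:p)))
  geno <- genotype_matrix(X)
  big <- "M00010"
  hits <- replicate(20, {
    y <- setNames(5 * scale(X[, big])[, 1] + rnorm(n), rownames(X))
    sel <- select_markers(y, geno, "largest_positive", m = 5,
                          seed = sample.int(1e6, 1))
    sel[1] == big
  })
  expect_gt(mean(hits), 0.99)

  # negating the marker coding flips the estimate's sign and eligibility
  y <- setNames(5 * scale(X[, big])[, 1] + rnorm(n), rownames(X))
  g2 <- geno
  g2$dosage[, big] <- 2 - g2$dosage[, big]
  sel_flip <- select_markers(y, g2, "largest_positive", m = 5)
  expect_false(big %in% sel_flip)

  # random mode with m = all markers returns the identity set
  usable <- names(which(apply(X, 2, var) > 0))
  sel_all <- select_markers(y, geno, "random", m = length(usable))
  expect_setequal(sel_all, usable)
})

test_that("scenario runs are deterministic and leak-free", {
  sim <- small_sim()
  geno <- impute_missing(sim$geno)
  data <- cached("gs_data_small",
                 gs_data(sim$ped, geno, sim$pheno, traits = "pilodyn",
                         K_A = sim$A))
  scn <- cv_scenario("gblup", "pilodyn", scope = "joint",
                     split = list(type = "kfold", k = 3),
                     n_replicates = 2, seed = 11)
  r1 <- run_scenario(scn, data)
  r2 <- run_scenario(scn, data)
  expect_identical(r1, r2)
  expect_true(all(!r1$failed))
  expect_true(all(r1$accuracy > 0.3))  # kinship prediction carries signal

  # no leakage: permuting validation phenotypes leaves the training-side
  # adjustment, and hence the selected marker set, unchanged
  tr <- data$pheno$tree[1:200]
  vs <- setdiff(data$pheno$tree, tr)
  data2 <- data
  perm <- data2$pheno$tree %in% vs
  set.seed(99)
  data2$pheno$pilodyn[perm] <- sample(data2$pheno$pilodyn[perm])
  y1 <- diallelGS:::adjust_on_train(data, "pilodyn", tr)
  y2 <- diallelGS:::adjust_on_train(data2, "pilodyn", tr)
  expect_equal(y1, y2)
  s1 <- select_markers(y1, geno, "largest_positive", m = 20)
  s2 <- select_markers(y2, geno, "largest_positive", m = 20)
  expect_identical(s1, s2)
})

test_that("within-site and cross-site scopes run with site-local adjustment", {
  sim <- small_sim()
  geno <- impute_missing(sim$geno)
  data <- cached("gs_data_small",
                 gs_data(sim$ped, geno, sim$pheno, traits = "pilodyn",
                         K_A = sim$A))
  for (scope in c("within_site1", "cross_2to1")) {
    r <- run_scenario(cv_scenario("gblup", "pilodyn", scope = scope,
                                  split = list(type = "ratio", ratio = 9),
                                  n_replicates = 1, seed = 3), data)
    expect_false(r$failed)
    expect_gt(r$accuracy, 0.2)
  }
})

test_that("accuracy under a random-phenotype null is centred at zero", {
  sim <- small_sim()
  ids <- sim$pheno$tree[sim$pheno$site == "S1"]
  A <- sim$A
  set.seed(77)
  accs <- replicate(40, {
    y <- setNames(rnorm(150), sample(ids, 150))
    tr <- names(y)[1:110]; vs <- names(y)[111:150]
    kb <- kinship_blup(y[tr], A[c(tr, vs), c(tr, vs)])
    suppressWarnings(cor(kb$gebv[vs], y[vs]))
  })
  expect_lt(abs(mean(accs)), 2 * sd(accs) / sqrt(length(accs)) + 0.05)
})
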
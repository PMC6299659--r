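test_that("diallel pedigree respects the mating design", {
  cfg3 <- sim_config(n_parents = 3, n_families = 3, progeny_range = c(2, 3),
                     n_markers = 10, n_qtl = 2, seed = 1)
  ped <- make_diallel_pedigree(cfg3)
  fam <- attr(ped, "families")
  pairs <- apply(fam[, c("parent1", "parent2")], 1,
                 function(x) paste(sort(x), collapse = "-"))
  expect_setequal(pairs, c("P001-P002", "P001-P003", "P002-P003"))

  cfg <- sim_config(n_parents = 15, n_families = 20, progeny_range = c(5, 20),
                    n_markers = 10, n_qtl = 2, n_sites = 2, seed = 5)
  ped <- make_diallel_pedigree(cfg)
  n_prog <- sum(ped$generation == 1)
  expect_gte(n_prog, 20 * 5 * 2)
  expect_lte(n_prog, 20 * 20 * 2)
  expect_true(all(!is.na(ped$sire[ped$generation == 1])))

  ped2 <- make_diallel_pedigree(cfg)
  expect_identical(ped, ped2)

  expect_error(sim_config(n_parents = 4, n_families = 10, n_markers = 10,
                          n_qtl = 2),
               "distinct parent pairs")
})

test_that("gene dropping transmits Mendelian dosages", {
  sim <- small_sim()
  ped <- sim$ped
  dos <- sim$geno$dosage
  asg <- attr(ped, "assignment")
  fam <- attr(ped, "families")
  f <- fam[1, ]
  kids <- asg$id[asg$family == f$family]
  both0 <- which(dos[f$parent1, ] == 0 & dos[f$parent2, ] == 0)
  both2 <- which(dos[f$parent1, ] == 2 & dos[f$parent2, ] == 2)
  expect_true(length(both0) > 0 && length(both2) > 0)
  expect_true(all(dos[kids, both0] == 0))
  expect_true(all(dos[kids, both2] == 2))

  bad <- data.frame(id = c("a", "b", "c"), sire = c(NA, NA, "a"),
                    dam = c(NA, NA, NA), generation = c(0, 0, 1))
  expect_error(drop_genotypes(bad, sim$cfg), "exactly one known parent")
})

test_that("realized genomic relationship of full sibs matches the pedigree", {
  cfg <- sim_config(n_parents = 20, n_families = 30, progeny_range = c(6, 6),
                    n_markers = 2500, n_qtl = 10, seed = 99,
                    trait_specs = list(trait_spec("height", 0.3, 0.5)))
  ped <- make_diallel_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  # realized relationship computed against the founder allele frequencies
  # (the generative base population), independent of g_matrix()
  p <- attr(geno, "founder_af")
  Zc <- sweep(geno$dosage, 2, 2 * p)
  Gf <- tcrossprod(Zc) / (2 * sum(p * (1 - p)))
  asg <- attr(ped, "assignment")
  sib_pairs <- do.call(rbind, lapply(split(asg$id, asg$family), function(ids) {
    t(combn(ids, 2))
  }))
  gvals <- Gf[cbind(sib_pairs[, 1], sib_pairs[, 2])]
  expect_lt(abs(mean(gvals) - 0.5), 0.05)

  # founder dosage means match 2p within binomial error
  cfg_f <- sim_config(n_parents = 300, n_families = 2,
                      progeny_range = c(1, 1), n_markers = 800, n_qtl = 10,
                      seed = 17, trait_specs = list(trait_spec("h", 0.3, 0.5)))
  ped_f <- make_diallel_pedigree(cfg_f)
  geno_f <- drop_genotypes(ped_f, cfg_f)
  fnd <- ped_f$id[ped_f$generation == 0]
  pf <- attr(geno_f, "founder_af")
  dev <- abs(colMeans(geno_f$dosage[fnd, ]) - 2 * pf)
  bound <- 4 * sqrt(2 * pf * (1 - pf) / length(fnd)) + 0.02
  expect_gt(mean(dev < bound), 0.95)
})

test_that("phenotype simulation hits its generative targets", {
  sim <- small_sim()
  truth <- sim$truth
  # type-B target 1 gives identical per-site effect vectors
  cfg1 <- sim_config(n_parents = 10, n_families = 12, progeny_range = c(4, 5),
                     n_markers = 200, n_qtl = 100, seed = 3,
                     trait_specs = list(trait_spec("w", 0.4, 1.0)))
  s1 <- simulate_trial(cfg1)
  eff <- s1$truth$traits$w$effects
  expect_equal(cor(eff[eff[, 1] != 0, 1], eff[eff[, 1] != 0, 2]), 1)

  # near-zero residual: block-adjusted phenotype is essentially TBV
  cfg2 <- sim_config(n_parents = 10, n_families = 12, progeny_range = c(4, 5),
                     n_markers = 200, n_qtl = 100, seed = 4,
                     block_var_frac = 0.1,
                     trait_specs = list(trait_spec("w", 0.999, 0.9)))
  s2 <- simulate_trial(cfg2)
  tw <- s2$truth$traits$w
  ph <- s2$pheno
  adj <- ph$w - tw$block_effects[ph$block]
  sites <- sort(unique(ph$site))
  for (s in sites) {
    rows <- ph$site == s
    tbv <- tw$tbv[ph$tree[rows], s]
    expect_gt(cor(adj[rows], tbv), 0.995)
  }

  # TBV = centred dosage x effects, and effect correlation near target
  tr <- truth$traits$pilodyn
  Zc <- sweep(sim$geno$dosage, 2, colMeans(sim$geno$dosage))
  expect_equal(unname(tr$tbv[, 1]), unname(drop(Zc %*% tr$effects[, 1])),
               tolerance = 1e-8)
  qtl <- truth$qtl$pilodyn
  expect_lt(abs(cor(tr$effects[qtl, 1], tr$effects[qtl, 2]) - 0.90), 0.06)

  # zero heritability with positive type-B is a configuration error
  expect_error(trait_spec("x", 0, 0.5), "h2")
})

test_that("trial files round-trip through VCF and CSV", {
  sim <- small_sim()
  geno <- sim$geno
  # inject missing genotypes to exercise ./.
  dos <- geno$dosage
  set.seed(8)
  idx <- cbind(sample(nrow(dos), 50, TRUE), sample(ncol(dos), 50, TRUE))
  dos[idx] <- NA
  geno2 <- genotype_matrix(dos)
  dir <- withr::local_tempdir()
  write_trial(geno2, sim$ped, sim$pheno, dir)
  back <- read_trial(dir)
  expect_equal(back$geno$dosage[rownames(dos), colnames(dos)], dos)
  expect_true(anyNA(back$geno$dosage))
  expect_setequal(back$ped$id, sim$ped$id)
  expect_equal(nrow(back$pheno), nrow(sim$pheno))

  # offspring listed before parents is reordered on read
  pd <- read.csv(file.path(dir, "pedigree.csv"), colClasses = "character")
  write.csv(pd[rev(seq_len(nrow(pd))), ], file.path(dir, "pedigree.csv"),
            row.names = FALSE, quote = FALSE)
  back2 <- read_trial(dir)
  par_pos <- match(back2$ped$sire, back2$ped$id)
  own_pos <- seq_len(nrow(back2$ped))
  expect_true(all(par_pos[!is.na(par_pos)] < own_pos[!is.na(back2$ped$sire)]))

  # a pedigree cycle is rejected with a diagnostic
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = c("0", "0"))
  write.csv(cyc, file.path(dir, "pedigree.csv"), row.names = FALSE,
            quote = FALSE)
  expect_error(read_trial(dir), "cycle")
})

test_that("generation is reproducible from config and seed", {
  cfg <- sim_config(n_parents = 8, n_families = 10, progeny_range = c(3, 4),
                    n_markers = 100, n_qtl = 50, seed = 77,
                    trait_specs = list(trait_spec("h", 0.3, 0.5)))
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno, b$pheno)
})
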
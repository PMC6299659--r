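# Independent oracle: pairwise kinship by the classic recursive definition
# (memoised), additive relationship = 2 * kinship. A different algorithmic
# route than the tabular sweep in a_matrix().
kinship_oracle <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  memo <- new.env(parent = emptyenv())
  kin <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(sort(c(i, j)), collapse = "-")
    if (!is.null(memo[[key]])) return(memo[[key]])
    si <- idx[ped$sire[i]]; di <- idx[ped$dam[i]]
    sj <- idx[ped$sire[j]]; dj <- idx[ped$dam[j]]
    si <- ifelse(is.na(si), 0, si); di <- ifelse(is.na(di), 0, di)
    sj <- ifelse(is.na(sj), 0, sj); dj <- ifelse(is.na(dj), 0, dj)
    val <- if (i == j) {
      0.5 * (1 + kin(si, di))
    } else if (max(i, j) == j) {
      0.5 * (kin(i, sj) + kin(i, dj))
    } else {
      0.5 * (kin(j, si) + kin(j, di))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    K[i, j] <- K[j, i] <- kin(i, j)
  }
  2 * K
}

test_that("A matrix reproduces the closed-form coefficients", {
  A <- a_matrix(toy_pedigree())
  expect_equal(A["o1", "o2"], 0.5)   # full sibs
  expect_equal(A["o1", "o1"], 1.0)
  expect_equal(A["o1", "h1"], 0.25)  # half sibs (shared sire f1)
  expect_equal(A["f1", "o1"], 0.5)   # parent-offspring
  # full sibs with related (non-inbred) parents o1, h1:
  # A = 0.5 * (1 + A(o1, h1) / 2) + A(o1, h1) / 2 ... = 0.625
  expect_equal(A["g1", "g2"], 0.625)
  expect_equal(A["g1", "g1"], 1 + 0.5 * A["o1", "h1"])
  expect_equal(A["u1", "o1"], 0)
})

test_that("A matrix matches the recursive-kinship oracle on 3 generations", {
  ped <- toy_pedigree()
  expect_equal(unclass(a_matrix(ped))[ped$id, ped$id],
               kinship_oracle(ped), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("A from generated pedigrees is PSD with exact sib coefficients", {
  sim <- small_sim()
  A <- sim$A
  expect_gte(min(eigen(unclass(A), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  asg <- attr(sim$ped, "assignment")
  fam <- split(asg$id, asg$family)
  sibs <- fam[[1]]
  expect_true(all(A[sibs[1], sibs[-1]] == 0.5))
  # low-rank structure agrees with the dense tabular matrix
  lr <- attr(A, "lowrank")
  expect_false(is.null(lr))
  prog <- rownames(lr$F)
  expect_equal(unclass(A)[prog, prog],
               diag(lr$c, length(prog)) + tcrossprod(lr$F),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("VanRaden G matches the worked example and its conventions", {
  dos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "m1"))
  G <- g_matrix(genotype_matrix(dos))
  expect_equal(unclass(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3),
               ignore_attr = TRUE)

  set.seed(2)
  dos2 <- matrix(rbinom(40 * 60, 2, runif(60, 0.1, 0.5)), 40, 60,
                 byrow = TRUE,
                 dimnames = list(sprintf("s%02d", 1:40), sprintf("m%02d", 1:60)))
  dos2 <- matrix(rbinom(40 * 60, 2, rep(runif(60, 0.1, 0.5), each = 40)),
                 40, 60, dimnames = dimnames(dos2))
  g2 <- genotype_matrix(rbind(dos2, dup = dos2[1, , drop = FALSE]))
  rownames(g2$dosage)[41] <- "dup"
  G2 <- g_matrix(genotype_matrix(g2$dosage))
  expect_equal(G2["s01", "dup"], G2["s01", "s01"])
  # row means ~ 0 when frequencies come from the same samples
  expect_lt(max(abs(rowMeans(G2))), 1e-10)
  # orientation invariance under the vanraden convention
  flip <- g2$dosage
  flip[, 1:10] <- 2 - flip[, 1:10]
  expect_equal(unclass(g_matrix(genotype_matrix(flip))), unclass(G2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # shifted differs unless p = 0.5
  Gl <- g_matrix(genotype_matrix(g2$dosage), convention = "shifted")
  expect_false(isTRUE(all.equal(unclass(Gl), unclass(G2))))
})

test_that("mean G diagonal is near 1 for founders under HWE", {
  cfg <- sim_config(n_parents = 120, n_families = 2, progeny_range = c(1, 1),
                    n_markers = 2000, n_qtl = 10, seed = 31,
                    trait_specs = list(trait_spec("h", 0.3, 0.5)))
  ped <- make_diallel_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  fnd <- ped$id[ped$generation == 0]
  G <- g_matrix(genotype_matrix(geno$dosage[fnd, ]))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("inversion is exact with an automatic ridge fallback", {
  I5 <- diag(5)
  dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_equal(unclass(invert_relmatrix(I5)), I5, ignore_attr = TRUE)

  set.seed(9)
  B <- matrix(rnorm(50 * 50), 50)
  K <- crossprod(B) / 50 + diag(0.1, 50)
  Ki <- invert_relmatrix(K)
  expect_lt(max(abs(K %*% Ki - diag(50))), 1e-8)

  # rank-deficient G (5 markers, 20 samples) forces the fallback
  dos <- matrix(rbinom(20 * 5, 2, 0.4), 20, 5,
                dimnames = list(sprintf("s%02d", 1:20), sprintf("m%d", 1:5)))
  Gd <- g_matrix(genotype_matrix(dos))
  Gi <- invert_relmatrix(Gd)
  expect_equal(attr(Gi, "ridge"), 1e-6)
  expect_error(invert_relmatrix(diag(c(1, 1, -1))), "singular")
})

test_that("G approaches A for full sibs at large marker counts", {
  cfg <- sim_config(n_parents = 20, n_families = 30, progeny_range = c(5, 6),
                    n_markers = 4000, n_qtl = 10, seed = 77,
                    trait_specs = list(trait_spec("h", 0.3, 0.5)))
  ped <- make_diallel_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  A <- a_matrix(ped)
  p <- attr(geno, "founder_af")
  Zc <- sweep(geno$dosage, 2, 2 * p)
  G <- tcrossprod(Zc) / (2 * sum(p * (1 - p)))
  asg <- attr(ped, "assignment")
  sib_pairs <- do.call(rbind, lapply(split(asg$id, asg$family),
                                     function(ids) t(combn(ids, 2))))
  idx <- cbind(sib_pairs[, 1], sib_pairs[, 2])
  expect_lt(mean(abs(G[idx] - A[idx])), 0.1)
})
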
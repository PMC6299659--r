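#' Simulate per-site phenotypes with controllable G x E
#'
#' For each trait, `n_qtl` causal markers are drawn among the genotyped
#' markers and receive per-site additive effects sampled from a bivariate
#' normal whose correlation equals the trait's type-B target; with a type-B
#' target of 1 the two sites' effect vectors are identical. True breeding
#' values (TBV) per site are centred dosages times the per-site effect
#' vector, rescaled so the realised additive variance among each site's
#' trees equals `h2 * sd_p^2`. Phenotypes add a fixed site offset, i.i.d.
#' normal post-block effects (variance `block_var_frac * sd_p^2`) and i.i.d.
#' normal residuals with variance `(1 - h2) * sd_p^2`, so the per-site
#' narrow-sense heritability (additive / (additive + residual)) matches the
#' target in expectation.
#'
#' @param geno [genotype_matrix()] over all pedigree individuals.
#' @param ped pedigree from [make_diallel_pedigree()].
#' @param cfg [sim_config()].
#' @return A list with `pheno` (a `data.frame`: tree, family, dam, sire,
#'   site, block, one column per trait) and `truth` (a `true_values` list
#'   holding per-trait per-site TBVs for every individual, per-marker true
#'   effects per site, block effects and generative variances).
#' @export
simulate_phenotypes <- function(geno, ped, cfg) {
  validate_sim_config(cfg)
  asg <- pedigree_assignment(ped)
  fam <- attr(ped, "families")
  assert_that(all(asg$id %in% geno$ids), "genotypes missing for some trees")
  sites <- sort(unique(asg$site))
  assert_that(length(sites) == cfg$n_sites, "assignment/site mismatch")
  n_tr <- nrow(asg)

  with_seed(stage_seed(cfg$seed, "phenotypes"), {
    # Randomized single-tree plots in post-blocks within site.
    block <- unlist(lapply(sites, function(s) {
      k <- sum(asg$site == s)
      sample(rep_len(seq_len(cfg$n_blocks_per_site), k))
    }))
    asg$block <- paste0(asg$site, "B", sprintf("%02d", block))

    Z <- geno$dosage
    Zc <- sweep(Z, 2, colMeans(Z))
    site_rows <- lapply(sites, function(s) match(asg$id[asg$site == s], geno$ids))

    pheno <- data.frame(tree = asg$id, family = asg$family,
                        dam = fam$parent2[match(asg$family, fam$family)],
                        sire = fam$parent1[match(asg$family, fam$family)],
                        site = asg$site, block = asg$block,
                        stringsAsFactors = FALSE)
    truth <- list(traits = list(), qtl = list(), config = cfg)

    for (ts in cfg$trait_specs) {
      if (ts$h2 <= 0 && ts$type_b > 0) {
        stop("configuration error: zero heritability with positive type-B target",
             call. = FALSE)
      }
      qtl <- sort(sample.int(cfg$n_markers, cfg$n_qtl))
      b1 <- rnorm(cfg$n_qtl)
      b2 <- ts$type_b * b1 +
        if (ts$type_b < 1) sqrt(1 - ts$type_b^2) * rnorm(cfg$n_qtl) else 0
      eff <- matrix(0, cfg$n_markers, cfg$n_sites,
                    dimnames = list(geno$markers, sites))
      tbv <- matrix(0, length(geno$ids), cfg$n_sites,
                    dimnames = list(geno$ids, sites))
      raw <- Zc[, qtl, drop = FALSE] %*% cbind(b1, b2)[, seq_len(cfg$n_sites), drop = FALSE]
      var_a_target <- ts$h2 * ts$sd_p^2
      for (s in seq_along(sites)) {
        v <- var(raw[site_rows[[s]], s])
        k <- sqrt(var_a_target / v)
        tbv[, s] <- raw[, s] * k
        eff[qtl, s] <- (if (s == 1) b1 else b2) * k
      }
      sd_e <- sqrt((1 - ts$h2) * ts$sd_p^2)
      sd_b <- sqrt(cfg$block_var_frac * ts$sd_p^2)
      blk_lev <- sort(unique(asg$block))
      blk_eff <- setNames(rnorm(length(blk_lev), 0, sd_b), blk_lev)
      site_idx <- match(asg$site, sites)
      y <- ts$mean + cfg$site_offset_sd[site_idx] * ts$sd_p +
        tbv[cbind(match(asg$id, geno$ids), site_idx)] +
        blk_eff[asg$block] +
        rnorm(n_tr, 0, sd_e)
      pheno[[ts$name]] <- as.numeric(y)
      truth$traits[[ts$name]] <- list(
        tbv = tbv, effects = eff, block_effects = blk_eff,
        sigma2_a = var_a_target, sigma2_e = sd_e^2, sigma2_b = sd_b^2,
        h2 = ts$h2, type_b = ts$type_b)
      truth$qtl[[ts$name]] <- geno$markers[qtl]
    }
    class(truth) <- "true_values"
    list(pheno = pheno, truth = truth)
  })
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper running [make_diallel_pedigree()],
#' [drop_genotypes()] and [simulate_phenotypes()] under one configuration.
#'
#' @param cfg [sim_config()].
#' @return A list `ped`, `geno`, `pheno`, `truth`.
#' @export
simulate_trial <- function(cfg = sim_config()) {
  ped <- make_diallel_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  sim <- simulate_phenotypes(geno, ped, cfg)
  list(ped = ped, geno = geno, pheno = sim$pheno, truth = sim$truth)
}
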
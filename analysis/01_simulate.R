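#!/usr/bin/env Rscript
# Generate the synthetic two-site partial-diallel progeny trial and write
# it in the standard exchange formats (VCF v4.2 + pedigree/phenotype CSV).
# To mimic a real genotyping run, a small fraction of genotypes is masked
# with low GQ/DP so the QC script has something to do.

source(file.path("analysis", "00_config.R"))

cfg <- trial_config()
sim <- simulate_trial(cfg)
cat(sprintf("simulated %d trees in %d families over %d sites; %d markers\n",
            nrow(sim$pheno), length(unique(sim$pheno$family)),
            length(unique(sim$pheno$site)), cfg$n_markers))

# inject realistic genotype-quality structure: ~3% low-GQ and ~2% low-DP
set.seed(ANALYSIS_SEED + 1)
n <- nrow(sim$geno$dosage); m <- ncol(sim$geno$dosage)
gq <- matrix(99L, n, m)
dp <- matrix(30L, n, m)
low_gq <- sample(length(gq), round(0.03 * length(gq)))
low_dp <- sample(length(dp), round(0.02 * length(dp)))
gq[low_gq] <- sample(0:5, length(low_gq), replace = TRUE)
dp[low_dp] <- sample(0:1, length(low_dp), replace = TRUE)

write_trial(sim$geno, sim$ped, sim$pheno, TRIAL_DIR, gq = gq, dp = dp)
saveRDS(sim$truth, file.path(OUT_ROOT, "true_values.rds"))
cat("trial written to", TRIAL_DIR, "\n")
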
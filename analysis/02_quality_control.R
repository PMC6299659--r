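#!/usr/bin/env Rscript
# Variant and sample QC of the trial VCF: the fixed filter chain (indels,
# biallelic, GQ < 6 and DP < 2 masked, sample call rate < 50%, variant
# call rate < 90%, MAF < 1%), a replicate-discordance check on simulated
# technical re-calls, and mean imputation of the remaining gaps.

source(file.path("analysis", "00_config.R"))

res <- filter_variants(file.path(TRIAL_DIR, "genotypes.vcf"),
                       qc_thresholds())
print(res$report)

# technical replicates: re-call 30 samples with 0.5% genotype error
set.seed(ANALYSIS_SEED + 2)
geno <- res$geno
reps <- sample(geno$ids, 30)
recall <- geno$dosage[reps, , drop = FALSE]
flip <- which(!is.na(recall) & runif(length(recall)) < 0.005)
recall[flip] <- (recall[flip] + sample(1:2, length(flip), TRUE)) %% 3
rownames(recall) <- paste0(reps, "_rep")
both <- genotype_matrix(rbind(geno$dosage, recall))
disc <- replicate_discordance(both, lapply(reps, function(s)
  c(s, paste0(s, "_rep"))))
cat(sprintf("replicate discordance: %.3f%% over %d pairs\n",
            100 * as.numeric(disc), length(reps)))

imputed <- impute_missing(geno, method = "mean")
cat(sprintf("imputed %.2f%% of genotypes (mean imputation)\n",
            100 * mean(is.na(geno$dosage))))
saveRDS(imputed, file.path(OUT_ROOT, "geno_qc.rds"))
jsonlite::write_json(
  c(unclass(res$report)[c("n_variants_in", "n_variants_out",
                          "removed_indel", "removed_multiallelic",
                          "removed_var_callrate", "removed_var_maf",
                          "removed_sample", "masked_gq", "masked_dp")],
    list(discordance = as.numeric(disc))),
  file.path(OUT_ROOT, "qc_summary.json"), auto_unbox = TRUE, pretty = TRUE)
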